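#' Default pipeline configuration
#'
#' Thresholds default to the standard analysis settings: LD partners at
#' r-squared >= 0.5 within 500 kb, gene ROIs of 100 kb upstream / 10 kb
#' downstream, enrichment FDR 5%, 1000 permutation replicates (200 at the
#' network level, where each replicate re-runs the optimizer).
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    levels = c("snp", "ld", "gene", "function", "network"),
    seed = 1,
    out_dir = NULL,
    inputs = list(snp_table = NULL, gene_models = NULL, gene_sets = NULL,
                  network = NULL, ld_table = NULL, subtype = NULL,
                  snp_universe = NULL),
    simulate = NULL,
    ld = list(r2_min = 0.5, max_dist_bp = 500000),
    roi = list(upstream_bp = 100000, downstream_bp = 10000,
               strand_aware = TRUE),
    enrich = list(fdr_max = 0.05, universe = "models"),
    perm = list(n_perm = 1000, n_perm_network = 200),
    subnet = list(restarts = 20, steps = 2000, ld_expand = TRUE))
}

merge_config <- function(base, override) {
  for (name in names(override)) {
    if (is.list(base[[name]]) && is.list(override[[name]]) &&
        !is.null(names(override[[name]]))) {
      base[[name]] <- merge_config(base[[name]], override[[name]])
    } else {
      base[[name]] <- override[[name]]
    }
  }
  base
}

#' Read a YAML run configuration
#' @param path YAML file; keys override [default_config()].
#' @return Merged configuration list.
#' @export
read_run_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}

#' Restrict a study collection to a subset of populations
#' @param collection a [study_collection()].
#' @param codes population codes to keep (at least 2).
#' @return The restricted `study_collection`.
#' @export
subset_populations <- function(collection, codes) {
  missing <- setdiff(codes, population_codes(collection))
  if (length(missing) > 0) {
    stop("unknown population code(s): ", paste(missing, collapse = ", "))
  }
  if (length(codes) < 2) stop("a study collection needs >= 2 populations")
  out <- collection
  out$populations <- collection$populations[sort(codes)]
  out
}

resolve_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    wp <- do.call(world_params,
                  merge_config(list(seed = config$seed),
                               config$simulate$world %||% list()))
    world <- generate_world(wp)
    sp <- do.call(study_params,
                  merge_config(list(seed = config$seed + 1),
                               config$simulate$study %||% list()))
    study <- generate_study(world, sp)
    list(collection = study$collection, models = world$models,
         catalog = world$catalog, network = world$network,
         ld = world$ld, subtype = world$subtypes,
         snp_universe = world$snps, truth = study$truth)
  } else {
    inp <- config$inputs
    if (is.null(inp$snp_table)) stop("config: inputs$snp_table is required")
    models <- if (is.null(inp$gene_models)) NULL else
      load_gene_models(inp$gene_models,
                       upstream_bp = config$roi$upstream_bp,
                       downstream_bp = config$roi$downstream_bp,
                       strand_aware = config$roi$strand_aware)
    list(
      collection = load_study(inp$snp_table),
      models = models,
      catalog = if (is.null(inp$gene_sets)) NULL else
        load_gene_sets(inp$gene_sets),
      network = if (is.null(inp$network)) NULL else load_network(inp$network),
      ld = if (is.null(inp$ld_table)) {
        ld_table(data.frame(snp_a = character(), snp_b = character(),
                            r2 = numeric(), dist_bp = integer()))
      } else {
        load_ld_table(inp$ld_table)
      },
      subtype = if (is.null(inp$subtype)) NULL else
        load_subtype_annotation(inp$subtype),
      snp_universe = if (is.null(inp$snp_universe)) NULL else
        read.delim(inp$snp_universe, stringsAsFactors = FALSE),
      truth = NULL)
  }
}

#' Run the five-level overlap analysis end to end
#'
#' Executes the SNP, LD, gene, function and network levels in order on real
#' or simulated inputs: per level it computes the entity sets, the pairwise
#' overlap matrix, the cumulative overlap function, a level-matched
#' permutation null and z/p significance. Populations whose gene sets are
#' enriched in no term are dropped from the function and network levels
#' (reducing k there). When `out_dir` is set, the clustered heatmaps,
#' overlap-function figures, TSV tables and a JSON manifest are written.
#'
#' @param config configuration list (see [default_config()]) or the path to
#'   a YAML file.
#' @return Object of class `overlap_run`: list with `results` (per level:
#'   `sets`, `matrix`, `cumulative`, `null`, `significance`), `inputs`,
#'   `dropped_populations`, `subtype_counts`, `config` and (if written) the
#'   report `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  config <- merge_config(default_config(), config)
  levels <- match.arg(config$levels,
                      c("snp", "ld", "gene", "function", "network"),
                      several.ok = TRUE)
  inputs <- resolve_inputs(config)
  collection <- inputs$collection
  results <- list()
  dropped <- character(0)

  sets_snp <- snp_sets(collection)
  sizes_snp <- vapply(sets_snp, length, integer(1))
  snp_pool <- build_pool("snp",
                         universe = if (is.null(inputs$snp_universe))
                           unlist(sets_snp, use.names = FALSE) else
                             inputs$snp_universe$snp_id,
                         observed_sets = sets_snp)

  if ("snp" %in% levels) {
    cum <- cumulative_overlap(sets_snp, level = "snp")
    null <- null_distribution("snp", sizes_snp, snp_pool,
                              n_perm = config$perm$n_perm,
                              seed = config$seed + 101)
    results$snp <- list(sets = sets_snp,
                        matrix = jaccard_overlap_matrix(sets_snp, "snp"),
                        cumulative = cum, null = null,
                        significance = significance(cum, null))
  }

  if ("ld" %in% levels) {
    support <- ld_support(collection, inputs$ld,
                          r2_min = config$ld$r2_min,
                          max_dist_bp = config$ld$max_dist_bp)
    cum <- ld_cumulative_overlap(support)
    null <- null_distribution("ld", sizes_snp, snp_pool,
                              n_perm = config$perm$n_perm,
                              seed = config$seed + 102, ld = inputs$ld,
                              r2_min = config$ld$r2_min,
                              max_dist_bp = config$ld$max_dist_bp)
    results$ld <- list(sets = sets_snp, support = support,
                       matrix = ld_overlap_matrix(collection, support),
                       cumulative = cum, null = null,
                       significance = significance(cum, null))
  }

  gene_sets <- NULL
  gene_pool <- NULL
  if (any(c("gene", "function", "network") %in% levels)) {
    if (is.null(inputs$models)) {
      stop("gene/function/network levels need gene models")
    }
    gene_sets <- map_snps_to_genes(collection, inputs$models)
    gene_pool <- build_pool("gene", universe = inputs$models$symbol,
                            observed_sets = gene_sets)
  }

  if ("gene" %in% levels) {
    cum <- cumulative_overlap(gene_sets, level = "gene")
    null <- null_distribution(
      "gene", vapply(gene_sets, length, integer(1)), gene_pool,
      n_perm = config$perm$n_perm, seed = config$seed + 103)
    results$gene <- list(sets = unclass(gene_sets),
                         matrix = jaccard_overlap_matrix(gene_sets, "gene"),
                         cumulative = cum, null = null,
                         significance = significance(cum, null))
  }

  retained <- population_codes(collection)
  if (any(c("function", "network") %in% levels)) {
    if (is.null(inputs$catalog)) {
      stop("function/network levels need a functional catalog")
    }
    enrich_universe <- if (identical(config$enrich$universe, "models"))
      inputs$models$symbol else NULL
    term_sets <- enrich_all(gene_sets, inputs$catalog,
                            universe = enrich_universe,
                            fdr_max = config$enrich$fdr_max)
    kept_sets <- drop_empty_populations(term_sets)
    dropped <- attr(kept_sets, "dropped")
    retained <- setdiff(population_codes(collection), dropped)
    if (length(retained) < 2) {
      warning("fewer than 2 populations with enriched terms; ",
              "function/network levels omitted")
    } else {
      if ("function" %in% levels) {
        f_sets <- term_sets[retained]
        cum <- cumulative_overlap(f_sets, level = "function")
        null <- null_distribution(
          "function",
          vapply(gene_sets[retained], length, integer(1)), gene_pool,
          n_perm = config$perm$n_perm, seed = config$seed + 104,
          catalog = inputs$catalog, enrich_universe = enrich_universe,
          fdr_max = config$enrich$fdr_max)
        results$`function` <- list(
          sets = f_sets,
          matrix = jaccard_overlap_matrix(f_sets, "function"),
          cumulative = cum, null = null,
          significance = significance(cum, null))
      }
      if ("network" %in% levels) {
        if (is.null(inputs$network)) {
          stop("network level needs an interaction network")
        }
        sub_coll <- subset_populations(collection, retained)
        subnets <- population_subnetwork(
          sub_coll, inputs$ld, inputs$models, inputs$network,
          r2_min = config$ld$r2_min, max_dist_bp = config$ld$max_dist_bp,
          ld_expand = config$subnet$ld_expand, seed = config$seed + 105,
          restarts = config$subnet$restarts, steps = config$subnet$steps)
        n_sets <- subnets$sets
        net_coords <- if (!is.null(inputs$snp_universe) &&
                          all(c("chrom", "pos") %in%
                                names(inputs$snp_universe))) {
          inputs$snp_universe
        } else {
          snp_coordinates(collection)
        }
        net_pool <- build_pool("network_snp",
                               universe = net_coords$snp_id,
                               observed_sets = snp_sets(sub_coll))
        class(net_pool) <- "entity_pool"
        cum <- cumulative_overlap(n_sets, level = "network")
        null <- null_distribution(
          "network", vapply(snp_sets(sub_coll), length, integer(1)),
          net_pool, n_perm = config$perm$n_perm_network,
          seed = config$seed + 106, ld = inputs$ld,
          r2_min = config$ld$r2_min, max_dist_bp = config$ld$max_dist_bp,
          snp_coords = net_coords, models = inputs$models,
          network = inputs$network,
          subnet_args = list(restarts = config$subnet$restarts,
                             steps = config$subnet$steps))
        results$network <- list(
          sets = n_sets, subnetworks = subnets,
          matrix = jaccard_overlap_matrix(n_sets, "network"),
          cumulative = cum, null = null,
          significance = significance(cum, null))
      }
    }
  }

  subtype_counts <- NULL
  if (!is.null(inputs$subtype)) {
    subtype_counts <- list()
    if (!is.null(results$gene)) {
      subtype_counts$gene <- stratify_by_subtype(results$gene$sets,
                                                 inputs$subtype, "gene")
    }
    if (!is.null(results$network)) {
      subtype_counts$network <- stratify_by_subtype(results$network$sets,
                                                    inputs$subtype, "network")
    }
    if (length(subtype_counts) == 0) subtype_counts <- NULL
  }

  manifest <- NULL
  if (!is.null(config$out_dir)) {
    manifest <- render_report(results, config$out_dir,
                              subtype_counts = subtype_counts,
                              config = config,
                              dropped_populations = dropped)
  }
  structure(list(results = results, inputs = inputs,
                 dropped_populations = dropped,
                 subtype_counts = subtype_counts, config = config,
                 manifest = manifest),
            class = "overlap_run")
}

#' @export
print.overlap_run <- function(x, ...) {
  cat("overlap_run:", length(x$results), "level(s) computed:",
      paste(names(x$results), collapse = ", "), "\n")
  if (length(x$dropped_populations) > 0) {
    cat("  populations dropped at function/network levels:",
        paste(x$dropped_populations, collapse = ", "), "\n")
  }
  for (level in names(x$results)) {
    cum <- x$results[[level]]$cumulative
    cat("  ", level, ": f(l) = ",
        paste(round(cum$values, 3), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}
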