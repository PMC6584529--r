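#' Entity pool for level-matched permutation tests
#'
#' The pool is the universe from which size-matched null sets are resampled:
#' all array SNPs for the SNP/LD levels, all mappable genes for the gene and
#' function levels, catalog terms or candidate genes for the remaining
#' levels. Observed entities missing from the supplied universe are added
#' with a warning so that the pool is always a superset of the observation.
#'
#' @param level granularity label.
#' @param universe character vector of pool entity ids.
#' @param observed_sets optional named list of observed entity sets whose ids
#'   must be contained in the pool.
#' @return Object of class `entity_pool`: list with `level` and sorted
#'   unique `ids`.
#' @export
build_pool <- function(level, universe, observed_sets = NULL) {
  ids <- sort(unique(as.character(universe)))
  if (!is.null(observed_sets)) {
    observed <- unique(unlist(observed_sets, use.names = FALSE))
    missing <- setdiff(observed, ids)
    if (length(missing) > 0) {
      warning(length(missing), " observed ", level,
              " entity id(s) absent from the supplied universe; added")
      ids <- sort(c(ids, missing))
    }
  }
  if (length(ids) == 0) stop("empty entity pool")
  structure(list(level = level, ids = ids), class = "entity_pool")
}

#' Draw one size-matched null collection from a pool
#'
#' Each population's null set is sampled uniformly without replacement
#' within the population (matching the duplicate-free observed sets) and
#' independently across populations, so an entity may recur in several
#' populations.
#'
#' @param pool an [build_pool()] entity pool.
#' @param sizes named integer vector, population code -> observed set size.
#' @return Named list of entity id vectors with exactly the requested sizes.
#' @export
sample_null_collection <- function(pool, sizes) {
  if (any(sizes > length(pool$ids))) {
    stop("requested set size exceeds pool size (", length(pool$ids), ")")
  }
  out <- lapply(sizes, function(n) sample(pool$ids, n, replace = FALSE))
  names(out) <- names(sizes)
  out
}

cum_values_from_sets <- function(sets, k) {
  ids <- unlist(lapply(sets, unique), use.names = FALSE)
  if (length(ids) == 0) return(rep(0, k))
  u <- unique(ids)
  cnt <- tabulate(match(ids, u), nbins = length(u))
  mm <- tabulate(pmin(cnt, k), nbins = k)
  rev(cumsum(rev(mm))) / length(u)
}

#' Permutation null distribution of a cumulative overlap function
#'
#' Resamples size-matched entity sets from the pool `n_perm` times and pushes
#' every replicate through the same level machinery as the observation: the
#' LD level applies the run's LD table to the sampled SNP sets, the function
#' level re-runs the enrichment analysis on sampled gene sets, and the
#' network level re-runs the locus pipeline and prix-fixe optimizer on
#' sampled SNP sets. Replicates where every population's entity set comes
#' out empty (possible at the function/network levels) score 0 at every l.
#'
#' @param level `"snp"`, `"ld"`, `"gene"`, `"function"` or `"network"`.
#' @param sizes named integer vector of observed per-population set sizes
#'   (SNP counts for snp/ld/network, gene counts for gene/function).
#' @param pool an [build_pool()] pool at the matching granularity.
#' @param n_perm number of permutation replicates (default 1000).
#' @param seed integer seed; the null is fully reproducible given it.
#' @param ld,r2_min,max_dist_bp LD table and thresholds (ld/network levels).
#' @param catalog,enrich_universe,fdr_max enrichment inputs (function level).
#' @param snp_coords data.frame `snp_id`, `chrom`, `pos` covering the pool
#'   (network level).
#' @param models,network gene models with ROIs and interaction network
#'   (network level).
#' @param subnet_args list of extra arguments for [optimize_selection()].
#' @return Object of class `permutation_null`: list with `level`, `n_perm`,
#'   `seed`, `replicates` (n_perm x k matrix of f(l) values) and `summary`
#'   (per-l min/max/mean/sd).
#' @export
null_distribution <- function(level = c("snp", "ld", "gene", "function",
                                        "network"),
                              sizes, pool, n_perm = 1000, seed = NULL,
                              ld = NULL, r2_min = 0.5, max_dist_bp = 500000,
                              catalog = NULL, enrich_universe = NULL,
                              fdr_max = 0.05, snp_coords = NULL,
                              models = NULL, network = NULL,
                              subnet_args = list()) {
  level <- match.arg(level)
  k <- length(sizes)
  if (!is.null(seed)) set.seed(seed)
  replicate_fun <- switch(
    level,
    snp = function(sets) cum_values_from_sets(sets, k),
    gene = function(sets) cum_values_from_sets(sets, k),
    ld = {
      if (is.null(ld)) stop("level 'ld' needs an LD table")
      function(sets) {
        sup <- ld_support_sets(sets, ld, r2_min = r2_min,
                               max_dist_bp = max_dist_bp)
        ld_cumulative_overlap(sup)$values
      }
    },
    `function` = {
      if (is.null(catalog)) stop("level 'function' needs a catalog")
      function(sets) {
        term_sets <- lapply(sets, function(g) {
          as.character(enrich_population(g, catalog,
                                         universe = enrich_universe,
                                         fdr_max = fdr_max))
        })
        cum_values_from_sets(term_sets, k)
      }
    },
    network = {
      if (is.null(snp_coords) || is.null(models) || is.null(network)) {
        stop("level 'network' needs snp_coords, models and network")
      }
      partner_map <- if (is.null(ld) || nrow(ld) == 0) NULL else
        ld_partners(pool$ids, ld, r2_min = r2_min,
                    max_dist_bp = max_dist_bp)
      coords_idx <- snp_coords[match(pool$ids, snp_coords$snp_id), ]
      if (anyNA(coords_idx$pos)) {
        stop("snp_coords must cover every pool SNP")
      }
      function(sets) {
        gene_sets <- lapply(sets, function(snp_ids) {
          coords <- coords_idx[match(snp_ids, pool$ids), ]
          pm <- if (is.null(partner_map)) {
            setNames(as.list(snp_ids), snp_ids)
          } else {
            partner_map[snp_ids]
          }
          loci <- define_loci(coords, pm)
          cand <- suppressWarnings(candidate_genes(loci, models, coords))
          if (length(cand) == 0) return(character(0))
          sol <- do.call(optimize_selection,
                         c(list(candidates = cand, network = network),
                           subnet_args))
          selected_subnetwork_genes(sol$selection, network)
        })
        cum_values_from_sets(gene_sets, k)
      }
    })
  replicates <- matrix(NA_real_, n_perm, k)
  for (r in seq_len(n_perm)) {
    sets <- sample_null_collection(pool, sizes)
    replicates[r, ] <- replicate_fun(sets)
  }
  colnames(replicates) <- paste0("l=", seq_len(k))
  summary <- data.frame(
    l = seq_len(k),
    min = apply(replicates, 2, min),
    max = apply(replicates, 2, max),
    mean = colMeans(replicates),
    sd = apply(replicates, 2, stats::sd))
  rownames(summary) <- NULL
  structure(list(level = level, n_perm = n_perm, seed = seed,
                 replicates = replicates, summary = summary, k = k),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("permutation_null (level:", x$level, ";", x$n_perm, "replicates)\n")
  print(round(x$summary, 4))
  invisible(x)
}

#' Significance of an observed cumulative overlap function
#'
#' Scores the observed f(l) against a permutation null: z-score from the
#' null mean and standard deviation, the add-one empirical p-value
#' (1 + number of replicates >= observed) / (n_perm + 1), and the upper-tail
#' normal p-value at z. A degenerate null (sd = 0) yields an undefined
#' (`NA`) z with the empirical p-value still reported.
#'
#' @param observed a [cumulative_overlap()] object (or numeric vector of
#'   f(l) values of matching length).
#' @param null a [null_distribution()] result at the same level.
#' @return data.frame of class `significance_result` with columns `l`,
#'   `observed`, `z`, `p_empirical`, `p_normal`, `sd_zero`.
#' @export
significance <- function(observed, null) {
  obs <- if (inherits(observed, "cumulative_overlap")) {
    if (!identical(observed$level, null$level)) {
      stop("level mismatch: observed '", observed$level, "' vs null '",
           null$level, "'")
    }
    observed$values
  } else {
    as.numeric(observed)
  }
  if (length(obs) != null$k) stop("k mismatch between observed and null")
  n_perm <- null$n_perm
  out <- data.frame(l = seq_len(null$k), observed = obs)
  out$z <- (obs - null$summary$mean) / null$summary$sd
  out$sd_zero <- null$summary$sd == 0
  out$z[out$sd_zero] <- NA_real_
  out$p_empirical <- vapply(seq_len(null$k), function(l) {
    (1 + sum(null$replicates[, l] >= obs[l] - 1e-12)) / (n_perm + 1)
  }, numeric(1))
  out$p_normal <- stats::pnorm(out$z, lower.tail = FALSE)
  class(out) <- c("significance_result", "data.frame")
  out
}
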