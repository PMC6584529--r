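#' Group significant SNPs into disease-associated loci
#'
#' Loci are the connected components of the graph whose vertices are the
#' significant SNPs and whose edges join LD partners on the same chromosome;
#' a SNP with no partners in the set forms a singleton locus. Locus ids are
#' assigned in order of (chrom, min position).
#'
#' @param tag_snps data.frame with columns `snp_id`, `chrom`, `pos`.
#' @param partner_map named list from [ld_partners()] covering the SNPs.
#' @return List of loci, each a list with `locus_id`, `member_snps`, `chrom`,
#'   `min_pos`, `max_pos`.
#' @export
define_loci <- function(tag_snps, partner_map) {
  ids <- tag_snps$snp_id
  if (length(ids) == 0) return(list())
  edges <- do.call(rbind, lapply(ids, function(s) {
    p <- intersect(partner_map[[s]] %||% s, ids)
    p <- setdiff(p, s)
    if (length(p) == 0) return(NULL)
    cbind(s, p)
  }))
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(ids)
  if (!is.null(edges)) {
    # LD is intra-chromosomal; drop any cross-chromosome pairing defensively
    chrom_of <- setNames(tag_snps$chrom, tag_snps$snp_id)
    same <- chrom_of[edges[, 1]] == chrom_of[edges[, 2]]
    edges <- edges[same, , drop = FALSE]
    if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)$membership
  pos_of <- setNames(tag_snps$pos, tag_snps$snp_id)
  chrom_of <- setNames(tag_snps$chrom, tag_snps$snp_id)
  loci <- lapply(split(names(comp), comp), function(members) {
    list(member_snps = sort(members),
         chrom = unname(chrom_of[members[1]]),
         min_pos = min(pos_of[members]), max_pos = max(pos_of[members]))
  })
  ord <- order(vapply(loci, `[[`, character(1), "chrom"),
               vapply(loci, `[[`, numeric(1), "min_pos"))
  loci <- loci[ord]
  for (i in seq_along(loci)) loci[[i]]$locus_id <- i
  unname(loci)
}

#' Candidate genes per locus
#'
#' A gene is a candidate for a locus when its region of interest contains the
#' position of at least one member SNP (same chromosome). Loci with no
#' candidate gene are dropped with a warning.
#'
#' @param loci list of loci from [define_loci()].
#' @param models a [gene_models()] table with ROIs built.
#' @param snp_coords data.frame `snp_id`, `chrom`, `pos` covering all member
#'   SNPs.
#' @return Named list (by locus id) of sorted candidate gene vectors; dropped
#'   locus ids in attribute `dropped`.
#' @export
candidate_genes <- function(loci, models, snp_coords) {
  pos_of <- setNames(snp_coords$pos, snp_coords$snp_id)
  candidates <- list()
  dropped <- integer(0)
  for (loc in loci) {
    on_chr <- models[models$chrom == loc$chrom, , drop = FALSE]
    p <- pos_of[loc$member_snps]
    hit <- vapply(seq_len(nrow(on_chr)), function(i) {
      any(on_chr$roi_start[i] <= p - 1 & p - 1 < on_chr$roi_end[i])
    }, logical(1))
    genes <- sort(on_chr$symbol[hit])
    if (length(genes) == 0) {
      dropped <- c(dropped, loc$locus_id)
    } else {
      candidates[[as.character(loc$locus_id)]] <- genes
    }
  }
  if (length(dropped) > 0) {
    warning(length(dropped), " locus/loci with no candidate gene dropped")
  }
  structure(candidates, dropped = dropped)
}

#' Coherence score of a gene selection
#'
#' Total network edge weight over all unordered pairs of the selected genes;
#' genes absent from the network (or pairs without an edge) contribute 0.
#'
#' @param selection character vector of gene symbols, one per locus.
#' @param network an [interaction_network()].
#' @return Non-negative numeric score.
#' @export
coherence_score <- function(selection, network) {
  genes <- unique(selection)
  if (length(genes) < 2) return(0)
  sub <- network[network$gene_a %in% genes & network$gene_b %in% genes, ,
                 drop = FALSE]
  sum(sub$weight)
}

weight_matrix <- function(genes, network) {
  W <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  sub <- network[network$gene_a %in% genes & network$gene_b %in% genes, ,
                 drop = FALSE]
  if (nrow(sub) > 0) {
    ia <- match(sub$gene_a, genes)
    ib <- match(sub$gene_b, genes)
    W[cbind(ia, ib)] <- sub$weight
    W[cbind(ib, ia)] <- sub$weight
  }
  W
}

#' Select the most coherent one-gene-per-locus subnetwork
#'
#' Chooses exactly one candidate gene from every locus so that the total
#' network edge weight among the chosen genes is maximal -- the prix-fixe
#' constraint (one dish per course). Small instances (product of candidate
#' counts at most `exhaustive_limit`) are solved exactly by enumeration;
#' larger ones by simulated annealing over single-locus swap moves with
#' geometric cooling, taking the best across restarts. Ties are broken by the
#' lexicographically smallest selected gene tuple. Given a seed the result is
#' reproducible.
#'
#' @param candidates named list locus id -> candidate gene vector (from
#'   [candidate_genes()]).
#' @param network an [interaction_network()].
#' @param method `"auto"` (default), `"exhaustive"` or `"anneal"`.
#' @param restarts annealing restarts (default 20).
#' @param steps annealing steps per restart (default 2000).
#' @param t0,cooling initial temperature and geometric cooling factor.
#' @param seed optional integer seed.
#' @param exhaustive_limit combination-count threshold for the automatic
#'   method switch (default 1e5).
#' @return Object of class `subnetwork_solution`: list with `selection`
#'   (named character vector locus -> gene), `score`, `method`, `seed` and
#'   `gene_scores` (fraction of restart-best solutions containing each
#'   selected-universe gene; 1 for the exhaustive method's optimum genes).
#' @export
optimize_selection <- function(candidates, network,
                               method = c("auto", "exhaustive", "anneal"),
                               restarts = 20, steps = 2000, t0 = 1,
                               cooling = 0.995, seed = NULL,
                               exhaustive_limit = 1e5) {
  method <- match.arg(method)
  if (length(candidates) == 0) stop("no loci with candidate genes")
  candidates <- lapply(candidates, function(g) sort(unique(g)))
  genes <- sort(unique(unlist(candidates, use.names = FALSE)))
  W <- weight_matrix(genes, network)
  cand_idx <- lapply(candidates, function(g) match(g, genes) - 1L)
  n_comb <- prod(vapply(candidates, length, integer(1)))
  if (method == "auto") {
    method <- if (n_comb <= exhaustive_limit) "exhaustive" else "anneal"
  }
  if (!is.null(seed)) set.seed(seed)
  if (method == "exhaustive") {
    res <- exhaustive_opt_cpp(cand_idx, W)
    selection <- genes[res$selection + 1L]
    gene_scores <- setNames(rep(1, length(unique(selection))),
                            sort(unique(selection)))
  } else {
    res <- anneal_opt_cpp(cand_idx, W, as.integer(restarts),
                          as.integer(steps), t0, cooling)
    selection <- genes[res$selection + 1L]
    per_restart <- apply(res$restart_selections + 1L, 1,
                         function(row) unique(genes[row]), simplify = FALSE)
    freq <- table(unlist(per_restart))
    gene_scores <- setNames(as.numeric(freq) / restarts, names(freq))
  }
  names(selection) <- names(candidates)
  structure(list(selection = selection,
                 score = coherence_score(selection, network),
                 method = method, seed = seed, n_combinations = n_comb,
                 gene_scores = gene_scores),
            class = "subnetwork_solution")
}

#' @export
print.subnetwork_solution <- function(x, ...) {
  cat("subnetwork_solution:", length(x$selection), "loci, score",
      round(x$score, 4), "(", x$method, ")\n")
  invisible(x)
}

#' Genes of the subnetwork induced by a selection
#'
#' The coherent subnetwork is the graph induced by the selected genes; a
#' selected gene with no edge to any other selected gene is an isolated
#' vertex forced in by the one-gene-per-locus constraint and is not part of
#' the subnetwork. With `connected_only = FALSE` every selected gene is kept.
#'
#' @param selection character vector of selected gene symbols.
#' @param network an [interaction_network()].
#' @param connected_only drop isolated selected genes (default `TRUE`).
#' @return Sorted character vector of subnetwork gene symbols.
#' @export
selected_subnetwork_genes <- function(selection, network,
                                      connected_only = TRUE) {
  genes <- sort(unique(unname(selection)))
  if (!connected_only || length(genes) < 2) return(genes)
  sub <- network[network$gene_a %in% genes & network$gene_b %in% genes, ,
                 drop = FALSE]
  connected <- unique(c(sub$gene_a, sub$gene_b))
  sort(intersect(genes, connected))
}

#' Most coherent disease subnetwork per population
#'
#' Runs the full locus pipeline for every population: LD partners of the
#' population's tagSNPs, connected-component loci, ROI candidate genes, and
#' prix-fixe selection. N_i is the set of genes forming the subnetwork
#' induced by the best solution (see [selected_subnetwork_genes()]);
#' per-gene disease-association scores are the restart frequencies from the
#' optimizer.
#'
#' @param collection a [study_collection()].
#' @param ld an [ld_table()].
#' @param models a [gene_models()] table with ROIs.
#' @param network an [interaction_network()].
#' @param r2_min,max_dist_bp LD thresholds.
#' @param ld_expand use LD partners when defining loci (default `TRUE`).
#' @param connected_only restrict N_i to non-isolated selected genes
#'   (default `TRUE`; see [selected_subnetwork_genes()]).
#' @param seed optional integer seed (per-population seeds are derived).
#' @param ... further arguments for [optimize_selection()].
#' @return Object of class `population_subnetworks`: list with `sets` (named
#'   list population -> N_i gene vector) and `solutions`.
#' @export
population_subnetwork <- function(collection, ld, models, network,
                                  r2_min = 0.5, max_dist_bp = 500000,
                                  ld_expand = TRUE, connected_only = TRUE,
                                  seed = NULL, ...) {
  codes <- population_codes(collection)
  solutions <- list()
  sets <- list()
  for (i in seq_along(codes)) {
    code <- codes[i]
    snps <- collection$populations[[code]]
    partner_map <- if (ld_expand) {
      ld_partners(snps$snp_id, ld, r2_min = r2_min,
                  max_dist_bp = max_dist_bp)
    } else {
      setNames(as.list(snps$snp_id), snps$snp_id)
    }
    loci <- define_loci(snps[, c("snp_id", "chrom", "pos")], partner_map)
    cand <- suppressWarnings(candidate_genes(loci, models, snps))
    if (length(cand) == 0) {
      warning("population ", code, ": no locus has candidate genes; ",
              "empty subnetwork")
      sets[[code]] <- character(0)
      solutions[code] <- list(NULL)
      next
    }
    pop_seed <- if (is.null(seed)) NULL else seed + i
    sol <- optimize_selection(cand, network, seed = pop_seed, ...)
    sets[[code]] <- selected_subnetwork_genes(sol$selection, network,
                                              connected_only)
    solutions[[code]] <- sol
  }
  structure(list(sets = sets, solutions = solutions),
            class = "population_subnetworks")
}

#' Combined cross-population subnetwork and annotated edge-list export
#'
#' Pools the loci of all populations (union of significant SNPs), runs the
#' prix-fixe optimizer once on the pooled instance, and exports the selected
#' subnetwork as node and edge tables annotated with the contributing
#' population(s) of every selected gene.
#'
#' @inheritParams population_subnetwork
#' @return List with `solution` (the pooled [optimize_selection()] result),
#'   `nodes` (data.frame `gene`, `populations`) and `edges` (data.frame
#'   `gene_a`, `gene_b`, `weight`, `populations_a`, `populations_b`).
#' @export
combined_network_export <- function(collection, ld, models, network,
                                    r2_min = 0.5, max_dist_bp = 500000,
                                    ld_expand = TRUE, seed = NULL, ...) {
  codes <- population_codes(collection)
  if (length(codes) < 2) stop("combined run needs at least 2 populations")
  coords <- snp_coordinates(collection)
  partner_map <- if (ld_expand) {
    ld_partners(coords$snp_id, ld, r2_min = r2_min, max_dist_bp = max_dist_bp)
  } else {
    setNames(as.list(coords$snp_id), coords$snp_id)
  }
  loci <- define_loci(coords, partner_map)
  cand <- suppressWarnings(candidate_genes(loci, models, coords))
  if (length(cand) == 0) stop("no locus has candidate genes")
  sol <- optimize_selection(cand, network, seed = seed, ...)
  sets <- snp_sets(collection)
  locus_by_id <- setNames(loci, vapply(loci, `[[`, integer(1), "locus_id"))
  gene_pops <- list()
  for (lid in names(sol$selection)) {
    gene <- sol$selection[[lid]]
    members <- locus_by_id[[lid]]$member_snps
    pops <- codes[vapply(sets, function(s) any(members %in% s), logical(1))]
    gene_pops[[gene]] <- sort(unique(c(gene_pops[[gene]], pops)))
  }
  sel_genes <- sort(unique(unname(sol$selection)))
  nodes <- data.frame(
    gene = sel_genes,
    populations = vapply(sel_genes,
                         function(g) paste(gene_pops[[g]], collapse = ","),
                         character(1)),
    stringsAsFactors = FALSE)
  edges <- network[network$gene_a %in% sel_genes &
                     network$gene_b %in% sel_genes, , drop = FALSE]
  edges <- as.data.frame(edges)
  edges$populations_a <- nodes$populations[match(edges$gene_a, nodes$gene)]
  edges$populations_b <- nodes$populations[match(edges$gene_b, nodes$gene)]
  rownames(edges) <- NULL
  rownames(nodes) <- NULL
  list(solution = sol, nodes = nodes, edges = edges)
}
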