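#' Upper-tail hypergeometric p-value for term over-representation
#'
#' Probability of drawing at least `overlap_n` members of a term of size
#' `term_n` when sampling `query_n` genes without replacement from a universe
#' of `universe_n` genes. This is the classic one-sided over-representation
#' (Fisher exact, alternative = greater) p-value.
#'
#' @param universe_n,term_n,query_n,overlap_n non-negative counts with
#'   `overlap_n <= min(term_n, query_n)` and `term_n, query_n <= universe_n`.
#' @return P(X >= overlap_n) for X ~ Hypergeometric(universe_n, term_n,
#'   query_n); equals 1 when `overlap_n` is 0.
#' @export
hypergeometric_tail <- function(universe_n, term_n, query_n, overlap_n) {
  if (overlap_n > min(term_n, query_n) || term_n > universe_n ||
      query_n > universe_n || overlap_n < 0) {
    stop("invalid hypergeometric counts: overlap <= min(term, query) and ",
         "term, query <= universe required")
  }
  if (overlap_n == 0) return(1)
  stats::phyper(overlap_n - 1, term_n, universe_n - term_n, query_n,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values; the set of terms with adjusted value at most
#' alpha is exactly the classic BH rejection set at level alpha.
#'
#' @param p_values numeric vector of raw p-values in (0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of one gene set against a catalog
#'
#' Tests every catalog term for enrichment in `genes` with the hypergeometric
#' tail, adjusts across terms by Benjamini-Hochberg, and returns the terms
#' passing the FDR threshold. Query genes outside the universe are dropped
#' (their count is attached as an attribute).
#'
#' @param genes character vector of gene symbols.
#' @param catalog a [functional_catalog()].
#' @param universe optional universe override (e.g. all mappable genes);
#'   defaults to the catalog universe. Term genes outside it are ignored.
#' @param fdr_max FDR threshold; default 0.05.
#' @param min_term_size,max_term_size term-size filter applied before testing.
#' @return Character vector of significant term ids, with the full result
#'   table (term, overlap, term_size, query_size, universe_size, p, fdr,
#'   significant) as attribute `table`.
#' @export
enrich_population <- function(genes, catalog, universe = NULL,
                              fdr_max = 0.05, min_term_size = 1,
                              max_term_size = Inf) {
  universe <- universe %||% catalog$universe
  universe <- unique(as.character(universe))
  query <- intersect(unique(genes), universe)
  dropped <- length(unique(genes)) - length(query)
  terms <- lapply(catalog$terms, intersect, universe)
  sizes <- vapply(terms, length, integer(1))
  terms <- terms[sizes >= min_term_size & sizes <= max_term_size]
  if (length(terms) == 0 || length(query) == 0) {
    tab <- data.frame(term = character(), overlap = integer(),
                      term_size = integer(), query_size = integer(),
                      universe_size = integer(), p = numeric(),
                      fdr = numeric(), significant = logical())
    return(structure(character(0), table = tab, dropped_genes = dropped))
  }
  n_univ <- length(universe)
  n_query <- length(query)
  tab <- data.frame(
    term = names(terms),
    overlap = vapply(terms, function(g) length(intersect(g, query)),
                     integer(1)),
    term_size = vapply(terms, length, integer(1)),
    query_size = n_query,
    universe_size = n_univ,
    stringsAsFactors = FALSE)
  tab$p <- mapply(hypergeometric_tail, n_univ, tab$term_size, n_query,
                  tab$overlap)
  tab$fdr <- bh_fdr(tab$p)
  tab$significant <- tab$fdr <= fdr_max
  rownames(tab) <- NULL
  structure(sort(tab$term[tab$significant]), table = tab,
            dropped_genes = dropped)
}

#' Enriched-term sets for every population of a gene-set map
#'
#' Runs [enrich_population()] per population, yielding the function-level
#' entity sets F_i. Populations whose gene set is enriched in no term keep an
#' empty set here; downstream analyses drop them (see
#' [drop_empty_populations()]).
#'
#' @param gene_sets a `gene_set_map` (or named list of gene vectors).
#' @param catalog a [functional_catalog()].
#' @param ... passed to [enrich_population()].
#' @return Named list, population code -> character vector of significant
#'   term ids, with per-population result tables in attribute `tables`.
#' @export
enrich_all <- function(gene_sets, catalog, ...) {
  out <- lapply(gene_sets, enrich_population, catalog = catalog, ...)
  tables <- lapply(out, attr, "table")
  sets <- lapply(out, as.character)
  structure(sets, tables = tables)
}

#' Drop populations with empty entity sets
#'
#' Populations whose gene sets are not enriched in any biological process
#' carry no information at the function or network level and are removed
#' before those analyses (reducing k).
#'
#' @param entity_sets named list, population -> entity id vector.
#' @return The list restricted to populations with non-empty sets; dropped
#'   codes in attribute `dropped`.
#' @export
drop_empty_populations <- function(entity_sets) {
  keep <- vapply(entity_sets, length, integer(1)) > 0
  structure(entity_sets[keep], dropped = names(entity_sets)[!keep])
}
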