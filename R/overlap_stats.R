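#' Pairwise Jaccard overlap matrix at one granularity level
#'
#' For entity sets E_1..E_k (tagSNPs, genes, enriched terms or subnetwork
#' genes per population), entry (i, j) is |E_i intersect E_j| / |E_i union
#' E_j|. Two empty sets give 0 (with a warning); the diagonal is 1 for every
#' population with a non-empty set.
#'
#' @param entity_sets named list, population code -> character vector of
#'   entity ids.
#' @param level one of `"snp"`, `"ld"`, `"gene"`, `"function"`, `"network"`.
#' @return A symmetric k x k matrix of class `overlap_matrix` with values in
#'   \[0, 1\], population codes as dimnames and the level as attribute.
#' @export
jaccard_overlap_matrix <- function(entity_sets, level = "snp") {
  k <- length(entity_sets)
  if (k < 2) stop("need at least 2 populations")
  codes <- names(entity_sets)
  sets <- lapply(entity_sets, unique)
  values <- matrix(0, k, k, dimnames = list(codes, codes))
  warned <- FALSE
  for (i in seq_len(k)) {
    for (j in i:k) {
      u <- length(union(sets[[i]], sets[[j]]))
      if (u == 0) {
        if (!warned && i != j) {
          warning("Jaccard of two empty sets defined as 0 (level ", level, ")")
          warned <- TRUE
        }
        v <- 0
      } else {
        v <- length(intersect(sets[[i]], sets[[j]])) / u
      }
      values[i, j] <- values[j, i] <- v
    }
  }
  new_overlap_matrix(values, level)
}

new_overlap_matrix <- function(values, level) {
  structure(values, level = level, class = c("overlap_matrix", "matrix"))
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("overlap_matrix (level:", attr(x, "level"), ")\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' LD-aware SNP overlap matrix
#'
#' Entry (i, j) is |L_ij union L_ji| / |S_i union S_j| where L_ij is the set
#' of population-i tagSNPs that are supported in population j (the SNP itself
#' or one of its qualifying LD partners is significant in j). Since every SNP
#' is its own LD partner, this dominates the plain SNP-level Jaccard matrix
#' and collapses to it exactly when the LD table is empty.
#'
#' @param collection a [study_collection()].
#' @param support an [ld_support()] built on the same collection.
#' @return An `overlap_matrix` at level `"ld"`.
#' @export
ld_overlap_matrix <- function(collection, support) {
  sets <- snp_sets(collection)
  codes <- population_codes(collection)
  k <- length(codes)
  values <- matrix(0, k, k, dimnames = list(codes, codes))
  supported_in <- function(i, j) {
    # L_ij: tagSNPs of population i supported in population j
    s <- sets[[i]]
    s[vapply(s, function(x) codes[j] %in% support[[x]], logical(1))]
  }
  for (i in seq_len(k)) {
    for (j in i:k) {
      denom <- length(union(sets[[i]], sets[[j]]))
      v <- if (denom == 0) 0 else
        length(union(supported_in(i, j), supported_in(j, i))) / denom
      values[i, j] <- values[j, i] <- v
    }
  }
  new_overlap_matrix(values, "ld")
}

#' Cumulative overlap function over k populations
#'
#' f(l) is the fraction of entities (relative to the union over all
#' populations) that are disease-associated in at least l of the k
#' populations. For any non-empty input f(1) = 1, f is monotonically
#' non-increasing and stays inside \[0, 1\].
#'
#' @param entity_sets named list, population code -> character vector of
#'   entity ids.
#' @param level granularity label stored on the result.
#' @return Object of class `cumulative_overlap`: list with `level`, `values`
#'   (f(1)..f(k)), `support_sets` (entities reaching each l) and
#'   `universe_size`.
#' @export
cumulative_overlap <- function(entity_sets, level = "snp") {
  k <- length(entity_sets)
  if (k < 1) stop("need at least 1 population")
  sets <- lapply(entity_sets, unique)
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  if (length(universe) == 0) stop("all entity sets are empty")
  counts <- table(unlist(sets, use.names = FALSE))
  values <- vapply(seq_len(k), function(l) {
    sum(counts >= l) / length(universe)
  }, numeric(1))
  support_sets <- lapply(seq_len(k), function(l) {
    sort(names(counts)[counts >= l])
  })
  structure(list(level = level, values = values, support_sets = support_sets,
                 universe_size = length(universe), k = k),
            class = "cumulative_overlap")
}

#' @export
print.cumulative_overlap <- function(x, ...) {
  cat("cumulative_overlap (level:", x$level, "; universe:", x$universe_size,
      "entities)\n")
  print(round(setNames(x$values, paste0("l=", seq_len(x$k))), 4))
  invisible(x)
}

#' LD-level cumulative overlap function
#'
#' lambda(l) is the fraction of union tagSNPs whose LD support (the
#' populations in which the SNP or a qualifying partner is significant)
#' covers at least l populations. Identity partnership guarantees
#' lambda(1) = 1.
#'
#' @param support an [ld_support()].
#' @return A `cumulative_overlap` at level `"ld"`.
#' @export
ld_cumulative_overlap <- function(support) {
  k <- length(attr(support, "codes"))
  n_support <- vapply(support, length, integer(1))
  s_all <- names(support)
  values <- vapply(seq_len(k), function(l) {
    sum(n_support >= l) / length(s_all)
  }, numeric(1))
  support_sets <- lapply(seq_len(k), function(l) sort(s_all[n_support >= l]))
  structure(list(level = "ld", values = values, support_sets = support_sets,
                 universe_size = length(s_all), k = k),
            class = "cumulative_overlap")
}

#' Stratify per-population gene sets by disease subtype
#'
#' Counts, per population, the genes annotated to each subtype label; genes
#' without an annotation are tallied in an `other` bucket.
#'
#' @param gene_sets named list, population -> character vector of gene
#'   symbols (gene-level sets or subnetwork gene sets).
#' @param annotation a [subtype_annotation()].
#' @param granularity `"gene"` or `"network"`, recorded on the result.
#' @return data.frame of class `subtype_counts` with one row per population
#'   and columns `secretion_deficiency`, `insulin_resistance`, `both`,
#'   `other`.
#' @export
stratify_by_subtype <- function(gene_sets, annotation,
                                granularity = c("gene", "network")) {
  granularity <- match.arg(granularity)
  labels <- c("secretion_deficiency", "insulin_resistance", "both")
  rows <- lapply(names(gene_sets), function(code) {
    genes <- unique(gene_sets[[code]])
    lab <- unclass(annotation)[genes]
    counts <- vapply(labels, function(x) sum(lab == x, na.rm = TRUE),
                     integer(1))
    data.frame(population = code, t(counts), other = sum(is.na(lab)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "granularity") <- granularity
  class(out) <- c("subtype_counts", "data.frame")
  out
}
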