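#' Construct a pairwise linkage-disequilibrium table
#'
#' Stores each unordered SNP pair once (`snp_a < snp_b`); the relation is
#' symmetric by construction and the identity pair (r2 = 1, distance 0) is
#' implicit, never stored.
#'
#' @param entries data.frame with columns `snp_a`, `snp_b`, `r2`, `dist_bp`.
#' @return data.frame of class `ld_table`.
#' @export
ld_table <- function(entries) {
  if (nrow(entries) == 0) {
    out <- data.frame(snp_a = character(), snp_b = character(),
                      r2 = numeric(), dist_bp = integer())
    class(out) <- c("ld_table", "data.frame")
    return(out)
  }
  required <- c("snp_a", "snp_b", "r2", "dist_bp")
  if (!all(required %in% names(entries))) {
    stop("LD table needs columns: ", paste(required, collapse = ", "))
  }
  if (any(entries$r2 < 0 | entries$r2 > 1)) stop("r2 must lie in [0, 1]")
  if (any(entries$dist_bp < 0)) stop("dist_bp must be >= 0")
  self <- entries$snp_a == entries$snp_b
  entries <- entries[!self, , drop = FALSE]
  a <- pmin(entries$snp_a, entries$snp_b)
  b <- pmax(entries$snp_a, entries$snp_b)
  canon <- data.frame(snp_a = a, snp_b = b, r2 = entries$r2,
                      dist_bp = as.integer(entries$dist_bp),
                      stringsAsFactors = FALSE)
  canon <- canon[!duplicated(canon[, c("snp_a", "snp_b")]), ]
  canon <- canon[order(canon$snp_a, canon$snp_b), ]
  rownames(canon) <- NULL
  class(canon) <- c("ld_table", "data.frame")
  canon
}

#' Read an LD table from TSV
#' @param path TSV with header `snp_a`, `snp_b`, `r2`, `dist_bp`.
#' @return An [ld_table()].
#' @export
load_ld_table <- function(path) {
  ld_table(read.delim(path, stringsAsFactors = FALSE))
}

#' Write an LD table as TSV
#' @param ld an `ld_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_table <- function(ld, path) {
  write.table(as.data.frame(ld), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Squared correlation (r2) between two allele-dosage vectors
#'
#' Composite LD: the squared Pearson correlation of per-sample allele dosages
#' (0/1/2 counts or fractional imputed dosages) at two sites.
#'
#' @param dosage_a,dosage_b equal-length numeric vectors, length >= 2.
#' @return r2 in \[0, 1\].
#' @export
compute_r2 <- function(dosage_a, dosage_b) {
  if (length(dosage_a) != length(dosage_b)) {
    stop("dosage vectors must have equal length")
  }
  if (length(dosage_a) < 2) stop("need at least 2 samples")
  if (stats::var(dosage_a) == 0 || stats::var(dosage_b) == 0) {
    stop("LD undefined: constant dosage vector (monomorphic site)")
  }
  r <- stats::cor(dosage_a, dosage_b)
  min(r^2, 1)
}

#' LD partners of each tagSNP under r2/distance thresholds
#'
#' Two SNPs are partners when their r2 is at least `r2_min` and they lie
#' within `max_dist_bp` of each other. Every SNP is additionally its own
#' partner (the identity pair has r2 = 1 at distance 0), so SNPs absent from
#' the table map to their singleton set.
#'
#' @param tag_snp_ids character vector of SNP ids to look up.
#' @param ld an [ld_table()].
#' @param r2_min minimum r2, in (0, 1\]; default 0.5.
#' @param max_dist_bp maximum pairwise distance in bp; default 500 kb.
#' @return Named list, snp_id -> character vector of partner ids (always
#'   containing the key itself).
#' @export
ld_partners <- function(tag_snp_ids, ld, r2_min = 0.5, max_dist_bp = 500000) {
  stopifnot(r2_min > 0, r2_min <= 1, max_dist_bp > 0)
  tag_snp_ids <- unique(as.character(tag_snp_ids))
  qualifying <- ld[ld$r2 >= r2_min & ld$dist_bp <= max_dist_bp, , drop = FALSE]
  partners <- lapply(tag_snp_ids, function(s) s)
  names(partners) <- tag_snp_ids
  if (nrow(qualifying) > 0) {
    hits_a <- qualifying[qualifying$snp_a %in% tag_snp_ids, c("snp_a", "snp_b")]
    hits_b <- qualifying[qualifying$snp_b %in% tag_snp_ids, c("snp_b", "snp_a")]
    names(hits_b) <- c("snp_a", "snp_b")
    hits <- rbind(hits_a, hits_b)
    if (nrow(hits) > 0) {
      extra <- split(hits$snp_b, hits$snp_a)
      for (s in names(extra)) {
        partners[[s]] <- sort(unique(c(s, extra[[s]])))
      }
    }
  }
  partners
}

#' Population support of each tagSNP through LD partnership
#'
#' For every tagSNP s in the union S, records the set of populations in which
#' s itself, or any qualifying LD partner of s, is significant. Because a SNP
#' is its own partner, support always includes every population whose set
#' contains s.
#'
#' @param collection a [study_collection()].
#' @param ld an [ld_table()].
#' @param r2_min,max_dist_bp thresholds passed to [ld_partners()].
#' @return Object of class `ld_support`: named list snp_id -> character
#'   vector of population codes, with the collection's codes as attribute.
#' @export
ld_support <- function(collection, ld, r2_min = 0.5, max_dist_bp = 500000) {
  ld_support_sets(snp_sets(collection), ld, r2_min = r2_min,
                  max_dist_bp = max_dist_bp)
}

#' LD support computed from plain id sets
#'
#' Set-level worker behind [ld_support()]; also used to score permutation
#' replicates, where sampled SNP sets have no surrounding study collection.
#'
#' @param sets named list, population code -> character vector of SNP ids.
#' @inheritParams ld_support
#' @return An `ld_support` object over the union of the sets.
#' @export
ld_support_sets <- function(sets, ld, r2_min = 0.5, max_dist_bp = 500000) {
  codes <- names(sets)
  all_snps <- sort(unique(unlist(sets, use.names = FALSE)))
  partners <- ld_partners(all_snps, ld, r2_min = r2_min,
                          max_dist_bp = max_dist_bp)
  membership <- lapply(sets, function(set) all_snps %in% set)
  direct <- do.call(cbind, membership) # |S| x k logical
  support <- lapply(seq_along(all_snps), function(si) {
    p <- partners[[all_snps[si]]]
    if (length(p) == 1) {
      codes[direct[si, ]]
    } else {
      codes[vapply(sets, function(set) any(p %in% set), logical(1))]
    }
  })
  names(support) <- all_snps
  structure(support, codes = codes, class = "ld_support")
}
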