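#' Attach strand-aware regions of interest to gene models
#'
#' The ROI extends each gene's transcript span upstream and downstream of the
#' direction of transcription (default 100 kb upstream, 10 kb downstream) and
#' is clamped at the chromosome origin. With `strand_aware = FALSE` the
#' upstream extension is always applied to the left, downstream to the right.
#'
#' @param models a [gene_models()] table.
#' @param upstream_bp,downstream_bp extension lengths in bp.
#' @param strand_aware interpret the extensions relative to transcription.
#' @return The `gene_models` table with `roi_start`, `roi_end` columns
#'   (0-based half-open, like the transcript span).
#' @export
build_roi <- function(models, upstream_bp = 100000, downstream_bp = 10000,
                      strand_aware = TRUE) {
  stopifnot(upstream_bp >= 0, downstream_bp >= 0)
  left <- ifelse(!strand_aware | models$strand == "+",
                 upstream_bp, downstream_bp)
  right <- ifelse(!strand_aware | models$strand == "+",
                  downstream_bp, upstream_bp)
  models$roi_start <- pmax(0L, as.integer(models$tx_start - left))
  models$roi_end <- as.integer(models$tx_end + right)
  models
}

#' Map each population's significant SNPs to genes via ROI containment
#'
#' A gene belongs to population i's gene set G_i when at least one of the
#' population's significant tagSNPs lies inside the gene's region of interest
#' on the same chromosome. A SNP inside several overlapping ROIs maps to all
#' of them. SNP positions are 1-based, ROIs 0-based half-open: position p is
#' inside \[s, e) iff s <= p - 1 < e.
#'
#' @param collection a [study_collection()].
#' @param models a [gene_models()] table with ROIs built.
#' @return Object of class `gene_set_map`: named list population code ->
#'   sorted character vector of gene symbols; attribute `audit` holds the
#'   (snp_id, gene, population) assignment table and `unmapped` the count of
#'   SNPs that hit no ROI.
#' @export
map_snps_to_genes <- function(collection, models) {
  if (!"roi_start" %in% names(models)) {
    stop("gene models have no ROI; call build_roi() first")
  }
  gene_ranges <- IRanges::IRanges(start = models$roi_start + 1L,
                                  end = models$roi_end)
  audit <- list()
  unmapped <- 0L
  sets <- lapply(population_codes(collection), function(code) {
    snps <- collection$populations[[code]]
    if (nrow(snps) == 0) return(character(0))
    hit_genes <- character(0)
    for (chr in unique(snps$chrom)) {
      on_chr <- models$chrom == chr
      if (!any(on_chr)) next
      snp_rows <- snps[snps$chrom == chr, , drop = FALSE]
      q <- IRanges::IRanges(start = snp_rows$pos, width = 1L)
      ov <- IRanges::findOverlaps(q, gene_ranges[on_chr])
      if (length(ov) > 0) {
        idx <- which(on_chr)[S4Vectors::subjectHits(ov)]
        audit[[length(audit) + 1L]] <<- data.frame(
          snp_id = snp_rows$snp_id[S4Vectors::queryHits(ov)],
          gene = models$symbol[idx],
          population = code, stringsAsFactors = FALSE)
        hit_genes <- c(hit_genes, models$symbol[idx])
      }
    }
    sort(unique(hit_genes))
  })
  names(sets) <- population_codes(collection)
  audit_df <- if (length(audit) > 0) do.call(rbind, audit) else
    data.frame(snp_id = character(), gene = character(),
               population = character())
  for (code in names(sets)) {
    pop_snps <- collection$populations[[code]]$snp_id
    mapped <- unique(audit_df$snp_id[audit_df$population == code])
    unmapped <- unmapped + sum(!pop_snps %in% mapped)
  }
  structure(sets, audit = audit_df, unmapped = unmapped,
            class = "gene_set_map")
}
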