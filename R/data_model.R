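#' @useDynLib gwasoverlap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats phyper p.adjust pnorm sd as.dist hclust cophenetic setNames
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a multi-population study collection
#'
#' A study collection holds, for each of k populations, the set of tagSNPs
#' reported as significantly disease-associated in that population. It is the
#' root input of the overlap pipeline: every level (SNP, LD, gene, function,
#' network) is derived from it.
#'
#' @param snp_table data.frame with columns `population`, `snp_id`, `chrom`,
#'   `pos` and optionally `pvalue`. One row per reported association; duplicate
#'   probes mapping to the same SNP are removed per population (see
#'   [dedup_population()]).
#' @param disease free-text label for the phenotype under study.
#' @return An object of class `study_collection`: a list with elements
#'   `populations` (named list of per-population SNP data.frames, sorted by
#'   population code) and `disease`.
#' @export
study_collection <- function(snp_table, disease = "disease") {
  required <- c("population", "snp_id", "chrom", "pos")
  missing_cols <- setdiff(required, names(snp_table))
  if (length(missing_cols) > 0) {
    stop("SNP table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"pvalue" %in% names(snp_table)) {
    snp_table$pvalue <- rep(NA_real_, nrow(snp_table))
  }
  snp_table$pos <- validate_positions(snp_table$pos)
  if (any(!is.na(snp_table$pvalue) &
          (snp_table$pvalue < 0 | snp_table$pvalue > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  if (any(!nzchar(snp_table$snp_id))) stop("snp_id must be non-empty")
  codes <- sort(unique(as.character(snp_table$population)))
  if (length(codes) < 2) {
    stop("a study collection needs at least 2 populations, got ",
         length(codes))
  }
  pops <- lapply(codes, function(code) {
    rows <- snp_table[snp_table$population == code,
                      c("snp_id", "chrom", "pos", "pvalue")]
    dedup_population(rows)
  })
  names(pops) <- codes
  structure(list(populations = pops, disease = disease),
            class = "study_collection")
}

validate_positions <- function(pos) {
  if (is.character(pos)) {
    parsed <- suppressWarnings(as.numeric(pos))
    bad <- which(is.na(parsed) & !is.na(pos))
    if (length(bad) > 0) {
      stop("malformed position at row ", bad[1], ": '", pos[bad[1]], "'")
    }
    pos <- parsed
  }
  if (any(is.na(pos)) || any(pos < 1)) {
    stop("SNP positions must be >= 1 (1-based coordinates)")
  }
  as.integer(pos)
}

#' Remove duplicate probe records within one population
#'
#' Genotyping arrays report several probes for the same SNP; within a
#' population each SNP must be counted once. When duplicates carry different
#' p-values the smallest (most significant) is kept. Duplicates that disagree
#' on genomic location indicate corrupt input and raise an error.
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos` and optionally
#'   `pvalue`.
#' @return The deduplicated data.frame, one row per `snp_id`, sorted by id.
#' @export
dedup_population <- function(snps) {
  if (!"pvalue" %in% names(snps)) snps$pvalue <- NA_real_
  if (nrow(snps) == 0) {
    return(data.frame(snp_id = character(), chrom = character(),
                      pos = integer(), pvalue = numeric()))
  }
  loc <- unique(snps[, c("snp_id", "chrom", "pos")])
  dup <- loc$snp_id[duplicated(loc$snp_id)]
  if (length(dup) > 0) {
    stop("inconsistent chrom/pos for duplicated snp_id(s): ",
         paste(unique(dup), collapse = ", "))
  }
  ord <- order(snps$snp_id, snps$pvalue, na.last = TRUE)
  snps <- snps[ord, , drop = FALSE]
  out <- snps[!duplicated(snps$snp_id), c("snp_id", "chrom", "pos", "pvalue")]
  rownames(out) <- NULL
  out
}

#' @export
print.study_collection <- function(x, ...) {
  sizes <- vapply(x$populations, nrow, integer(1))
  cat("study_collection:", x$disease, "\n")
  cat("  k =", length(sizes), "populations;",
      "union of", length(snp_union(x)), "tagSNPs\n")
  for (code in names(sizes)) cat("  ", code, ": ", sizes[[code]],
                                 " tagSNPs\n", sep = "")
  invisible(x)
}

#' Population codes of a study collection
#' @param collection a `study_collection`.
#' @return Character vector of population codes, in collection order.
#' @export
population_codes <- function(collection) names(collection$populations)

#' Per-population tagSNP id sets
#' @param collection a `study_collection`.
#' @return Named list of character vectors (S_i), one per population.
#' @export
snp_sets <- function(collection) {
  lapply(collection$populations, function(p) p$snp_id)
}

#' Deduplicated union of all populations' tagSNPs (the set S)
#' @param collection a `study_collection`.
#' @return Sorted character vector of unique SNP ids.
#' @export
snp_union <- function(collection) {
  sort(unique(unlist(lapply(collection$populations, function(p) p$snp_id),
                     use.names = FALSE)))
}

#' Genomic coordinates of every SNP in a collection
#' @param collection a `study_collection`.
#' @return data.frame `snp_id`, `chrom`, `pos` with one row per unique SNP.
#' @keywords internal
snp_coordinates <- function(collection) {
  all_rows <- do.call(rbind, lapply(collection$populations,
                                    function(p) p[, c("snp_id", "chrom", "pos")]))
  out <- unique(all_rows)
  dup <- out$snp_id[duplicated(out$snp_id)]
  if (length(dup) > 0) {
    stop("SNP(s) with conflicting coordinates across populations: ",
         paste(unique(dup), collapse = ", "))
  }
  rownames(out) <- NULL
  out[order(out$snp_id), ]
}

#' Read a per-population significant-SNP table
#'
#' Expects a TSV with header columns `population`, `snp_id`, `chrom`, `pos`
#' and optionally `pvalue`. Row order is irrelevant: populations are sorted by
#' code and SNPs by id, so shuffled inputs load to identical collections.
#'
#' @param path path to the TSV file.
#' @param disease phenotype label stored on the collection.
#' @return A [study_collection()].
#' @export
load_study <- function(path, disease = "disease") {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  study_collection(tab, disease = disease)
}

#' Write a study collection back to its TSV format
#' @param collection a `study_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study <- function(collection, path) {
  rows <- do.call(rbind, lapply(population_codes(collection), function(code) {
    p <- collection$populations[[code]]
    cbind(population = rep(code, nrow(p)), p)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from a BED6 file and attach regions of interest
#'
#' Coordinates follow the BED convention: 0-based, half-open. Rows sharing a
#' gene symbol (multiple transcripts) are merged to the union span per symbol
#' before the ROI extension is applied, since mapping operates at gene
#' granularity.
#'
#' @param path path to a BED6 file (chrom, start, end, name, score, strand).
#' @param upstream_bp,downstream_bp ROI extension relative to the direction of
#'   transcription; defaults 100 kb upstream, 10 kb downstream.
#' @param strand_aware if `FALSE`, extend upstream to the left and downstream
#'   to the right regardless of strand.
#' @return data.frame of class `gene_models` with columns `symbol`, `chrom`,
#'   `strand`, `tx_start`, `tx_end`, `roi_start`, `roi_end`.
#' @export
load_gene_models <- function(path, upstream_bp = 100000, downstream_bp = 10000,
                             strand_aware = TRUE) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 6) stop("BED6 input required (6 columns, strand in column 6)")
  names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (!all(bed$strand %in% c("+", "-"))) {
    stop("strand column must be '+' or '-'")
  }
  bad <- which(bed$start >= bed$end)
  if (length(bad) > 0) {
    stop("BED row ", bad[1], ": start >= end (", bed$start[bad[1]], " >= ",
         bed$end[bad[1]], ")")
  }
  merged <- do.call(rbind, lapply(split(bed, bed$name), function(rows) {
    if (length(unique(rows$chrom)) > 1 || length(unique(rows$strand)) > 1) {
      stop("gene '", rows$name[1], "' has rows on multiple chromosomes/strands")
    }
    data.frame(symbol = rows$name[1], chrom = rows$chrom[1],
               strand = rows$strand[1], tx_start = min(rows$start),
               tx_end = max(rows$end), stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  build_roi(gene_models(merged), upstream_bp, downstream_bp,
            strand_aware = strand_aware)
}

#' Construct a gene-model table
#' @param df data.frame with columns `symbol`, `chrom`, `strand`, `tx_start`,
#'   `tx_end` (0-based half-open).
#' @return data.frame of class `gene_models` (ROI columns added by
#'   [build_roi()]).
#' @export
gene_models <- function(df) {
  required <- c("symbol", "chrom", "strand", "tx_start", "tx_end")
  if (!all(required %in% names(df))) {
    stop("gene models need columns: ", paste(required, collapse = ", "))
  }
  if (any(df$tx_start >= df$tx_end)) stop("tx_start must be < tx_end")
  if (anyDuplicated(df$symbol)) stop("gene symbols must be unique")
  df <- df[order(df$symbol), ]
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Read a functional catalog from a GMT file
#'
#' Standard GMT: one term per line, tab-separated `term_id`, `description`,
#' then member genes. Terms with no genes are dropped with a warning; a
#' duplicated term id keeps the last definition seen.
#'
#' @param path path to the GMT file.
#' @param universe optional explicit gene universe; defaults to the union of
#'   all term gene sets.
#' @return A `functional_catalog`: list with `terms` (named list of gene
#'   symbol vectors) and `universe`.
#' @export
load_gene_sets <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  terms <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    term_id <- fields[1]
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      warning("dropping term '", term_id, "': no member genes")
      next
    }
    if (term_id %in% names(terms)) {
      warning("duplicate term '", term_id, "': keeping the later definition")
    }
    terms[[term_id]] <- sort(genes)
  }
  functional_catalog(terms, universe = universe)
}

#' Construct a functional catalog
#' @param terms named list, term id -> character vector of gene symbols.
#' @param universe optional gene universe; defaults to the union of all terms.
#' @return Object of class `functional_catalog`.
#' @export
functional_catalog <- function(terms, universe = NULL) {
  if (length(terms) == 0) {
    return(structure(list(terms = setNames(list(), character(0)),
                          universe = sort(unique(as.character(
                            universe %||% character(0))))),
                     class = "functional_catalog"))
  }
  terms <- lapply(terms, function(g) sort(unique(as.character(g))))
  if (any(vapply(terms, length, integer(1)) < 1)) {
    stop("every term must contain at least one gene")
  }
  union_genes <- sort(unique(unlist(terms, use.names = FALSE)))
  if (is.null(universe)) {
    universe <- union_genes
  } else {
    universe <- sort(unique(as.character(universe)))
    outside <- setdiff(union_genes, universe)
    if (length(outside) > 0) {
      stop(length(outside), " catalog gene(s) missing from the supplied ",
           "universe, e.g. ", outside[1])
    }
  }
  structure(list(terms = terms[order(names(terms))], universe = universe),
            class = "functional_catalog")
}

#' Write a functional catalog as GMT
#' @param catalog a `functional_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(catalog, path) {
  lines <- vapply(names(catalog$terms), function(tid) {
    paste(c(tid, "na", catalog$terms[[tid]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a weighted undirected gene network from a TSV edge list
#'
#' Columns `gene_a`, `gene_b` and optionally `weight` (missing weights default
#' to 1). Reciprocal and duplicate edges are collapsed keeping the maximum
#' weight; self-loops are dropped with a warning.
#'
#' @param path path to the edge-list TSV.
#' @return An `interaction_network`.
#' @export
load_network <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(tab))) {
    stop("network TSV needs columns gene_a, gene_b")
  }
  if (!"weight" %in% names(tab)) tab$weight <- 1
  interaction_network(tab)
}

#' Construct an interaction network from an edge table
#' @param edges data.frame with columns `gene_a`, `gene_b`, `weight`
#'   (`weight` optional, defaulting to 1).
#' @return Object of class `interaction_network`: a canonicalized edge
#'   data.frame (`gene_a < gene_b`, one row per unordered pair, maximum weight
#'   kept) plus a `nodes` attribute.
#' @export
interaction_network <- function(edges) {
  if (!"weight" %in% names(edges)) edges$weight <- 1
  bad <- which(edges$weight <= 0)
  if (length(bad) > 0) {
    stop("edge row ", bad[1], ": weight must be > 0, got ",
         edges$weight[bad[1]])
  }
  loops <- edges$gene_a == edges$gene_b
  if (any(loops)) {
    warning("dropping ", sum(loops), " self-loop edge(s)")
    edges <- edges[!loops, , drop = FALSE]
  }
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  canon <- data.frame(gene_a = a, gene_b = b, weight = edges$weight,
                      stringsAsFactors = FALSE)
  key <- paste(canon$gene_a, canon$gene_b, sep = "\r")
  keep <- tapply(canon$weight, key, max)
  canon <- unique(canon[, c("gene_a", "gene_b")])
  canon$weight <- as.numeric(keep[paste(canon$gene_a, canon$gene_b,
                                        sep = "\r")])
  canon <- canon[order(canon$gene_a, canon$gene_b), ]
  rownames(canon) <- NULL
  attr(canon, "nodes") <- sort(unique(c(canon$gene_a, canon$gene_b)))
  class(canon) <- c("interaction_network", "data.frame")
  canon
}

#' Write a network edge list as TSV
#' @param network an `interaction_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  write.table(as.data.frame(network)[, c("gene_a", "gene_b", "weight")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-disease-subtype annotation
#'
#' TSV with columns `gene`, `subtype`; subtype labels are restricted to
#' `secretion_deficiency`, `insulin_resistance` and `both` (the two T2D
#' etiological axes and their intersection).
#'
#' @param path path to the TSV.
#' @return Named character vector, gene symbol -> subtype label, of class
#'   `subtype_annotation`.
#' @export
load_subtype_annotation <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "subtype") %in% names(tab))) {
    stop("subtype TSV needs columns gene, subtype")
  }
  subtype_annotation(setNames(tab$subtype, tab$gene))
}

#' Construct a subtype annotation
#' @param assignment named character vector, gene -> label.
#' @return Object of class `subtype_annotation`.
#' @export
subtype_annotation <- function(assignment) {
  allowed <- c("secretion_deficiency", "insulin_resistance", "both")
  bad <- setdiff(unique(assignment), allowed)
  if (length(bad) > 0) {
    stop("subtype labels must be one of ", paste(allowed, collapse = ", "),
         "; got: ", paste(bad, collapse = ", "))
  }
  structure(assignment[order(names(assignment))], class = "subtype_annotation")
}
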