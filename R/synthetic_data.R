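#' Parameters of a synthetic genome/annotation world
#'
#' The world emulates the fixed reference resources the analysis consumes: a
#' multi-chromosome genome with non-overlapping genes on random strands, a
#' SNP catalog, block-structured LD (r-squared high within haplotype blocks,
#' absent across them), a term catalog over the genes, and an interaction
#' network whose edges are enriched within terms (genes sharing a term
#' connect with probability `p_in`, others with `p_out`), mirroring a
#' shared-function network.
#'
#' @param n_chrom number of chromosomes (default 3).
#' @param chrom_length_bp chromosome length in bp (default 1e7).
#' @param n_genes,n_snps totals across the genome (defaults 200 and 5000).
#' @param gene_length_range transcript length range in bp.
#' @param ld_block_size_bp haplotype block size (default 20 kb).
#' @param within_block_r2_mean mean r-squared inside a block, in (0, 1).
#' @param r2_concentration Beta concentration of within-block r-squared.
#' @param n_terms,term_size_mean,term_size_sd,term_size_min functional
#'   catalog shape.
#' @param p_in,p_out network edge probabilities for term-sharing and
#'   background gene pairs; requires `p_in > p_out >= 0`.
#' @param weight_range uniform range of edge weights.
#' @param roi_upstream_bp,roi_downstream_bp ROI extensions applied to the
#'   generated gene models.
#' @param seed integer seed; the world is deterministic given it.
#' @return List of class `world_params`.
#' @export
world_params <- function(n_chrom = 3, chrom_length_bp = 1e7, n_genes = 200,
                         n_snps = 5000, gene_length_range = c(5000, 30000),
                         ld_block_size_bp = 20000,
                         within_block_r2_mean = 0.75, r2_concentration = 10,
                         n_terms = 25, term_size_mean = 12, term_size_sd = 3,
                         term_size_min = 4, p_in = 0.25, p_out = 0.02,
                         weight_range = c(0.5, 1.5),
                         roi_upstream_bp = 100000, roi_downstream_bp = 10000,
                         seed = 1) {
  stopifnot(p_in > p_out, p_out >= 0,
            within_block_r2_mean > 0, within_block_r2_mean < 1,
            n_chrom >= 1, n_genes >= 1, n_snps >= 1, n_terms >= 1)
  structure(as.list(environment()), class = "world_params")
}

#' Generate a synthetic world
#'
#' @param params a [world_params()] list.
#' @return Object of class `synthetic_world`: list with `models` (gene
#'   models, ROIs built), `snps` (snp_id/chrom/pos), `ld` ([ld_table()]),
#'   `catalog` ([functional_catalog()]), `network`
#'   ([interaction_network()]), `subtypes` ([subtype_annotation()]) and the
#'   originating `params`.
#' @export
generate_world <- function(params = world_params()) {
  set.seed(params$seed)
  chroms <- paste0("chr", seq_len(params$n_chrom))
  genes_per_chrom <- diff(round(seq(0, params$n_genes,
                                    length.out = params$n_chrom + 1)))
  snps_per_chrom <- diff(round(seq(0, params$n_snps,
                                   length.out = params$n_chrom + 1)))
  gene_rows <- list()
  snp_rows <- list()
  g_offset <- 0
  for (ci in seq_along(chroms)) {
    ng <- genes_per_chrom[ci]
    lens <- sample(seq(params$gene_length_range[1],
                       params$gene_length_range[2], by = 100), ng,
                   replace = TRUE)
    free <- params$chrom_length_bp - sum(lens)
    if (free < 0) {
      stop("infeasible packing: total gene length exceeds chromosome length")
    }
    gap_frac <- stats::runif(ng + 1)
    gaps <- floor(gap_frac / sum(gap_frac) * free)
    starts <- cumsum(gaps[seq_len(ng)]) + c(0, cumsum(lens[-ng]))
    gene_rows[[ci]] <- data.frame(
      symbol = sprintf("G%04d", g_offset + seq_len(ng)),
      chrom = chroms[ci],
      strand = sample(c("+", "-"), ng, replace = TRUE),
      tx_start = as.integer(starts),
      tx_end = as.integer(starts + lens),
      stringsAsFactors = FALSE)
    g_offset <- g_offset + ng
    ns <- snps_per_chrom[ci]
    pos <- sort(sample.int(params$chrom_length_bp, ns))
    snp_rows[[ci]] <- data.frame(chrom = chroms[ci], pos = pos,
                                 stringsAsFactors = FALSE)
  }
  models <- build_roi(gene_models(do.call(rbind, gene_rows)),
                      upstream_bp = params$roi_upstream_bp,
                      downstream_bp = params$roi_downstream_bp)
  snps <- do.call(rbind, snp_rows)
  snps <- data.frame(snp_id = sprintf("rs%06d", seq_len(nrow(snps))),
                     chrom = snps$chrom, pos = snps$pos,
                     stringsAsFactors = FALSE)
  ld <- generate_block_ld(snps, params)
  catalog <- generate_catalog(models$symbol, params)
  network <- generate_term_network(models$symbol, catalog, params)
  subtypes <- derive_subtypes(catalog)
  structure(list(models = models, snps = snps, ld = ld, catalog = catalog,
                 network = network, subtypes = subtypes, params = params),
            class = "synthetic_world")
}

generate_block_ld <- function(snps, params) {
  block <- paste(snps$chrom, snps$pos %/% params$ld_block_size_bp)
  groups <- split(seq_len(nrow(snps)), block)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  if (length(groups) == 0) {
    return(ld_table(data.frame(snp_a = character(), snp_b = character(),
                               r2 = numeric(), dist_bp = integer())))
  }
  m <- params$within_block_r2_mean
  c0 <- params$r2_concentration
  entries <- lapply(groups, function(idx) {
    pairs <- utils::combn(idx, 2)
    data.frame(snp_a = snps$snp_id[pairs[1, ]],
               snp_b = snps$snp_id[pairs[2, ]],
               r2 = stats::rbeta(ncol(pairs), m * c0, (1 - m) * c0),
               dist_bp = abs(snps$pos[pairs[1, ]] - snps$pos[pairs[2, ]]),
               stringsAsFactors = FALSE)
  })
  ld_table(do.call(rbind, c(entries, list(make.row.names = FALSE))))
}

generate_catalog <- function(symbols, params) {
  sizes <- pmax(params$term_size_min,
                round(stats::rnorm(params$n_terms, params$term_size_mean,
                                   params$term_size_sd)))
  sizes <- pmin(sizes, length(symbols))
  terms <- lapply(sizes, function(n) sample(symbols, n))
  names(terms) <- sprintf("T%03d", seq_len(params$n_terms))
  functional_catalog(terms, universe = symbols)
}

generate_term_network <- function(symbols, catalog, params) {
  n <- length(symbols)
  membership <- vapply(catalog$terms, function(g) symbols %in% g,
                       logical(n))
  shares_term <- tcrossprod(membership * 1) > 0
  pair_idx <- which(upper.tri(shares_term), arr.ind = TRUE)
  p <- ifelse(shares_term[pair_idx], params$p_in, params$p_out)
  keep <- stats::runif(nrow(pair_idx)) < p
  pair_idx <- pair_idx[keep, , drop = FALSE]
  edges <- data.frame(
    gene_a = symbols[pair_idx[, 1]],
    gene_b = symbols[pair_idx[, 2]],
    weight = stats::runif(nrow(pair_idx), params$weight_range[1],
                          params$weight_range[2]),
    stringsAsFactors = FALSE)
  interaction_network(edges)
}

derive_subtypes <- function(catalog) {
  term_ids <- names(catalog$terms)
  half <- ceiling(length(term_ids) / 2)
  secretion_terms <- term_ids[seq_len(half)]
  resistance_terms <- setdiff(term_ids, secretion_terms)
  sec_genes <- unique(unlist(catalog$terms[secretion_terms]))
  res_genes <- unique(unlist(catalog$terms[resistance_terms]))
  genes <- union(sec_genes, res_genes)
  label <- ifelse(genes %in% sec_genes & genes %in% res_genes, "both",
                  ifelse(genes %in% sec_genes, "secretion_deficiency",
                         "insulin_resistance"))
  subtype_annotation(setNames(label, genes))
}

#' Parameters of a synthetic multi-population study
#'
#' Sharing between populations is modeled at two separable levels. Each
#' population picks `n_causal_terms` causal pathways; each pick comes from a
#' pool shared by all populations with probability `theta_func_share`,
#' otherwise from the population's private pool. Significant SNPs then fall
#' inside the causal pathways' gene ROIs; each causal hit is copied from a
#' fixed cross-population shared SNP list with probability
#' `theta_snp_share`, otherwise drawn fresh. This decouples pathway-level
#' from SNP-level sharing: high `theta_func_share` with low
#' `theta_snp_share` produces populations that agree on biology but not on
#' individual markers.
#'
#' @param k number of populations (default 5).
#' @param n_sig significant tagSNPs per population (default 100).
#' @param theta_func_share probability a causal term comes from the shared
#'   pool, in \[0, 1\].
#' @param theta_snp_share probability a causal SNP is copied from the shared
#'   causal-SNP list, in \[0, 1\].
#' @param noise_frac fraction of hits drawn uniformly from the whole SNP
#'   catalog (default 0.2).
#' @param n_shared_terms size of the shared causal-term pool.
#' @param n_private_terms private causal-term pool size per population.
#' @param n_causal_terms causal terms drawn per population.
#' @param disease label stored on the collection.
#' @param seed integer seed.
#' @return List of class `study_params`.
#' @export
study_params <- function(k = 5, n_sig = 100, theta_func_share = 0.5,
                         theta_snp_share = 0.5, noise_frac = 0.2,
                         n_shared_terms = 3, n_private_terms = 2,
                         n_causal_terms = 3, disease = "synthetic",
                         seed = 1) {
  stopifnot(k >= 2, n_sig >= 1,
            theta_func_share >= 0, theta_func_share <= 1,
            theta_snp_share >= 0, theta_snp_share <= 1,
            noise_frac >= 0, noise_frac <= 1)
  structure(as.list(environment()), class = "study_params")
}

roi_snp_index <- function(world) {
  models <- world$models
  snps <- world$snps
  out <- setNames(vector("list", nrow(models)), models$symbol)
  for (chr in unique(models$chrom)) {
    on_chr <- which(models$chrom == chr)
    snp_rows <- snps[snps$chrom == chr, , drop = FALSE]
    if (nrow(snp_rows) == 0) next
    q <- IRanges::IRanges(start = snp_rows$pos, width = 1L)
    subj <- IRanges::IRanges(start = models$roi_start[on_chr] + 1L,
                             end = models$roi_end[on_chr])
    ov <- IRanges::findOverlaps(q, subj)
    hits <- split(snp_rows$snp_id[S4Vectors::queryHits(ov)],
                  models$symbol[on_chr[S4Vectors::subjectHits(ov)]])
    out[names(hits)] <- hits
  }
  out
}

#' Generate a multi-population study over a synthetic world
#'
#' @param world a [generate_world()] result.
#' @param params a [study_params()] list.
#' @return Object of class `synthetic_study`: list with `collection` (a
#'   [study_collection()]) and `truth` (shared term pool, shared causal-SNP
#'   list, and per-population causal terms/genes/SNPs).
#' @export
generate_study <- function(world, params = study_params()) {
  set.seed(params$seed)
  if (params$n_sig > nrow(world$snps)) {
    stop("n_sig exceeds the number of SNPs in the world")
  }
  term_ids <- names(world$catalog$terms)
  if (params$n_shared_terms + params$k * params$n_private_terms >
      length(term_ids)) {
    stop("not enough catalog terms for the requested shared/private pools")
  }
  shared_pool <- sample(term_ids, params$n_shared_terms)
  remaining <- sample(setdiff(term_ids, shared_pool),
                      params$k * params$n_private_terms)
  private_pools <- split(remaining,
                         rep(seq_len(params$k), each = params$n_private_terms))
  gene2snps <- roi_snp_index(world)
  term_genes <- world$catalog$terms
  n_noise <- round(params$noise_frac * params$n_sig)
  n_causal <- params$n_sig - n_noise
  shared_genes <- unique(unlist(term_genes[shared_pool]))
  shared_roi_snps <- unique(unlist(gene2snps[shared_genes]))
  if (params$theta_snp_share > 0 && length(shared_roi_snps) < n_causal) {
    stop("causal ROIs contain fewer SNPs than required; ",
         "generate a larger world")
  }
  shared_snp_list <- sample(shared_roi_snps,
                            min(n_causal, length(shared_roi_snps)))
  all_snp_ids <- world$snps$snp_id
  codes <- sprintf("P%d", seq_len(params$k))
  truth <- list(shared_terms = sort(shared_pool),
                shared_snp_list = sort(shared_snp_list),
                populations = list())
  rows <- list()
  for (i in seq_len(params$k)) {
    n_shared_slots <- stats::rbinom(1, params$n_causal_terms,
                                    params$theta_func_share)
    n_shared_slots <- min(n_shared_slots, length(shared_pool))
    n_private_slots <- min(params$n_causal_terms - n_shared_slots,
                           length(private_pools[[i]]))
    causal_terms <- c(
      if (n_shared_slots > 0) sample(shared_pool, n_shared_slots),
      if (n_private_slots > 0) sample(private_pools[[i]], n_private_slots))
    causal_genes <- sort(unique(unlist(term_genes[causal_terms])))
    roi_pool <- unique(unlist(gene2snps[causal_genes]))
    n_copy <- stats::rbinom(1, n_causal, params$theta_snp_share)
    n_copy <- min(n_copy, length(shared_snp_list))
    copied <- if (n_copy > 0) sample(shared_snp_list, n_copy) else character(0)
    fresh_pool <- setdiff(roi_pool, copied)
    n_fresh <- n_causal - length(copied)
    if (length(fresh_pool) < n_fresh) {
      stop("causal ROIs contain fewer SNPs than required; ",
           "generate a larger world")
    }
    fresh <- if (n_fresh > 0) sample(fresh_pool, n_fresh) else character(0)
    causal_snps <- c(copied, fresh)
    noise_pool <- setdiff(all_snp_ids, causal_snps)
    noise <- if (n_noise > 0) sample(noise_pool, n_noise) else character(0)
    sig <- c(causal_snps, noise)
    idx <- match(sig, all_snp_ids)
    rows[[i]] <- data.frame(
      population = codes[i], snp_id = sig,
      chrom = world$snps$chrom[idx], pos = world$snps$pos[idx],
      pvalue = 10^-stats::runif(length(sig), 8, 20),
      stringsAsFactors = FALSE)
    truth$populations[[codes[i]]] <- list(
      causal_terms = sort(causal_terms),
      causal_genes = causal_genes,
      causal_snps = sort(causal_snps))
  }
  collection <- study_collection(do.call(rbind, rows),
                                 disease = params$disease)
  structure(list(collection = collection, truth = truth, params = params),
            class = "synthetic_study")
}
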