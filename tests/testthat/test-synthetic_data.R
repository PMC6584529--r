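# small world, sized for unit tests (analysis-scale defaults are exercised
# by the acceptance suite)
small_world <- function(seed = 1, ...) {
  generate_world(world_params(n_chrom = 2, chrom_length_bp = 4e6,
                              n_genes = 60, n_snps = 1200, n_terms = 12,
                              term_size_mean = 8, term_size_sd = 2,
                              seed = seed, ...))
}

test_that("worlds are internally consistent and deterministic per seed", {
  w1 <- small_world(5)
  w2 <- small_world(5)
  expect_identical(serialize(w1, NULL), serialize(w2, NULL))
  expect_false(identical(w1$snps, small_world(6)$snps))

  expect_true(all(w1$ld$r2 >= 0 & w1$ld$r2 <= 1))
  expect_true(all(w1$network$weight > 0))
  expect_true(all(unlist(w1$catalog$terms) %in% w1$models$symbol))
  expect_true(all(names(unclass(w1$subtypes)) %in% w1$models$symbol))
  # LD respects block bounds: no pair farther apart than the block size
  expect_true(all(w1$ld$dist_bp <= w1$params$ld_block_size_bp))
  # genes do not overlap within a chromosome
  for (chr in unique(w1$models$chrom)) {
    m <- w1$models[w1$models$chrom == chr, ]
    m <- m[order(m$tx_start), ]
    expect_true(all(utils::head(m$tx_end, -1) <= m$tx_start[-1]))
  }
})

test_that("with p_out = 0 every network edge joins genes sharing a term", {
  w <- small_world(7, p_out = 0)
  shares <- mapply(function(a, b) {
    any(vapply(w$catalog$terms, function(g) a %in% g && b %in% g,
               logical(1)))
  }, w$network$gene_a, w$network$gene_b)
  expect_true(all(shares))
})

test_that("within-term edge density exceeds background density", {
  dens <- vapply(1:5, function(seed) {
    w <- small_world(seed + 100)
    in_term <- mapply(function(a, b) {
      any(vapply(w$catalog$terms, function(g) a %in% g && b %in% g,
                 logical(1)))
    }, w$network$gene_a, w$network$gene_b)
    n <- nrow(w$models)
    share_pairs <- 0
    for (t in w$catalog$terms) share_pairs <- share_pairs + choose(length(t), 2)
    within <- sum(in_term) / share_pairs           # upper bound on denominator
    background <- sum(!in_term) / choose(n, 2)
    within / background
  }, numeric(1))
  expect_true(all(dens > 1))
})

test_that("studies hit the exact size contract and are duplicate-free", {
  w <- small_world(9)
  s <- generate_study(w, study_params(k = 3, n_sig = 40, seed = 2))
  expect_equal(population_codes(s$collection), c("P1", "P2", "P3"))
  for (p in s$collection$populations) {
    expect_equal(nrow(p), 40L)
    expect_false(any(duplicated(p$snp_id)))
  }
  truth <- s$truth$populations$P1
  expect_true(all(truth$causal_genes %in% w$models$symbol))
  expect_true(all(truth$causal_snps %in% w$snps$snp_id))
  # causal SNPs of the identical-term limit live inside causal-gene ROIs
  expect_true(all(truth$causal_terms %in% names(w$catalog$terms)))
})

test_that("full SNP sharing with no noise duplicates the sets exactly", {
  w <- small_world(10)
  s <- generate_study(w, study_params(
    k = 3, n_sig = 30, theta_func_share = 1, theta_snp_share = 1,
    noise_frac = 0, n_causal_terms = 2, n_shared_terms = 2, seed = 3))
  sets <- snp_sets(s$collection)
  m <- jaccard_overlap_matrix(sets)
  expect_true(all(m == 1))
})

test_that("fully private pathways with no sharing give near-zero overlap", {
  vals <- vapply(1:4, function(seed) {
    w <- small_world(seed + 200)
    s <- generate_study(w, study_params(
      k = 3, n_sig = 30, theta_func_share = 0, theta_snp_share = 0,
      noise_frac = 0, n_causal_terms = 2, n_private_terms = 2, seed = seed))
    m <- jaccard_overlap_matrix(snp_sets(s$collection))
    mean(m[upper.tri(m)])
  }, numeric(1))
  expect_lt(mean(vals), 0.05)
})

test_that("mean SNP-level overlap rises with the SNP-sharing parameter", {
  grid <- c(0, 0.5, 1)
  means <- vapply(grid, function(theta) {
    vals <- vapply(1:4, function(seed) {
      w <- small_world(seed + 300)
      s <- generate_study(w, study_params(
        k = 3, n_sig = 30, theta_func_share = 1, theta_snp_share = theta,
        noise_frac = 0.1, seed = seed))
      m <- jaccard_overlap_matrix(snp_sets(s$collection))
      mean(m[upper.tri(m)])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
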