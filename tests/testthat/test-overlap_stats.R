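empty_ld <- function() {
  ld_table(data.frame(snp_a = character(), snp_b = character(),
                      r2 = numeric(), dist_bp = integer()))
}

test_that("Jaccard matrices reproduce hand-computed overlaps", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"))
  m <- jaccard_overlap_matrix(sets, "snp")
  expect_equal(m["A", "B"], 0.5)
  expect_equal(diag(unclass(m)), c(A = 1, B = 1))
  expect_equal(jaccard_overlap_matrix(list(A = "x", B = "x"))["A", "B"], 1)
  expect_equal(jaccard_overlap_matrix(list(A = "x", B = "y"))["A", "B"], 0)
  expect_warning(
    m0 <- jaccard_overlap_matrix(list(A = character(0), B = character(0),
                                      C = "x")),
    "empty")
  expect_equal(m0["A", "B"], 0)
})

test_that("LD overlap matrix counts support-bridged tagSNPs", {
  coll <- study_collection(data.frame(
    population = rep(c("P1", "P2"), each = 2),
    snp_id = c("a", "b", "c", "d"), chrom = "chr1",
    pos = c(100, 10000, 12000, 50000)))
  qual <- ld_table(data.frame(snp_a = "b", snp_b = "c", r2 = 0.9,
                              dist_bp = 2000))
  m <- ld_overlap_matrix(coll, ld_support(coll, qual))
  expect_equal(m["P1", "P2"], 0.5) # |{b,c}| / |{a,b,c,d}|
  m0 <- ld_overlap_matrix(coll, ld_support(coll, empty_ld()))
  expect_equal(m0["P1", "P2"], 0)
  shared <- study_collection(data.frame(
    population = c("P1", "P2"), snp_id = "a", chrom = "chr1", pos = 100))
  expect_equal(
    ld_overlap_matrix(shared, ld_support(shared, empty_ld()))["P1", "P2"], 1)
})

test_that("cumulative overlap counts entities shared by at least l sets", {
  f <- cumulative_overlap(list(A = c("a", "b"), B = c("b", "c"), C = "b"))
  expect_equal(f$values, c(1, 1 / 3, 1 / 3))
  same <- cumulative_overlap(list(A = "x", B = "x", C = "x"))
  expect_equal(same$values, c(1, 1, 1))
  disjoint <- cumulative_overlap(list(A = "x", B = "y", C = "z"))
  expect_equal(disjoint$values, c(1, 0, 0))
  expect_error(cumulative_overlap(list(A = character(0))), "empty")
})

test_that("overlap matrices and functions satisfy their invariants randomly", {
  set.seed(61)
  for (rep in 1:40) {
    k <- sample(2:6, 1)
    sets <- random_entity_sets(k, 30, 15)
    m <- jaccard_overlap_matrix(sets)
    expect_equal(unclass(m), t(unclass(m)))
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(unname(diag(unclass(m))), rep(1, k))
    expect_equal(unclass(m), oracle_jaccard_matrix(sets), ignore_attr = TRUE)

    f <- cumulative_overlap(sets)
    expect_equal(f$values[1], 1)
    expect_true(all(diff(f$values) <= 1e-12))
    expect_true(all(f$values >= 0 & f$values <= 1))
    expect_equal(f$values, oracle_cumulative(sets))
  }
})

test_that("LD level dominates SNP level and degenerates exactly without LD", {
  set.seed(62)
  for (rep in 1:15) {
    k <- sample(2:4, 1)
    tab <- data.frame(
      population = rep(paste0("P", 1:k), each = 12),
      snp_id = sample(sprintf("s%02d", 1:30), 12 * k, replace = TRUE),
      chrom = "chr1", pos = NA)
    tab$pos <- as.integer(as.factor(tab$snp_id)) * 1000L
    tab <- tab[!duplicated(tab[, c("population", "snp_id")]), ]
    coll <- study_collection(tab)
    snp_m <- jaccard_overlap_matrix(snp_sets(coll), "snp")

    ld <- ld_table(random_ld_df(sprintf("s%02d", 1:30), 25))
    lam <- ld_overlap_matrix(coll, ld_support(coll, ld))
    expect_true(all(unclass(lam) - unclass(snp_m) >= -1e-12))

    lam0 <- ld_overlap_matrix(coll, ld_support(coll, empty_ld()))
    expect_equal(unclass(lam0), unclass(snp_m), ignore_attr = TRUE)
    f0 <- ld_cumulative_overlap(ld_support(coll, empty_ld()))
    expect_equal(f0$values, cumulative_overlap(snp_sets(coll))$values)
  }
})

test_that("subtype stratification tallies labels with an 'other' bucket", {
  ann <- subtype_annotation(c(g1 = "secretion_deficiency",
                              g2 = "insulin_resistance", g3 = "both"))
  counts <- stratify_by_subtype(list(A = c("g1", "g3"), B = character(0),
                                     C = c("g1", "g9")), ann)
  a <- counts[counts$population == "A", ]
  expect_equal(c(a$secretion_deficiency, a$insulin_resistance, a$both,
                 a$other), c(1, 0, 1, 0))
  b <- counts[counts$population == "B", ]
  expect_equal(sum(b[, -1]), 0)
  expect_equal(counts$other[counts$population == "C"], 1)
})
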