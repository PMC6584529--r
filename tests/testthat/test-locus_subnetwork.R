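snp_df <- function(ids, pos, chrom = "chr1") {
  data.frame(snp_id = ids, chrom = chrom, pos = pos,
             stringsAsFactors = FALSE)
}

net_from_edges <- function(...) {
  interaction_network(do.call(rbind, lapply(list(...), function(e) {
    data.frame(gene_a = e[[1]], gene_b = e[[2]], weight = as.numeric(e[[3]]))
  })))
}

test_that("loci are LD-partnership connected components", {
  snps <- snp_df(c("a", "b", "c"), c(100, 200, 5000))
  pm <- list(a = c("a", "b"), b = c("a", "b"), c = "c")
  loci <- define_loci(snps, pm)
  expect_equal(lapply(loci, `[[`, "member_snps"), list(c("a", "b"), "c"))
  # no LD pairs: one singleton locus per SNP
  pm0 <- list(a = "a", b = "b", c = "c")
  expect_equal(length(define_loci(snps, pm0)), 3L)
})

test_that("loci match an independent union-find on random LD graphs", {
  set.seed(51)
  for (rep in 1:25) {
    ids <- sprintf("s%02d", 1:20)
    snps <- snp_df(ids, sample.int(100000, 20))
    n_edges <- sample(0:15, 1)
    edges <- if (n_edges > 0) {
      cbind(sample(ids, n_edges, replace = TRUE),
            sample(ids, n_edges, replace = TRUE))
    } else {
      NULL
    }
    if (!is.null(edges)) edges <- edges[edges[, 1] != edges[, 2], ,
                                        drop = FALSE]
    pm <- setNames(as.list(ids), ids)
    if (!is.null(edges) && nrow(edges) > 0) {
      for (r in seq_len(nrow(edges))) {
        pm[[edges[r, 1]]] <- union(pm[[edges[r, 1]]], edges[r, 2])
        pm[[edges[r, 2]]] <- union(pm[[edges[r, 2]]], edges[r, 1])
      }
    }
    got <- lapply(define_loci(snps, pm), `[[`, "member_snps")
    want <- oracle_components(ids, edges)
    expect_setequal(got, want)
  }
})

test_that("candidate genes come from ROI containment; empty loci are dropped", {
  models <- build_roi(gene_models(data.frame(
    symbol = "G1", chrom = "chr1", strand = "+",
    tx_start = 200000L, tx_end = 300000L)))
  snps <- snp_df(c("a", "b"), c(150001, 950000))
  loci <- define_loci(snps, list(a = "a", b = "b"))
  expect_warning(cand <- candidate_genes(loci, models, snps), "dropped")
  expect_equal(length(cand), 1L)
  expect_equal(cand[["1"]], "G1")
  expect_equal(attr(cand, "dropped"), 2L)
})

test_that("coherence score sums edge weights over selected pairs", {
  net <- net_from_edges(list("g1", "g3", 1))
  expect_equal(coherence_score(c("g1", "g3"), net), 1)
  expect_equal(coherence_score(c("g2", "g4"), net), 0)
  clique <- net_from_edges(
    list("a", "b", 1), list("a", "c", 2), list("a", "d", 3),
    list("b", "c", 4), list("b", "d", 5), list("c", "d", 6))
  expect_equal(coherence_score(c("a", "b", "c", "d"), clique), 21)
  # adding a positive edge between selected genes can only raise the score
  more <- net_from_edges(list("g1", "g3", 1), list("g1", "g2", 0.5))
  expect_gte(coherence_score(c("g1", "g2", "g3"), more),
             coherence_score(c("g1", "g2", "g3"), net))
})

test_that("optimize_selection finds the optimum and breaks ties lexically", {
  net <- net_from_edges(list("g1", "g3", 1))
  sol <- optimize_selection(list(`1` = c("g1", "g2"), `2` = c("g3", "g4")),
                            net)
  expect_equal(unname(sol$selection), c("g1", "g3"))
  expect_equal(sol$score, 1)
  expect_equal(sol$method, "exhaustive")

  # no edges at all: score 0, lexicographically smallest tuple
  empty_net <- interaction_network(
    data.frame(gene_a = "x", gene_b = "y", weight = 1))
  sol0 <- optimize_selection(list(`1` = c("g2", "g1"), `2` = c("g4", "g3")),
                             empty_net)
  expect_equal(unname(sol0$selection), c("g1", "g3"))
  expect_equal(sol0$score, 0)
  expect_error(optimize_selection(list(), net), "no loci")
})

test_that("exhaustive search matches full enumeration on random instances", {
  set.seed(52)
  for (rep in 1:15) {
    genes <- sprintf("g%02d", 1:9)
    cand <- split(genes, rep(1:3, each = 3))
    names(cand) <- as.character(1:3)
    pairs <- t(combn(genes, 2))
    keep <- runif(nrow(pairs)) < 0.4
    net <- interaction_network(data.frame(
      gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
      weight = round(runif(sum(keep), 0.1, 2), 3)))
    sol <- optimize_selection(cand, net, method = "exhaustive")
    want <- oracle_best_selection(cand, net)
    expect_equal(sol$score, want$score, tolerance = 1e-9)
  }
})

test_that("annealing is reproducible and matches the exhaustive optimum", {
  set.seed(53)
  for (rep in 1:10) {
    genes <- sprintf("g%02d", 1:12)
    cand <- split(genes, rep(1:4, each = 3))
    names(cand) <- as.character(1:4)
    pairs <- t(combn(genes, 2))
    keep <- runif(nrow(pairs)) < 0.35
    net <- interaction_network(data.frame(
      gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
      weight = round(runif(sum(keep), 0.1, 2), 3)))
    exact <- optimize_selection(cand, net, method = "exhaustive")
    ann <- optimize_selection(cand, net, method = "anneal", seed = rep)
    expect_equal(ann$score, exact$score, tolerance = 1e-9)
    ann2 <- optimize_selection(cand, net, method = "anneal", seed = rep)
    expect_identical(ann$selection, ann2$selection)
    expect_identical(ann$gene_scores, ann2$gene_scores)
  }
})

test_that("subnetwork genes exclude isolated forced picks", {
  net <- net_from_edges(list("g1", "g3", 1))
  sel <- c(`1` = "g1", `2` = "g3", `3` = "g9")
  expect_equal(selected_subnetwork_genes(sel, net), c("g1", "g3"))
  expect_equal(selected_subnetwork_genes(sel, net, connected_only = FALSE),
               c("g1", "g3", "g9"))
})

test_that("population_subnetwork composes the locus pipeline", {
  starts <- c(1900000, 2000000, 4000000, 4100000)
  models <- build_roi(gene_models(data.frame(
    symbol = c("g1", "g2", "g3", "g4"), chrom = "chr1",
    strand = "+", tx_start = starts, tx_end = starts + 50000)))
  # two loci; g1/g2 compete at locus 1, g3/g4 at locus 2; sole edge g1-g3
  coll <- study_collection(data.frame(
    population = c("A", "A", "B", "B"),
    snp_id = c("s1", "s2", "s3", "s4"), chrom = "chr1",
    pos = c(1950000, 4050000, 1950000, 4050000)))
  net <- net_from_edges(list("g1", "g3", 1))
  empty_ld <- ld_table(data.frame(snp_a = character(), snp_b = character(),
                                  r2 = numeric(), dist_bp = integer()))
  out <- population_subnetwork(coll, empty_ld, models, net)
  expect_equal(out$sets$A, c("g1", "g3"))
  expect_equal(out$sets$B, c("g1", "g3"))

  # singleton candidate loci force the genes deterministically
  coll2 <- study_collection(data.frame(
    population = c("A", "A", "B"), snp_id = c("s1", "s2", "s3"),
    chrom = "chr1", pos = c(1020000, 4020000, 1020000)))
  models2 <- build_roi(gene_models(data.frame(
    symbol = c("g1", "g3"), chrom = "chr1", strand = "+",
    tx_start = c(1e6, 4e6), tx_end = c(1e6, 4e6) + 50000)))
  out2 <- population_subnetwork(coll2, empty_ld, models2, net)
  expect_equal(out2$sets$A, c("g1", "g3"))
  expect_equal(out2$solutions$A$gene_scores, c(g1 = 1, g3 = 1))
})

test_that("combined run on nested loci scores at least each single population", {
  models <- build_roi(gene_models(data.frame(
    symbol = c("g1", "g2", "g3"), chrom = "chr1", strand = "+",
    tx_start = c(1e6, 3e6, 5e6), tx_end = c(1e6, 3e6, 5e6) + 50000)))
  net <- net_from_edges(list("g1", "g2", 1), list("g2", "g3", 2),
                        list("g1", "g3", 0.5))
  empty_ld <- ld_table(data.frame(snp_a = character(), snp_b = character(),
                                  r2 = numeric(), dist_bp = integer()))
  # population A's loci are a subset of population B's
  coll <- study_collection(data.frame(
    population = c("A", "B", "B", "B"),
    snp_id = c("s1", "s1", "s2", "s3"), chrom = "chr1",
    pos = c(1020000, 1020000, 3020000, 5020000)))
  combined <- combined_network_export(coll, empty_ld, models, net)
  solo <- population_subnetwork(coll, empty_ld, models, net)
  for (sol in solo$solutions) {
    expect_gte(combined$solution$score, sol$score)
  }
  expect_true(all(c("gene", "populations") %in% names(combined$nodes)))
  expect_true(all(c("populations_a", "populations_b") %in%
                    names(combined$edges)))
  # the strong cross-population edge is exported with its weight
  expect_true(any(combined$edges$gene_a == "g2" &
                    combined$edges$gene_b == "g3" &
                    combined$edges$weight == 2))
})
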