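make_snp_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("load_study parses per-population sets and deduplicates probes", {
  rows <- data.frame(
    population = c("A", "A", "B", "B"),
    snp_id = c("rs1", "rs2", "rs3", "rs4"),
    chrom = "chr1", pos = c(100, 200, 300, 400), pvalue = 1e-8)
  coll <- load_study(make_snp_tsv(rows))
  expect_s3_class(coll, "study_collection")
  expect_equal(population_codes(coll), c("A", "B"))
  expect_equal(vapply(snp_sets(coll), length, integer(1)),
               c(A = 2L, B = 2L))

  # rs1 listed three times in A counts once, keeping the smallest p-value
  rows2 <- data.frame(
    population = c(rep("A", 4), "B", "B"),
    snp_id = c("rs1", "rs1", "rs1", "rs2", "rs3", "rs4"),
    chrom = "chr1", pos = c(100, 100, 100, 200, 300, 400),
    pvalue = c(0.1, 0.01, 0.05, 0.2, 0.3, 0.4))
  coll2 <- load_study(make_snp_tsv(rows2))
  expect_equal(nrow(coll2$populations$A), 2L)
  expect_equal(coll2$populations$A$pvalue[coll2$populations$A$snp_id == "rs1"],
               0.01)
})

test_that("load_study rejects bad input with clear errors", {
  rows <- data.frame(population = "A", snp_id = "rs1", chrom = "chr1",
                     pos = 1)
  expect_error(load_study(make_snp_tsv(rows)), "at least 2")
  expect_error(load_study(make_snp_tsv(rows[0, ])), "at least 2")
  expect_error(load_study(make_snp_tsv(rows[, -4])), "pos")
  bad_pos <- data.frame(population = c("A", "B"), snp_id = c("rs1", "rs2"),
                        chrom = "chr1", pos = c("100", "12x4"))
  expect_error(load_study(make_snp_tsv(bad_pos)), "malformed position")
})

test_that("dedup_population keeps min p-value and flags coordinate conflicts", {
  snps <- data.frame(snp_id = c("rs1", "rs1", "rs2"), chrom = "chr1",
                     pos = c(100, 100, 200), pvalue = c(0.1, 0.01, 0.5))
  out <- dedup_population(snps)
  expect_equal(out$snp_id, c("rs1", "rs2"))
  expect_equal(out$pvalue, c(0.01, 0.5))
  expect_equal(nrow(dedup_population(snps[0, ])), 0L)
  conflict <- data.frame(snp_id = c("rs1", "rs1"), chrom = c("chr1", "chr2"),
                         pos = c(100, 200), pvalue = NA_real_)
  expect_error(dedup_population(conflict), "rs1")
})

test_that("load_study is row-order invariant and round-trips through TSV", {
  set.seed(11)
  rows <- data.frame(
    population = sample(c("A", "B", "C"), 30, replace = TRUE),
    snp_id = sprintf("rs%d", sample.int(20, 30, replace = TRUE)),
    chrom = "chr1", pos = NA, pvalue = round(runif(30), 3))
  rows$pos <- as.integer(as.factor(rows$snp_id)) * 50L
  rows$pvalue <- ave(rows$pvalue, rows$snp_id, FUN = min) # keep records consistent
  coll <- load_study(make_snp_tsv(rows))
  shuffled <- load_study(make_snp_tsv(rows[sample(nrow(rows)), ]))
  expect_equal(coll, shuffled)

  out <- tempfile(fileext = ".tsv")
  write_study(coll, out)
  expect_equal(load_study(out), coll)

  # |S| equals the brute-force union size
  expect_equal(length(snp_union(coll)),
               length(unique(unlist(lapply(coll$populations,
                                           function(p) p$snp_id)))))
})

test_that("gene models load from BED6 with union-merge, clamping and strand", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10000\t20000\tG1\t0\t+",
               "chr1\t15000\t30000\tG1\t0\t+",
               "chr1\t500000\t600000\tG2\t0\t-"), bed)
  models <- load_gene_models(bed)
  expect_equal(nrow(models), 2L)
  g1 <- models[models$symbol == "G1", ]
  expect_equal(c(g1$tx_start, g1$tx_end), c(10000L, 30000L))
  expect_equal(c(g1$roi_start, g1$roi_end), c(0L, 40000L)) # clamped at origin
  g2 <- models[models$symbol == "G2", ]
  expect_equal(c(g2$roi_start, g2$roi_end), c(490000L, 700000L))

  writeLines("chr1\t100\t50\tG1\t0\t+", bed)
  expect_error(load_gene_models(bed), "start >= end")
  writeLines("chr1\t100\t500\tG1\t0", bed)
  expect_error(load_gene_models(bed), "BED6")
})

test_that("GMT catalogs load with union universe and last-wins duplicates", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("T1\tna\tg1\tg2\tg3", "T2\tna\tg3\tg4"), gmt)
  cat1 <- load_gene_sets(gmt)
  expect_equal(length(cat1$terms), 2L)
  expect_equal(length(cat1$universe), 4L)

  writeLines(c("T1\tna\tg1", "T1\tna\tg2"), gmt)
  expect_warning(cat2 <- load_gene_sets(gmt), "duplicate term")
  expect_equal(cat2$terms$T1, "g2")

  writeLines(c("T1\tna\tg1", "T2\tna"), gmt)
  expect_warning(cat3 <- load_gene_sets(gmt), "no member genes")
  expect_equal(names(cat3$terms), "T1")

  writeLines(character(0), gmt)
  cat4 <- load_gene_sets(gmt)
  expect_equal(length(cat4$terms), 0L)

  rt <- tempfile(fileext = ".gmt")
  write_gene_sets(cat1, rt)
  expect_equal(load_gene_sets(rt), cat1)
})

test_that("network edge lists collapse reciprocals, drop loops, round-trip", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tweight", "a\tb\t1", "b\ta\t2"), tsv)
  net <- load_network(tsv)
  expect_equal(nrow(net), 1L)
  expect_equal(net$weight, 2)

  writeLines(c("gene_a\tgene_b\tweight", "a\ta\t1"), tsv)
  expect_warning(net2 <- load_network(tsv), "self-loop")
  expect_equal(nrow(net2), 0L)

  writeLines(c("gene_a\tgene_b\tweight", "a\tb\t1", "b\tc\t1", "c\ta\t1"),
             tsv)
  net3 <- load_network(tsv)
  expect_equal(nrow(net3), 3L)
  expect_equal(attr(net3, "nodes"), c("a", "b", "c"))

  writeLines(c("gene_a\tgene_b\tweight", "a\tb\t-1"), tsv)
  expect_error(load_network(tsv), "weight")

  writeLines(c("gene_a\tgene_b", "a\tb"), tsv) # absent weight defaults to 1
  expect_equal(load_network(tsv)$weight, 1)

  rt <- tempfile(fileext = ".tsv")
  write_network(net3, rt)
  expect_equal(load_network(rt), net3)
})

test_that("subtype annotations restrict labels to the three-value domain", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tsubtype", "g1\tsecretion_deficiency", "g2\tboth"), tsv)
  ann <- load_subtype_annotation(tsv)
  expect_equal(unname(unclass(ann)["g2"]), "both")
  writeLines(c("gene\tsubtype", "g1\tmystery"), tsv)
  expect_error(load_subtype_annotation(tsv), "mystery")
})
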