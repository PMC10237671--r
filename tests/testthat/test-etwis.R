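# Small meta-analysis table over a null scan, reused across set tests.
null_meta <- function(n = 400, n_genes = 12, seed = 1) {
  nd <- null_dataset(n, n_genes, seed = seed)
  sc <- run_pairwise_scan(nd, nd$coords)
  meta_analyze(list(d = sc))
}

test_that("GMT parsing deduplicates members and enforces minimum size", {
  td <- withr::local_tempdir()
  gmt <- file.path(td, "sets.gmt")
  writeLines(c(
    paste(c("setA", "desc", "g1", "g2", "g2"), collapse = "\t"),
    paste(c("setB", "desc", sprintf("h%02d", 1:9)), collapse = "\t"),
    paste(c("setC", "desc", sprintf("k%02d", 1:12)), collapse = "\t")),
    gmt)
  expect_message(sets <- read_gene_sets(gmt), "excluded")
  # setA deduplicates to 2 members (below min), setB has 9: both excluded
  expect_equal(names(sets), "setC")
  expect_equal(length(sets$setC$members), 12)

  sets2 <- suppressMessages(read_gene_sets(gmt, min_size = 2))
  expect_equal(length(sets2$setA$members), 2)

  writeLines("badline\tonly2fields", file.path(td, "bad.gmt"))
  expect_error(read_gene_sets(file.path(td, "bad.gmt")), "line 1")
  writeLines(character(0), file.path(td, "empty.gmt"))
  expect_error(read_gene_sets(file.path(td, "empty.gmt")), "empty")
})

test_that("GMT round trip agrees with the fgsea reader", {
  skip_if_not_installed("fgsea")
  td <- withr::local_tempdir()
  path <- file.path(td, "x.gmt")
  sets <- list(s1 = list(name = "s1", category = "c",
                         members = sprintf("g%02d", 1:15)),
               s2 = list(name = "s2", category = "c",
                         members = sprintf("g%02d", 5:20)))
  write_gmt(sets, path)
  ours <- read_gene_sets(path)
  theirs <- fgsea::gmtPathways(path)
  expect_equal(lapply(ours, `[[`, "members"), theirs[names(ours)])
})

test_that("chi-squared set statistic sums retained squared Z-scores", {
  mt <- null_meta(seed = 2)
  genes <- sort(unique(c(mt$gene1, mt$gene2)))[1:5]
  res <- set_statistic_chi2(mt, list(name = "s", members = genes))
  keep <- mt$gene1 %in% genes & mt$gene2 %in% genes & !nzchar(mt$flags)
  expect_equal(res$m_pairs, sum(keep))
  expect_equal(res$S, sum(mt$z_meta[keep]^2), tolerance = 1e-12)
  expect_true(res$m_pairs <= choose(res$n_genes_used, 2))

  # chi-square tail against the normal-tail oracle for one pair
  one <- data.frame(gene1 = "a", gene2 = "b", z_meta = sqrt(3.8415),
                    flags = "")
  r1 <- set_statistic_chi2(one, c("a", "b"))
  expect_equal(r1$p_chi2, 2 * pnorm(-sqrt(3.8415)), tolerance = 1e-10)
  expect_lt(abs(r1$p_chi2 - 0.05), 1e-4)

  # zero Z: S = 0, p = 1
  zero <- data.frame(gene1 = "a", gene2 = "b", z_meta = 0, flags = "")
  r0 <- set_statistic_chi2(zero, c("a", "b"))
  expect_equal(r0$S, 0)
  expect_equal(r0$p_chi2, 1)

  # all pairs filtered: untestable
  filt <- data.frame(gene1 = "a", gene2 = "b", z_meta = 1,
                     flags = "proximal_1mb")
  expect_true(is.na(set_statistic_chi2(filt, c("a", "b"))$p_chi2))
})

test_that("resampling p-value floors at 1/(B+1) and validates input", {
  mt <- null_meta(n_genes = 14, seed = 3)
  genes <- sort(unique(c(mt$gene1, mt$gene2)))
  # plant an extreme set: inflate Z of all pairs within the first 4 genes
  boost <- mt$gene1 %in% genes[1:4] & mt$gene2 %in% genes[1:4]
  mt$z_meta[boost] <- 10
  rs <- resampling_pvalue(mt, genes[1:4], B = 99, matching = "uniform",
                          seed = 4)
  expect_equal(rs$p, 1 / 100)
  expect_true(rs$at_floor)

  expect_error(resampling_pvalue(mt, genes[1:4], B = 0), "at least 1")
  expect_error(resampling_pvalue(mt, c("nope1", "nope2"), B = 10),
               "fewer than 2")
  expect_error(resampling_pvalue(mt, genes[1:4], B = 10,
                                 matching = "variant_bins"),
               "variant_counts")
})

test_that("variant-count matching preserves the bin composition", {
  mt <- null_meta(n_genes = 16, seed = 5)
  genes <- sort(unique(c(mt$gene1, mt$gene2)))
  vc <- stats::setNames(rep(c(5L, 50L), each = 8), genes)
  rs <- resampling_pvalue(mt, genes[c(1, 2, 9, 10)], B = 50,
                          matching = "variant_bins", variant_counts = vc,
                          bins = 2, seed = 6)
  expect_true(is.finite(rs$p))
  expect_equal(rs$m_pairs, sum(mt$gene1 %in% genes[c(1, 2, 9, 10)] &
                                 mt$gene2 %in% genes[c(1, 2, 9, 10)] &
                                 !nzchar(mt$flags)))
})

test_that("BH q-values match the hand-executed step-up", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  q <- fdr_bh(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  # hand-executed step-up at rank 3: min over ranks >= 3 of p * 8 / rank
  expect_equal(q[3], 0.0672, tolerance = 1e-12)
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.5, 0)), "0, 1")
})

test_that("etwis driver screens all sets and ranks consistently", {
  mt <- null_meta(n_genes = 14, seed = 7)
  genes <- sort(unique(c(mt$gene1, mt$gene2)))
  boost <- mt$gene1 %in% genes[1:5] & mt$gene2 %in% genes[1:5]
  mt$z_meta[boost] <- 6
  sets <- list(hot = list(name = "hot", category = "x",
                          members = genes[1:5]),
               cold = list(name = "cold", category = "x",
                           members = genes[6:11]))
  res <- etwis(mt, sets, matching = "uniform", seed = 8)
  expect_equal(nrow(res), 2)
  expect_lt(res$p_chi2[res$set == "hot"], res$p_chi2[res$set == "cold"])
  expect_true(all(res$q >= res$p_chi2 - 1e-15))
})
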