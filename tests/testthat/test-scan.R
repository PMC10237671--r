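test_that("interaction test matches the generic least-squares solver", {
  set.seed(1)
  for (rep in 1:25) {
    n <- sample(30:200, 1)
    t1 <- rnorm(n); t2 <- rnorm(n)
    y <- 0.2 * t1 - 0.1 * t2 + 0.3 * t1 * t2 + rnorm(n)
    it <- interaction_test(y, t1, t2)
    sm <- summary(lm(y ~ t1 * t2))$coefficients
    expect_equal(it$beta_int, sm["t1:t2", 1], tolerance = 1e-8)
    expect_equal(it$se, sm["t1:t2", 2], tolerance = 1e-8)
    expect_equal(it$p, sm["t1:t2", 4], tolerance = 1e-8)
  }
})

test_that("interaction test recovers a planted effect and is symmetric", {
  set.seed(2)
  n <- 50000
  t1 <- rnorm(n); t2 <- rnorm(n)
  y <- 0.5 * t1 * t2 + rnorm(n)
  it <- interaction_test(y, t1, t2)
  expect_lt(abs(it$beta_int - 0.5), 3 * it$se)

  sw <- interaction_test(y, t2, t1)
  expect_equal(sw$beta_int, it$beta_int, tolerance = 1e-10)
  expect_equal(sw$se, it$se, tolerance = 1e-10)
  expect_equal(sw$p, it$p, tolerance = 1e-10)
})

test_that("collinear designs are flagged, or pivoted on request", {
  set.seed(3)
  t1 <- rnorm(100)
  y <- 0.2 * t1 + rnorm(100)
  flagged <- interaction_test(y, t1, t1)
  expect_true(flagged$singular)
  expect_true(is.na(flagged$p))

  piv <- interaction_test(y, t1, t1, on_collinear = "pivot")
  # pivoted fit tests the quadratic term in y ~ t1 + t1^2
  sm <- summary(lm(y ~ t1 + I(t1^2)))$coefficients
  expect_equal(piv$beta_int, sm[3, 1], tolerance = 1e-8)
  expect_equal(piv$p, sm[3, 4], tolerance = 1e-8)
})

test_that("under the global null the rejection rate matches alpha", {
  set.seed(4)
  n <- 500; reps <- 4000
  Y <- matrix(rnorm(n * reps), n)
  T1 <- matrix(rnorm(n * reps), n)
  T2 <- matrix(rnorm(n * reps), n)
  p <- interaction_test_many(Y, T1, T2)$p
  for (a in c(0.05, 0.01, 0.001)) {
    expect_lt(abs(mean(p < a) - a), 3 * sqrt(a * (1 - a) / reps))
  }
})

test_that("pair filters drop correlated and proximal pairs with reasons", {
  f1 <- pair_filter("1", "2", 1e6, 5e6, r_expr = 0.06)
  expect_false(f1$keep)
  expect_equal(f1$reasons, "correlated_expression")

  f2 <- pair_filter("3", "3", 1e6, 15e5, r_expr = 0.0)
  expect_false(f2$keep)
  expect_equal(f2$reasons, "proximal_1mb")

  f3 <- pair_filter("1", "2", 1e6, 5e6, r_expr = 0.01)
  expect_true(f3$keep)

  # boundary: exactly 1 Mb apart is kept; |r| exactly 0.05 is kept
  f4 <- pair_filter("3", "3", 1e6, 2e6, r_expr = 0.05)
  expect_true(f4$keep)

  expect_error(pair_filter(NA, "1", 1, 2, 0), "coordinates")
})

test_that("the scan equals direct per-pair calls and is chunk-invariant", {
  nd <- null_dataset(400, 6, seed = 5)
  full <- run_pairwise_scan(nd, nd$coords)
  expect_equal(nrow(full), 15)

  # bit-identical to calling interaction_test pair by pair
  for (k in c(1, 7, 15)) {
    pr <- pair_from_linear_index(k, 6)
    it <- interaction_test(nd$y_resid, nd$T_resid[, pr[1]],
                           nd$T_resid[, pr[2]])
    expect_equal(full$beta_int[k], it$beta_int, tolerance = 1e-10)
    expect_equal(full$se[k], it$se, tolerance = 1e-10)
  }

  # chunked runs concatenate to the full result for any chunk count
  chunked <- do.call(rbind, lapply(1:7, function(cid) {
    run_pairwise_scan(nd, nd$coords, chunks = 7, chunk_id = cid)
  }))
  rownames(chunked) <- NULL
  expect_equal(chunked, full)
})

test_that("scan output is invariant to gene input order up to relabeling", {
  nd <- null_dataset(300, 5, seed = 6)
  full <- run_pairwise_scan(nd, nd$coords)
  perm <- c(3, 1, 5, 2, 4)
  nd2 <- list(y_resid = nd$y_resid, T_resid = nd$T_resid[, perm])
  full2 <- run_pairwise_scan(nd2, nd$coords)
  key <- function(df) {
    k1 <- pmin(df$gene1, df$gene2); k2 <- pmax(df$gene1, df$gene2)
    ord <- order(k1, k2)
    data.frame(k1 = k1[ord], k2 = k2[ord], p = df$p[ord],
               beta = abs(df$beta_int[ord]))
  }
  expect_equal(key(full), key(full2), tolerance = 1e-10)
})

test_that("zero-variance genes are flagged, not fatal, in scan mode", {
  nd <- null_dataset(200, 4, seed = 7)
  nd$T_resid[, 2] <- 0
  res <- run_pairwise_scan(nd, nd$coords)
  bad <- res$gene1 == "g002" | res$gene2 == "g002"
  expect_true(all(grepl("zero_variance", res$flags[bad])))
  expect_true(all(is.na(res$p[bad])))
  expect_true(all(!is.na(res$p[!bad])))
})

test_that("single-predictor scan matches lm and recovers main effects", {
  set.seed(8)
  n <- 2000
  E <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  y <- 0.3 * E[, 1] + rnorm(n)
  res <- run_single_predictor_scan(list(y_resid = y, T_resid = E))
  sm <- summary(lm(y ~ E[, 1]))$coefficients
  expect_equal(res$beta[1], sm[2, 1], tolerance = 1e-8)
  expect_equal(res$p[1], sm[2, 4], tolerance = 1e-8)
  expect_lt(abs(res$beta[1] - 0.3), 3 * res$se[1])
})

test_that("null single-predictor p-values are uniform", {
  set.seed(9)
  n <- 300; reps <- 2000
  E <- matrix(rnorm(n * reps), n)
  y <- rnorm(n)
  res <- run_single_predictor_scan(list(y_resid = y, T_resid = E))
  expect_gt(suppressWarnings(ks.test(res$p, "punif"))$p.value, 0.01)
})

test_that("scan results round-trip through gzip TSV", {
  nd <- null_dataset(150, 4, seed = 10)
  res <- run_pairwise_scan(nd, nd$coords)
  path <- withr::local_tempfile(fileext = ".tsv.gz")
  write_scan_results(res, path)
  back <- read_scan_results(path)
  expect_equal(back$p, res$p, tolerance = 1e-12)
  expect_equal(back$flags, res$flags)
})

test_that("SNP window selection is inclusive and chromosome-aware", {
  v <- data.frame(variant_id = c("a", "b", "c", "d"),
                  chrom = c("1", "1", "1", "2"),
                  pos = c(5e5, 1e6, 15e5 + 1, 5e5))
  got <- snp_window_variants(v, chrom = "1", tss = 1e6, window = 5e5)
  expect_equal(got, c("a", "b")) # c is 1 bp outside; d on another chrom
})
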