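# Reduced-size runs of the calibration experiments; the full-size study
# conditions run in the acceptance suite.

test_that("power grid: monotone in N, and error never helps", {
  rep_n <- 400L
  pg <- power_grid(n_grid = c(2000, 8000), pve_grid = 0.005,
                   reps = rep_n, alphas = 0.05, error = FALSE, seed = 3)
  lo <- pg$rejection_rate[pg$n == 2000]
  hi <- pg$rejection_rate[pg$n == 8000]
  expect_gt(hi, lo - 2 * sqrt(0.25 / rep_n))

  # paired seeds: with-error power cannot exceed no-error power by > 2 SE
  pe <- power_grid(n_grid = 8000, pve_grid = 0.005, reps = rep_n,
                   alphas = 0.05, error = TRUE, seed = 3)
  se2 <- 2 * sqrt(hi * (1 - hi) / rep_n + 0.25 / rep_n)
  expect_lt(pe$rejection_rate, hi + se2)

  # power at a stringent alpha never exceeds power at 0.05 (same cell)
  pa <- power_grid(n_grid = 4000, pve_grid = 0.005, reps = rep_n,
                   alphas = c(0.05, 5.86e-10), error = FALSE, seed = 4)
  expect_lte(pa$rejection_rate[pa$alpha < 0.05],
             pa$rejection_rate[pa$alpha == 0.05])

  expect_warning(power_grid(n_grid = 500, pve_grid = 0, reps = 50,
                            alphas = 0.05, error = FALSE, seed = 1),
                 "100 replicates")
  expect_error(power_grid(n_grid = numeric(0), pve_grid = 0), "empty")
})

test_that("rejection-rate cells are reproducible bit-exactly from the seed", {
  a <- power_grid(n_grid = 1000, pve_grid = 0.005, reps = 150,
                  alphas = 0.05, error = TRUE, seed = 11)
  b <- power_grid(n_grid = 1000, pve_grid = 0.005, reps = 150,
                  alphas = 0.05, error = TRUE, seed = 11)
  expect_identical(a$rejection_rate, b$rejection_rate)
})

test_that("gaussian expression never inflates; linked noisy scores do", {
  reps <- 400L
  se3 <- 3 * sqrt(0.05 * 0.95 / reps)
  gz <- ld_false_positive_experiment(
    n = 2000, expr_mode = "gaussian", snps_per_gene = 2, ld = c(0, 1),
    error_levels = c(1, 0.1), reps = reps, alphas = 0.05, seed = 5)
  expect_true(all(abs(gz$rejection_rate - 0.05) < se3 + 0.01))

  pg <- ld_false_positive_experiment(
    n = 2000, expr_mode = "pgs", snps_per_gene = 2, ld = c(0, 1),
    error_levels = c(1, 0.1), reps = reps, alphas = 0.05, seed = 5)
  unl <- pg[pg$ld == 0, ]
  expect_true(all(abs(unl$rejection_rate - 0.05) < se3 + 0.01))
  inflated <- pg[pg$ld == 1 & pg$accuracy < 1, ]
  expect_gt(inflated$rejection_rate, 0.05 + se3)
})

test_that("causal SNP-by-SNP interactions leak into the expression test", {
  cs <- causal_snp_experiment(n = 1500, reps = 120, effect = 0.3,
                              choose = c("max_ld", "min_ld"), seed = 6)
  r_max <- cs$rejection_rate[cs$choose == "max_ld"]
  r_min <- cs$rejection_rate[cs$choose == "min_ld"]
  # strongly linked causal SNPs are tagged by the expression score
  expect_gt(r_max, 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
  # and the leak grows with the causal SNPs' LD scores
  expect_gt(r_max, r_min)
})

test_that("alpha determination matches the order-statistic closed form", {
  ad <- alpha_determination(G = 50, n_studies = 400, n = 300, seed = 7)
  closed <- 1 - 0.95^(1 / 50)
  expect_equal(ad$closed_form, closed)
  # compare on the probability-integral-transformed scale, where the
  # 5th percentile of F(min p) is exactly 0.05 and its MC SE is binomial
  u <- 1 - (1 - ad$min_p)^50
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(quantile(u, 0.05, names = FALSE) - 0.05), 3 * se)
  # equivalently, the implied alpha sits near the closed form
  dens <- 50 * (1 - closed)^49
  expect_lt(abs(ad$alpha - closed), 3 * se / dens)

  # G = 1: the 5th percentile of a single uniform p is ~ 0.05
  ad1 <- alpha_determination(G = 1, n_studies = 400, n = 200, seed = 8)
  expect_lt(abs(ad1$alpha - 0.05), 0.02)

  expect_warning(alpha_determination(G = 5, n_studies = 10, n = 200,
                                     seed = 9),
                 "unstable")
})

test_that("implied alpha shrinks as the number of tests grows", {
  alphas <- vapply(c(10, 100), function(G) {
    alpha_determination(G = G, n_studies = 60, n = 300, seed = 10)$alpha
  }, numeric(1))
  expect_true(diff(alphas) < 0)
})

test_that("K-S uniformity diagnostics behave at both extremes", {
  set.seed(11)
  ok <- ks_uniformity(runif(10000))
  expect_gt(ok$ks_p, 1e-4)

  bad <- ks_uniformity(rep(0.5, 1000))
  expect_lt(bad$ks_p, 1e-10)

  mixed <- ks_uniformity(c(runif(50), rep(0.2, 30), runif(5)),
                         bins = c(rep("a", 50), rep("b", 30),
                                  rep("c", 5)))
  expect_true(mixed$skipped[mixed$bin == "c"])
  expect_false(any(mixed$skipped[mixed$bin != "c"]))
})

test_that("p-values stay uniform at low expression correlation, not high", {
  # same-chromosome analogue at desk scale: linked noisy scores vs
  # unlinked ones, K-S against uniform
  reps <- 600L
  p_unl <- twiskit:::sim_ld_cell(2500, 2, 0, "pgs", 0.1, reps, 0.1,
                                 c(0.05, 0.5),
                                 substream_seed(12, "ks_unl"))
  p_lnk <- twiskit:::sim_ld_cell(2500, 2, 1, "pgs", 0.1, reps, 0.1,
                                 c(0.05, 0.5),
                                 substream_seed(12, "ks_lnk"))
  expect_gt(suppressWarnings(ks.test(p_unl, "punif"))$p.value, 0.01)
  expect_lt(suppressWarnings(ks.test(p_lnk, "punif"))$p.value, 0.001)
})

test_that("residualized and full models agree; the product variant fails", {
  rc <- residualization_comparison(n = 1500, reps = 400, seed = 13)
  rate <- function(ap) rc$rejection_rate[rc$approach == ap]
  se3 <- 3 * sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(rate("residualize_expression") - rate("full_model")),
            se3 * sqrt(2))
  expect_lt(abs(rate("residualize_expression") - 0.05), se3)
  expect_gt(rate("residualize_product"), 0.05 + se3)

  # orthogonal covariates: all three calibrated
  rc0 <- residualization_comparison(n = 1500, reps = 400,
                                    covariate_correlation = 0,
                                    covariate_interaction = 0, seed = 14)
  expect_true(all(abs(rc0$rejection_rate - 0.05) < se3))
})
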