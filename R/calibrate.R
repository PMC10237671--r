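# Monte-Carlo calibration experiments: power under expression prediction
# error, LD-driven false positives, genome-wide alpha from minimum-p order
# statistics, K-S uniformity diagnostics, and residualization strategies
# compared against the full covariate-interaction model.

new_sim_report <- function(df, experiment, reps, seed) {
  attr(df, "experiment") <- experiment
  attr(df, "reps") <- reps
  attr(df, "seed") <- seed
  class(df) <- c("twis_sim_report", class(df))
  df
}

mc_se <- function(rate, reps) sqrt(rate * (1 - rate) / reps)

# One power-grid cell, fully vectorized over replicates (chunked to bound
# memory). Returns the replicate p-values.
sim_power_cell <- function(n, pve, reps, b1, b2, error, accuracy_spec,
                           seed) {
  block <- max(1L, min(reps, floor(2e7 / n)))
  starts <- seq(1L, reps, by = block)
  p_out <- numeric(reps)
  set.seed(seed, kind = "Mersenne-Twister")
  for (s in starts) {
    r <- min(block, reps - s + 1L)
    T1 <- matrix(rnorm(n * r), n, r)
    T2 <- matrix(rnorm(n * r), n, r)
    prod12 <- T1 * T2
    vprod <- colSums(prod12^2) / (n - 1) -
      (colSums(prod12) / n)^2 * n / (n - 1)
    bint <- if (pve == 0) rep(0, r) else sqrt(pve / vprod)
    signal <- b1 * T1 + b2 * T2 + prod12 * rep(bint, each = n)
    vsig <- apply(signal, 2L, var)
    if (any(vsig >= 1)) {
      stop("main and interaction effects explain >= 100% of variance")
    }
    Y <- signal + matrix(rnorm(n * r), n, r) *
      rep(sqrt(1 - vsig), each = n)
    if (error) {
      acc1 <- simulate_accuracies(r, accuracy_spec)
      acc2 <- simulate_accuracies(r, accuracy_spec)
      T1 <- T1 + matrix(rnorm(n * r), n, r) * rep(sqrt(1 - acc1), each = n)
      T2 <- T2 + matrix(rnorm(n * r), n, r) * rep(sqrt(1 - acc2), each = n)
    }
    p_out[s:(s + r - 1L)] <- interaction_test_many(Y, T1, T2)$p
  }
  p_out
}

#' Monte-Carlo power grid for the interaction test
#'
#' For every combination of sample size and interaction variance share
#' (PVE), simulates standard-normal expression pairs, phenotypes with the
#' configured main effects plus the interaction PVE, optionally injects
#' expression prediction error (per-replicate accuracies drawn from
#' `accuracy_spec`, noise variance one minus the accuracy), and reports the
#' fraction of interaction p-values below each alpha.
#'
#' @param n_grid Sample sizes.
#' @param pve_grid Interaction PVE values (0 = null).
#' @param reps Replicates per cell (default 2000; a warning below 100).
#' @param alphas Significance levels.
#' @param error Inject prediction error.
#' @param accuracy_spec Accuracy distribution, see [accuracy_beta_spec()].
#' @param b1,b2 Standardized main effects (default 0.1; the interaction
#'   test is nearly insensitive to them).
#' @param seed Integer master seed; each cell gets its own sub-stream. With
#'   `error` both arms can be compared pairwise by running the grid twice
#'   with the same seed (common random numbers for the shared draws).
#' @return A `twis_sim_report` data frame: `n`, `pve`, `error`, `alpha`,
#'   `rejection_rate`, `mc_se`, `reps`.
#' @export
power_grid <- function(n_grid = c(5000, 10000), pve_grid = c(0, 5e-3),
                       reps = 2000L, alphas = c(0.05, 5.86e-10),
                       error = TRUE, accuracy_spec = accuracy_beta_spec(),
                       b1 = 0.1, b2 = 0.1, seed = 1L) {
  if (length(n_grid) == 0L || length(pve_grid) == 0L) stop("empty grid")
  if (reps < 100L) warning("fewer than 100 replicates: wide confidence
 intervals", call. = FALSE)
  rows <- list()
  for (n in n_grid) {
    for (pve in pve_grid) {
      cell_seed <- substream_seed(seed, sprintf("power_%g_%g", n, pve))
      p <- sim_power_cell(n, pve, reps, b1, b2, error, accuracy_spec,
                          cell_seed)
      for (a in alphas) {
        rate <- mean(p < a)
        rows[[length(rows) + 1L]] <- data.frame(
          n = n, pve = pve, error = error, alpha = a,
          rejection_rate = rate, mc_se = mc_se(rate, reps), reps = reps)
      }
    }
  }
  new_sim_report(do.call(rbind, rows), "power_grid", reps, seed)
}

# One LD-experiment cell: per-replicate genotypes, polygenic-score or
# gaussian expression, main-effects-only phenotype, interaction test on
# the (optionally noisy) predictors. Perfect-LD error-free replicates are
# rank deficient and fall back to the pivoted fit.
sim_ld_cell <- function(n, s, ld, expr_mode, accuracy, reps, b, maf_range,
                        seed) {
  set.seed(seed, kind = "Mersenne-Twister")
  block <- max(1L, min(reps, floor(2e7 / n)))
  p_out <- numeric(reps)
  done <- 0L
  while (done < reps) {
    r <- min(block, reps - done)
    T1 <- matrix(NA_real_, n, r)
    T2 <- matrix(NA_real_, n, r)
    for (j in seq_len(r)) {
      if (expr_mode == "gaussian") {
        t1 <- rnorm(n)
        t2 <- if (ld >= 1) t1 else rnorm(n)
      } else {
        maf <- runif(s, maf_range[1], maf_range[2])
        g1 <- matrix(rbinom(n * s, 2L, rep(maf, each = n)), n)
        g2 <- if (ld >= 1) g1 else
          matrix(rbinom(n * s, 2L, rep(maf, each = n)), n)
        t1 <- rowSums(g1)
        t2 <- rowSums(g2)
      }
      T1[, j] <- (t1 - mean(t1)) / sd(t1)
      T2[, j] <- (t2 - mean(t2)) / sd(t2)
    }
    ve <- 1 - apply(b * T1 + b * T2, 2L, var)
    Y <- b * T1 + b * T2 + matrix(rnorm(n * r), n, r) *
      rep(sqrt(pmax(ve, 1e-6)), each = n)
    if (accuracy < 1) {
      T1 <- T1 + matrix(rnorm(n * r), n, r) * sqrt(1 - accuracy)
      T2 <- T2 + matrix(rnorm(n * r), n, r) * sqrt(1 - accuracy)
    }
    res <- interaction_test_many(Y, T1, T2)
    if (any(res$singular)) {
      for (j in which(res$singular)) {
        res$p[j] <- pivoted_interaction_test(Y[, j], T1[, j], T2[, j])$p
      }
    }
    p_out[done + seq_len(r)] <- res$p
    done <- done + r
  }
  p_out
}

#' LD-driven false-positive experiment
#'
#' Simulates pairs of gene expression either as standard normals or as
#' simple polygenic scores (the sum of minor alleles over binomially
#' distributed SNPs) of varying polygenicity, with the two genes' SNP sets
#' unlinked (`ld = 0`) or identical (`ld = 1`), generates phenotypes from
#' main effects only, and measures the type-I error of the interaction test
#' using the exact predictor (`accuracy = 1`) or a noise-injected one.
#' The binomial-score-plus-error-plus-LD combination is the one that
#' inflates the test; gaussian expression stays calibrated at any error
#' level. With `ld = 1` and no error the two predictors are identical and
#' the product term is tested in the pivoted (quadratic) model.
#'
#' @param n Sample size per replicate.
#' @param snps_per_gene Polygenicity levels (default `c(2, 10, 20, 50, 100)`).
#' @param ld LD settings, subset of `c(0, 1)`.
#' @param expr_mode `"pgs"`, `"gaussian"`, or both.
#' @param error_levels Prediction accuracies (r-squared) of the predictor;
#'   1 = exact expression (default `c(1, 0.1)`).
#' @param reps Replicates per cell.
#' @param alphas Significance levels (default `c(0.05, 5e-8, 2.5e-10)`).
#' @param maf_range Minor allele frequency range.
#' @param b Standardized main effect of each gene.
#' @param seed Master seed; one sub-stream per cell.
#' @return A `twis_sim_report`: `expr_mode`, `snps_per_gene`, `ld`,
#'   `accuracy`, `alpha`, `rejection_rate`, `mc_se`, `reps`.
#' @export
ld_false_positive_experiment <- function(n = 5000L,
                                         snps_per_gene = c(2, 10, 20, 50, 100),
                                         ld = c(0, 1),
                                         expr_mode = "pgs",
                                         error_levels = c(1, 0.1),
                                         reps = 2000L,
                                         alphas = c(0.05, 5e-8, 2.5e-10),
                                         maf_range = c(0.05, 0.5),
                                         b = 0.1, seed = 1L) {
  rows <- list()
  for (mode in expr_mode) {
    spg <- if (mode == "gaussian") NA_integer_ else snps_per_gene
    for (s in spg) {
      for (l in ld) {
        for (acc in error_levels) {
          cell_seed <- substream_seed(
            seed, sprintf("ld_%s_%s_%g_%g", mode, s, l, acc))
          p <- sim_ld_cell(n, s, l, mode, acc, reps, b, maf_range,
                           cell_seed)
          for (a in alphas) {
            rate <- mean(p < a, na.rm = TRUE)
            rows[[length(rows) + 1L]] <- data.frame(
              expr_mode = mode, snps_per_gene = s, ld = l, accuracy = acc,
              alpha = a, rejection_rate = rate, mc_se = mc_se(rate, reps),
              reps = reps)
          }
        }
      }
    }
  }
  new_sim_report(do.call(rbind, rows), "ld_false_positive", reps, seed)
}

#' Causal SNP-by-SNP interactions tested at the expression level
#'
#' Plants a true SNP-by-SNP interaction between one causal SNP per gene --
#' chosen as the SNP with the locally maximal or minimal LD score within
#' its gene -- while the phenotype is unaffected by expression itself, then
#' tests the gene-gene interaction of the two expression scores. Rejections
#' are expression-level false positives driven by LD tagging of the causal
#' interaction; they grow with the causal SNPs' LD scores. Within-gene LD
#' is generated by per-SNP sharing of a latent allele pair (sharing
#' probabilities uniform on (0, 1), pairwise genotype correlation the
#' product of the two), and a SNP's LD score is its within-gene sum of
#' squared genotype correlations.
#'
#' @param n Sample size.
#' @param snps_per_gene SNPs per gene region.
#' @param choose `"max_ld"` or `"min_ld"` causal SNP.
#' @param effect Standardized causal SNP-by-SNP interaction slope.
#' @param reps Replicates.
#' @param alphas Significance levels.
#' @param maf Allele frequency of the latent and private alleles.
#' @param seed Master seed.
#' @return A `twis_sim_report` with the expression-level rejection rates.
#' @export
causal_snp_experiment <- function(n = 5000L, snps_per_gene = 10L,
                                  choose = c("max_ld", "min_ld"),
                                  effect = 0.15, reps = 500L,
                                  alphas = 0.05, maf = 0.3, seed = 1L) {
  rows <- list()
  for (ch in match.arg(choose, several.ok = TRUE)) {
    set.seed(substream_seed(seed, paste0("causal_", ch)),
             kind = "Mersenne-Twister")
    p_out <- numeric(reps)
    for (rix in seq_len(reps)) {
      gene <- function() {
        q <- runif(snps_per_gene)
        base <- matrix(rbinom(n * 2L, 1L, maf), n)
        G <- sapply(q, function(qj) {
          k1 <- runif(n) < qj; k2 <- runif(n) < qj
          ifelse(k1, base[, 1L], rbinom(n, 1L, maf)) +
            ifelse(k2, base[, 2L], rbinom(n, 1L, maf))
        })
        ldscore <- vapply(seq_len(snps_per_gene), function(j) {
          sum(1 + q[j]^2 * q[-j]^2)
        }, numeric(1))
        causal <- if (ch == "max_ld") which.max(ldscore) else
          which.min(ldscore)
        list(G = G, causal = causal)
      }
      g1 <- gene(); g2 <- gene()
      c1 <- scale(g1$G[, g1$causal])[, 1L]
      c2 <- scale(g2$G[, g2$causal])[, 1L]
      y <- effect * c1 * c2 + rnorm(n)
      t1 <- scale(rowSums(g1$G))[, 1L]
      t2 <- scale(rowSums(g2$G))[, 1L]
      p_out[rix] <- interaction_test(y, t1, t2)$p
    }
    for (a in alphas) {
      rate <- mean(p_out < a)
      rows[[length(rows) + 1L]] <- data.frame(
        choose = ch, snps_per_gene = snps_per_gene, effect = effect,
        alpha = a, rejection_rate = rate, mc_se = mc_se(rate, reps),
        reps = reps)
    }
  }
  new_sim_report(do.call(rbind, rows), "causal_snp", reps, seed)
}

#' Genome-wide alpha from minimum p-value order statistics
#'
#' Simulates `n_studies` independent null interaction studies of `G` tests
#' each (every test gets its own phenotype with main effects only), records
#' each study's minimum p-value, and returns the 5th percentile of the
#' minima as the multiple-testing alpha. For independent tests this
#' converges on the order-statistic closed form
#' `1 - 0.95^(1/G)` (nearly the Bonferroni bound `0.05/G`). The
#' `"same_chrom"` split instead uses perfectly linked polygenic-score
#' expression with prediction error, the regime in which LD drags the
#' minimum p (and hence the implied alpha) far lower.
#'
#' @param G Tests per study.
#' @param n_studies Number of simulated studies (warning below 20).
#' @param n Samples per test.
#' @param split `"diff_chrom"` (independent expression) or `"same_chrom"`.
#' @param b Standardized main effects.
#' @param accuracy Prediction accuracy for the `"same_chrom"` split.
#' @param snps_per_gene Polygenicity for the `"same_chrom"` split.
#' @param seed Master seed.
#' @return List: `alpha` (5th percentile), `min_p` (per study), `G`,
#'   `closed_form` (`1 - 0.95^(1/G)`, the independent-test reference).
#' @export
alpha_determination <- function(G = 100L, n_studies = 100L, n = 1000L,
                                split = c("diff_chrom", "same_chrom"),
                                b = 0.1, accuracy = 0.1,
                                snps_per_gene = 2L, seed = 1L) {
  split <- match.arg(split)
  if (n_studies < 20L) {
    warning("fewer than 20 studies: the 5th percentile is unstable",
            call. = FALSE)
  }
  min_p <- numeric(n_studies)
  for (st in seq_len(n_studies)) {
    cell_seed <- substream_seed(seed, sprintf("alpha_%s_%d", split, st))
    p <- if (split == "diff_chrom") {
      sim_power_cell(n, 0, G, b, b, error = FALSE,
                     accuracy_spec = accuracy_beta_spec(), seed = cell_seed)
    } else {
      sim_ld_cell(n, snps_per_gene, 1, "pgs", accuracy, G, b,
                  c(0.05, 0.5), cell_seed)
    }
    min_p[st] <- min(p, na.rm = TRUE)
  }
  list(alpha = quantile(min_p, 0.05, names = FALSE), min_p = min_p, G = G,
       closed_form = 1 - 0.95^(1 / G))
}

#' Kolmogorov-Smirnov uniformity of interaction p-values by bin
#'
#' Tests each bin of p-values (typically binned by pairwise expression
#' correlation) against Uniform(0, 1) with a two-sided K-S test. Bins with
#' fewer than `min_bin` values are skipped with a note.
#'
#' @param p_values Vector of p-values.
#' @param bins Bin labels aligned with `p_values` (`NULL` = one bin).
#' @param min_bin Minimum p-values per bin (default 20).
#' @return Data frame: `bin`, `n`, `ks_stat`, `ks_p`, `uniform`
#'   (`ks_p > 0.05`), `skipped`.
#' @export
ks_uniformity <- function(p_values, bins = NULL, min_bin = 20L) {
  if (is.null(bins)) bins <- rep("all", length(p_values))
  stopifnot(length(bins) == length(p_values))
  groups <- split(p_values, bins)
  rows <- lapply(names(groups), function(bn) {
    pv <- groups[[bn]][!is.na(groups[[bn]])]
    if (length(pv) < min_bin) {
      return(data.frame(bin = bn, n = length(pv), ks_stat = NA_real_,
                        ks_p = NA_real_, uniform = NA, skipped = TRUE))
    }
    kt <- suppressWarnings(ks.test(pv, "punif"))
    data.frame(bin = bn, n = length(pv), ks_stat = unname(kt$statistic),
               ks_p = kt$p.value, uniform = kt$p.value > 0.05,
               skipped = FALSE)
  })
  do.call(rbind, rows)
}

# The invalid strategy kept as a negative control: residualize the product
# term separately and regress the residualized trait on it. Anti-
# conservative whenever covariates interact with expression; the main
# pipeline never does this.
product_residualized_test <- function(y, t1, t2, design) {
  qd <- qr(design)
  yr <- qr.resid(qd, y)
  t1r <- qr.resid(qd, t1)
  t2r <- qr.resid(qd, t2)
  pr <- qr.resid(qd, t1 * t2)
  X <- cbind(1, t1r, t2r, pr)
  fit <- .lm.fit(X, yr)
  n <- length(y)
  sigma2 <- sum(fit$residuals^2) / (n - 4)
  se <- sqrt(solve(crossprod(X))[4, 4] * sigma2)
  tval <- fit$coefficients[4] / se
  2 * pt(abs(tval), n - 4, lower.tail = FALSE)
}

#' Residualization strategies versus the full covariate-interaction model
#'
#' Under a null with no gene-gene interaction -- but with a covariate that
#' is correlated with both genes' expression, affects the trait, and
#' interacts with each gene's main effect -- compares the type-I error of
#' three strategies: (i) the full model with all covariate main and
#' covariate-by-expression interaction terms plus the product; (ii) the
#' pipeline's approach, residualizing trait and expression on the covariate
#' before the three-term interaction test; (iii) the invalid variant that
#' additionally residualizes the product term separately. The first two
#' agree; the third is anti-conservative exactly when covariate and
#' expression are correlated.
#'
#' @param n Sample size (default 5000).
#' @param reps Replicates (default 2000).
#' @param covariate_correlation Correlation between the covariate and each
#'   gene's expression (default 0.5).
#' @param covariate_effect Standardized covariate main effect on the trait.
#' @param covariate_interaction Standardized covariate-by-expression
#'   interaction effects.
#' @param b Standardized expression main effects.
#' @param alpha Significance level (default 0.05).
#' @param seed Master seed.
#' @return A `twis_sim_report`: `approach`, `alpha`, `rejection_rate`,
#'   `mc_se`, `reps`; attribute `"p_values"` holds the reps x 3 matrix.
#' @export
residualization_comparison <- function(n = 5000L, reps = 2000L,
                                       covariate_correlation = 0.5,
                                       covariate_effect = 0.3,
                                       covariate_interaction = 0.1,
                                       b = 0.1, alpha = 0.05, seed = 1L) {
  rho <- covariate_correlation
  set.seed(substream_seed(seed, "resid_comparison"),
           kind = "Mersenne-Twister")
  P <- matrix(NA_real_, reps, 3,
              dimnames = list(NULL, c("full_model", "residualize_expression",
                                      "residualize_product")))
  for (r in seq_len(reps)) {
    cvt <- rnorm(n)
    t1 <- rho * cvt + sqrt(1 - rho^2) * rnorm(n)
    t2 <- rho * cvt + sqrt(1 - rho^2) * rnorm(n)
    y <- b * t1 + b * t2 + covariate_effect * cvt +
      covariate_interaction * cvt * t1 +
      covariate_interaction * cvt * t2 + rnorm(n)

    X <- cbind(1, t1, t2, cvt, cvt * t1, cvt * t2, t1 * t2)
    fit <- .lm.fit(X, y)
    sigma2 <- sum(fit$residuals^2) / (n - ncol(X))
    se <- sqrt(solve(crossprod(X))[7, 7] * sigma2)
    P[r, 1] <- 2 * pt(abs(fit$coefficients[7] / se), n - ncol(X),
                      lower.tail = FALSE)

    design <- cbind(1, cvt)
    qd <- qr(design)
    P[r, 2] <- interaction_test(qr.resid(qd, y), qr.resid(qd, t1),
                                qr.resid(qd, t2))$p
    P[r, 3] <- product_residualized_test(y, t1, t2, design)
  }
  rows <- lapply(colnames(P), function(ap) {
    rate <- mean(P[, ap] < alpha)
    data.frame(approach = ap, alpha = alpha, rejection_rate = rate,
               mc_se = mc_se(rate, reps), reps = reps)
  })
  out <- new_sim_report(do.call(rbind, rows), "residualization_comparison",
                        reps, seed)
  attr(out, "p_values") <- P
  out
}
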