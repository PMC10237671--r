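# Closed-form OLS for the fixed interaction design [1, t1, t2, t1*t2].
#
# All inputs are centered second moments (intercept eliminated), so the
# slope system is 3x3 and can be solved with vectorized adjugate formulas
# across thousands of pairs or replicates at once. The batch path is
# required to agree with a generic least-squares solver to 1e-8 relative
# tolerance; tests enforce that contract.

# Vectorized solve of the centered 3x3 normal equations. Arguments are
# vectors of equal length (one element per pair/replicate). Returns the
# interaction slope, its SE, t, two-sided p (t distribution, df = n - 4),
# and a singularity flag.
batch_interaction_stats <- function(s11, s22, spp, s12, s1p, s2p,
                                    s1y, s2y, spy, syy, n) {
  a11 <- s22 * spp - s2p^2
  a12 <- s1p * s2p - s12 * spp
  a13 <- s12 * s2p - s1p * s22
  a22 <- s11 * spp - s1p^2
  a23 <- s12 * s1p - s11 * s2p
  a33 <- s11 * s22 - s12^2
  det <- s11 * a11 + s12 * a12 + s1p * a13
  scale <- pmax(s11, 1e-300) * pmax(s22, 1e-300) * pmax(spp, 1e-300)
  singular <- !is.finite(det) | abs(det) <= 1e-12 * scale
  det_safe <- ifelse(singular, 1, det)

  b1 <- (a11 * s1y + a12 * s2y + a13 * spy) / det_safe
  b2 <- (a12 * s1y + a22 * s2y + a23 * spy) / det_safe
  bp <- (a13 * s1y + a23 * s2y + a33 * spy) / det_safe

  df <- n - 4
  rss <- pmax(syy - (b1 * s1y + b2 * s2y + bp * spy), 0)
  sigma2 <- rss / df
  var_bp <- a33 / det_safe * sigma2
  se <- sqrt(pmax(var_bp, 0))
  t <- bp / se
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  bad <- singular | !is.finite(se) | se <= 0
  list(beta1 = ifelse(bad, NA_real_, b1),
       beta2 = ifelse(bad, NA_real_, b2),
       beta_int = ifelse(bad, NA_real_, bp),
       se = ifelse(bad, NA_real_, se),
       t = ifelse(bad, NA_real_, t),
       p = ifelse(bad, NA_real_, p),
       sigma2 = sigma2, singular = bad)
}

# Centered moments for one (y, t1, t2) triple.
centered_moments <- function(y, t1, t2) {
  n <- length(y)
  y <- y - mean(y); t1 <- t1 - mean(t1); t2 <- t2 - mean(t2)
  pr <- t1 * t2
  s12 <- sum(t1 * t2)
  list(s11 = sum(t1^2), s22 = sum(t2^2),
       spp = sum(pr^2) - s12^2 / n, s12 = s12,
       s1p = sum(t1^2 * t2), s2p = sum(t1 * t2^2),
       s1y = sum(t1 * y), s2y = sum(t2 * y),
       spy = sum(pr * y) - s12 * sum(y) / n, syy = sum(y^2), n = n)
}

#' Three-term gene-gene interaction test
#'
#' Ordinary least squares of `y` on `[1, t1, t2, t1*t2]`; reports the
#' interaction slope, its standard error, the t statistic, and the
#' two-sided p-value from a t distribution with `n - 4` degrees of freedom.
#' A collinear design (e.g. `t1` identical to `t2`) yields a flagged result
#' with `p = NA` rather than an error, so a multi-million-pair scan never
#' aborts; with `on_collinear = "pivot"` the aliased column is dropped and
#' the product term tested in the reduced model (used by the calibration
#' experiments, where perfectly linked genes make the product a quadratic).
#'
#' @param y,t1,t2 Numeric vectors of equal length (>= 5), typically
#'   residualized phenotype and expression.
#' @param on_collinear `"flag"` (default) or `"pivot"`.
#' @return List with `beta1`, `beta2`, `beta_int`, `se`, `t`, `p`, `n`,
#'   `df`, and `singular`.
#' @export
#' @examples
#' set.seed(1)
#' t1 <- rnorm(500); t2 <- rnorm(500)
#' y <- 0.3 * t1 * t2 + rnorm(500)
#' interaction_test(y, t1, t2)$beta_int
interaction_test <- function(y, t1, t2, on_collinear = c("flag", "pivot")) {
  on_collinear <- match.arg(on_collinear)
  stopifnot(length(y) == length(t1), length(y) == length(t2))
  n <- length(y)
  if (n < 5L) stop("need at least 5 observations")
  if (!all(is.finite(y), is.finite(t1), is.finite(t2))) {
    stop("inputs must be finite")
  }
  mo <- centered_moments(y, t1, t2)
  st <- batch_interaction_stats(mo$s11, mo$s22, mo$spp, mo$s12, mo$s1p,
                                mo$s2p, mo$s1y, mo$s2y, mo$spy, mo$syy, n)
  out <- list(beta1 = st$beta1, beta2 = st$beta2, beta_int = st$beta_int,
              se = st$se, t = st$t, p = st$p, n = n, df = n - 4L,
              singular = st$singular)
  if (st$singular && on_collinear == "pivot") {
    out <- pivoted_interaction_test(y, t1, t2)
  }
  out
}

# QR fit with pivoting for rank-deficient designs: aliased columns are
# dropped and the product coefficient tested in the reduced model (it stays
# estimable when t1 == t2, where it is the quadratic term).
pivoted_interaction_test <- function(y, t1, t2) {
  X <- cbind(`(Intercept)` = 1, t1 = t1, t2 = t2, p = t1 * t2)
  n <- length(y)
  fit <- lm.fit(X, y)
  k <- fit$rank
  cf <- fit$coefficients
  if (is.na(cf["p"]) || k >= n) {
    return(list(beta1 = unname(cf["t1"]), beta2 = unname(cf["t2"]),
                beta_int = NA_real_, se = NA_real_, t = NA_real_,
                p = NA_real_, n = n, df = n - k, singular = TRUE))
  }
  R <- qr.R(fit$qr)[seq_len(k), seq_len(k), drop = FALSE]
  XtXi <- chol2inv(R)
  j <- match(4L, fit$qr$pivot[seq_len(k)])
  sigma2 <- sum(fit$residuals^2) / (n - k)
  se <- sqrt(XtXi[j, j] * sigma2)
  tval <- unname(cf["p"]) / se
  list(beta1 = unname(cf["t1"]), beta2 = unname(cf["t2"]),
       beta_int = unname(cf["p"]), se = se, t = tval,
       p = 2 * pt(abs(tval), n - k, lower.tail = FALSE),
       n = n, df = n - k, singular = TRUE)
}

#' Batched interaction tests over replicate columns
#'
#' Runs [interaction_test()] independently for each column triple
#' `(Y[, r], T1[, r], T2[, r])` using vectorized closed-form OLS; the
#' workhorse of the Monte-Carlo calibration experiments.
#'
#' @param Y,T1,T2 Numeric matrices of identical dimension
#'   (observations x replicates).
#' @return Data frame with one row per replicate: `beta_int`, `se`, `t`,
#'   `p`, `singular`.
#' @export
interaction_test_many <- function(Y, T1, T2) {
  stopifnot(all(dim(Y) == dim(T1)), all(dim(Y) == dim(T2)))
  n <- nrow(Y)
  cc <- function(M) sweep(M, 2L, colMeans(M), "-")
  Y <- cc(Y); T1 <- cc(T1); T2 <- cc(T2)
  P <- T1 * T2
  s12 <- colSums(P)
  st <- batch_interaction_stats(
    s11 = colSums(T1^2), s22 = colSums(T2^2),
    spp = colSums(P^2) - s12^2 / n, s12 = s12,
    s1p = colSums(T1 * P), s2p = colSums(T2 * P),
    s1y = colSums(T1 * Y), s2y = colSums(T2 * Y),
    spy = colSums(P * Y), syy = colSums(Y^2), n = n)
  data.frame(beta_int = st$beta_int, se = st$se, t = st$t, p = st$p,
             singular = st$singular)
}

#' Single-predictor (TWAS-style) association test
#'
#' OLS of `y` on `[1, t]`: the per-gene main-effect model against which
#' interaction discoveries are compared. Two-sided p from a t distribution
#' with `n - 2` degrees of freedom.
#'
#' @param y,t Numeric vectors of equal length.
#' @return List with `beta`, `se`, `t`, `p`, `n`.
#' @export
single_predictor_test <- function(y, t) {
  stopifnot(length(y) == length(t))
  n <- length(y)
  yc <- y - mean(y); tc <- t - mean(t)
  s11 <- sum(tc^2)
  if (s11 <= 0) {
    return(list(beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
                n = n, singular = TRUE))
  }
  beta <- sum(tc * yc) / s11
  rss <- sum(yc^2) - beta^2 * s11
  se <- sqrt(max(rss, 0) / (n - 2) / s11)
  tval <- beta / se
  list(beta = beta, se = se, t = tval,
       p = 2 * pt(abs(tval), n - 2, lower.tail = FALSE), n = n,
       singular = FALSE)
}
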