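#' Simulate binomially distributed SNP dosages
#'
#' Each column j is an independent draw from Binomial(2, `maf[j]`), the
#' additive dosage coding of a biallelic variant under Hardy-Weinberg
#' proportions.
#'
#' @param n_ind Number of individuals (rows).
#' @param n_snp Number of variants (columns).
#' @param maf Minor allele frequencies, length `n_snp` (or scalar, recycled);
#'   each must lie in (0, 0.5].
#' @param seed Integer seed (sub-stream `"genotypes"`).
#' @return Integer dosage matrix (`n_ind` x `n_snp`) with values 0/1/2.
#' @export
#' @examples
#' g <- simulate_genotypes(1000, 5, maf = 0.3, seed = 1)
#' colMeans(g) # close to 2 * 0.3
simulate_genotypes <- function(n_ind, n_snp, maf, seed = NULL) {
  maf <- rep_len(as.numeric(maf), n_snp)
  if (any(!is.finite(maf)) || any(maf <= 0 | maf > 0.5)) {
    stop("`maf` must lie in (0, 0.5]")
  }
  with_substream(seed, "genotypes", {
    matrix(rbinom(n_ind * n_snp, 2L, rep(maf, each = n_ind)),
           nrow = n_ind, ncol = n_snp)
  })
}

#' Simulate the dosage matrices of two genes with controlled LD
#'
#' `ld_mode = "none"` draws the two genes' SNPs independently;
#' `"perfect"` reuses gene 1's columns for gene 2, so cross-gene genotype
#' correlation is exactly 1; `"block"` redraws each allele of gene 2
#' independently with probability `1 - ld_r` (an exchange construction whose
#' per-SNP genotype correlation is `ld_r`).
#'
#' @inheritParams simulate_genotypes
#' @param ld_mode `"none"`, `"perfect"`, or `"block"`.
#' @param ld_r Target genotype correlation for `"block"`.
#' @return List with dosage matrices `gene1` and `gene2` and the `maf` used.
#' @export
simulate_genotype_pair <- function(n_ind, n_snp, maf,
                                   ld_mode = c("none", "perfect", "block"),
                                   ld_r = 0.5, seed = NULL) {
  ld_mode <- match.arg(ld_mode)
  maf <- rep_len(as.numeric(maf), n_snp)
  if (any(maf <= 0 | maf > 0.5)) stop("`maf` must lie in (0, 0.5]")
  with_substream(seed, "genotype_pair", {
    draw_alleles <- function() {
      matrix(rbinom(n_ind * n_snp, 1L, rep(maf, each = n_ind)),
             nrow = n_ind)
    }
    a1 <- draw_alleles(); a2 <- draw_alleles()
    g1 <- a1 + a2
    g2 <- switch(ld_mode,
      none = draw_alleles() + draw_alleles(),
      perfect = g1,
      block = {
        keep1 <- matrix(runif(n_ind * n_snp) < ld_r, nrow = n_ind)
        keep2 <- matrix(runif(n_ind * n_snp) < ld_r, nrow = n_ind)
        b1 <- ifelse(keep1, a1, draw_alleles())
        b2 <- ifelse(keep2, a2, draw_alleles())
        b1 + b2
      })
    list(gene1 = g1, gene2 = g2, maf = maf)
  })
}

#' Simulate gene expression values
#'
#' In `"gaussian"` mode each gene's expression is i.i.d. standard normal.
#' In `"pgs"` mode expression is a local polygenic score: the weighted sum of
#' SNP dosages (unit weights give the sum of minor alleles), mean-centered.
#'
#' @param mode `"gaussian"` or `"pgs"`.
#' @param n_ind Number of individuals (gaussian mode).
#' @param n_genes Number of genes (gaussian mode).
#' @param dosages A dosage matrix, or a list of per-gene dosage matrices
#'   (pgs mode).
#' @param weights Numeric weight vector, or a list of per-gene weight vectors
#'   matching `dosages`; defaults to unit weights.
#' @param standardize Scale each gene to unit variance after centering
#'   (default `TRUE`).
#' @param seed Integer seed (sub-stream `"expression"`, gaussian mode only).
#' @return Numeric matrix (individuals x genes).
#' @export
simulate_expression <- function(mode = c("gaussian", "pgs"),
                                n_ind = NULL, n_genes = NULL,
                                dosages = NULL, weights = NULL,
                                standardize = TRUE, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "gaussian") {
    stopifnot(!is.null(n_ind), !is.null(n_genes))
    expr <- with_substream(seed, "expression", {
      matrix(rnorm(n_ind * n_genes), nrow = n_ind, ncol = n_genes)
    })
  } else {
    if (is.null(dosages)) stop("pgs mode requires `dosages`")
    if (is.matrix(dosages)) dosages <- list(dosages)
    if (is.null(weights)) {
      weights <- lapply(dosages, function(d) rep(1, ncol(d)))
    } else if (!is.list(weights)) {
      weights <- list(weights)
    }
    if (length(weights) != length(dosages)) {
      stop("`weights` and `dosages` describe different numbers of genes")
    }
    cols <- mapply(function(d, w) {
      if (ncol(d) != length(w)) {
        stop("weight length does not match dosage columns")
      }
      as.numeric(d %*% w)
    }, dosages, weights, SIMPLIFY = FALSE)
    expr <- do.call(cbind, cols)
    expr <- sweep(expr, 2L, colMeans(expr), "-")
  }
  if (standardize) {
    s <- apply(expr, 2L, sd)
    s[s == 0] <- 1 # zero-variance columns left centered, flagged downstream
    expr <- sweep(expr, 2L, s, "/")
  }
  expr
}

#' Add expression prediction error
#'
#' Emulates imperfect genetic prediction of expression: for a gene with
#' prediction accuracy r-squared, independent noise with variance
#' `1 - r2` is added to the (unit-variance) true expression, so the
#' observed predictor retains the stated share of the truth's variance.
#' `r2 = 1` returns the input untouched.
#'
#' @param expression Numeric matrix (individuals x genes), columns
#'   standardized to unit variance.
#' @param accuracies Per-gene prediction r-squared, in (0, 1]; scalar
#'   recycled.
#' @param seed Integer seed (sub-stream `"prediction_error"`).
#' @return Noisy expression matrix of the same shape.
#' @export
add_prediction_error <- function(expression, accuracies, seed = NULL) {
  expression <- as.matrix(expression)
  accuracies <- rep_len(as.numeric(accuracies), ncol(expression))
  if (any(!is.finite(accuracies)) || any(accuracies <= 0 | accuracies > 1)) {
    stop("`accuracies` must lie in (0, 1]")
  }
  sds <- sqrt(1 - accuracies)
  if (all(sds == 0)) return(expression)
  with_substream(seed, "prediction_error", {
    noise <- matrix(rnorm(length(expression)), nrow = nrow(expression))
    expression + sweep(noise, 2L, sds, "*")
  })
}

#' Simulate a phenotype with main and interaction expression effects
#'
#' Builds `y = b1*t1 + b2*t2 + beta_int*t1*t2 + e`, where `beta_int` is set
#' so the interaction term explains the requested fraction `pve_int` of
#' phenotypic variance (using the realized variance of the product), and the
#' error variance is chosen so the total phenotypic variance is 1. For
#' independent standardized predictors the product has variance ~1, giving
#' `beta_int = sqrt(pve_int)`. Binary traits threshold the unit-variance
#' latent liability at the stated prevalence.
#'
#' @param t1,t2 Standardized expression vectors of equal length.
#' @param b1,b2 Standardized main-effect slopes.
#' @param pve_int Fraction of phenotypic variance explained by the
#'   interaction, in `[0, 1)`.
#' @param binary Threshold the liability into a 0/1 trait.
#' @param prevalence Case fraction for binary traits.
#' @param seed Integer seed (sub-stream `"phenotype"`).
#' @return Numeric phenotype vector; attribute `"beta_int"` records the
#'   interaction slope used.
#' @export
simulate_phenotype <- function(t1, t2, b1 = 0.1, b2 = 0.1, pve_int = 0,
                               binary = FALSE, prevalence = 0.5,
                               seed = NULL) {
  stopifnot(length(t1) == length(t2))
  if (pve_int < 0 || pve_int >= 1) stop("`pve_int` must lie in [0, 1)")
  prod12 <- t1 * t2
  vp <- var(prod12)
  beta_int <- if (pve_int == 0) 0 else sqrt(pve_int / vp)
  signal <- b1 * t1 + b2 * t2 + beta_int * prod12
  ve <- 1 - var(signal)
  if (ve <= 0) {
    stop("main and interaction effects explain >= 100% of phenotypic variance")
  }
  y <- with_substream(seed, "phenotype", {
    signal + rnorm(length(t1), 0, sqrt(ve))
  })
  if (binary) {
    y <- as.integer(y > quantile(y, 1 - prevalence, names = FALSE))
  }
  attr(y, "beta_int") <- beta_int
  y
}
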