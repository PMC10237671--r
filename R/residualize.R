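#' Build a covariate design matrix
#'
#' Expands a covariate table into a full-rank numeric design with an
#' intercept. Character and factor columns are dummy-coded against a
#' reference level; levels observed fewer than `min_level_count` times are
#' merged into `"other"` so sparse batch/center labels cannot break the fit.
#' Rank deficiency is an error that names the collinear columns.
#'
#' @param covariates Data frame of covariates (a `sample_id` column, if
#'   present, is carried through as rownames, not as a covariate).
#' @param min_level_count Minimum observations per categorical level
#'   (default 2).
#' @return Numeric design matrix including an intercept column.
#' @export
covariate_design <- function(covariates, min_level_count = 2L) {
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  ids <- NULL
  if ("sample_id" %in% names(covariates)) {
    ids <- as.character(covariates$sample_id)
    covariates$sample_id <- NULL
  }
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.character(v) || is.factor(v) || is.logical(v)) {
      v <- as.character(v)
      tab <- table(v)
      rare <- names(tab)[tab < min_level_count]
      if (length(rare) > 0) v[v %in% rare] <- "other"
      covariates[[nm]] <- factor(v)
    }
  }
  X <- stats::model.matrix(~ ., data = covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("covariate design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(ids)) rownames(X) <- ids
  X
}

#' Residualize a quantitative variable on covariates
#'
#' Returns `x` minus its least-squares projection onto the covariate design
#' (intercept included), i.e. the residuals of `x = mu + sum_k a_k cov_k + e`.
#'
#' @param x Numeric vector, no missing values.
#' @param design Numeric design matrix from [covariate_design()], or a
#'   covariate data frame (expanded on the fly).
#' @return Residual vector, orthogonal to every design column.
#' @export
residualize_quantitative <- function(x, design) {
  if (is.data.frame(design)) design <- covariate_design(design)
  stopifnot(length(x) == nrow(design), all(is.finite(x)))
  qr.resid(qr(design), x)
}

#' Residualize a binary variable via logistic regression
#'
#' Fits the logistic regression of `y` on the covariates by maximum
#' likelihood and returns response residuals `y - p_hat`. The score
#' equations of the logistic MLE make these residuals orthogonal to every
#' design column, the property the downstream linear interaction test uses.
#' Deviance residuals are available behind `type = "deviance"`.
#'
#' @param y 0/1 vector with both classes present.
#' @param design As in [residualize_quantitative()].
#' @param type `"response"` (default) or `"deviance"`.
#' @return Residual vector.
#' @export
residualize_binary <- function(y, design, type = c("response", "deviance")) {
  type <- match.arg(type)
  if (is.data.frame(design)) design <- covariate_design(design)
  stopifnot(length(y) == nrow(design))
  if (!all(y %in% c(0, 1))) stop("`y` must be 0/1")
  if (length(unique(y)) < 2L) stop("`y` has a single class")
  fit <- suppressWarnings(glm.fit(design, y, family = binomial()))
  p_hat <- fit$fitted.values
  eps <- 1e-8
  if (!fit$converged || any(p_hat < eps | p_hat > 1 - eps)) {
    stop("perfect or quasi-perfect separation in the logistic fit; ",
         "prune or coarsen covariates")
  }
  if (type == "response") {
    y - p_hat
  } else {
    sign(y - p_hat) * sqrt(-2 * (y * log(p_hat) + (1 - y) * log(1 - p_hat)))
  }
}

#' Residualize a phenotype and an expression matrix on shared covariates
#'
#' Takes the complete-case intersection of phenotype, covariates, and
#' expression once, then projects the phenotype (linear or logistic by
#' `trait_type`) and every gene column (always linear) onto the identical
#' covariate design. The result feeds the pairwise interaction scan
#' directly.
#'
#' @param phenotype Data frame with columns `sample_id` and `y`.
#' @param expression Expression matrix with sample IDs as rownames.
#' @param covariates Covariate data frame with a `sample_id` column.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param min_samples Minimum complete cases (default 50).
#' @return Object of class `resid_dataset`: list with `y_resid`, `T_resid`,
#'   `n`, `trait_type`, `sample_ids`, and the `design` used.
#' @export
residualize_dataset <- function(phenotype, expression, covariates,
                                trait_type = c("quantitative", "binary"),
                                min_samples = 50L) {
  trait_type <- match.arg(trait_type)
  stopifnot(all(c("sample_id", "y") %in% names(phenotype)))
  ids <- Reduce(intersect, list(as.character(phenotype$sample_id),
                                rownames(expression),
                                as.character(covariates$sample_id)))
  phenotype <- phenotype[match(ids, phenotype$sample_id), , drop = FALSE]
  covariates <- covariates[match(ids, covariates$sample_id), , drop = FALSE]
  expression <- expression[ids, , drop = FALSE]
  cc <- complete.cases(phenotype$y) & complete.cases(covariates) &
    rowSums(!is.finite(expression)) == 0
  if (sum(cc) < min_samples) {
    stop("only ", sum(cc), " complete cases; need at least ", min_samples)
  }
  phenotype <- phenotype[cc, , drop = FALSE]
  covariates <- covariates[cc, , drop = FALSE]
  expression <- expression[cc, , drop = FALSE]

  design <- covariate_design(covariates)
  qd <- qr(design)
  y_resid <- if (trait_type == "binary") {
    residualize_binary(phenotype$y, design)
  } else {
    qr.resid(qd, as.numeric(phenotype$y))
  }
  T_resid <- qr.resid(qd, expression)
  dimnames(T_resid) <- dimnames(expression)
  structure(list(y_resid = as.numeric(y_resid), T_resid = T_resid,
                 n = nrow(T_resid), trait_type = trait_type,
                 sample_ids = phenotype$sample_id, design = design),
            class = "resid_dataset")
}

#' @export
print.resid_dataset <- function(x, ...) {
  cat("<resid_dataset>", x$n, "samples,", ncol(x$T_resid), "genes,",
      x$trait_type, "trait\n")
  invisible(x)
}
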