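#' Impute gene expression from dosages and expression weights
#'
#' Computes each gene's local polygenic score
#' `T_g(i) = sum_j w_gj * d_ij`, where `d_ij` is the dosage of the weight's
#' effect allele. When the dosage file counts the opposite allele, the
#' dosage is replaced by `2 - d`; after mean-centering this is exactly
#' equivalent to negating the weight, so imputed expression is invariant to
#' the allele encoding of the dosage source. Each gene column is
#' mean-centered and, by default, scaled to unit variance so interaction
#' effect sizes are comparable across pairs.
#'
#' Genes with more than `max_missing` of their weighted variants absent from
#' the dosage source are dropped with a warning; variants missing below that
#' threshold contribute zero (their dosage is treated as the mean after
#' centering).
#'
#' @param dosages A [dosage_set()].
#' @param weights A [weight_set()].
#' @param standardize Scale columns to unit variance (default `TRUE`).
#' @param max_missing Maximum tolerated fraction of a gene's weighted
#'   variants missing from the dosage source (default 0.1).
#' @return Numeric matrix (samples x genes) with sample IDs as rownames and
#'   gene IDs as colnames; attribute `"dropped_genes"` lists genes removed
#'   for missingness, `"zero_variance"` flags constant columns (left
#'   centered, not scaled).
#' @export
#' @examples
#' v <- data.frame(variant_id = "rs1", chrom = "1", pos = 100,
#'                 ref = "A", alt = "G", counted_allele = "G")
#' d <- dosage_set(matrix(c(0, 1, 2), ncol = 1,
#'                        dimnames = list(NULL, "rs1")), v)
#' co <- data.frame(gene_id = "g1", chrom = "1", midpoint = 100)
#' w <- weight_set(data.frame(gene_id = "g1", variant_id = "rs1",
#'                            effect_allele = "G", weight = 1), co)
#' impute_expression(d, w, standardize = FALSE) # centered (-1, 0, 1)
impute_expression <- function(dosages, weights, standardize = TRUE,
                              max_missing = 0.1) {
  stopifnot(inherits(dosages, "dosage_set"), inherits(weights, "weight_set"))
  wtab <- weights$weights
  vmeta <- dosages$variants
  idx <- match(wtab$variant_id, vmeta$variant_id)
  present <- !is.na(idx)

  genes <- unique(wtab$gene_id)
  miss_frac <- vapply(genes, function(gid) {
    sel <- wtab$gene_id == gid
    1 - sum(present[sel]) / sum(sel)
  }, numeric(1))
  dropped <- genes[miss_frac > max_missing]
  if (length(dropped) > 0) {
    warning(length(dropped), " gene(s) dropped: >",
            round(100 * max_missing), "% of weighted variants missing (",
            paste(utils::head(dropped, 5), collapse = ", "), ")")
  }
  keep_genes <- setdiff(genes, dropped)
  if (length(keep_genes) == 0L) stop("no genes imputable")

  keep <- present & wtab$gene_id %in% keep_genes
  wtab <- wtab[keep, , drop = FALSE]
  idx <- idx[keep]

  # flip to the weight's effect allele: d_eff = 2 - d when the dosage counts
  # the other allele; the additive offset is absorbed by centering
  flip <- wtab$effect_allele != vmeta$counted_allele[idx]
  w <- ifelse(flip, -wtab$weight, wtab$weight)

  n <- nrow(dosages$dosages)
  # sparse accumulation: score = D[, idx] %*% w grouped by gene
  gidx <- match(wtab$gene_id, keep_genes)
  expr <- matrix(0, nrow = n, ncol = length(keep_genes))
  for (k in seq_along(idx)) {
    expr[, gidx[k]] <- expr[, gidx[k]] + w[k] * dosages$dosages[, idx[k]]
  }
  colnames(expr) <- keep_genes
  rownames(expr) <- rownames(dosages$dosages)
  expr <- sweep(expr, 2L, colMeans(expr), "-")
  sds <- apply(expr, 2L, sd)
  zero_var <- keep_genes[sds == 0]
  if (standardize) {
    s <- ifelse(sds == 0, 1, sds)
    expr <- sweep(expr, 2L, s, "/")
  }
  attr(expr, "dropped_genes") <- dropped
  attr(expr, "zero_variance") <- zero_var
  expr
}

#' Pairwise Pearson correlation of imputed expression
#'
#' The correlation matrix that feeds the pair filter: pairs with
#' `|r| > 0.05` are excluded from significance accounting downstream.
#' Zero-variance genes yield undefined correlations; they are flagged and
#' their rows/columns set to `NA`.
#'
#' @param expr Expression matrix (samples x genes), at least 3 rows.
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `"zero_variance"` names flagged genes.
#' @export
expression_correlation <- function(expr) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 3L) stop("need at least 3 samples")
  sds <- apply(expr, 2L, sd)
  zv <- colnames(expr)[sds == 0]
  r <- suppressWarnings(cor(expr))
  if (length(zv) > 0) {
    r[sds == 0, ] <- NA_real_
    r[, sds == 0] <- NA_real_
  }
  diag(r) <- 1
  attr(r, "zero_variance") <- zv
  r
}
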