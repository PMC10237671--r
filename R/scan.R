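#' Proximity and correlation filter for a gene pair
#'
#' A pair is dropped from significance accounting when its imputed
#' expression correlation exceeds the threshold in absolute value
#' (`|r| > 0.05` by default) or when both genes sit on the same chromosome
#' with physical midpoints less than 1 Mb apart -- the two situations in
#' which LD makes the interaction statistic anti-conservative. Reasons
#' accumulate; filtered pairs are still tested and recorded.
#'
#' @param chrom1,chrom2 Chromosome labels (vectorized).
#' @param mid1,mid2 Physical midpoints in bp.
#' @param r_expr Imputed-expression Pearson correlation of the pair.
#' @param r_threshold Absolute correlation cutoff (default 0.05).
#' @param dist_threshold Minimum same-chromosome midpoint distance in bp
#'   (default 1e6).
#' @return Data frame with logical `keep` and character `reasons`
#'   (comma-separated, empty when kept).
#' @export
#' @examples
#' pair_filter("1", "2", 1e6, 5e6, r_expr = 0.06) # dropped: correlated
pair_filter <- function(chrom1, chrom2, mid1, mid2, r_expr,
                        r_threshold = 0.05, dist_threshold = 1e6) {
  if (any(is.na(chrom1) | is.na(chrom2) | is.na(mid1) | is.na(mid2))) {
    stop("missing gene coordinates")
  }
  k <- max(length(chrom1), length(r_expr))
  chrom1 <- rep_len(as.character(chrom1), k)
  chrom2 <- rep_len(as.character(chrom2), k)
  mid1 <- rep_len(mid1, k); mid2 <- rep_len(mid2, k)
  r_expr <- rep_len(r_expr, k)
  correlated <- !is.na(r_expr) & abs(r_expr) > r_threshold
  proximal <- chrom1 == chrom2 & abs(mid1 - mid2) < dist_threshold
  zero_var <- is.na(r_expr)
  reasons <- character(k)
  add <- function(reasons, flag, code) {
    ifelse(flag, ifelse(nzchar(reasons), paste(reasons, code, sep = ","),
                        code), reasons)
  }
  reasons <- add(reasons, correlated, "correlated_expression")
  reasons <- add(reasons, proximal, "proximal_1mb")
  reasons <- add(reasons, zero_var, "zero_variance")
  data.frame(keep = !correlated & !proximal & !zero_var, reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Exhaustive pairwise interaction scan
#'
#' Tests every unordered pair of genes (or any chunk of them) with the
#' three-term interaction regression on residualized data. Per-pair second
#' moments are assembled from a handful of gene-by-gene matrix products, so
#' a chunk of tests costs a few dense multiplications rather than millions
#' of regression calls; the closed form matches a generic least-squares
#' solver to 1e-8 relative tolerance. Pairs failing the correlation or
#' proximity filters are still tested, with their reasons recorded in
#' `flags`. The same machinery runs SNP-by-SNP scans when the columns of
#' `T_resid` are residualized dosages and `coords` carries per-variant
#' positions.
#'
#' @param data A [residualize_dataset()] result, or any list with elements
#'   `y_resid` (vector) and `T_resid` (matrix with gene colnames).
#' @param coords Gene coordinate table covering all scanned genes (columns
#'   `gene_id`, `chrom`, and `midpoint` or `start`/`end`).
#' @param chunks Number of contiguous chunks the full scan is split into.
#' @param chunk_id Which chunk to run (`NULL` = everything).
#' @param r_threshold,dist_threshold Filter settings, see [pair_filter()].
#' @return Data frame ordered by linear pair index: `gene1`, `gene2`,
#'   `beta_int`, `se`, `t`, `p`, `n`, `r_expr`, `flags`, `keep`.
#' @export
run_pairwise_scan <- function(data, coords, chunks = 1L, chunk_id = NULL,
                              r_threshold = 0.05, dist_threshold = 1e6) {
  y <- as.numeric(data$y_resid)
  E <- as.matrix(data$T_resid)
  g <- ncol(E)
  if (g < 2L) stop("need at least two genes")
  genes <- colnames(E)
  if (is.null(genes)) genes <- sprintf("G%d", seq_len(g))
  coords <- normalize_coords(coords)
  pos <- match(genes, coords$gene_id)
  if (anyNA(pos)) {
    stop("genes missing from coordinate table: ",
         paste(utils::head(genes[is.na(pos)], 5), collapse = ", "))
  }
  chrom <- coords$chrom[pos]
  mid <- coords$midpoint[pos]

  n <- length(y)
  m <- pair_count(g)
  if (is.null(chunk_id)) {
    from <- 1; to <- m
  } else {
    rng <- pair_chunk_range(chunk_id, g, chunks)
    from <- rng["from"]; to <- rng["to"]
    if (to < from) return(empty_scan_frame())
  }
  idx <- seq(from, to)
  pr <- pair_from_linear_index(idx, g)
  a <- pr[, 1L]; b <- pr[, 2L]

  y <- y - mean(y)
  E <- sweep(E, 2L, colMeans(E), "-")
  sds <- sqrt(colSums(E^2) / (n - 1))
  rmat <- suppressWarnings(stats::cor(E))
  E2 <- E * E
  S <- crossprod(E)
  Q <- crossprod(E2, E)
  PP <- crossprod(E2, E2)
  SY <- crossprod(E * y, E)
  sy <- as.numeric(crossprod(E, y))
  syy <- sum(y^2)

  lin_ab <- (b - 1) * g + a
  lin_ba <- (a - 1) * g + b
  st <- batch_interaction_stats(
    s11 = S[cbind(a, a)], s22 = S[cbind(b, b)],
    spp = PP[lin_ab] - S[lin_ab]^2 / n, s12 = S[lin_ab],
    s1p = Q[lin_ab], s2p = Q[lin_ba],
    s1y = sy[a], s2y = sy[b], spy = SY[lin_ab], syy = syy, n = n)

  r_expr <- rmat[lin_ab]
  r_expr[sds[a] == 0 | sds[b] == 0] <- NA_real_
  filt <- pair_filter(chrom[a], chrom[b], mid[a], mid[b], r_expr,
                      r_threshold, dist_threshold)
  flags <- filt$reasons
  flags <- ifelse(st$singular & !grepl("zero_variance", flags),
                  ifelse(nzchar(flags), paste(flags, "collinear", sep = ","),
                         "collinear"), flags)
  data.frame(gene1 = genes[a], gene2 = genes[b],
             beta_int = st$beta_int, se = st$se, t = st$t, p = st$p,
             n = n, r_expr = r_expr, flags = flags,
             keep = filt$keep & !st$singular,
             stringsAsFactors = FALSE)
}

empty_scan_frame <- function() {
  data.frame(gene1 = character(), gene2 = character(),
             beta_int = numeric(), se = numeric(), t = numeric(),
             p = numeric(), n = integer(), r_expr = numeric(),
             flags = character(), keep = logical(),
             stringsAsFactors = FALSE)
}

#' Per-gene single-predictor scan (TWAS analogue)
#'
#' OLS of the residualized phenotype on each gene's residualized expression
#' alone, `df = n - 2`; the main-effect results against which interaction
#' discoveries are compared.
#'
#' @inheritParams run_pairwise_scan
#' @return Data frame: `gene`, `beta`, `se`, `t`, `p`, `n`, `flags`.
#' @export
run_single_predictor_scan <- function(data) {
  y <- as.numeric(data$y_resid)
  E <- as.matrix(data$T_resid)
  n <- length(y)
  genes <- colnames(E)
  if (is.null(genes)) genes <- sprintf("G%d", seq_len(ncol(E)))
  y <- y - mean(y)
  E <- sweep(E, 2L, colMeans(E), "-")
  s11 <- colSums(E^2)
  sy <- as.numeric(crossprod(E, y))
  zero <- s11 <= 0
  s11_safe <- ifelse(zero, 1, s11)
  beta <- sy / s11_safe
  rss <- pmax(sum(y^2) - beta^2 * s11_safe, 0)
  se <- sqrt(rss / (n - 2) / s11_safe)
  tval <- beta / se
  p <- 2 * pt(abs(tval), n - 2, lower.tail = FALSE)
  beta[zero] <- se[zero] <- tval[zero] <- p[zero] <- NA_real_
  data.frame(gene = genes, beta = beta, se = se, t = tval, p = p, n = n,
             flags = ifelse(zero, "zero_variance", ""),
             stringsAsFactors = FALSE)
}

#' Write and read pairwise scan results
#'
#' Tab-separated; paths ending in `.gz` are gzip-compressed. Row order is
#' the deterministic linear pair index order.
#'
#' @param results Scan data frame from [run_pairwise_scan()].
#' @param path Output path (`.tsv` or `.tsv.gz`).
#' @export
write_scan_results <- function(results, path) {
  data.table::fwrite(results, path, sep = "\t",
                     compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' @rdname write_scan_results
#' @export
read_scan_results <- function(path) {
  df <- if (grepl("\\.gz$", path)) {
    con <- gzfile(path)
    on.exit(try(close(con), silent = TRUE))
    utils::read.delim(con, stringsAsFactors = FALSE)
  } else {
    as.data.frame(data.table::fread(path, header = TRUE))
  }
  if ("flags" %in% names(df)) df$flags[is.na(df$flags)] <- ""
  if ("keep" %in% names(df)) df$keep <- as.logical(df$keep)
  df
}

#' Variants within a window of a gene TSS
#'
#' Selects the variants inside `tss - window .. tss + window` (inclusive,
#' 1-based) on the gene's chromosome -- the SNP-by-SNP follow-up window
#' around an associated gene.
#'
#' @param variants Variant table (columns `variant_id`, `chrom`, `pos`).
#' @param chrom Gene chromosome.
#' @param tss Transcription start site (bp).
#' @param window Half-width in bp (default 500,000).
#' @return Character vector of variant IDs.
#' @export
snp_window_variants <- function(variants, chrom, tss, window = 5e5) {
  sel <- variants$chrom == as.character(chrom) &
    variants$pos >= tss - window & variants$pos <= tss + window
  variants$variant_id[sel]
}
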