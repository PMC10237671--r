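#' Signed Z-score from a two-sided p-value
#'
#' METAL's convention: `z = qnorm(1 - p/2) * sign(effect)`. Residualization
#' changes effect scales across cohorts, so meta-analysis weights Z-scores
#' by sample size instead of combining betas and SEs.
#'
#' @param p Two-sided p-values in (0, 1].
#' @param sign Effect signs (+1/-1, or the effects themselves).
#' @return Signed Z-scores.
#' @export
z_from_p_sign <- function(p, sign) {
  stopifnot(all(p > 0 & p <= 1, na.rm = TRUE))
  qnorm(p / 2, lower.tail = FALSE) * base::sign(sign)
}

#' Sample-size-weighted meta-analysis of one pair
#'
#' Combines per-cohort signed Z-scores with weights `sqrt(N_i)`:
#' `z_meta = sum(sqrt(N_i) z_i) / sqrt(sum(N_i))`, with
#' `p_meta = 2 * pnorm(-|z_meta|)`. Cohorts with a missing Z contribute a
#' `"?"` to the direction string and are excluded from the weights.
#'
#' @param z Per-cohort signed Z-scores (`NA` = missing cohort).
#' @param n Per-cohort sample sizes.
#' @return List with `z_meta`, `p_meta`, `direction` (a string of
#'   `+`/`-`/`?` per cohort), and `n_total`.
#' @export
#' @examples
#' meta_z(c(1, 1), c(1000, 1000))$z_meta # sqrt(2)
meta_z <- function(z, n) {
  stopifnot(length(z) == length(n), length(z) >= 1L)
  ok <- !is.na(z)
  if (!any(ok)) stop("all cohorts missing")
  w <- sqrt(n[ok])
  z_meta <- sum(w * z[ok]) / sqrt(sum(n[ok]))
  direction <- paste(ifelse(is.na(z), "?",
                            ifelse(z >= 0, "+", "-")), collapse = "")
  list(z_meta = z_meta, p_meta = 2 * pnorm(-abs(z_meta)),
       direction = direction, n_total = sum(n[ok]))
}

#' Meta-analyze pairwise scan results across cohorts
#'
#' Joins per-cohort scans on `(gene1, gene2)` (unordered), converts each
#' cohort's interaction p-value and effect sign to a signed Z, and combines
#' them with sample-size weights. Pairs absent from a cohort get `"?"` in
#' the direction string. Filter flags are taken from the first cohort in
#' which the pair appears (the discovery cohort by convention).
#'
#' @param scans Named list of scan data frames (from
#'   [run_pairwise_scan()]); the first is treated as discovery.
#' @param ns Optional per-cohort sample sizes (defaults to each scan's `n`).
#' @return Data frame: `gene1`, `gene2`, `z_meta`, `p_meta`, `direction`,
#'   `n_total`, `flags`, plus per-cohort `z_<name>` and `p_<name>` columns.
#' @export
meta_analyze <- function(scans, ns = NULL) {
  stopifnot(is.list(scans), length(scans) >= 1L)
  if (is.null(names(scans)) || any(!nzchar(names(scans)))) {
    names(scans) <- paste0("cohort", seq_along(scans))
  }
  if (is.null(ns)) {
    ns <- vapply(scans, function(s) as.numeric(s$n[1]), numeric(1))
  }
  keyed <- lapply(scans, function(s) {
    flip <- s$gene1 > s$gene2
    key1 <- ifelse(flip, s$gene2, s$gene1)
    key2 <- ifelse(flip, s$gene1, s$gene2)
    data.frame(gene1 = key1, gene2 = key2,
               z = z_from_p_sign(s$p, s$beta_int), p = s$p,
               flags = if ("flags" %in% names(s)) s$flags else "",
               stringsAsFactors = FALSE)
  })
  all_pairs <- unique(do.call(rbind, lapply(keyed, function(k) {
    k[, c("gene1", "gene2")]
  })))
  all_pairs <- all_pairs[order(all_pairs$gene1, all_pairs$gene2), ,
                         drop = FALSE]
  key <- paste(all_pairs$gene1, all_pairs$gene2, sep = "\r")

  zmat <- matrix(NA_real_, nrow(all_pairs), length(scans))
  pmat <- matrix(NA_real_, nrow(all_pairs), length(scans))
  flags <- rep(NA_character_, nrow(all_pairs))
  for (j in seq_along(keyed)) {
    k <- keyed[[j]]
    pos <- match(paste(k$gene1, k$gene2, sep = "\r"), key)
    zmat[pos, j] <- k$z
    pmat[pos, j] <- k$p
    take <- is.na(flags[pos])
    flags[pos[take]] <- k$flags[take]
  }
  flags[is.na(flags)] <- ""

  wn <- matrix(rep(ns, each = nrow(zmat)), nrow = nrow(zmat))
  ok <- !is.na(zmat)
  wn_ok <- wn * ok
  z_meta <- rowSums(sqrt(wn) * zmat * ok, na.rm = TRUE) /
    sqrt(rowSums(wn_ok))
  direction <- apply(zmat, 1L, function(zz) {
    paste(ifelse(is.na(zz), "?", ifelse(zz >= 0, "+", "-")), collapse = "")
  })
  out <- data.frame(all_pairs, z_meta = z_meta,
                    p_meta = 2 * pnorm(-abs(z_meta)),
                    direction = direction,
                    n_total = rowSums(wn_ok), flags = flags,
                    stringsAsFactors = FALSE)
  for (j in seq_along(scans)) {
    out[[paste0("z_", names(scans)[j])]] <- zmat[, j]
    out[[paste0("p_", names(scans)[j])]] <- pmat[, j]
  }
  rownames(out) <- NULL
  out
}

#' Default significance ladder thresholds
#'
#' Genome-wide discovery and final thresholds of 5.86e-10 (the 5th
#' percentile of simulated minimum p-values for unlinked pairs, close to
#' the Bonferroni bound 0.05 / choose(20000, 2) ~ 2.5e-10), nominal
#' replication at 0.05 with a same-direction requirement, BH FDR at 0.05
#' within the discovery-significant set, and a suggestive tier at 1e-5.
#'
#' @return Named list of thresholds.
#' @export
twis_thresholds <- function() {
  list(discovery = 5.86e-10, replication_nominal = 0.05,
       replication_fdr = 0.05, final = 5.86e-10, suggestive = 1e-5)
}

#' Stage classification of meta-analyzed pairs
#'
#' Applies the discovery -> replication -> combined significance ladder to
#' filtered pairs: `discovery_sig` when the discovery p passes the
#' genome-wide threshold (filtered pairs never qualify);
#' `replication_nominal` when the replication p is below 0.05 *and* the
#' replication effect has the discovery direction; `replication_fdr` when
#' the BH q-value of the replication p, computed within the
#' discovery-significant set, is below 0.05; `final_sig` when the combined
#' meta p passes the genome-wide threshold; `suggestive` at meta p <= 1e-5.
#'
#' @param discovery_p,replication_p,meta_p Per-pair p-values (`NA` allowed).
#' @param discovery_sign,replication_sign Effect signs per stage.
#' @param flags Filter flags (pairs with non-empty flags are excluded from
#'   significance accounting).
#' @param thresholds A list like [twis_thresholds()].
#' @return Data frame of logical stage flags plus `replication_q`.
#' @export
classify_significance <- function(discovery_p, replication_p, meta_p,
                                  discovery_sign = 1, replication_sign = 1,
                                  flags = "",
                                  thresholds = twis_thresholds()) {
  req <- c("discovery", "replication_nominal", "replication_fdr", "final",
           "suggestive")
  if (!all(req %in% names(thresholds))) {
    stop("unknown or incomplete threshold set; need: ",
         paste(req, collapse = ", "))
  }
  k <- length(discovery_p)
  flags <- rep_len(flags, k)
  discovery_sign <- rep_len(discovery_sign, k)
  replication_sign <- rep_len(replication_sign, k)
  filtered <- nzchar(flags)

  discovery_sig <- !filtered & !is.na(discovery_p) &
    discovery_p < thresholds$discovery
  same_dir <- sign(discovery_sign) == sign(replication_sign)
  replication_nominal <- discovery_sig & !is.na(replication_p) &
    replication_p < thresholds$replication_nominal & same_dir
  replication_q <- rep(NA_real_, k)
  if (any(discovery_sig & !is.na(replication_p))) {
    sel <- discovery_sig & !is.na(replication_p)
    replication_q[sel] <- p.adjust(replication_p[sel], method = "BH")
  }
  replication_fdr <- !is.na(replication_q) &
    replication_q < thresholds$replication_fdr
  final_sig <- !filtered & !is.na(meta_p) & meta_p < thresholds$final
  suggestive <- !filtered & !is.na(meta_p) & meta_p <= thresholds$suggestive
  data.frame(discovery_sig = discovery_sig,
             replication_nominal = replication_nominal,
             replication_q = replication_q,
             replication_fdr = replication_fdr,
             final_sig = final_sig, suggestive = suggestive)
}
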