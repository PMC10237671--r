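#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name <TAB> description <TAB> member...`. Duplicate members are
#' deduplicated. Sets with fewer than `min_size` members -- after
#' intersecting with `tested_genes` when supplied -- are excluded, with the
#' count reported via `message()`.
#'
#' @param path GMT file path.
#' @param min_size Minimum post-intersection set size (default 10).
#' @param tested_genes Optional character vector restricting members to the
#'   genes actually tested.
#' @return A named list of class `gene_set_collection`; each element has
#'   `name`, `category` (the description field), and `members`.
#' @export
read_gene_sets <- function(path, min_size = 10L, tested_genes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0) {
    stop("malformed GMT line ", bad[1], ": fewer than 3 tab-separated fields")
  }
  sets <- lapply(fields, function(f) {
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    list(name = f[1], category = f[2], members = members)
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  if (!is.null(tested_genes)) {
    sets <- lapply(sets, function(s) {
      s$members <- intersect(s$members, tested_genes)
      s
    })
  }
  sizes <- vapply(sets, function(s) length(s$members), integer(1))
  n_excluded <- sum(sizes < min_size)
  if (n_excluded > 0) {
    message(n_excluded, " gene set(s) excluded with fewer than ",
            min_size, " genes")
  }
  structure(sets[sizes >= min_size], class = "gene_set_collection")
}

#' Write gene sets as GMT
#' @param sets A `gene_set_collection` or named list with `members` (and
#'   optionally `category`) per set.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    nm <- if (!is.null(s$name)) s$name else names(sets)[i]
    cat_ <- if (!is.null(s$category)) s$category else "na"
    paste(c(nm, cat_, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Retained within-set pairs: rows of `meta` whose two genes are both set
# members and whose filter flags are empty.
within_set_pairs <- function(meta, members) {
  sel <- meta$gene1 %in% members & meta$gene2 %in% members
  if ("flags" %in% names(meta)) sel <- sel & !nzchar(meta$flags)
  sel <- sel & !is.na(meta$z_meta)
  meta[sel, , drop = FALSE]
}

#' Chi-squared gene-set interaction statistic
#'
#' Sums the squared meta-analyzed interaction Z-scores of all retained
#' within-set pairs: `S = sum(Z^2)` over the `m` pairs surviving the
#' correlation/proximity filters, referred to an upper-tail chi-squared
#' distribution with `m` degrees of freedom. With no retained pair the set
#' is flagged untestable (`p = NA`).
#'
#' @param meta Meta-analysis data frame (needs `gene1`, `gene2`, `z_meta`,
#'   and optionally `flags`).
#' @param set A gene set (list with `name` and `members`) or a character
#'   vector of members.
#' @return One-row data frame: `set`, `n_genes_used`, `m_pairs`, `S`,
#'   `p_chi2`.
#' @export
set_statistic_chi2 <- function(meta, set) {
  if (is.character(set)) set <- list(name = "set", members = set)
  pairs <- within_set_pairs(meta, set$members)
  m <- nrow(pairs)
  genes_used <- length(intersect(set$members,
                                 unique(c(meta$gene1, meta$gene2))))
  S <- sum(pairs$z_meta^2)
  p <- if (m == 0L) NA_real_ else pchisq(S, df = m, lower.tail = FALSE)
  data.frame(set = set$name, n_genes_used = genes_used, m_pairs = m,
             S = S, p_chi2 = p, stringsAsFactors = FALSE)
}

#' Competitive resampling p-value for a gene set
#'
#' Draws `B` random gene sets of the same size from the tested genome,
#' matched on binned weighted-variant counts when available, and compares
#' the observed mean squared interaction Z over retained within-set pairs
#' with the resampled values. The p-value uses add-one smoothing,
#' `p = (1 + #{resamples >= observed}) / (B + 1)`, so the smallest
#' reportable value is `1/(B+1)` (the "< 1/B" floor).
#'
#' @param meta Meta-analysis data frame.
#' @param set Gene set as in [set_statistic_chi2()].
#' @param B Number of resamples (default 1000).
#' @param matching `"variant_bins"` (decile bins of `variant_count`) or
#'   `"uniform"`.
#' @param variant_counts Optional named vector of weighted-variant counts
#'   per gene (names = gene IDs); required for `"variant_bins"`.
#' @param bins Number of matching bins (default 10).
#' @param seed Integer seed (sub-stream `"resampling"`).
#' @return List: `p`, `observed` (mean Z^2), `m_pairs`, `B`, `at_floor`.
#' @export
resampling_pvalue <- function(meta, set, B = 1000L,
                              matching = c("variant_bins", "uniform"),
                              variant_counts = NULL, bins = 10L,
                              seed = NULL) {
  matching <- match.arg(matching)
  if (B < 1L) stop("`B` must be at least 1")
  if (is.character(set)) set <- list(name = "set", members = set)
  pool <- unique(c(meta$gene1, meta$gene2))
  members <- intersect(set$members, pool)
  n_set <- length(members)
  if (n_set < 2L) stop("set has fewer than 2 tested genes")
  if (length(pool) < n_set) stop("gene pool smaller than the set")

  obs_pairs <- within_set_pairs(meta, members)
  if (nrow(obs_pairs) == 0L) stop("no retained within-set pairs")
  observed <- mean(obs_pairs$z_meta^2)

  if (matching == "variant_bins") {
    if (is.null(variant_counts)) {
      stop("`variant_counts` required for variant_bins matching")
    }
    vc <- variant_counts[pool]
    if (anyNA(vc)) stop("variant counts missing for some tested genes")
    brk <- unique(quantile(vc, probs = seq(0, 1, length.out = bins + 1)))
    bin <- cut(vc, breaks = brk, include.lowest = TRUE, labels = FALSE)
    names(bin) <- pool
    target_bins <- bin[members]
    by_bin <- split(pool, bin)
  }

  # pre-index meta by unordered pair for fast lookup across resamples
  key <- paste(meta$gene1, meta$gene2, sep = "\r")
  retained <- if ("flags" %in% names(meta)) !nzchar(meta$flags) else
    rep(TRUE, nrow(meta))
  retained <- retained & !is.na(meta$z_meta)
  z2 <- meta$z_meta^2

  stat_for <- function(genes) {
    cmb <- utils::combn(sort(genes), 2L)
    pos <- match(paste(cmb[1L, ], cmb[2L, ], sep = "\r"), key)
    pos <- pos[!is.na(pos)]
    pos <- pos[retained[pos]]
    if (length(pos) == 0L) return(NA_real_)
    mean(z2[pos])
  }

  resampled <- with_substream(seed, "resampling", {
    vapply(seq_len(B), function(b) {
      draw <- if (matching == "uniform") {
        sample(pool, n_set)
      } else {
        unlist(lapply(split(names(target_bins), target_bins),
                      function(mem) {
                        bb <- bin[mem[1]]
                        sample(by_bin[[as.character(bb)]], length(mem),
                               replace = length(by_bin[[as.character(bb)]]) <
                                 length(mem))
                      }), use.names = FALSE)
      }
      stat_for(draw)
    }, numeric(1))
  })
  resampled <- resampled[!is.na(resampled)]
  p <- (1 + sum(resampled >= observed)) / (length(resampled) + 1)
  list(p = p, observed = observed, m_pairs = nrow(obs_pairs),
       B = length(resampled), at_floor = p <= 1 / (length(resampled) + 1))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; significance at `q <= 0.05`.
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return Vector of BH q-values.
#' @export
fdr_bh <- function(p_values) {
  if (length(p_values) == 0L) stop("empty p-value vector")
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Gene-set enrichment of interaction associations (E-TWIS)
#'
#' Screens every set with the chi-squared statistic, then (by default)
#' re-tests large sets -- where shared genes across pairs make the
#' chi-squared reference anti-conservative -- with the competitive
#' resampling null. BH q-values are computed over the chi-squared p-values.
#'
#' @param meta Meta-analysis data frame.
#' @param sets A `gene_set_collection` (or named list of member vectors).
#' @param resample_min_genes Set size from which resampling is triggered
#'   (default 150).
#' @param B,matching,variant_counts,seed Passed to [resampling_pvalue()].
#' @return Data frame: `set`, `category`, `n_genes_used`, `m_pairs`, `S`,
#'   `p_chi2`, `p_resample`, `q`.
#' @export
etwis <- function(meta, sets, resample_min_genes = 150L, B = 1000L,
                  matching = c("variant_bins", "uniform"),
                  variant_counts = NULL, seed = NULL) {
  matching <- match.arg(matching)
  if (length(sets) == 0L) {
    stop("no gene sets to test (all excluded by the minimum-size rule?)")
  }
  if (!is.list(sets[[1]])) {
    sets <- lapply(seq_along(sets), function(i) {
      list(name = names(sets)[i], category = "na", members = sets[[i]])
    })
    names(sets) <- vapply(sets, `[[`, character(1), "name")
  }
  rows <- lapply(sets, function(s) {
    out <- set_statistic_chi2(meta, s)
    out$category <- if (!is.null(s$category)) s$category else "na"
    out$p_resample <- NA_real_
    if (!is.na(out$p_chi2) && out$n_genes_used >= resample_min_genes) {
      rs <- resampling_pvalue(meta, s, B = B, matching = matching,
                              variant_counts = variant_counts, seed = seed)
      out$p_resample <- rs$p
    }
    out
  })
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  ok <- !is.na(res$p_chi2)
  if (any(ok)) res$q[ok] <- fdr_bh(res$p_chi2[ok])
  res <- res[, c("set", "category", "n_genes_used", "m_pairs", "S",
                 "p_chi2", "p_resample", "q")]
  rownames(res) <- NULL
  res
}
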