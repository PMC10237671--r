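#' Per-gene interaction degree at a p-value threshold
#'
#' Counts, for every gene involved in at least one retained pair with
#' `p <= p_threshold`, the number of distinct interaction partners.
#' Genes with degree at or above `hub_degree` are flagged as hubs. The sum
#' of degrees is twice the number of retained edges (handshake lemma);
#' ties are broken lexicographically by gene ID, so the table is invariant
#' to edge input order.
#'
#' @param meta Meta-analysis (or scan) data frame with `gene1`, `gene2`,
#'   a p-value column, and optionally `flags`.
#' @param p_threshold Edge inclusion threshold (default 1e-5, the
#'   suggestive tier).
#' @param p_column Which p-value column to threshold (default `"p_meta"`,
#'   falling back to `"p"`).
#' @param hub_degree Degree from which a gene is labeled a hub (default 5).
#' @return Data frame sorted by decreasing degree then gene ID: `gene`,
#'   `degree`, `hub`; attribute `"threshold"` records the cutoff.
#' @export
degree_counts <- function(meta, p_threshold = 1e-5, p_column = NULL,
                          hub_degree = 5L) {
  if (is.null(p_column)) {
    p_column <- if ("p_meta" %in% names(meta)) "p_meta" else "p"
  }
  edges <- retained_edges(meta, p_threshold, p_column)
  if (nrow(edges) == 0L) {
    out <- data.frame(gene = character(), degree = integer(),
                      hub = logical(), stringsAsFactors = FALSE)
  } else {
    tab <- table(c(edges$gene1, edges$gene2))
    out <- data.frame(gene = names(tab), degree = as.integer(tab),
                      stringsAsFactors = FALSE)
    out$hub <- out$degree >= hub_degree
    out <- out[order(-out$degree, out$gene), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "threshold") <- p_threshold
  out
}

retained_edges <- function(meta, p_threshold, p_column) {
  p <- meta[[p_column]]
  sel <- !is.na(p) & p <= p_threshold
  if ("flags" %in% names(meta)) sel <- sel & !nzchar(meta$flags)
  meta[sel, , drop = FALSE]
}

#' Compare TWIS-identified genes with single-gene TWAS results
#'
#' Takes the unique genes appearing in retained interaction pairs with
#' `p <= threshold`, looks each up in the single-predictor (TWAS) results,
#' and reports the proportion that the single-gene model would also have
#' identified at the same threshold -- typically a small minority, because
#' genes acting through interactions carry muted main effects. Also exports
#' the paired (largest absolute interaction Z, main-effect Z) per gene for
#' effect-size comparisons.
#'
#' @param meta Meta-analysis data frame.
#' @param twas Single-predictor results from [run_single_predictor_scan()].
#' @param threshold Significance threshold applied to both (default 1e-5).
#' @param p_column Interaction p-value column (default `p_meta`/`p`).
#' @return List: `proportion`, `n_twis_genes`, `n_twas_significant`, and
#'   `genes` (per-gene table with TWIS and TWAS statistics). With no TWIS
#'   gene at the threshold, `proportion` is `NA` and `untestable = TRUE`.
#' @export
twis_vs_twas <- function(meta, twas, threshold = 1e-5, p_column = NULL) {
  if (is.null(p_column)) {
    p_column <- if ("p_meta" %in% names(meta)) "p_meta" else "p"
  }
  edges <- retained_edges(meta, threshold, p_column)
  if (nrow(edges) == 0L) {
    return(list(proportion = NA_real_, n_twis_genes = 0L,
                n_twas_significant = 0L, genes = NULL, untestable = TRUE))
  }
  zcol <- if ("z_meta" %in% names(meta)) "z_meta" else "t"
  long <- rbind(
    data.frame(gene = edges$gene1, z_int = edges[[zcol]]),
    data.frame(gene = edges$gene2, z_int = edges[[zcol]]))
  # one record per gene: its strongest interaction
  long <- long[order(long$gene, -abs(long$z_int)), , drop = FALSE]
  per_gene <- long[!duplicated(long$gene), , drop = FALSE]
  hit <- match(per_gene$gene, twas$gene)
  per_gene$twas_beta <- twas$beta[hit]
  per_gene$twas_p <- twas$p[hit]
  per_gene$twas_significant <- !is.na(per_gene$twas_p) &
    per_gene$twas_p <= threshold
  rownames(per_gene) <- NULL
  list(proportion = mean(per_gene$twas_significant),
       n_twis_genes = nrow(per_gene),
       n_twas_significant = sum(per_gene$twas_significant),
       genes = per_gene, untestable = FALSE)
}

#' Export the interaction network edge list
#'
#' Writes retained edges (pairs passing flags and the p threshold) as a
#' TSV edge list (`gene1`, `gene2`, `z`, `p`) and, optionally, GraphML for
#' network tools. Reading the TSV back reproduces the degree table exactly.
#'
#' @param meta Meta-analysis data frame.
#' @param path Output TSV path.
#' @param p_threshold Edge threshold (default 1e-5).
#' @param p_column See [degree_counts()].
#' @param graphml Optional GraphML output path.
#' @return Invisibly, the edge data frame written.
#' @export
export_edges <- function(meta, path, p_threshold = 1e-5, p_column = NULL,
                         graphml = NULL) {
  if (is.null(p_column)) {
    p_column <- if ("p_meta" %in% names(meta)) "p_meta" else "p"
  }
  edges <- retained_edges(meta, p_threshold, p_column)
  zcol <- if ("z_meta" %in% names(meta)) "z_meta" else "t"
  out <- data.frame(gene1 = edges$gene1, gene2 = edges$gene2,
                    z = edges[[zcol]], p = edges[[p_column]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene1, out$gene2), , drop = FALSE]
  data.table::fwrite(out, path, sep = "\t")
  if (!is.null(graphml)) {
    gr <- igraph::graph_from_data_frame(out, directed = FALSE)
    igraph::write_graph(gr, graphml, format = "graphml")
  }
  invisible(out)
}

#' Plot-ready chromosome/position export for interaction associations
#'
#' Emits one row per gene per retained pair (two rows per interaction)
#' with chromosome, midpoint position, the pair's p-value and a pair
#' identifier -- the coordinates needed to draw paired-point association
#' plots in any plotting tool.
#'
#' @param meta Meta-analysis data frame.
#' @param coords Gene coordinate table.
#' @param path Output TSV path.
#' @param p_threshold Inclusion threshold (default 1e-5).
#' @param p_column See [degree_counts()].
#' @return Invisibly, the exported data frame.
#' @export
export_pair_coordinates <- function(meta, coords, path, p_threshold = 1e-5,
                                    p_column = NULL) {
  if (is.null(p_column)) {
    p_column <- if ("p_meta" %in% names(meta)) "p_meta" else "p"
  }
  coords <- normalize_coords(coords)
  edges <- retained_edges(meta, p_threshold, p_column)
  pair_id <- seq_len(nrow(edges))
  long <- data.frame(
    pair = rep(pair_id, 2L),
    gene = c(edges$gene1, edges$gene2),
    p = rep(edges[[p_column]], 2L), stringsAsFactors = FALSE)
  pos <- match(long$gene, coords$gene_id)
  long$chrom <- coords$chrom[pos]
  long$position <- coords$midpoint[pos]
  long <- long[order(long$pair), c("pair", "gene", "chrom", "position", "p")]
  data.table::fwrite(long, path, sep = "\t")
  invisible(long)
}

#' Descriptive degree-distribution summary
#'
#' Histogram of interaction degrees plus the least-squares slope of
#' log10(count) on log10(degree) -- a descriptive check of the heavy
#' (power-law-like) tail, not a formal power-law fit.
#'
#' @param degrees A [degree_counts()] table.
#' @return List: `histogram` (degree, count) and `loglog_slope`.
#' @export
degree_distribution <- function(degrees) {
  tab <- table(degrees$degree)
  hist <- data.frame(degree = as.integer(names(tab)),
                     count = as.integer(tab))
  slope <- NA_real_
  if (nrow(hist) >= 2L) {
    fit <- stats::lm(log10(count) ~ log10(degree), data = hist)
    slope <- unname(stats::coef(fit)[2L])
  }
  list(histogram = hist, loglog_slope = slope)
}
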