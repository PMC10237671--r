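# Shared in-code fixtures for the suite. Everything is generated
# programmatically; no data files.

# A coordinate table with every gene on its own chromosome slot, spaced so
# the default proximity filter keeps cross-gene pairs.
spread_coords <- function(gene_ids) {
  g <- length(gene_ids)
  data.frame(gene_id = gene_ids,
             chrom = as.character(rep_len(1:22, g)),
             midpoint = 1e6 + 2.5e6 * ave(seq_len(g),
                                          rep_len(1:22, g), FUN = seq_along),
             stringsAsFactors = FALSE)
}

# Independent-gene null dataset: gaussian expression, y with main effects
# scaled to keep total variance 1 and no interaction.
null_dataset <- function(n, n_genes, b_total = 0.5, seed = 1) {
  set.seed(seed)
  E <- matrix(rnorm(n * n_genes), n, n_genes)
  colnames(E) <- sprintf("g%03d", seq_len(n_genes))
  b <- sqrt(b_total / n_genes)
  sig <- as.numeric(E %*% rep(b, n_genes))
  y <- sig + rnorm(n, 0, sqrt(1 - b_total))
  list(y_resid = y, T_resid = E, n = n,
       coords = spread_coords(colnames(E)))
}

# Tiny weight/dosage fixture used across the imputation tests.
toy_imputation_fixture <- function() {
  variants <- data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    chrom = "1", pos = c(100L, 200L, 300L),
    ref = "A", alt = "G", counted_allele = "G",
    stringsAsFactors = FALSE)
  dos <- matrix(c(2, 0, 1,
                  0, 0, 1,
                  1, 2, 0), nrow = 3, byrow = TRUE,
                dimnames = list(c("s1", "s2", "s3"),
                                variants$variant_id))
  coords <- data.frame(gene_id = c("gA", "gB"), chrom = c("1", "2"),
                       midpoint = c(200, 5e6), stringsAsFactors = FALSE)
  weights <- data.frame(
    gene_id = c("gA", "gA", "gB"),
    variant_id = c("rs1", "rs2", "rs3"),
    effect_allele = "G",
    weight = c(0.5, -0.25, 1),
    stringsAsFactors = FALSE)
  list(dosages = dosage_set(dos, variants),
       weights = weight_set(weights, coords),
       coords = coords, raw_weights = weights, variants = variants,
       dosage_matrix = dos)
}
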