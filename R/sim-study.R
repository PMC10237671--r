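#' Simulate a complete TWIS study input bundle
#'
#' Generates everything a downstream analysis consumes: per-gene SNP
#' dosages with variant metadata, a per-gene linear weight set, gene
#' coordinates, true and noise-injected imputed expression, a phenotype
#' driven by the first two genes (main effects plus the configured
#' interaction variance share), and a small covariate table (age, sex, two
#' genotype principal-component stand-ins) with modest effects on the trait.
#'
#' Genes are laid out along chromosomes 2.5 Mb apart so default proximity
#' filters keep cross-gene pairs; SNP weights are drawn standard normal.
#'
#' @param config A [sim_config()].
#' @return List with elements `dosages` (a `dosage_set`), `weights`
#'   (a `weight_set`), `coords`, `expression_true`, `expression_observed`,
#'   `accuracies`, `phenotype` (data.frame `sample_id`, `y`),
#'   `covariates` (data.frame), and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  g <- config$n_genes
  spg <- rep_len(config$snps_per_gene, g)
  seed <- config$seed

  sample_ids <- sprintf("S%05d", seq_len(n))
  gene_ids <- sprintf("GENE%04d", seq_len(g))

  maf <- with_substream(seed, "maf", {
    lapply(seq_len(g), function(j) {
      runif(spg[j], config$maf_range[1], config$maf_range[2])
    })
  })

  # gene layout: round-robin over 22 chromosomes, 2.5 Mb apart within one
  chrom <- as.character(rep_len(1:22, g))
  slot <- ave(seq_len(g), chrom, FUN = seq_along)
  start <- 1e6 + (slot - 1) * 25e5
  end <- start + 2e4
  coords <- data.frame(gene_id = gene_ids, chrom = chrom,
                       start = start, end = end,
                       tss = start, midpoint = (start + end) / 2,
                       stringsAsFactors = FALSE)

  dmats <- vector("list", g)
  for (j in seq_len(g)) {
    if (j == 2L && config$ld_mode != "none") {
      pair <- simulate_genotype_pair(n, spg[1], maf[[1]],
                                     ld_mode = config$ld_mode,
                                     ld_r = config$ld_r,
                                     seed = seed + 101L)
      dmats[[1]] <- pair$gene1
      dmats[[2]] <- pair$gene2
      maf[[2]] <- maf[[1]]
    } else if (is.null(dmats[[j]])) {
      dmats[[j]] <- simulate_genotypes(n, spg[j], maf[[j]],
                                       seed = seed + 101L + j)
    }
  }

  variant_ids <- unlist(lapply(seq_len(g), function(j) {
    sprintf("rs%s_%d", gsub("GENE", "", gene_ids[j]), seq_len(spg[j]))
  }))
  dos <- do.call(cbind, dmats)
  colnames(dos) <- variant_ids
  rownames(dos) <- sample_ids
  variants <- data.frame(
    variant_id = variant_ids,
    chrom = rep(chrom, spg),
    pos = unlist(lapply(seq_len(g), function(j) start[j] + 50L * seq_len(spg[j]))),
    ref = "A", alt = "G", counted_allele = "G",
    stringsAsFactors = FALSE)
  dosages <- dosage_set(dos, variants)

  wvals <- with_substream(seed, "weights", {
    lapply(seq_len(g), function(j) rnorm(spg[j]))
  })
  weights <- weight_set(data.frame(
    gene_id = rep(gene_ids, spg),
    variant_id = variant_ids,
    effect_allele = "G",
    weight = unlist(wvals),
    stringsAsFactors = FALSE), coords)

  expr_true <- simulate_expression("pgs", dosages = dmats, weights = wvals)
  colnames(expr_true) <- gene_ids
  rownames(expr_true) <- sample_ids

  accuracies <- simulate_accuracies(g, config$accuracy_spec, seed = seed)
  expr_obs <- add_prediction_error(expr_true, accuracies, seed = seed)

  covariates <- with_substream(seed, "covariates", {
    data.frame(sample_id = sample_ids,
               age = round(rnorm(n, 55, 8), 1),
               sex = sample(c("F", "M"), n, replace = TRUE),
               pc1 = rnorm(n), pc2 = rnorm(n),
               stringsAsFactors = FALSE)
  })

  if (g >= 2L) {
    y <- simulate_phenotype(expr_true[, 1L], expr_true[, 2L],
                            b1 = config$main_effects[1],
                            b2 = config$main_effects[2],
                            pve_int = config$pve_interaction,
                            seed = seed)
  } else {
    y <- with_substream(seed, "phenotype", rnorm(n))
  }
  # small covariate contributions so residualization has work to do
  cov_sig <- with_substream(seed, "covariate_effects", {
    0.1 * scale(covariates$age)[, 1] + 0.1 * (covariates$sex == "M")
  })
  y <- as.numeric(y) + cov_sig
  if (config$binary_trait) {
    y <- as.integer(y > quantile(y, 1 - config$prevalence, names = FALSE))
  }
  phenotype <- data.frame(sample_id = sample_ids, y = y,
                          stringsAsFactors = FALSE)

  list(dosages = dosages, weights = weights, coords = coords,
       expression_true = expr_true, expression_observed = expr_obs,
       accuracies = accuracies, phenotype = phenotype,
       covariates = covariates, config = config)
}
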