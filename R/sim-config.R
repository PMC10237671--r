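#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generator: cohort size, number of
#' genes, per-gene polygenicity, allele-frequency range, linkage
#' disequilibrium between paired genes, the share of phenotypic variance
#' carried by the gene-gene interaction, standardized main effects, the
#' distribution of expression prediction accuracy (imputation r-squared),
#' and the trait type.
#'
#' Defaults mirror the conditions of the calibration experiments shipped
#' with the package: unlinked genes, minor allele frequencies uniform on
#' (0.05, 0.5], main effects of 0.1 on the standardized scale, and
#' prediction accuracies drawn from a Beta(2, 1) distribution rescaled to
#' (0.01, 1], a right-skewed stand-in for the empirical accuracy histograms
#' of FUSION-style expression models.
#'
#' @param n_individuals Cohort size.
#' @param n_genes Number of genes.
#' @param snps_per_gene SNPs underlying each gene's expression score.
#' @param maf_range Length-2 numeric, minor allele frequency range in (0, 0.5].
#' @param ld_mode One of `"none"`, `"perfect"`, `"block"`; LD between the
#'   SNP sets of paired genes. `"block"` uses `ld_r`.
#' @param ld_r Genotype correlation for `ld_mode = "block"`.
#' @param pve_interaction Fraction of phenotypic variance explained by the
#'   interaction term; must lie in `[0, 1)`.
#' @param main_effects Length-2 standardized main-effect slopes.
#' @param accuracy_spec List describing the prediction-accuracy (r-squared)
#'   distribution; see [simulate_accuracies()].
#' @param binary_trait Logical; threshold a latent liability into a 0/1 trait.
#' @param prevalence Case fraction for binary traits.
#' @param seed Integer master seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 10000L,
                       n_genes = 2L,
                       snps_per_gene = 10L,
                       maf_range = c(0.05, 0.5),
                       ld_mode = c("none", "perfect", "block"),
                       ld_r = 0.5,
                       pve_interaction = 0,
                       main_effects = c(0.1, 0.1),
                       accuracy_spec = accuracy_beta_spec(),
                       binary_trait = FALSE,
                       prevalence = 0.5,
                       seed = 1L) {
  ld_mode <- match.arg(ld_mode)
  stopifnot(n_individuals >= 1, n_genes >= 1, all(snps_per_gene >= 1))
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("`maf_range` must be an increasing interval within (0, 0.5]")
  }
  if (pve_interaction < 0 || pve_interaction >= 1) {
    stop("`pve_interaction` must lie in [0, 1)")
  }
  stopifnot(length(main_effects) == 2L)
  if (binary_trait && (prevalence <= 0 || prevalence >= 1)) {
    stop("`prevalence` must lie in (0, 1)")
  }
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_genes = as.integer(n_genes),
         snps_per_gene = as.integer(snps_per_gene),
         maf_range = as.numeric(maf_range),
         ld_mode = ld_mode, ld_r = ld_r,
         pve_interaction = pve_interaction,
         main_effects = as.numeric(main_effects),
         accuracy_spec = accuracy_spec,
         binary_trait = binary_trait, prevalence = prevalence,
         seed = as.integer(seed),
         rng_kind = "Mersenne-Twister"),
    class = "sim_config"
  )
}

#' Prediction-accuracy distribution specifications
#'
#' `accuracy_beta_spec()` describes a Beta(`shape1`, `shape2`) distribution
#' over prediction r-squared, rescaled to `[min, max]`. The default
#' Beta(2, 1) on (0.01, 1] is right-skewed toward high accuracies.
#' `accuracy_empirical_spec()` resamples a supplied vector of observed
#' r-squared values, matching the practice of drawing prediction error from
#' an empirical accuracy distribution.
#'
#' @param shape1,shape2 Beta shape parameters.
#' @param min,max Rescaling range within (0, 1].
#' @param values Numeric vector of observed r-squared values in (0, 1].
#' @return A list consumed by [simulate_accuracies()].
#' @export
accuracy_beta_spec <- function(shape1 = 2, shape2 = 1, min = 0.01, max = 1) {
  stopifnot(min > 0, max <= 1, min < max)
  list(type = "beta", shape1 = shape1, shape2 = shape2, min = min, max = max)
}

#' @rdname accuracy_beta_spec
#' @export
accuracy_empirical_spec <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values)) ||
      any(values <= 0 | values > 1)) {
    stop("empirical accuracies must be finite values in (0, 1]")
  }
  list(type = "empirical", values = values)
}

#' Draw per-gene expression prediction accuracies
#'
#' @param n_genes Number of genes.
#' @param spec An accuracy specification, see [accuracy_beta_spec()].
#' @param seed Integer seed (sub-stream `"accuracies"`).
#' @return Numeric vector of r-squared values in (0, 1].
#' @export
simulate_accuracies <- function(n_genes, spec = accuracy_beta_spec(),
                                seed = NULL) {
  with_substream(seed, "accuracies", {
    r2 <- switch(spec$type,
      beta = spec$min + (spec$max - spec$min) *
        rbeta(n_genes, spec$shape1, spec$shape2),
      empirical = sample(spec$values, n_genes, replace = TRUE),
      stop("unknown accuracy spec type: ", spec$type)
    )
    r2
  })
}
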