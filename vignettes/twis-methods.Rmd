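---
title: "Methods: pairwise interaction testing on imputed expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise interaction testing on imputed expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

twiskit tests statistical epistasis at the level of genetically imputed
gene expression. Each gene's expression is a local polygenic score
$T_g = \sum_j w_{gj} d_j$ over the SNP dosages $d_j$ of its expression
model, and for every unordered pair of genes the package fits

$$y_{\mathrm{resid}} = \mu + \beta_1 T_{1,\mathrm{resid}}
  + \beta_2 T_{2,\mathrm{resid}}
  + \beta_{\mathrm{int}}\, T_{1,\mathrm{resid}} T_{2,\mathrm{resid}}
  + \varepsilon,$$

reporting $\beta_{\mathrm{int}}$, its standard error, and a two-sided
p-value from a $t$ distribution with $n-4$ degrees of freedom. This is an
additive-by-additive definition of interaction on the expression scale; it
does not require physical contact of gene products, and it does not cover
dominance or higher-order terms.

Proper covariate control in interaction models requires every
covariate-by-main-effect term, which is prohibitively slow across tens of
millions of pairs. The package therefore projects the phenotype and every
expression column once onto the covariate design (ordinary least squares
for quantitative traits, logistic response residuals $y - \hat p$ for
binary ones) and runs the three-term model on residuals. The suite
verifies, by simulation, that this residualization matches the type-I
error of the full covariate-interaction model, while the superficially
similar variant that residualizes the *product* $T_1 T_2$ separately is
anti-conservative whenever covariates both correlate with expression and
interact with its effect — which is why `residualize_dataset()` never
residualizes products, and the product variant exists only inside the
calibration suite as a negative control.

## Filters and thresholds

Correlated predictors inflate interaction statistics. Two filters are
applied to every pair, and filtered pairs are recorded but excluded from
significance accounting:

* imputed-expression correlation $|r| > 0.05$ (`r_threshold`);
* same chromosome with gene midpoints less than 1 Mb apart
  (`dist_threshold`).

The significance ladder (`twis_thresholds()`) uses a genome-wide
$p < 5.86 \times 10^{-10}$ at discovery and in the combined meta-analysis,
nominal $p < 0.05$ with a same-direction requirement (plus a BH
$q < 0.05$ tier within the discovery-significant set) at replication, and
$p \le 10^{-5}$ as a suggestive tier for degree counting and set
enrichment. The genome-wide constant is consumed as a constant: it is the
5th percentile of minimum p-values over simulated unlinked genome-scale
studies, close to the Bonferroni bound
$0.05/\binom{20000}{2} \approx 2.5\times10^{-10}$. Reproducing it exactly
requires on the order of $10^9$ tests per study; the package instead
validates the *procedure* (`alpha_determination()`) at reduced test
counts, where the 5th percentile of minimum p must match the
order-statistic closed form $1 - 0.95^{1/G}$ for independent tests.

Cohorts are combined by METAL-style sample-size weighting,
$Z = \sum_i \sqrt{N_i} z_i / \sqrt{\sum_i N_i}$, with $z_i$ derived from
each cohort's two-sided p-value and effect sign. Residualization changes
effect scales across cohorts, so an inverse-variance combination of betas
would be inappropriate; sample-size weighting is deliberate.

## Scan mechanics

The exhaustive scan enumerates the $m = n(n-1)/2$ pairs by a 1-based
linear index (`pair_from_linear_index()`), so work splits into contiguous
chunks that concatenate to the full result regardless of the chunk count.
Per-pair second moments come from a handful of gene-by-gene matrix
products ($E^\top E$, $(E\circ E)^\top E$, $(E\circ E)^\top (E\circ E)$,
$(E\circ y)^\top E$), after which each pair's slope system is a $3\times3$
solve performed with vectorized adjugate formulas. The batch path is
required by tests to match `lm()` to $10^{-8}$ relative tolerance.

Numerical edge cases: a singular system (determinant below $10^{-12}$
times the product of the diagonal moments, e.g. duplicated genes) yields
a flagged record with `p = NA` rather than an exception, so a
hundred-million-pair scan never aborts; the calibration experiments use a
pivoted QR fallback instead, because their perfectly linked error-free
cells make the product term a quadratic that remains estimable.
P-values are kept in full double precision with no underflow clipping.

## Gene-set enrichment

E-TWIS aggregates meta-analyzed interaction Z-scores within a gene set:
$S = \sum_{\text{retained pairs}} Z^2$, referred to $\chi^2_m$. Because
pairs within a set share genes, and genes carry main effects, $S$ is
overdispersed for large sets; the suite demonstrates this
anti-conservatism (sets of hundreds of genes reject well above nominal
under the null) as a documented diagnostic. The competitive resampling
path redraws `n` genes `B = 1000` times from the tested genome, matched
on decile bins of weighted-variant count (the observable stand-in for
"gene size"; genomic span is carried in the coordinate table but not used
by default), and compares mean $Z^2$. The empirical p-value uses add-one
smoothing $(1+k)/(B+1)$, so it floors at $1/(B+1)$ rather than zero.
Resampling is auto-triggered for sets of 150 genes or more. Sets with
fewer than 10 tested genes are excluded on input.

## The synthetic-data generator

`simulate_study()` and the lower-level generators emulate the statistical
structure the calibration experiments assume:

* genotypes are independent Binomial(2, MAF) dosages under Hardy-Weinberg
  proportions, MAF uniform on (0.05, 0.5] by default; paired genes can
  share SNP columns exactly (`ld_mode = "perfect"`) or partially
  (`"block"`, an allele-exchange construction with genotype correlation
  `ld_r`);
* expression is either i.i.d. standard normal or a local polygenic score
  (weighted dosage sum), standardized to unit variance *before* noise
  injection and not re-standardized afterwards;
* prediction error adds $N(0, 1-r^2)$ noise per gene, with accuracies
  $r^2$ drawn from a Beta(2, 1) distribution rescaled to (0.01, 1] — a
  right-skewed stand-in for the accuracy histograms of FUSION-style
  expression models; an empirical accuracy vector can be supplied
  instead and is resampled;
* phenotypes are
  $y = b_1 t_1 + b_2 t_2 + \beta_{\mathrm{int}} t_1 t_2 + e$ with
  $\beta_{\mathrm{int}} = \sqrt{\mathrm{PVE}/\widehat{\mathrm{Var}}(t_1 t_2)}$
  and the error variance chosen so $\mathrm{Var}(y) = 1$; main effects
  default to 0.1 on the standardized scale (the interaction test is
  nearly insensitive to them);
* binary traits threshold the latent liability at a stated prevalence
  (default 0.5) — a liability-threshold construction chosen because no
  more specific mechanism is implied by the linear-on-residuals test that
  consumes the data.

Randomness is Mersenne-Twister throughout, with per-operation sub-streams
derived from `(seed, operation name)` so call order cannot change any one
operation's output, and the caller's RNG state is always restored.

What the generator does *not* emulate: haplotype-level (coalescent) LD,
population structure, relatedness, and real expression-weight sparsity
patterns. Passing calibration on these synthetic inputs therefore shows
the statistics behave as designed under the stated generating model, not
that any particular real dataset is free of the LD pathologies the
filters exist for.

## Calibration experiments and problem sizes

The shipped experiments run at desk scale, with flags to enlarge them:

* `power_grid()` — defaults 2,000 replicates per cell; the acceptance
  workflow uses N = 10,000 under the null with prediction error;
* `ld_false_positive_experiment()` — N = 5,000, 2,000 replicates per
  cell, polygenicity {2, 10, 20, 50, 100} crossed with LD {0, 1};
  the inflation-producing condition is a binomial score in perfect LD
  with large added error (accuracy 0.1), while gaussian expression and
  exact scores stay calibrated;
* `causal_snp_experiment()` — a faithful analogue, not a replication, of
  the causal-SNP scenario: within-gene LD comes from latent-allele
  sharing with per-SNP probabilities uniform on (0, 1), and a SNP's LD
  score is its within-gene sum of squared genotype correlations;
* `alpha_determination()` — 100–400 studies of 50–100 tests each;
  genome-scale runs are explicitly not attempted;
* `residualization_comparison()` — n = 5,000, 2,000 replicates, one
  covariate with correlation 0.5 to each gene's expression, covariate
  main effect 0.3 and covariate-by-expression interactions 0.1. The
  covariate-by-expression interactions are the ingredient that makes the
  product-residualization variant fail: under a purely linear truth all
  three strategies are calibrated (which the suite also checks), whereas
  any nonzero interaction biases the separately residualized product
  term. Their strength is kept moderate deliberately — at much larger
  values the unmodeled interaction terms leave heteroskedastic residuals
  whose plain OLS standard errors are slightly too small, so even the
  residualized-expression approach drifts above nominal; 0.1 is well
  inside the regime where it is indistinguishable from the full model.

Every rejection-rate cell is reproducible bit-exactly from its
`(configuration, seed)` pair, and with/without-error power comparisons
share their base draws (common random numbers) to sharpen paired
contrasts.

## Known limitations

Only additive-by-additive interactions are modeled; binary traits are
residualized by logistic regression but then tested with the linear
model, which is an approximation at extreme prevalence; the resampling
matcher bins on variant count only; and the chi-squared set statistic
should not be trusted for sets of more than ~150 genes without the
resampling confirmation.
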