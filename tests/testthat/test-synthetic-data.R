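test_that("simulated genotypes have binomial moments and respect maf bounds", {
  g <- simulate_genotypes(10000, 4, maf = 0.5, seed = 11)
  expect_true(all(g %in% 0:2))
  expect_true(all(abs(colMeans(g) - 1) < 0.05))
  expect_true(all(abs(apply(g, 2, var) - 0.5) < 0.05))

  # near-zero maf: all dosages zero with overwhelming probability
  g0 <- simulate_genotypes(100, 3, maf = 1e-6, seed = 1)
  expect_true(all(g0 == 0))

  expect_error(simulate_genotypes(10, 2, maf = 0.6), "maf")
  expect_error(simulate_genotypes(10, 2, maf = 0), "maf")
})

test_that("genotype pair LD modes give the intended cross-gene correlation", {
  pp <- simulate_genotype_pair(500, 3, maf = 0.3, ld_mode = "perfect",
                               seed = 2)
  expect_identical(pp$gene1, pp$gene2)

  pn <- simulate_genotype_pair(50000, 1, maf = 0.3, ld_mode = "none",
                               seed = 2)
  expect_lt(abs(cor(pn$gene1[, 1], pn$gene2[, 1])), 0.05)

  pb <- simulate_genotype_pair(50000, 1, maf = 0.3, ld_mode = "block",
                               ld_r = 0.6, seed = 2)
  expect_lt(abs(cor(pb$gene1[, 1], pb$gene2[, 1]) - 0.6), 0.05)
})

test_that("gaussian expression is standard normal and mutually independent", {
  e <- simulate_expression("gaussian", n_ind = 50000, n_genes = 20,
                           standardize = FALSE, seed = 3)
  expect_true(all(abs(apply(e, 2, var) - 1) < 0.03))
  r <- cor(e)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
})

test_that("pgs expression is the centered weighted dosage sum", {
  d <- matrix(c(0, 1, 2), ncol = 1)
  e <- simulate_expression("pgs", dosages = d, weights = 1,
                           standardize = FALSE)
  expect_equal(as.numeric(e), c(-1, 0, 1))

  # 10 unlinked maf-0.5 SNPs, unit weights: variance ~ 10 * 0.5 = 5
  d10 <- simulate_genotypes(50000, 10, maf = 0.5, seed = 4)
  e10 <- simulate_expression("pgs", dosages = d10,
                             weights = rep(1, 10), standardize = FALSE)
  expect_lt(abs(var(as.numeric(e10)) - 5), 0.15)

  expect_error(simulate_expression("pgs"), "dosages")
  expect_error(simulate_expression("pgs", dosages = d, weights = c(1, 2)),
               "match")
})

test_that("prediction error injection follows the one-minus-r2 noise law", {
  set.seed(5)
  e <- matrix(rnorm(100000), ncol = 1)
  expect_identical(add_prediction_error(e, 1, seed = 5), e)

  noisy <- add_prediction_error(e, 0.5, seed = 5)
  expect_lt(abs(cor(noisy, e) - 1 / sqrt(1.5)), 0.01)
  expect_lt(abs(var(as.numeric(noisy)) - 1.5), 0.03)

  expect_error(add_prediction_error(e, 0), "accuracies")
  expect_error(add_prediction_error(e, 1.2), "accuracies")
})

test_that("phenotype construction hits the requested interaction PVE", {
  set.seed(6)
  t1 <- rnorm(200000); t2 <- rnorm(200000)
  y <- simulate_phenotype(t1, t2, pve_int = 0.005, seed = 6)
  # independent standard normals: Var(t1*t2) ~ 1, so beta ~ sqrt(0.005)
  expect_lt(abs(attr(y, "beta_int") - sqrt(0.005)), 0.005)
  expect_lt(abs(var(as.numeric(y)) - 1), 0.02)

  # pve 0: interaction slope not significantly different from zero
  y0 <- simulate_phenotype(t1[1:20000], t2[1:20000], pve_int = 0, seed = 7)
  it <- interaction_test(as.numeric(y0), t1[1:20000], t2[1:20000])
  expect_lt(abs(it$beta_int), 3 * it$se)

  expect_error(simulate_phenotype(t1, t2, b1 = 0.9, b2 = 0.9,
                                  pve_int = 0.5),
               "100%")
})

test_that("binary phenotypes match the requested prevalence", {
  set.seed(8)
  t1 <- rnorm(20000); t2 <- rnorm(20000)
  y <- simulate_phenotype(t1, t2, binary = TRUE, prevalence = 0.2, seed = 8)
  expect_true(all(y %in% 0:1))
  expect_lt(abs(mean(y) - 0.2), 0.02)
})

test_that("fixed seed gives byte-identical output; substreams are isolated", {
  a <- simulate_genotypes(100, 5, maf = 0.3, seed = 42)
  b <- simulate_genotypes(100, 5, maf = 0.3, seed = 42)
  expect_identical(a, b)

  # interleaving other stochastic calls does not shift the substream
  a2 <- local({
    simulate_expression("gaussian", n_ind = 10, n_genes = 2, seed = 9)
    simulate_genotypes(100, 5, maf = 0.3, seed = 42)
  })
  expect_identical(a, a2)

  # user RNG state is restored after a seeded call
  set.seed(1); x1 <- rnorm(1)
  set.seed(1); invisible(simulate_genotypes(10, 2, maf = 0.2, seed = 3))
  expect_identical(rnorm(1), x1)
})

test_that("accuracy specs validate and draw within their support", {
  r2 <- simulate_accuracies(5000, accuracy_beta_spec(), seed = 10)
  expect_true(all(r2 > 0 & r2 <= 1))
  expect_gt(mean(r2), 0.5) # Beta(2,1) is right-skewed toward 1

  emp <- accuracy_empirical_spec(c(0.2, 0.4, 0.9))
  r2e <- simulate_accuracies(100, emp, seed = 10)
  expect_true(all(r2e %in% c(0.2, 0.4, 0.9)))
  expect_error(accuracy_empirical_spec(c(0.5, 1.2)), "0, 1")
})

test_that("a simulated study round-trips through its file writers", {
  st <- simulate_study(sim_config(n_individuals = 60, n_genes = 4,
                                  snps_per_gene = 3, seed = 21))
  td <- withr::local_tempdir()

  stem <- file.path(td, "dos")
  write_dosage_tsv(st$dosages, stem)
  ds2 <- read_dosage_tsv(stem)
  expect_equal(ds2$dosages, st$dosages$dosages)

  wdir <- file.path(td, "weights")
  write_score_files(st$weights, wdir)
  ws2 <- read_weights(wdir, st$coords)
  w1 <- st$weights$weights[order(st$weights$weights$variant_id), ]
  w2 <- ws2$weights[order(ws2$weights$variant_id), ]
  expect_equal(w2$weight, w1$weight, tolerance = 1e-12)

  cpath <- file.path(td, "genes.bed.tsv")
  write_gene_coords(st$coords, cpath)
  co <- read_gene_coords(cpath)
  expect_equal(co$midpoint, st$coords$midpoint)

  ppath <- file.path(td, "pheno.tsv")
  write_sample_table(st$phenotype, ppath)
  expect_equal(read_sample_table(ppath)$y, st$phenotype$y)
})

test_that("minimal DS-field VCF round-trips through vcfR", {
  skip_if_not_installed("vcfR")
  st <- simulate_study(sim_config(n_individuals = 20, n_genes = 2,
                                  snps_per_gene = 2, seed = 22))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_dosage_vcf(st$dosages, path)
  ds2 <- read_dosage_vcf(path)
  expect_equal(unname(ds2$dosages), unname(st$dosages$dosages),
               tolerance = 1e-6)
  expect_equal(ds2$variants$pos, st$dosages$variants$pos)
})
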