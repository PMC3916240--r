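test_that("genotype simulation matches the binomial sampling model", {
  g <- simulate_genotypes(10000, 10000, mafs = c(0, 1, 0.3), seed = 7)

  # degenerate frequencies are exact
  expect_true(all(g$female_dosages[, 1] == 0))
  expect_true(all(g$male_dosages[, 1] == 0))
  expect_true(all(g$female_dosages[, 2] == 2))
  expect_true(all(g$male_dosages[, 2] == 1))

  # maf 0.3: empirical frequency within 3 binomial SEs
  se_f <- sqrt(0.3 * 0.7 / (2 * 10000))
  se_m <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(g$snps$eaf_female[3] - 0.3), 3 * se_f)
  expect_lt(abs(g$snps$eaf_male[3] - 0.3), 3 * se_m)

  # dosage ranges and metadata lengths
  expect_true(all(g$female_dosages %in% 0:2))
  expect_true(all(g$male_dosages %in% 0:1))
  expect_equal(nrow(g$snps), 3)

  # seeded runs are bit-reproducible
  g2 <- simulate_genotypes(10000, 10000, mafs = c(0, 1, 0.3), seed = 7)
  expect_identical(g$female_dosages, g2$female_dosages)
  expect_identical(g$male_dosages, g2$male_dosages)

  expect_error(simulate_genotypes(-1, 10, 0.1, seed = 1), "non-negative")
  expect_error(simulate_genotypes(10, 10, 1.2, seed = 1), "\\[0, 1\\]")
})

test_that("phenotype simulation inverts the dosage-compensation contrast", {
  skip_if_not_installed("xcwas")
  g <- simulate_genotypes(50000, 50000, mafs = 0.3, seed = 21)

  # NDC: regression on {0,2} male coding recovers b/2; female slope = b
  arch <- x_architecture(1, 0.5, "NDC", resid_var = 1)
  ph <- simulate_phenotype(g, arch, seed = 22)
  fem <- ph[ph$sex == "female", ]
  mal <- ph[ph$sex == "male", ]
  slope_f <- stats::coef(stats::lm(fem$trait ~ g$female_dosages[, 1]))[2]
  slope_m02 <- stats::coef(stats::lm(mal$trait ~ I(2 * g$male_dosages[, 1])))[2]
  expect_equal(unname(slope_f), 0.5, tolerance = 0.05)
  expect_equal(unname(slope_m02), 0.25, tolerance = 0.05)

  # FDC: male carrier shift equals female homozygote-class shift
  arch_f <- x_architecture(1, 0.5, "FDC", resid_var = 0.25)
  phf <- simulate_phenotype(g, arch_f, seed = 23)
  gm <- phf$genetic_value[phf$sex == "male"]
  gf <- phf$genetic_value[phf$sex == "female"]
  d_m <- mean(gm[g$male_dosages[, 1] == 1]) - mean(gm[g$male_dosages[, 1] == 0])
  d_f <- mean(gf[g$female_dosages[, 1] == 2]) - mean(gf[g$female_dosages[, 1] == 0])
  expect_equal(d_m, d_f, tolerance = 1e-10)  # genetic values are noiseless

  # null architecture: trait variance ~ residual variance in both sexes
  ph0 <- simulate_phenotype(g, x_architecture(integer(), numeric(), "FDC", 1),
                            seed = 24)
  expect_equal(stats::var(ph0$trait[ph0$sex == "male"]), 1, tolerance = 0.05)
  expect_equal(stats::var(ph0$trait[ph0$sex == "female"]), 1, tolerance = 0.05)

  expect_error(simulate_phenotype(g, x_architecture(5, 1, "FDC", 1), seed = 1),
               "out of range")
})

test_that("per-sex genetic variance ratios follow the dosage-compensation model", {
  g <- simulate_genotypes(20000, 20000, mafs = c(0.2, 0.4), seed = 31)
  ratio <- function(model) {
    ph <- simulate_phenotype(g, x_architecture(1:2, 0.4, model, 1), seed = 32)
    stats::var(ph$genetic_value[ph$sex == "male"]) /
      stats::var(ph$genetic_value[ph$sex == "female"])
  }
  expect_equal(ratio("FDC"), 2, tolerance = 0.1)
  expect_equal(ratio("NDC"), 0.5, tolerance = 0.05)
  expect_equal(ratio("EV"), 1, tolerance = 0.1)
})

test_that("inverse normal transform is the Blom rank-quantile map", {
  # two distinct values: symmetric +/- z from the quantile function itself
  z <- stats::qnorm((1 - 3 / 8) / (2 + 1 / 4))
  expect_equal(inverse_normal_transform(c(10, 3)), c(-z, z))

  # invariance under strictly monotone transforms
  x <- c(3.2, -1, 0.5, 7, 2, 2.5)
  expect_equal(inverse_normal_transform(x), inverse_normal_transform(exp(x)))

  # mean ~ 0 by symmetry of the offsets; sd ~ 1
  set.seed(1)
  for (n in c(5, 50, 500)) {
    y <- inverse_normal_transform(stats::rexp(n))
    expect_lt(abs(mean(y)), 1e-8)
    expect_equal(stats::sd(y), 1, tolerance = 0.15)
  }

  # ties get average ranks: tied inputs map to identical outputs
  yt <- inverse_normal_transform(c(1, 2, 2, 3))
  expect_equal(yt[2], yt[3])

  expect_error(inverse_normal_transform(rep(1, 5)), "constant")
  expect_error(inverse_normal_transform(c(1, NA, NA)), "finite")
})

test_that("covariate adjustment matches a hand-computed OLS fit", {
  # 6-sample fixture, residuals from the normal equations
  trait <- c(1.2, 0.7, -0.3, 2.2, 1.1, 0.4)
  cov1 <- c(0.5, -0.2, 0.1, 1.4, 0.8, -0.5)
  X <- cbind(1, cov1)
  r_oracle <- trait - X %*% solve(t(X) %*% X, t(X) %*% trait)

  ph <- tibble::tibble(iid = letters[1:6], sex = rep("female", 6),
                       trait = trait, cov1 = cov1)
  out <- adjust_covariates(ph, covariates = "cov1", sex_separate = FALSE)
  expect_equal(out$normalized_residual,
               inverse_normal_transform(drop(r_oracle)))

  # no covariates: residual is the centred trait, so INT(centred) = INT(trait)
  out0 <- adjust_covariates(ph, covariates = character(), sex_separate = FALSE)
  expect_equal(out0$normalized_residual, inverse_normal_transform(trait))

  # within-sex normalisation: mean ~ 0, sd ~ 1 per sex and order preserved
  st <- make_small_study(50, 50, m = 5, covs = 2)
  byg <- split(st$pheno$normalized_residual, st$pheno$sex)
  for (v in byg) {
    expect_lt(abs(mean(v)), 1e-8)
    expect_equal(stats::sd(v), 1, tolerance = 0.05)
  }

  # covariate equal to the trait: residuals constant, INT must error
  ph_bad <- dplyr::mutate(ph, cov1 = trait)
  expect_error(adjust_covariates(ph_bad, "cov1", sex_separate = FALSE),
               "constant")

  # collinear covariates named in the error
  ph2 <- dplyr::mutate(ph, cov2 = 2 * cov1)
  expect_error(adjust_covariates(ph2, c("cov1", "cov2"), sex_separate = FALSE),
               "cov2")
})
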