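test_that("GRM entries match a direct summation oracle", {
  # 3 females x 4 SNPs toy matrix, hand-expanded sum
  g <- simulate_genotypes(3, 2, mafs = c(0.2, 0.3, 0.4, 0.5), seed = 1)
  grm <- make_grm(g, "EV", maf_min = 0)
  nf <- 3; nm <- 2
  p <- (colSums(g$female_dosages) + colSums(g$male_dosages)) / (2 * nf + nm)
  poly <- p > 0 & p < 1  # the builder skips sample-monomorphic SNPs
  p <- p[poly]
  Z <- rbind(
    sweep(sweep(g$female_dosages[, poly, drop = FALSE], 2, 2 * p),
          2, sqrt(2 * p * (1 - p)), "/"),
    sweep(sweep(g$male_dosages[, poly, drop = FALSE], 2, p),
          2, sqrt(p * (1 - p)), "/")
  )
  direct <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    direct[i, j] <- mean(Z[i, ] * Z[j, ])
  }
  expect_equal(unname(grm$matrix), direct)
})

test_that("male diagonal scaling tracks the dosage-compensation model", {
  g <- simulate_genotypes(400, 400, mafs = runif(300, 0.1, 0.5), seed = 3)
  fdc <- make_grm(g, "FDC"); ndc <- make_grm(g, "NDC"); ev <- make_grm(g, "EV")
  male <- ev$sex == "male"

  # male-male block ratio FDC/NDC = (sqrt(2))^2 / (1/sqrt(2))^2 = 4 exactly
  expect_equal(fdc$matrix[male, male], 4 * ndc$matrix[male, male])

  # EV diagonal means ~ 1 in both sexes; FDC males ~ 2; NDC males ~ 0.5
  expect_equal(mean(diag(ev$matrix)[!male]), 1, tolerance = 0.05)
  expect_equal(mean(diag(ev$matrix)[male]), 1, tolerance = 0.05)
  expect_equal(mean(diag(fdc$matrix)[male]), 2, tolerance = 0.1)
  expect_equal(mean(diag(ndc$matrix)[male]), 0.5, tolerance = 0.03)

  # duplicate samples: identical rows give off-diagonal equal to diagonal
  g2 <- g
  g2$female_dosages[2, ] <- g2$female_dosages[1, ]
  grm2 <- make_grm(g2, "EV")
  expect_equal(grm2$matrix[1, 2], grm2$matrix[1, 1])

  # permutation invariance via a plain diploid matrix
  W <- matrix(rbinom(50 * 60, 2, 0.3), 50, 60)
  A <- make_grm(W)$matrix
  perm <- sample(50)
  Ap <- make_grm(W[perm, ])$matrix
  expect_equal(Ap, A[perm, perm], ignore_attr = TRUE)

  expect_error(make_grm(matrix(0, 10, 3)), "polymorphic")
})

test_that("greedy relatedness pruning leaves no pair above threshold", {
  # no pair above threshold: everyone kept
  A <- diag(10)
  expect_length(prune_related(A, 0.05), 10)

  # one pair above: exactly one of the two dropped
  A[1, 2] <- A[2, 1] <- 0.2
  kept <- prune_related(A, 0.05)
  expect_length(kept, 9)
  expect_length(intersect(kept, c("1", "2")), 1)

  # random 50x50: validity checked by exhaustive pairwise scan
  set.seed(4)
  R <- matrix(rnorm(2500, 0, 0.05), 50, 50)
  R <- (R + t(R)) / 2; diag(R) <- 1
  rownames(R) <- colnames(R) <- paste0("s", 1:50)
  kept <- prune_related(R, 0.05)
  sub <- R[kept, kept]
  diag(sub) <- 0
  expect_true(all(abs(sub) <= 0.05))
  # determinism
  expect_identical(kept, prune_related(R, 0.05))
})

test_that("REML matches a 1-D spectral grid search on a toy GRM", {
  # two-eigenvalue GRM: restricted likelihood evaluable in closed form
  set.seed(6)
  n <- 500
  Q <- qr.Q(qr(matrix(rnorm(n * n), n)))
  lam <- rep(c(2, 0.5), length.out = n)
  A <- Q %*% diag(lam) %*% t(Q)
  A <- (A + t(A)) / 2
  y <- drop(Q %*% (sqrt(lam) * rnorm(n))) * sqrt(0.4) + rnorm(n, 0, sqrt(0.6))

  fit <- reml_fit(y, A)
  expect_true(fit$converged)

  # oracle: profile restricted log-likelihood over h = sg/(sg+se) on a grid,
  # using the eigendecomposition of A
  X <- matrix(1, n, 1)
  rll <- function(sg, se) {
    V <- sg * A + se * diag(n)
    Vi <- solve(V)
    XtViX <- crossprod(X, Vi %*% X)
    P <- Vi - Vi %*% X %*% solve(XtViX) %*% crossprod(X, Vi)
    -0.5 * (determinant(V)$modulus[1] + log(XtViX[1, 1]) + sum(y * (P %*% y)))
  }
  grid <- expand.grid(sg = seq(0.05, 1, by = 0.025),
                      se = seq(0.05, 1, by = 0.025))
  vals <- mapply(rll, grid$sg, grid$se)
  best <- grid[which.max(vals), ]
  expect_equal(unname(fit$sigma2["G1"]), best$sg, tolerance = 0.03)
  expect_equal(unname(fit$sigma2["residual"]), best$se, tolerance = 0.03)
  expect_gte(fit$loglik, max(vals) - 1e-6)
})

test_that("REML recovers a simulated X-linked heritability", {
  set.seed(11)
  g <- simulate_genotypes(1000, 1000, runif(1000, 0.05, 0.5), seed = 11)
  grm <- make_grm(g, "EV")
  n <- 2000
  L <- chol(grm$matrix + diag(1e-6, n))
  y <- drop(t(L) %*% rnorm(n)) * sqrt(0.3) + rnorm(n, 0, sqrt(0.7))
  fit <- reml_fit(y, grm)
  expect_true(fit$converged)
  expect_lt(abs(unname(fit$h2) - 0.30), 2 * fit$h2_se)

  # null trait: estimate near zero and boundary LRT well-behaved
  y0 <- rnorm(n)
  f1 <- reml_fit(y0, grm)
  f0_ll <- local({
    # null model: residual only; restricted likelihood has closed form
    X <- matrix(1, n, 1)
    s2 <- sum((y0 - mean(y0))^2) / (n - 1)
    -0.5 * (n * log(s2) + log(n / s2) + (n - 1))
  })
  expect_lt(unname(f1$h2), 0.05)
  lrt <- lrt_zero_variance(f1$loglik, f0_ll)
  expect_gte(lrt$lr, 0)
  # a null trait should not look significant; boundary mixture caps p at 0.5
  expect_gt(lrt$p, 0.01)
  expect_lte(lrt$p, 0.5)
})

test_that("boundary LRT uses the half-half chi-square mixture", {
  expect_equal(lrt_zero_variance(-10, -10)$p, 0.5)
  expect_equal(lrt_zero_variance(-10, -10 - 2.706 / 2)$p, 0.05,
               tolerance = 1e-3)
  # monotone decreasing in LR
  p <- vapply(seq(0, 10, by = 0.5),
              function(l) lrt_zero_variance(l / 2, 0)$p, 0)
  expect_true(all(diff(p) < 0))
  expect_error(lrt_zero_variance(-10, -9), "optimizer")
})

test_that("identity-only GRM is flagged unidentifiable, not an error", {
  f <- reml_fit(rnorm(100), diag(100))
  expect_false(f$converged)
  expect_s3_class(tidy(f), "tbl_df")
  expect_s3_class(glance(f), "tbl_df")
})

test_that("GRM text serialisation round-trips bit-exactly", {
  g <- simulate_genotypes(20, 15, runif(40, 0.1, 0.5), seed = 8)
  grm <- make_grm(g, "NDC")
  prefix <- file.path(withr::local_tempdir(), "toy")
  write_grm(grm, prefix)
  back <- read_grm(prefix, dc_model = "NDC")
  expect_identical(unname(back$matrix), unname(grm$matrix))
  expect_identical(back$sample_ids, grm$sample_ids)
  expect_identical(back$sex, grm$sex)
  expect_identical(back$m_snps, grm$m_snps)
})
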