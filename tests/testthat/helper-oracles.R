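# Independent oracles used across test files.

# Marginal likelihood by 1-D quadrature over the shared effect theta:
# integral of N(bF; theta, seF^2) N(bM; c*theta, seM^2) N(theta; 0, s^2)
quadrature_log_marginal <- function(b_f, se_f, b_m, se_m, s, c) {
  f <- function(theta) {
    stats::dnorm(b_f, theta, se_f) * stats::dnorm(b_m, c * theta, se_m) *
      stats::dnorm(theta, 0, s)
  }
  # integrate around the posterior mode of theta: the integrand can be a
  # narrow spike far from zero when one se is small
  prec <- 1 / s^2 + 1 / se_f^2 + c^2 / se_m^2
  mu <- (b_f / se_f^2 + c * b_m / se_m^2) / prec
  hw <- 12 / sqrt(prec)
  log(stats::integrate(f, mu - hw, mu + hw, rel.tol = 1e-12)$value)
}

# OLS slope/se via the normal equations, independent of fit_additive
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  bh <- solve(t(X) %*% X, t(X) %*% y)
  r <- y - X %*% bh
  s2 <- sum(r^2) / (length(y) - 2)
  covb <- s2 * solve(t(X) %*% X)
  c(beta = bh[2], se = sqrt(covb[2, 2]))
}

# A small genotype + phenotype pair for pipeline tests
make_small_study <- function(n_f = 300, n_m = 300, m = 30, seed = 42,
                             dc_model = "FDC", causal = integer(), b = 0,
                             covs = 0) {
  g <- simulate_genotypes(n_f, n_m, mafs = seq(0.1, 0.5, length.out = m),
                          seed = seed)
  arch <- x_architecture(causal, b, dc_model, resid_var = 1)
  ph <- simulate_phenotype(g, arch, seed = seed + 1L, n_covariates = covs)
  list(geno = g, pheno = adjust_covariates(ph))
}
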