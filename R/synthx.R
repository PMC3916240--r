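#' Simulate non-pseudoautosomal X-chromosome genotypes
#'
#' Draws unlinked SNP genotypes for a sample of diploid females and
#' hemizygous males. Female genotypes are Binomial(2, maf) allele counts
#' (Hardy-Weinberg), male genotypes are Bernoulli(maf) single-copy counts.
#' Male dosages are stored on the raw \{0,1\} scale; the \{0,2\} coding used
#' by full-dosage-compensation association is applied downstream by
#' [encode_dosage()].
#'
#' @param n_females,n_males Non-negative sample sizes.
#' @param mafs Numeric vector of effect-allele frequencies in \[0,1\], one
#'   per SNP.
#' @param seed Integer seed; every draw is reproducible given it.
#' @param positions Optional integer base-pair positions (defaults to a
#'   regular grid on chrX).
#' @param info Optional per-SNP imputation quality scores in \[0,1\]
#'   (defaults to 1, i.e. directly genotyped).
#'
#' @return An object of class `x_genotypes`: a list with
#'   `snps` (tibble: `snp_id`, `pos`, `ea`, `oa`, `maf`, `eaf_female`,
#'   `eaf_male`, `info_female`), `female_dosages` (n_F x m matrix, values
#'   in \[0,2\]) and `male_dosages` (n_M x m matrix, values in \[0,1\]).
#'   Row names are sample ids (`F0001`..., `M0001`...).
#' @export
#' @examples
#' g <- simulate_genotypes(50, 50, mafs = c(0.1, 0.4), seed = 1)
#' g$snps
simulate_genotypes <- function(n_females, n_males, mafs, seed,
                               positions = NULL, info = NULL) {
  stopifnot(length(n_females) == 1L, length(n_males) == 1L)
  if (n_females < 0 || n_males < 0) {
    stop("sample sizes must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(mafs)) || any(mafs < 0) || any(mafs > 1)) {
    stop("`mafs` must lie in [0, 1]", call. = FALSE)
  }
  m <- length(mafs)
  if (is.null(positions)) positions <- as.integer(seq(2699521L, 154931043L, length.out = max(m, 2L)))[seq_len(m)]
  if (is.null(info)) info <- rep(1, m)
  stopifnot(length(positions) == m, length(info) == m)

  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  dat <- withr_seed({
    fem <- matrix(stats::rbinom(n_females * m, 2L, rep(mafs, each = n_females)),
                  nrow = n_females, ncol = m)
    mal <- matrix(stats::rbinom(n_males * m, 1L, rep(mafs, each = n_males)),
                  nrow = n_males, ncol = m)
    list(fem = fem, mal = mal)
  })
  snp_id <- sprintf("snpX_%05d", seq_len(m))
  dimnames(dat$fem) <- list(sprintf("F%04d", seq_len(n_females)), snp_id)
  dimnames(dat$mal) <- list(sprintf("M%04d", seq_len(n_males)), snp_id)

  eaf_f <- if (n_females > 0) colMeans(dat$fem) / 2 else rep(NA_real_, m)
  eaf_m <- if (n_males > 0) colMeans(dat$mal) else rep(NA_real_, m)
  out <- list(
    snps = tibble::tibble(
      snp_id = snp_id, pos = positions, ea = "A", oa = "G",
      maf = mafs, eaf_female = eaf_f, eaf_male = eaf_m,
      info_female = info
    ),
    female_dosages = dat$fem,
    male_dosages = dat$mal
  )
  class(out) <- "x_genotypes"
  out
}

#' @export
print.x_genotypes <- function(x, ...) {
  cat(sprintf("<x_genotypes> %d SNPs, %d females, %d males\n",
              nrow(x$snps), nrow(x$female_dosages), nrow(x$male_dosages)))
  print(x$snps, n = 5)
  invisible(x)
}

#' Specify an X-linked genetic architecture
#'
#' Declares which SNPs are causal, their per-allele effects on the female
#' scale, the dosage-compensation model governing male effect sizes, and
#' the residual variance.
#'
#' Under full dosage compensation (FDC) the single male copy acts like a
#' female homozygote, so each carried male allele contributes `2 * b`;
#' under no dosage compensation (NDC) it contributes `b`; under the
#' equal-variance convention (EV) it contributes `sqrt(2) * b`, which makes
#' the male genetic variance equal the female one.
#'
#' @param causal Integer indices of causal SNPs.
#' @param b Per-allele effects on the female scale (recycled to
#'   `length(causal)`).
#' @param dc_model One of `"FDC"`, `"NDC"`, `"EV"`.
#' @param resid_var Residual (environmental) variance, > 0.
#' @return A list of class `x_architecture`.
#' @export
x_architecture <- function(causal, b, dc_model = c("FDC", "NDC", "EV"),
                           resid_var = 1) {
  dc_model <- match.arg(dc_model)
  if (!is.numeric(resid_var) || resid_var <= 0) {
    stop("`resid_var` must be > 0", call. = FALSE)
  }
  b <- rep_len(b, length(causal))
  structure(list(causal = as.integer(causal), b = b,
                 dc_model = dc_model, resid_var = resid_var),
            class = "x_architecture")
}

male_per_copy_multiplier <- function(dc_model) {
  switch(dc_model, FDC = 2, NDC = 1, EV = sqrt(2),
         stop("unknown dc_model", call. = FALSE))
}

#' Simulate a quantitative trait from X-linked genotypes
#'
#' Female genetic values are `sum(b_i * g_i)` over causal SNPs with
#' `g in {0,1,2}`; male values apply the per-copy multiplier implied by the
#' architecture's dosage-compensation model (see [x_architecture()]).
#' Gaussian noise with the architecture's residual variance is added and
#' the raw (un-normalised) trait is returned.
#'
#' @param geno An `x_genotypes` object.
#' @param arch An `x_architecture` object.
#' @param seed Integer seed for the environmental noise.
#' @param n_covariates Number of standard-normal nuisance covariates to
#'   attach (each also nudges the trait, so covariate adjustment has
#'   something to remove). Default 0.
#' @return A tibble with columns `iid`, `sex` (`"male"`/`"female"`),
#'   `genetic_value`, `trait`, and `cov1..covk` when requested.
#' @export
simulate_phenotype <- function(geno, arch, seed, n_covariates = 0) {
  stopifnot(inherits(geno, "x_genotypes"), inherits(arch, "x_architecture"))
  m <- nrow(geno$snps)
  if (m == 0) stop("empty genotype object", call. = FALSE)
  if (length(arch$causal) &&
      (min(arch$causal) < 1 || max(arch$causal) > m)) {
    stop("causal index out of range", call. = FALSE)
  }
  bvec <- numeric(m)
  bvec[arch$causal] <- arch$b
  gf <- drop(geno$female_dosages %*% bvec)
  gm <- drop(geno$male_dosages %*% bvec) * male_per_copy_multiplier(arch$dc_model)
  nf <- length(gf); nm <- length(gm); n <- nf + nm
  set.seed(seed)
  e <- stats::rnorm(n, 0, sqrt(arch$resid_var))
  out <- tibble::tibble(
    iid = c(rownames(geno$female_dosages), rownames(geno$male_dosages)),
    sex = rep(c("female", "male"), c(nf, nm)),
    genetic_value = c(gf, gm)
  )
  covs <- NULL
  if (n_covariates > 0) {
    covs <- matrix(stats::rnorm(n * n_covariates), n, n_covariates,
                   dimnames = list(NULL, paste0("cov", seq_len(n_covariates))))
  }
  out$trait <- out$genetic_value + e +
    if (is.null(covs)) 0 else drop(covs %*% rep(0.5, n_covariates))
  if (!is.null(covs)) out <- dplyr::bind_cols(out, tibble::as_tibble(covs))
  out
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles of Blom-offset ranks,
#' `qnorm((rank - 3/8) / (n + 1/4))`, with ties given average ranks. The
#' result has mean approximately 0 and standard deviation approximately 1,
#' and is invariant to any strictly monotone transform of the input.
#'
#' @param x Numeric vector with at least two finite values and not all tied.
#' @return Transformed vector of the same length (NAs preserved).
#' @export
#' @examples
#' inverse_normal_transform(c(3, 1, 4, 1, 5))
inverse_normal_transform <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 2) stop("need at least two finite values", call. = FALSE)
  rng <- range(x[ok])
  if (diff(rng) <= .Machine$double.eps^0.75 * max(1, abs(rng[1]), abs(rng[2]))) {
    stop("inverse normal transform undefined for constant input", call. = FALSE)
  }
  n <- sum(ok)
  r <- rank(x[ok], ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Residualise a trait on covariates and inverse-normal transform
#'
#' Regresses the raw trait on the given covariate columns by ordinary
#' least squares — within each sex separately when `sex_separate` is TRUE,
#' mirroring standard sex-stratified GWAS phenotype preparation — and
#' applies [inverse_normal_transform()] to the residuals, yielding a
#' phenotype with mean 0 and sd 1 within each stratum.
#'
#' @param pheno Tibble with columns `iid`, `sex`, `trait`, plus covariates.
#' @param covariates Character vector of covariate column names (may be
#'   empty, in which case residuals are the centred trait).
#' @param sex_separate Adjust and transform within sex? Default TRUE.
#' @return The input tibble with a `normalized_residual` column appended.
#' @export
adjust_covariates <- function(pheno, covariates = grep("^cov", names(pheno), value = TRUE),
                              sex_separate = TRUE) {
  stopifnot(all(c("iid", "sex", "trait") %in% names(pheno)))
  if (!all(covariates %in% names(pheno))) {
    stop("missing covariate columns: ",
         paste(setdiff(covariates, names(pheno)), collapse = ", "), call. = FALSE)
  }
  resid_one <- function(d) {
    X <- cbind(`(Intercept)` = 1, as.matrix(d[covariates]))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[-seq_len(qrX$rank)]
      stop("rank-deficient covariates: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    d$normalized_residual <- inverse_normal_transform(qr.resid(qrX, d$trait))
    d
  }
  if (sex_separate) {
    pheno |>
      dplyr::group_by(.data$sex) |>
      dplyr::group_modify(~ resid_one(.x)) |>
      dplyr::ungroup() |>
      dplyr::relocate("iid") |>
      dplyr::arrange(match(.data$iid, pheno$iid))
  } else {
    resid_one(pheno)
  }
}
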