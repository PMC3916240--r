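#' Prior standard deviation for the female allelic effect
#'
#' The prior on the female per-allele effect is `b_F ~ N(0, s^2)` with `s`
#' chosen so that, with probability `prob`, the SNP explains less than
#' `max_var` of the (unit) trait variance in females. Since the variance
#' explained is `2 p (1-p) b_F^2`, this gives
#' `s = sqrt(max_var / (2 p (1-p))) / qnorm(1 - (1-prob)/2)`.
#'
#' @param eaf Effect-allele frequency in (0, 1).
#' @param max_var Variance-explained bound (default 0.01, i.e. 1%).
#' @param prob Prior coverage of the bound (default 0.95).
#' @return Prior standard deviation `s` (vectorised over `eaf`).
#' @export
#' @examples
#' prior_sd(0.5)  # ~0.0722
prior_sd <- function(eaf, max_var = 0.01, prob = 0.95) {
  if (any(eaf <= 0 | eaf >= 1)) {
    stop("`eaf` must be strictly inside (0, 1)", call. = FALSE)
  }
  sqrt(max_var / (2 * eaf * (1 - eaf))) / stats::qnorm(1 - (1 - prob) / 2)
}

#' Log marginal likelihood of sex-stratified effect estimates
#'
#' Approximates the likelihood of the underlying effects by normal
#' densities centred at the estimates (`b_F_hat ~ N(b_F, se_F^2)`,
#' `b_M_hat ~ N(b_M, se_M^2)`) and integrates over the perfectly
#' correlated prior `b_F ~ N(0, s^2)`, `b_M = c * b_F`. The male
#' multiplier is `c = 1` under full dosage compensation and `c = 0.5`
#' under no dosage compensation, with male effects on the \{0,2\}
#' (`slope02`) coding scale. The rank-1 prior integrates analytically:
#' the estimates are jointly normal with mean 0 and covariance
#' `[[s^2 + se_F^2, c s^2], [c s^2, c^2 s^2 + se_M^2]]`.
#'
#' @param b_f,se_f Female estimate and standard error.
#' @param b_m,se_m Male estimate (slope02 scale) and standard error.
#' @param s Prior standard deviation (see [prior_sd()]); `s = 0` reduces
#'   to independent null densities.
#' @param male_multiplier Prior ratio `b_M / b_F`: 1 (FDC) or 0.5 (NDC).
#' @return Log marginal likelihood (scalar, vectorised over inputs).
#' @export
log_marginal <- function(b_f, se_f, b_m, se_m, s, male_multiplier) {
  if (any(se_f <= 0) || any(se_m <= 0)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  if (any(s < 0)) stop("`s` must be non-negative", call. = FALSE)
  c2 <- male_multiplier
  v11 <- s^2 + se_f^2
  v22 <- c2^2 * s^2 + se_m^2
  v12 <- c2 * s^2
  det <- v11 * v22 - v12^2
  if (any(det <= 0)) stop("covariance not positive definite", call. = FALSE)
  quad <- (v22 * b_f^2 - 2 * v12 * b_f * b_m + v11 * b_m^2) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * quad
}

#' Compare dosage-compensation models at a SNP
#'
#' Computes the Bayes factor between the no-dosage-compensation (NDC,
#' `b_F = 2 b_M`) and full-dosage-compensation (FDC, `b_F = b_M`) models
#' from sex-stratified summary statistics, and the posterior probability
#' of NDC under the given prior model probability. Male estimates must be
#' tagged `slope02`; a `per_copy` tag is an error (preventing silent
#' factor-of-2 mistakes) — convert with `beta/2`, `se/2` first.
#'
#' @param data Tibble with one row per SNP and columns `snp_id`,
#'   `beta_f`, `se_f`, `beta_m`, `se_m`, `eaf` (combined-sample effect
#'   allele frequency), and optionally `male_coding` (checked).
#' @param prior_ndc Prior probability of the NDC model (default 0.5,
#'   equal model odds).
#' @param max_var,prob Prior-scale parameters passed to [prior_sd()].
#' @return A tibble of class `dc_comparison`: `snp_id`, `s`, `logml_fdc`,
#'   `logml_ndc`, `log10_bf_ndc_fdc`, `prior_ndc`, `posterior_ndc`, plus
#'   the input estimate columns (kept for plotting).
#' @export
#' @examples
#' dc_compare(tibble::tibble(snp_id = "rs1751138",
#'   beta_f = 0.093, se_f = 0.014, beta_m = 0.036, se_m = 0.010,
#'   eaf = 0.643))
dc_compare <- function(data, prior_ndc = 0.5, max_var = 0.01, prob = 0.95) {
  need <- c("beta_f", "se_f", "beta_m", "se_m", "eaf")
  stopifnot(all(need %in% names(data)))
  if ("male_coding" %in% names(data) &&
      any(data$male_coding != "slope02", na.rm = TRUE)) {
    stop("male estimates must be on the slope02 coding scale; ",
         "convert per_copy estimates (beta/2, se/2) first", call. = FALSE)
  }
  stopifnot(prior_ndc > 0, prior_ndc < 1)
  out <- data |>
    dplyr::mutate(
      s = prior_sd(.data$eaf, max_var = max_var, prob = prob),
      logml_fdc = log_marginal(.data$beta_f, .data$se_f, .data$beta_m,
                               .data$se_m, .data$s, male_multiplier = 1),
      logml_ndc = log_marginal(.data$beta_f, .data$se_f, .data$beta_m,
                               .data$se_m, .data$s, male_multiplier = 0.5),
      log10_bf_ndc_fdc = (.data$logml_ndc - .data$logml_fdc) / log(10),
      prior_ndc = prior_ndc,
      posterior_ndc = 1 / (1 + exp(.data$logml_fdc - .data$logml_ndc) *
                             (1 - prior_ndc) / prior_ndc)
    )
  class(out) <- c("dc_comparison", class(out))
  out
}

#' Confidence-ellipse and model-line parameters for a SNP
#'
#' Parameters of the axis-aligned joint confidence region for
#' `(b_F_hat, b_M_hat)` (semi-axes `sqrt(qchisq(level, 2)) * se`) and the
#' two model lines `b_M = b_F` (FDC) and `b_M = b_F / 2` (NDC).
#'
#' @param b_f,se_f,b_m,se_m Estimates and standard errors.
#' @param level Confidence level (default 0.95).
#' @return A list: `center`, `semi_axes`, `fdc_slope` (1),
#'   `ndc_slope` (0.5).
#' @export
model_lines_and_ellipse <- function(b_f, se_f, b_m, se_m, level = 0.95) {
  stopifnot(se_f > 0, se_m > 0)
  r <- sqrt(stats::qchisq(level, 2))
  list(center = c(b_f, b_m), semi_axes = c(r * se_f, r * se_m),
       fdc_slope = 1, ndc_slope = 0.5)
}

#' Effect-size plane plot of dosage-compensation comparisons
#'
#' Female versus male (slope02-coded) effect estimates with joint
#' confidence ellipses and the FDC (`b_M = b_F`) and NDC (`b_M = b_F/2`)
#' model lines.
#'
#' @param object A `dc_comparison` tibble.
#' @param level Ellipse confidence level (default 0.95).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dc_comparison <- function(object, level = 0.95, ...) {
  r <- sqrt(stats::qchisq(level, 2))
  theta <- seq(0, 2 * pi, length.out = 181)
  ell <- object |>
    dplyr::rowwise() |>
    dplyr::reframe(snp_id = .data$snp_id,
                   x = .data$beta_f + r * .data$se_f * cos(theta),
                   y = .data$beta_m + r * .data$se_m * sin(theta))
  lim <- range(c(0, ell$x, ell$y))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$beta_f, y = .data$beta_m)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "steelblue") +
    ggplot2::geom_abline(slope = 0.5, intercept = 0, colour = "firebrick") +
    ggplot2::geom_path(data = ell,
                       ggplot2::aes(x = .data$x, y = .data$y, group = .data$snp_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$snp_id), vjust = -1, size = 3) +
    ggplot2::coord_equal(xlim = lim, ylim = lim) +
    ggplot2::labs(x = "effect in females (per allele)",
                  y = "effect in males (genotypes coded 0/2)",
                  caption = "blue: FDC (b_M = b_F); red: NDC (b_M = b_F/2)") +
    ggplot2::theme_minimal()
}
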