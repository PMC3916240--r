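#' Fixed-effects (inverse-variance weighted) meta-analysis
#'
#' Combines effect estimates with weights `w_i = 1/se_i^2`:
#' `beta = sum(w b) / sum(w)`, `se = 1/sqrt(sum(w))`, two-sided normal p.
#'
#' @param beta,se Numeric vectors of estimates and standard errors
#'   (all `se > 0`).
#' @return A one-row tibble: `beta`, `se`, `p`, `k` (number of strata).
#' @export
#' @examples
#' fixed_effects_meta(c(-0.092559, -0.071802), c(0.013934, 0.019274))
fixed_effects_meta <- function(beta, se) {
  stopifnot(length(beta) == length(se), length(beta) >= 1)
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("all standard errors must be positive", call. = FALSE)
  }
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  tibble::tibble(beta = b, se = s, p = 2 * stats::pnorm(-abs(b / s)),
                 k = length(beta))
}

#' Sex-differentiated association test
#'
#' Combines the per-sex meta-analysed estimates while allowing the
#' allelic effects to differ between men and women:
#' `chi2 = z_F^2 + z_M^2` with `z = beta/se`, referred to a chi-square
#' with 2 degrees of freedom. If one sex is absent the test falls back to
#' 1 df on the present sex and flags it.
#'
#' @param beta_f,se_f Female estimate and standard error (or NA).
#' @param beta_m,se_m Male estimate and standard error (or NA).
#' @return A one-row tibble: `chi2`, `df`, `p`, `complete` (both sexes
#'   present?).
#' @export
sex_differentiated_test <- function(beta_f, se_f, beta_m, se_m) {
  zf <- if (is.na(beta_f) || is.na(se_f)) NA_real_ else beta_f / se_f
  zm <- if (is.na(beta_m) || is.na(se_m)) NA_real_ else beta_m / se_m
  if (!is.na(se_f) && se_f <= 0 || !is.na(se_m) && se_m <= 0) {
    stop("standard errors must be positive", call. = FALSE)
  }
  z2 <- c(zf^2, zm^2)
  df <- sum(!is.na(z2))
  if (df == 0) stop("no estimates supplied", call. = FALSE)
  chi2 <- sum(z2, na.rm = TRUE)
  tibble::tibble(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 complete = df == 2L)
}

#' Sex-heterogeneity test
#'
#' Wald test of equality of the female and male effects:
#' `q = (b_F - b_M)^2 / (se_F^2 + se_M^2)`, referred to chi-square with
#' 1 df. Algebraically identical to two-group Cochran's Q.
#'
#' @inheritParams sex_differentiated_test
#' @return A one-row tibble: `q`, `p`.
#' @export
sex_heterogeneity_test <- function(beta_f, se_f, beta_m, se_m) {
  if (any(c(se_f, se_m) <= 0, na.rm = TRUE)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  if (any(is.na(c(beta_f, se_f, beta_m, se_m)))) {
    return(tibble::tibble(q = NA_real_, p = NA_real_))
  }
  q <- (beta_f - beta_m)^2 / (se_f^2 + se_m^2)
  tibble::tibble(q = q, p = stats::pchisq(q, 1, lower.tail = FALSE))
}

#' Genomic control
#'
#' Estimates the inflation factor `lambda` as the median association
#' chi-square divided by the chi-square(1) median (`qchisq(0.5, 1)`,
#' about 0.4549). When `lambda` exceeds `apply_if_above` (default 1, i.e.
#' only on indication of inflation) all statistics are divided by
#' `lambda` and p-values recomputed; deflation is never applied.
#'
#' @param p Vector of two-sided p-values (1 df tests), or NULL if `chi2`
#'   given.
#' @param chi2 Vector of 1-df chi-square statistics (computed from `p`
#'   when absent).
#' @param apply_if_above Correct only when lambda exceeds this (default 1).
#' @param min_n Minimum number of statistics for a stable median
#'   (default 100; fewer than 2 is an error).
#' @return A list: `lambda`, `applied` (logical), `chi2` and `p`
#'   (corrected when applied, otherwise the input).
#' @export
genomic_control <- function(p = NULL, chi2 = NULL, apply_if_above = 1.0,
                            min_n = 100) {
  if (is.null(chi2)) {
    if (is.null(p)) stop("supply `p` or `chi2`", call. = FALSE)
    chi2 <- stats::qchisq(p, 1, lower.tail = FALSE)
  }
  chi2 <- chi2[is.finite(chi2)]
  if (length(chi2) < 2) stop("need at least two statistics", call. = FALSE)
  if (length(chi2) < min_n) {
    warning("fewer than ", min_n, " statistics; lambda may be unstable")
  }
  lambda <- stats::median(chi2) / stats::qchisq(0.5, 1)
  applied <- lambda > apply_if_above
  out_chi2 <- if (applied) chi2 / lambda else chi2
  list(lambda = lambda, applied = applied, chi2 = out_chi2,
       p = stats::pchisq(out_chi2, 1, lower.tail = FALSE))
}

#' Meta-analyse sex-stratified X-chromosome summary statistics
#'
#' Combines per-cohort, per-sex summary statistics the way X-aware GWAS
#' pipelines do: genomic control within each cohort x sex stratum first
#' (optional), then a fixed-effects meta-analysis per sex across cohorts,
#' then the overall fixed-effects combination plus the sex-differentiated
#' (2 df) and sex-heterogeneity (1 df) tests on the per-sex meta results.
#' SNPs present in fewer than `min_strata` input strata are dropped.
#'
#' @param sumstats A list of tibbles in [assoc_scan()] format (one per
#'   cohort x sex stratum; each must have a single `sex` value) or a
#'   single long tibble with a `stratum` column.
#' @param gc Apply per-stratum genomic control? Default FALSE (it needs
#'   hundreds of SNPs per stratum to be meaningful).
#' @param min_strata Minimum number of strata a SNP must appear in
#'   (default 2).
#' @return A tibble of class `xwas_meta`, one row per SNP: `snp_id`,
#'   `beta`, `se`, `p` (overall fixed effects), `beta_f`, `se_f`, `p_f`,
#'   `beta_m`, `se_m`, `p_m` (per-sex meta), `chi2_sexdiff`, `p_sexdiff`,
#'   `q_het`, `p_het`, `n_total`, `n_strata`, and the per-stratum lambdas
#'   as an attribute `"lambda"`.
#' @export
xwas_meta <- function(sumstats, gc = FALSE, min_strata = 2) {
  if (is.data.frame(sumstats)) {
    stopifnot("stratum" %in% names(sumstats))
    sumstats <- split(sumstats, sumstats$stratum)
  }
  lambdas <- rep(NA_real_, length(sumstats))
  strata <- vector("list", length(sumstats))
  for (i in seq_along(sumstats)) {
    d <- sumstats[[i]]
    stopifnot(all(c("snp_id", "sex", "beta", "se", "p", "n") %in% names(d)),
              dplyr::n_distinct(d$sex) == 1)
    if (gc) {
      g <- genomic_control(chi2 = (d$beta / d$se)^2)
      lambdas[i] <- g$lambda
      if (g$applied) {
        # inflate SEs so z^2 becomes chi2/lambda; betas untouched
        d$se <- d$se * sqrt(g$lambda)
        d$p <- 2 * stats::pnorm(-abs(d$beta / d$se))
      }
    }
    strata[[i]] <- d
  }
  names(strata) <- if (is.null(names(sumstats))) paste0("stratum", seq_along(strata)) else names(sumstats)
  long <- dplyr::bind_rows(strata, .id = "stratum")
  counts <- dplyr::count(long, .data$snp_id, name = "n_strata")
  long <- dplyr::inner_join(long, counts, by = "snp_id") |>
    dplyr::filter(.data$n_strata >= min_strata)
  if (nrow(long) == 0) {
    return(structure(tibble::tibble(), class = c("xwas_meta", "tbl_df", "tbl", "data.frame")))
  }

  per_sex <- long |>
    dplyr::group_by(.data$snp_id, .data$sex) |>
    dplyr::summarise(
      res = list(fixed_effects_meta(.data$beta, .data$se)),
      n = sum(.data$n), .groups = "drop"
    ) |>
    tidyr::unnest("res")

  overall <- long |>
    dplyr::group_by(.data$snp_id) |>
    dplyr::summarise(res = list(fixed_effects_meta(.data$beta, .data$se)),
                     n_total = sum(.data$n),
                     n_strata = .data$n_strata[1], .groups = "drop") |>
    tidyr::unnest("res")

  wide <- per_sex |>
    dplyr::select("snp_id", "sex", "beta", "se", "p", "n") |>
    tidyr::pivot_wider(names_from = "sex",
                       values_from = c("beta", "se", "p", "n"),
                       names_glue = "{.value}_{substr(sex, 1, 1)}")
  for (col in c("beta_f", "se_f", "p_f", "n_f", "beta_m", "se_m", "p_m", "n_m")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }

  out <- dplyr::left_join(overall, wide, by = "snp_id") |>
    dplyr::rowwise() |>
    dplyr::mutate(
      sd = list(sex_differentiated_test(.data$beta_f, .data$se_f,
                                        .data$beta_m, .data$se_m)),
      het = list(sex_heterogeneity_test(.data$beta_f, .data$se_f,
                                        .data$beta_m, .data$se_m))
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      chi2_sexdiff = purrr::map_dbl(.data$sd, "chi2"),
      p_sexdiff = purrr::map_dbl(.data$sd, "p"),
      q_het = purrr::map_dbl(.data$het, "q"),
      p_het = purrr::map_dbl(.data$het, "p")
    ) |>
    dplyr::select(-"sd", -"het", -"k")
  attr(out, "lambda") <- lambdas
  class(out) <- c("xwas_meta", class(out))
  out
}

#' Report genome-wide significant hits
#'
#' @param meta An `xwas_meta` tibble.
#' @param threshold Significance threshold (default 5e-8).
#' @return The significant rows, ordered by p.
#' @export
report_hits <- function(meta, threshold = 5e-8) {
  meta |>
    dplyr::filter(.data$p < threshold | .data$p_sexdiff < threshold) |>
    dplyr::arrange(.data$p)
}

#' QQ plot of meta-analysis p-values
#'
#' @param object An `xwas_meta` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.xwas_meta <- function(object, ...) {
  d <- tibble::tibble(obs = sort(-log10(object$p)),
                      exp = sort(-log10(stats::ppoints(nrow(object)))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$exp, y = .data$obs)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}
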