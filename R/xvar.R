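#' Phenotypic variance explained by an X-linked SNP, per sex
#'
#' Under the full-dosage-compensation coding (males \{0,2\}, females
#' \{0,1,2\}) the genotype variance in men is twice that in women, so
#' variance explained on a unit-variance trait must be computed per sex:
#' `2 P (1-P) b^2` for females and `4 P (1-P) b^2` for males, where `b`
#' is the standardised effect on the slope02 scale and `P` the effect
#' allele frequency in that sex.
#'
#' @param eaf Effect-allele frequency (per-sex), in \[0,1\].
#' @param beta_slope02 Standardised effect size on the slope02 scale.
#' @param sex `"female"` or `"male"` (recycled).
#' @return Fraction of trait variance explained (vectorised).
#' @export
#' @examples
#' variance_explained(0.642, 0.036, "male")   # ~0.0012 (0.12%)
#' variance_explained(0.645, 0.093, "female") # ~0.0040 (0.40%)
variance_explained <- function(eaf, beta_slope02, sex) {
  stopifnot(all(eaf >= 0 & eaf <= 1), all(is.finite(beta_slope02)))
  sex <- match.arg(sex, c("female", "male"), several.ok = TRUE)
  sex <- rep_len(sex, length(eaf))
  mult <- ifelse(sex == "male", 4, 2)
  degen <- eaf == 0 | eaf == 1
  if (any(degen)) warning("monomorphic EAF: variance explained is 0")
  mult * eaf * (1 - eaf) * beta_slope02^2
}

#' Combined per-copy allelic effect in trait units
#'
#' Inverse-variance combination of the female and male per-copy effects
#' on the normalised trait, rescaled to raw trait units by the trait
#' standard deviation. The male input must be tagged `per_copy` (i.e.
#' already `2 x` the slope02 estimate); a `slope02` tag is an error
#' rather than a silent doubling.
#'
#' @param b_f,se_f Female per-copy estimate and standard error.
#' @param b_m_per_copy,se_m Male per-copy estimate and standard error.
#' @param trait_sd Trait standard deviation in raw units (> 0).
#' @param male_coding Coding tag of the male input; must be `"per_copy"`.
#' @return A one-row tibble: `b`, `se` (trait units).
#' @export
#' @examples
#' per_copy_effect_combined(-0.092559, 0.013934, -0.071802, 0.019274, 6.5)
per_copy_effect_combined <- function(b_f, se_f, b_m_per_copy, se_m, trait_sd,
                                     male_coding = "per_copy") {
  if (!identical(male_coding, "per_copy")) {
    stop("male estimate must be per_copy coded; double a slope02 estimate ",
         "(beta*2, se*2) before combining", call. = FALSE)
  }
  stopifnot(trait_sd > 0)
  m <- fixed_effects_meta(c(b_f, b_m_per_copy), c(se_f, se_m))
  tibble::tibble(b = m$beta * trait_sd, se = m$se * trait_sd)
}

#' Shift in the male-female trait mean difference due to an
#' uncompensated SNP
#'
#' If each copy of the minor allele (frequency `f_a`) shifts the trait by
#' `b` in both sexes (no dosage compensation), the male mean is
#' `m + f_a b` and the female mean `m + 2 f_a b`, so the sex difference
#' `m_M - m_F` changes by `-f_a * b` relative to a population
#' monomorphic for the major allele.
#'
#' @param f_a Minor-allele frequency in \[0,1\].
#' @param b Signed per-copy effect in trait units.
#' @return Shift in `m_M - m_F` (trait units).
#' @export
#' @examples
#' sex_mean_shift(0.36, -0.555)  # +0.1998
sex_mean_shift <- function(f_a, b) {
  stopifnot(all(f_a >= 0 & f_a <= 1))
  -f_a * b
}

#' Fraction of an observed sexual dimorphism attributable to a shift
#'
#' @param shift Shift in the sex difference (see [sex_mean_shift()]).
#' @param observed_diff Observed population sex difference in trait
#'   units; must be nonzero.
#' @return `shift / observed_diff`.
#' @export
#' @examples
#' fraction_of_dimorphism(0.1998, 13.7)  # ~0.0146
fraction_of_dimorphism <- function(shift, observed_diff) {
  if (any(observed_diff == 0)) {
    stop("observed sex difference must be nonzero", call. = FALSE)
  }
  shift / observed_diff
}

#' Per-SNP variance-explained report from sex-stratified summary
#' statistics
#'
#' @param sumstats Tibble with columns `snp_id`, `eaf_f`, `beta_f`,
#'   `eaf_m`, `beta_m` (slope02 male coding).
#' @return Tibble: `snp_id`, `var_explained_female`,
#'   `var_explained_male` (fractions).
#' @export
snp_variance_report <- function(sumstats) {
  stopifnot(all(c("snp_id", "eaf_f", "beta_f", "eaf_m", "beta_m") %in%
                  names(sumstats)))
  sumstats |>
    dplyr::transmute(
      snp_id = .data$snp_id,
      var_explained_female = variance_explained(.data$eaf_f, .data$beta_f, "female"),
      var_explained_male = variance_explained(.data$eaf_m, .data$beta_m, "male")
    )
}
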