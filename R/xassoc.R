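#' Apply an X-chromosome male genotype coding convention
#'
#' On the non-pseudoautosomal X, males carry a single allele copy. Under
#' the full-dosage-compensation coding used by standard X-aware
#' association tools, hemizygous males are treated as equivalent to
#' homozygous females: male genotypes are coded \{0,2\} (`"slope02"`).
#' Under `"per_copy"` the raw \{0,1\} count is kept, so the regression
#' slope is the full per-copy effect. Female dosages are never changed.
#'
#' @param raw_dosage Numeric dosages: females in \[0,2\], males in \[0,1\]
#'   (expected counts for imputed data are fine).
#' @param sex `"male"` or `"female"` (recycled).
#' @param convention `"slope02"` (default) or `"per_copy"`.
#' @param snp_id Optional id used in error messages.
#' @return Coded dosage vector.
#' @export
#' @examples
#' encode_dosage(c(0, 1), sex = "male", convention = "slope02")  # 0 2
encode_dosage <- function(raw_dosage, sex, convention = c("slope02", "per_copy"),
                          snp_id = NULL) {
  convention <- match.arg(convention)
  sex <- rep_len(sex, length(raw_dosage))
  male <- sex == "male"
  bad <- (male & (raw_dosage < 0 | raw_dosage > 1)) |
    (!male & (raw_dosage < 0 | raw_dosage > 2))
  bad[is.na(raw_dosage)] <- FALSE
  if (any(bad)) {
    stop("dosage out of range",
         if (!is.null(snp_id)) paste0(" for SNP ", snp_id) else "",
         call. = FALSE)
  }
  out <- raw_dosage
  if (convention == "slope02") out[male] <- 2 * out[male]
  out
}

#' Single-SNP additive association
#'
#' Fits the simple linear regression of a normalised trait on coded
#' dosage over complete pairs. The two-sided p-value uses the
#' large-sample normal approximation `z = beta / se`, matching
#' summary-statistic GWAS pipelines.
#'
#' @param coded_dosage Numeric dosage vector (already coded; see
#'   [encode_dosage()]).
#' @param normalized_trait Numeric trait vector of the same length.
#' @param snp_id,sex,male_coding Metadata carried into the result.
#' @param min_n Minimum number of complete pairs (default 10).
#' @return A one-row tibble: `snp_id`, `sex`, `beta`, `se`, `p`, `n`,
#'   `eaf`, `male_coding`.
#' @export
fit_additive <- function(coded_dosage, normalized_trait, snp_id = NA_character_,
                         sex = NA_character_, male_coding = "slope02",
                         min_n = 10) {
  ok <- is.finite(coded_dosage) & is.finite(normalized_trait)
  x <- coded_dosage[ok]; y <- normalized_trait[ok]
  n <- length(x)
  if (n < min_n) stop("insufficient data: ", n, " complete pairs", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("monomorphic variant: zero dosage variance", call. = FALSE)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  rss <- sum((y - mean(y) - beta * (x - mean(x)))^2)
  se <- sqrt(rss / (n - 2) / sxx)
  p <- if (se > 0) 2 * stats::pnorm(-abs(beta / se)) else 0
  # eaf on the per-copy scale: mean dosage / ploidy implied by the coding
  denom <- if (identical(sex, "male") && male_coding == "per_copy") 1 else 2
  tibble::tibble(snp_id = snp_id, sex = sex, beta = beta, se = se,
                 p = p, n = n, eaf = mean(x) / denom,
                 male_coding = if (identical(sex, "female")) NA_character_ else male_coding)
}

#' Variant quality-control filter
#'
#' Keeps variants passing the standard X-association filters: female
#' imputation info strictly above `info_min` and female minor allele
#' count strictly above `mac_min` (i.e. "more than" the threshold).
#'
#' @param qc Tibble with columns `snp_id`, `info_female`, `mac_female`.
#' @param info_min Info threshold (default 0.4, strict).
#' @param mac_min Minor-allele-count threshold (default 3, strict).
#' @return Character vector of kept `snp_id`s.
#' @export
filter_variants <- function(qc, info_min = 0.4, mac_min = 3) {
  stopifnot(info_min >= 0, mac_min >= 0)
  if (nrow(qc) == 0) return(character())
  qc$snp_id[qc$info_female > info_min & qc$mac_female > mac_min]
}

#' Female minor allele count from dosages
#'
#' `min(sum(d), 2 n - sum(d))` rounded to the nearest integer, so expected
#' counts from imputation yield an integral MAC.
#'
#' @param female_dosages Numeric vector or matrix (samples x SNPs) of
#'   female dosages in \[0,2\].
#' @return Integer MAC (per column for a matrix).
#' @export
mac_female <- function(female_dosages) {
  d <- as.matrix(female_dosages)
  s <- colSums(d, na.rm = TRUE)
  n2 <- 2 * colSums(!is.na(d))
  as.integer(round(pmin(s, n2 - s)))
}

#' Sex-stratified X-chromosome association scan
#'
#' Runs [fit_additive()] for every SNP in one or both sexes after the
#' standard QC filter ([filter_variants()]). Males are coded with
#' `convention` (default `"slope02"`, hemizygotes equivalent to
#' homozygous females).
#'
#' @param geno An `x_genotypes` object.
#' @param pheno Tibble with `iid`, `sex` and `normalized_residual`
#'   (see [adjust_covariates()]); rows are matched to genotype sample ids.
#' @param sex `"both"` (default), `"male"` or `"female"`.
#' @param convention Male coding convention.
#' @param info_min,mac_min QC thresholds passed to [filter_variants()].
#' @param min_n Minimum complete pairs per SNP.
#' @return Tibble of per-SNP, per-sex estimates (one row per SNP x sex),
#'   columns as in [fit_additive()] plus `pos`, `ea`, `oa`.
#' @export
assoc_scan <- function(geno, pheno, sex = c("both", "male", "female"),
                       convention = "slope02", info_min = 0.4, mac_min = 3,
                       min_n = 10) {
  sex <- match.arg(sex)
  stopifnot(inherits(geno, "x_genotypes"),
            all(c("iid", "sex", "normalized_residual") %in% names(pheno)))
  qc <- tibble::tibble(
    snp_id = geno$snps$snp_id,
    info_female = geno$snps$info_female,
    mac_female = mac_female(geno$female_dosages)
  )
  keep <- filter_variants(qc, info_min, mac_min)
  sexes <- if (sex == "both") c("female", "male") else sex
  purrr::map_dfr(sexes, function(sx) {
    mat <- if (sx == "female") geno$female_dosages else geno$male_dosages
    ids <- rownames(mat)
    ph <- pheno[match(ids, pheno$iid), ]
    y <- ph$normalized_residual
    y[!is.na(ph$sex) & ph$sex != sx] <- NA_real_
    purrr::map_dfr(keep, function(s) {
      j <- match(s, geno$snps$snp_id)
      d <- encode_dosage(mat[, j], sex = sx, convention = if (sx == "male") convention else "slope02",
                         snp_id = s)
      res <- tryCatch(
        fit_additive(d, y, snp_id = s, sex = sx,
                     male_coding = if (sx == "male") convention else "slope02",
                     min_n = min_n),
        error = function(e) NULL)
      if (is.null(res)) return(NULL)
      res$pos <- geno$snps$pos[j]; res$ea <- geno$snps$ea[j]; res$oa <- geno$snps$oa[j]
      res
    })
  })
}
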