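#' Write X-chromosome genotypes to a VCF file
#'
#' Emits a plain-text VCFv4.2 with one record per SNP on chrX. Female
#' genotypes are diploid (`0/0`, `0/1`, `1/1`); males are emitted haploid
#' (`0` / `1`) by default, or homozygous-diploid (`0/0` / `1/1`) with
#' `diploid_males = TRUE`. The ALT allele is the effect allele, so the
#' alternate-allele dosage equals the stored effect-allele dosage.
#' Non-integral (imputed) dosages are written to a `DS` FORMAT field with
#' the GT hard call rounded.
#'
#' @param geno An `x_genotypes` object.
#' @param path Output file path (plain text).
#' @param diploid_males Emit male calls as homozygous diploid?
#' @return `path`, invisibly.
#' @export
write_x_vcf <- function(geno, path, diploid_males = FALSE) {
  stopifnot(inherits(geno, "x_genotypes"))
  ids <- c(rownames(geno$female_dosages), rownames(geno$male_dosages))
  nf <- nrow(geno$female_dosages)
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=X>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Effect allele dosage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  )
  gt_f <- c("0/0", "0/1", "1/1")
  gt_m_hap <- c("0", "1")
  gt_m_dip <- c("0/0", "1/1")
  recs <- vapply(seq_len(nrow(geno$snps)), function(j) {
    df <- geno$female_dosages[, j]
    dm <- geno$male_dosages[, j]
    fem <- paste0(gt_f[round(df) + 1], ":", formatC(df, format = "g", digits = 6))
    mal_gt <- if (diploid_males) gt_m_dip[round(dm) + 1] else gt_m_hap[round(dm) + 1]
    mal <- paste0(mal_gt, ":", formatC(dm, format = "g", digits = 6))
    paste(c("X", geno$snps$pos[j], geno$snps$snp_id[j], geno$snps$oa[j],
            geno$snps$ea[j], ".", "PASS",
            sprintf("INFO_F=%g", geno$snps$info_female[j]), "GT:DS",
            fem, mal), collapse = "\t")
  }, "")
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read non-pseudoautosomal X genotypes from a VCF file
#'
#' Parses the VCF with \pkg{vcfR} and splits samples by the supplied sex
#' labels into an [x_genotypes][simulate_genotypes] object. The `DS`
#' field is preferred when present; otherwise dosages come from GT calls.
#' Males may be haploid (`0`/`1`) or homozygous diploid (`0/0`/`1/1`);
#' heterozygous male calls are rejected per SNP (mixed ploidy), as are
#' male dosages above 1.
#'
#' @param path VCF file path.
#' @param sex Named character vector (or tibble with `iid`, `sex`)
#'   mapping sample ids to `"male"`/`"female"`.
#' @return An `x_genotypes` object (with `eaf_*` recomputed from data and
#'   `info_female` taken from an `INFO_F` INFO key when present).
#' @export
read_x_vcf <- function(path, sex) {
  if (is.data.frame(sex)) sex <- stats::setNames(sex$sex, sex$iid)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  sx <- sex[samples]
  if (any(is.na(sx))) {
    stop("sex missing for samples: ",
         paste(utils::head(samples[is.na(sx)]), collapse = ", "), call. = FALSE)
  }
  fmt <- v@gt[, 1]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    d <- suppressWarnings(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE))
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    cnt <- function(g) {
      ifelse(is.na(g), NA_real_,
             vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), 0))
    }
    d <- apply(gt, 2, cnt)
    if (is.null(dim(d))) d <- matrix(d, nrow = nrow(v@gt), dimnames = dimnames(gt))
  }
  male <- sx == "male"
  if (any(male)) {
    gt <- vcfR::extract.gt(v, element = "GT")
    mg <- gt[, male, drop = FALSE]
    het <- matrix(grepl("^0[/|]1$|^1[/|]0$", mg), nrow = nrow(mg),
                  dimnames = dimnames(mg))
    if (any(het, na.rm = TRUE)) {
      bad <- rownames(mg)[apply(het, 1, any, na.rm = TRUE)]
      stop("heterozygous male calls (mixed ploidy) at: ",
           paste(utils::head(bad), collapse = ", "), call. = FALSE)
    }
    # homozygous-diploid male convention stores the allele count twice
    dm <- d[, male, drop = FALSE]
    if (!has_ds) {
      dip <- grepl("[/|]", mg)
      dm[dip] <- dm[dip] / 2
    }
    if (any(dm > 1 + 1e-8, na.rm = TRUE)) {
      stop("male dosage above 1; male calls must be haploid or ",
           "homozygous diploid", call. = FALSE)
    }
    d[, male] <- dm
  }
  info_f <- suppressWarnings(as.numeric(vcfR::extract.info(v, "INFO_F")))
  info_f[is.na(info_f)] <- 1
  fem_mat <- t(d[, !male, drop = FALSE])
  mal_mat <- t(d[, male, drop = FALSE])
  m <- nrow(v@fix)
  out <- list(
    snps = tibble::tibble(
      snp_id = v@fix[, "ID"], pos = as.integer(v@fix[, "POS"]),
      ea = v@fix[, "ALT"], oa = v@fix[, "REF"],
      maf = NA_real_,
      eaf_female = if (nrow(fem_mat)) colMeans(fem_mat, na.rm = TRUE) / 2 else rep(NA_real_, m),
      eaf_male = if (nrow(mal_mat)) colMeans(mal_mat, na.rm = TRUE) else rep(NA_real_, m),
      info_female = info_f
    ),
    female_dosages = fem_mat,
    male_dosages = mal_mat
  )
  colnames(out$female_dosages) <- colnames(out$male_dosages) <- out$snps$snp_id
  class(out) <- "x_genotypes"
  out
}

#' Write / read a phenotype table as TSV
#'
#' Columns: `IID`, `SEX` (1 = male, 2 = female), `TRAIT`, then any
#' covariate columns.
#'
#' @param pheno Tibble with `iid`, `sex`, `trait` and covariates.
#' @param path File path.
#' @return `path` invisibly (writer); a tibble with `iid`, `sex`
#'   (`"male"`/`"female"`), `trait`, covariates (reader).
#' @export
write_pheno_tsv <- function(pheno, path) {
  out <- pheno |>
    dplyr::transmute(IID = .data$iid,
                     SEX = ifelse(.data$sex == "male", 1L, 2L),
                     TRAIT = .data$trait)
  covs <- setdiff(names(pheno), c("iid", "sex", "trait", "genetic_value",
                                  "normalized_residual"))
  out <- dplyr::bind_cols(out, pheno[covs])
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_pheno_tsv
#' @export
read_pheno_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("IID", "SEX", "TRAIT") %in% names(d)))
  covs <- setdiff(names(d), c("IID", "SEX", "TRAIT"))
  dplyr::bind_cols(
    tibble::tibble(iid = as.character(d$IID),
                   sex = ifelse(d$SEX == 1, "male", "female"),
                   trait = d$TRAIT),
    d[covs]
  )
}

#' Write / read sex-stratified summary statistics as TSV
#'
#' Columns: `SNP`, `POS`, `EA`, `OA`, `SEX`, `EAF`, `BETA`, `SE`, `P`,
#' `N`, `INFO`, `MALE_CODING`.
#'
#' @param sumstats Tibble in [assoc_scan()] format.
#' @param path File path.
#' @return `path` invisibly (writer); the tibble (reader).
#' @export
write_sumstats_tsv <- function(sumstats, path) {
  col_or <- function(nm, default) {
    if (nm %in% names(sumstats)) sumstats[[nm]] else default
  }
  out <- tibble::tibble(
    SNP = sumstats$snp_id,
    POS = col_or("pos", NA_integer_),
    EA = col_or("ea", NA_character_),
    OA = col_or("oa", NA_character_),
    SEX = sumstats$sex, EAF = sumstats$eaf, BETA = sumstats$beta,
    SE = sumstats$se, P = sumstats$p, N = sumstats$n,
    INFO = col_or("info", NA_real_),
    MALE_CODING = sumstats$male_coding
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_sumstats_tsv
#' @export
read_sumstats_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  tibble::tibble(
    snp_id = as.character(d$SNP), pos = d$POS, ea = d$EA, oa = d$OA,
    sex = d$SEX, eaf = d$EAF, beta = d$BETA, se = d$SE, p = d$P, n = d$N,
    info = d$INFO, male_coding = as.character(d$MALE_CODING)
  )
}
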