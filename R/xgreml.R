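#' Genetic relationship matrix with X-aware dosage-compensation scaling
#'
#' Standardises each SNP column — females `(x - 2p)/sqrt(2p(1-p))`, males
#' `(x - p)/sqrt(p(1-p))` with `p` estimated from the pooled X allele
#' count (males counted once) — and averages cross-products over SNPs.
#' Males are then rescaled by a model-dependent factor `d_M` so that male
#' genetic variance is `2x` (FDC, `d_M = sqrt(2)`), `0.5x` (NDC,
#' `d_M = 1/sqrt(2)`) or `1x` (EV, `d_M = 1`) the female variance.
#' Also accepts a plain dosage matrix (e.g. autosomal 0/1/2 genotypes),
#' standardised as diploid throughout.
#'
#' @param geno An `x_genotypes` object, or a numeric samples x SNPs
#'   dosage matrix treated as diploid.
#' @param dc_model `"FDC"`, `"NDC"` or `"EV"` (ignored for a plain
#'   matrix).
#' @param maf_min Minimum pooled MAF; SNPs at or below it are skipped
#'   (default 0.01).
#' @return A list of class `x_grm`: `matrix` (n x n), `sample_ids`,
#'   `sex`, `dc_model`, `m_snps`.
#' @export
make_grm <- function(geno, dc_model = c("EV", "FDC", "NDC"), maf_min = 0.01) {
  dc_model <- match.arg(dc_model)
  if (is.matrix(geno)) {
    W <- geno
    p <- colMeans(W, na.rm = TRUE) / 2
    sex <- rep("autosomal", nrow(W))
    ids <- rownames(W) %||% as.character(seq_len(nrow(W)))
    keep <- pmin(p, 1 - p) > maf_min
    if (!any(keep)) stop("no polymorphic SNPs after MAF filter", call. = FALSE)
    W <- W[, keep, drop = FALSE]; p <- p[keep]
    Z <- sweep(sweep(W, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
    A <- tcrossprod(Z) / ncol(Z)
    out <- list(matrix = A, sample_ids = ids, sex = sex,
                dc_model = "autosomal", m_snps = ncol(Z))
    class(out) <- "x_grm"
    return(out)
  }
  stopifnot(inherits(geno, "x_genotypes"))
  nf <- nrow(geno$female_dosages); nm <- nrow(geno$male_dosages)
  # pooled allele frequency: females contribute 2 chromosomes, males 1
  p <- (colSums(geno$female_dosages) + colSums(geno$male_dosages)) /
    (2 * nf + nm)
  keep <- pmin(p, 1 - p) > maf_min
  if (!any(keep)) stop("no polymorphic SNPs after MAF filter", call. = FALSE)
  if (any(!keep)) {
    message(sum(!keep), " SNP(s) skipped by the MAF filter")
  }
  p <- p[keep]
  Zf <- sweep(sweep(geno$female_dosages[, keep, drop = FALSE], 2, 2 * p),
              2, sqrt(2 * p * (1 - p)), "/")
  Zm <- sweep(sweep(geno$male_dosages[, keep, drop = FALSE], 2, p),
              2, sqrt(p * (1 - p)), "/")
  dm <- switch(dc_model, FDC = sqrt(2), NDC = 1 / sqrt(2), EV = 1)
  Z <- rbind(Zf, dm * Zm)
  A <- tcrossprod(Z) / ncol(Z)
  ids <- c(rownames(geno$female_dosages), rownames(geno$male_dosages))
  dimnames(A) <- list(ids, ids)
  out <- list(matrix = A, sample_ids = ids,
              sex = rep(c("female", "male"), c(nf, nm)),
              dc_model = dc_model, m_snps = ncol(Z))
  class(out) <- "x_grm"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.x_grm <- function(x, ...) {
  cat(sprintf("<x_grm> %d samples, %d SNPs, model %s\n",
              length(x$sample_ids), x$m_snps, x$dc_model))
  invisible(x)
}

#' Greedy relatedness pruning
#'
#' While any off-diagonal relationship exceeds `threshold`, drops the
#' individual involved in the most such pairs (ties broken towards the
#' larger index). The returned set has no pair above the threshold.
#'
#' @param grm An `x_grm` object or a symmetric numeric matrix.
#' @param threshold Relatedness cutoff (default 0.05, > 0).
#' @return Character vector of kept sample ids.
#' @export
prune_related <- function(grm, threshold = 0.05) {
  stopifnot(threshold > 0)
  A <- if (inherits(grm, "x_grm")) grm$matrix else grm
  ids <- if (inherits(grm, "x_grm")) grm$sample_ids else
    rownames(A) %||% as.character(seq_len(nrow(A)))
  keep <- rep(TRUE, nrow(A))
  R <- abs(A) > threshold
  diag(R) <- FALSE
  repeat {
    deg <- rowSums(R[keep, keep, drop = FALSE])
    if (!length(deg) || max(deg) == 0) break
    worst <- which(keep)[max(which(deg == max(deg)))]
    keep[worst] <- FALSE
  }
  ids[keep]
}

#' REML variance-component estimation (average information)
#'
#' Fits `y = X b + sum_k u_k + e` with `u_k ~ N(0, sigma2_k G_k)` and
#' `e ~ N(0, sigma2_e I)` by average-information REML, falling back to an
#' EM step whenever the AI update leaves the feasible region. Variance
#' components are constrained non-negative (floored at a tiny fraction of
#' the phenotypic variance); standard errors come from the inverse AI
#' matrix at convergence. Non-convergence (including an unidentifiable
#' model, e.g. a GRM numerically proportional to the identity) is flagged
#' in the result rather than raised.
#'
#' @param y Numeric trait vector (typically the inverse-normal
#'   transformed residual).
#' @param grms A single `x_grm`/matrix or a list of them (components in
#'   order).
#' @param X Fixed-effect design matrix (default intercept only).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter Maximum iterations (default 100).
#' @return An object of class `xcwas_reml`: `sigma2` (named, components
#'   then `residual`), `se`, `h2` (per genetic component, share of total
#'   variance), `h2_se`, `loglik`, `converged`, `n_used`, `iterations`.
#' @export
reml_fit <- function(y, grms, X = NULL, tol = 1e-8, max_iter = 100) {
  if (inherits(grms, "x_grm") || is.matrix(grms)) grms <- list(grms)
  Gs <- lapply(grms, function(g) if (inherits(g, "x_grm")) g$matrix else g)
  nm <- names(grms) %||% paste0("G", seq_along(Gs))
  nm[nm == ""] <- paste0("G", which(nm == ""))
  n <- length(y)
  stopifnot(all(vapply(Gs, function(G) all(dim(G) == n), TRUE)))
  if (is.null(X)) X <- matrix(1, n, 1)
  K <- length(Gs)
  vp <- stats::var(y)
  theta <- rep(vp / (K + 1), K + 1)  # components then residual
  floor_v <- 1e-6 * vp
  Glist <- c(Gs, list(diag(n)))

  loglik <- -Inf
  converged <- FALSE
  AI <- NULL
  for (iter in seq_len(max_iter)) {
    V <- matrix(0, n, n)
    for (k in seq_len(K)) V <- V + theta[k] * Gs[[k]]
    diag(V) <- diag(V) + theta[K + 1]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) break
    Vi <- chol2inv(ch)
    XtViX <- crossprod(X, Vi %*% X)
    XtViX_i <- tryCatch(solve(XtViX), error = function(e) NULL)
    if (is.null(XtViX_i)) break
    P <- Vi - Vi %*% X %*% XtViX_i %*% crossprod(X, Vi)
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(ch))) +
                    determinant(XtViX, logarithm = TRUE)$modulus[1] +
                    sum(y * Py))
    # tr(P G) = sum(P * G) for symmetric G; y'PGPy = (Py)' G (Py)
    GPy <- lapply(Glist, function(G) G %*% Py)
    tr_PG <- vapply(Glist, function(G) sum(P * G), 0)
    yPGPy <- vapply(GPy, function(v) sum(Py * v), 0)
    score <- -0.5 * (tr_PG - yPGPy)
    AI <- matrix(0, K + 1, K + 1)
    PGPy <- lapply(GPy, function(v) P %*% v)
    for (k in seq_len(K + 1)) for (l in k:(K + 1)) {
      AI[k, l] <- AI[l, k] <- 0.5 * sum(GPy[[k]] * PGPy[[l]])
    }
    if (iter > 1 && abs(ll - loglik) < tol) {
      loglik <- ll
      converged <- TRUE
      break
    }
    loglik <- ll
    step <- if (rcond(AI) > 1e-12) tryCatch(solve(AI, score), error = function(e) NULL) else NULL
    new_theta <- NULL
    if (!is.null(step) && all(is.finite(step))) {
      # halve an AI step that overshoots the feasible region
      alpha <- 1
      for (h in 1:12) {
        cand <- theta + alpha * step
        if (all(is.finite(cand)) && all(cand >= 0)) { new_theta <- cand; break }
        alpha <- alpha / 2
      }
    }
    if (is.null(new_theta)) {
      # EM fallback always stays feasible
      new_theta <- theta + (theta^2 / n) * (yPGPy - tr_PG)
      new_theta <- pmax(new_theta, floor_v)
    }
    theta <- pmax(new_theta, floor_v)
  }

  se <- rep(NA_real_, K + 1)
  h2_se <- rep(NA_real_, K)
  identifiable <- !is.null(AI) && rcond(AI) > 1e-12
  if (identifiable) {
    AIi <- solve(AI)
    se <- sqrt(pmax(diag(AIi), 0))
    tot <- sum(theta)
    # delta method for h2_k = theta_k / sum(theta)
    for (k in seq_len(K)) {
      grad <- -theta[k] / tot^2 * rep(1, K + 1)
      grad[k] <- grad[k] + 1 / tot
      h2_se[k] <- sqrt(max(drop(t(grad) %*% AIi %*% grad), 0))
    }
  } else {
    converged <- FALSE
  }
  names(theta) <- names(se) <- c(nm, "residual")
  structure(list(sigma2 = theta, se = se,
                 h2 = theta[seq_len(K)] / sum(theta), h2_se = h2_se,
                 loglik = loglik, converged = converged,
                 n_used = n, iterations = iter),
            class = "xcwas_reml")
}

#' @export
print.xcwas_reml <- function(x, ...) {
  cat(sprintf("<xcwas_reml> n = %d, logLik = %.4f, %s after %d iterations\n",
              x$n_used, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a REML fit
#'
#' @param x An `xcwas_reml` object.
#' @param ... Unused.
#' @return A tibble with one row per variance component: `component`,
#'   `sigma2`, `se`, `h2`, `h2_se` (NA for the residual).
#' @export
tidy.xcwas_reml <- function(x, ...) {
  K <- length(x$h2)
  tibble::tibble(
    component = names(x$sigma2),
    sigma2 = unname(x$sigma2),
    se = unname(x$se),
    h2 = c(unname(x$h2), NA_real_)[seq_along(x$sigma2)],
    h2_se = c(x$h2_se, rep(NA_real_, length(x$sigma2) - K))
  )
}

#' Glance at a REML fit
#'
#' @param x An `xcwas_reml` object.
#' @param ... Unused.
#' @return One-row tibble: `loglik`, `converged`, `iterations`, `n_used`.
#' @export
glance.xcwas_reml <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, converged = x$converged,
                 iterations = x$iterations, n_used = x$n_used)
}

#' Likelihood-ratio test of zero genetic variance
#'
#' Tests `h2 = 0` for a variance component on the boundary of its
#' parameter space: `LR = 2 (ll_full - ll_null)` referred to the mixture
#' `0.5 chi2_0 + 0.5 chi2_1`, i.e. `p = 0.5 P(chi2_1 > LR)`.
#'
#' @param loglik_full,loglik_null Restricted log-likelihoods of the
#'   nested fits.
#' @param tol Negative-LR tolerance (default 0.01): a full fit stopped at
#'   the non-negativity boundary can sit marginally below the exact null
#'   optimum; anything worse indicates an optimizer fault.
#' @return A one-row tibble: `lr`, `p`.
#' @export
#' @examples
#' lrt_zero_variance(-100, -100)       # p = 0.5
#' lrt_zero_variance(-100, -101.353)   # p ~ 0.05
lrt_zero_variance <- function(loglik_full, loglik_null, tol = 0.01) {
  lr <- 2 * (loglik_full - loglik_null)
  if (lr < -tol) stop("negative likelihood ratio: optimizer fault", call. = FALSE)
  lr <- max(lr, 0)
  tibble::tibble(lr = lr, p = 0.5 * stats::pchisq(lr, 1, lower.tail = FALSE))
}

#' Write a GRM as gzipped text triples
#'
#' Writes `<prefix>.grm.gz` with tab-separated rows
#' `i j m_snps value` over the lower triangle (1-based indices, diagonal
#' included, values at full precision) and `<prefix>.grm.id` with
#' `sample_id sex` per row. [read_grm()] round-trips bit-exactly.
#'
#' @param grm An `x_grm` object.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_grm <- function(grm, prefix) {
  stopifnot(inherits(grm, "x_grm"))
  n <- length(grm$sample_ids)
  idx <- which(lower.tri(grm$matrix, diag = TRUE), arr.ind = TRUE)
  con <- gzfile(paste0(prefix, ".grm.gz"), "w")
  writeLines(sprintf("%d\t%d\t%d\t%s", idx[, 1], idx[, 2], grm$m_snps,
                     formatC(grm$matrix[idx], format = "g", digits = 17)),
             con)
  close(con)
  utils::write.table(data.frame(id = grm$sample_ids, sex = grm$sex),
                     paste0(prefix, ".grm.id"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a GRM written by [write_grm()]
#'
#' @param prefix Path prefix used when writing.
#' @param dc_model Model tag to record (default `"EV"`).
#' @return An `x_grm` object.
#' @export
read_grm <- function(prefix, dc_model = "EV") {
  ids <- utils::read.table(paste0(prefix, ".grm.id"), sep = "\t",
                           col.names = c("id", "sex"),
                           colClasses = "character")
  tri <- utils::read.table(gzfile(paste0(prefix, ".grm.gz")), sep = "\t",
                           col.names = c("i", "j", "m", "value"))
  n <- nrow(ids)
  A <- matrix(0, n, n, dimnames = list(ids$id, ids$id))
  A[cbind(tri$i, tri$j)] <- tri$value
  A[cbind(tri$j, tri$i)] <- tri$value
  out <- list(matrix = A, sample_ids = ids$id, sex = ids$sex,
              dc_model = dc_model, m_snps = tri$m[1])
  class(out) <- "x_grm"
  out
}
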