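# Linear mixed model with kinship and read-depth random effects.
#
# cov(y) = sigma2_g K + sigma2_d D + sigma2_e I,  D = diag(1 / n_reads).
# Variance ratios gamma = sigma2_./sigma2_e are estimated by REML on the log
# scale with multiple starts; sigma2_e is profiled out. Association tests are
# generalized least squares with the correlation structure fixed from the
# null fit and the scale re-estimated per regression, so the test reduces
# exactly to OLS when both variance components are zero.

reml_negll <- function(lg, K, D, X, y) {
  gg <- exp(lg[1]); gd <- exp(lg[2])
  if (!is.finite(gg) || !is.finite(gd) || gg > 1e8 || gd > 1e8)
    return(1e10)
  n <- length(y)
  S <- diag(n) + gg * K + gd * D
  U <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(U)) return(1e10)
  Xt <- backsolve(U, X, transpose = TRUE)
  yt <- backsolve(U, y, transpose = TRUE)
  XtX <- crossprod(Xt)
  b <- tryCatch(solve(XtX, crossprod(Xt, yt)), error = function(e) NULL)
  if (is.null(b)) return(1e10)
  r <- yt - Xt %*% b
  rss <- sum(r^2)
  p <- ncol(X)
  ldet <- 2 * sum(log(diag(U)))
  ldetX <- determinant(XtX, logarithm = TRUE)$modulus
  0.5 * (ldet + as.numeric(ldetX) + (n - p) * log(rss))
}

#' Fit the null linear mixed model for one gene
#'
#' REML estimation of the two-random-effect model
#' `cov(y) = sigma2_g K + sigma2_d D + sigma2_e I`, where `K` is the kinship
#' matrix (population structure) and `D = diag(1/n_i)` encodes per-donor read
#' depth. Fixed effects are an intercept plus optional covariates.
#' Optimization is over the two variance ratios on the log scale
#' (Nelder-Mead, multiple starts). A non-positive-semi-definite `K` is
#' eigenvalue-clipped with a warning; non-convergence is flagged and the fit
#' falls back to OLS (both ratios zero).
#'
#' @param y Donor-level expression vector (named by donor or aligned to `K`).
#' @param K Kinship matrix aligned to `y`.
#' @param reads Per-donor total read counts (positive).
#' @param covariates Optional donor-by-covariate matrix of fixed effects.
#' @return Object of class `"lmm_fit"` with variance components `sigma2_g`,
#'   `sigma2_d`, `sigma2_e`, the REML log-likelihood, a convergence flag and
#'   the relative-covariance Cholesky factor used by [test_snp()].
#' @export
fit_null_lmm <- function(y, K, reads, covariates = NULL) {
  n <- length(y)
  if (n < 10L) stop("need at least 10 donors")
  stopifnot(nrow(K) == n, ncol(K) == n, length(reads) == n, all(reads > 0))
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    warning("kinship not PSD; clipping negative eigenvalues")
    ed <- eigen(K, symmetric = TRUE)
    K <- ed$vectors %*% (pmax(ed$values, 0) * t(ed$vectors))
  }
  D <- diag(1 / reads)
  X <- cbind(`(Intercept)` = rep(1, n), covariates)

  starts <- list(c(-1, -1), c(-6, -6), c(0, -6), c(-6, 0))
  best <- NULL
  for (s in starts) {
    opt <- stats::optim(s, reml_negll, K = K, D = D, X = X, y = y,
                        method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  converged <- !is.null(best) && best$value < 1e9
  if (!converged) {
    gg <- 0; gd <- 0
    warning("REML did not converge; falling back to OLS covariance")
  } else {
    gg <- exp(best$par[1]); gd <- exp(best$par[2])
    # treat tiny ratios as boundary zeros
    if (gg < 1e-6) gg <- 0
    if (gd < 1e-6) gd <- 0
  }
  S0 <- diag(n) + gg * K + gd * D
  U <- chol(S0)
  Xt <- backsolve(U, X, transpose = TRUE)
  yt <- backsolve(U, y, transpose = TRUE)
  b <- solve(crossprod(Xt), crossprod(Xt, yt))
  rss <- sum((yt - Xt %*% b)^2)
  s2e <- rss / (n - ncol(X))
  fit <- list(sigma2_g = gg * s2e, sigma2_d = gd * s2e, sigma2_e = s2e,
              gamma_g = gg, gamma_d = gd,
              loglik = if (converged) -best$value else NA_real_,
              converged = converged,
              chol_rel = U, X = X, n = n,
              donors = names(y) %||% rownames(K))
  class(fit) <- "lmm_fit"
  fit
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Two-random-effect LMM (REML)\n")
  cat(sprintf("  sigma2_g (kinship):    %.4g\n", x$sigma2_g))
  cat(sprintf("  sigma2_d (read depth): %.4g\n", x$sigma2_d))
  cat(sprintf("  sigma2_e (residual):   %.4g\n", x$sigma2_e))
  if (!x$converged) cat("  [not converged; OLS fallback]\n")
  invisible(x)
}

#' Test one SNP against a fitted null covariance
#'
#' Generalized least squares of expression on alt-allele dosage with the
#' covariance structure fixed from the null LMM fit; the Wald statistic
#' `beta/se` is referred to the t distribution with `n - p` degrees of
#' freedom (so the test is exactly the OLS t-test when both variance
#' components are zero, and stays calibrated at cohort-scale donor counts).
#' Donors with missing dosage are dropped pairwise
#' (the covariance is re-projected onto the retained donors). When both
#' fitted variance components are zero the test is exactly ordinary least
#' squares.
#'
#' @param y Expression vector used in the null fit.
#' @param g_dosage Dosage vector aligned to `y` (`NA` allowed).
#' @param fit The `lmm_fit` from [fit_null_lmm()].
#' @param K,reads Kinship and read totals (needed only when donors are
#'   dropped for missingness and the covariance must be rebuilt).
#' @return List `(beta, se, p_nominal, n_used)`, or `NULL` when the dosage
#'   has zero variance after dropping.
#' @export
test_snp <- function(y, g_dosage, fit, K = NULL, reads = NULL) {
  ok <- !is.na(g_dosage)
  if (all(ok)) {
    U <- fit$chol_rel
    X <- cbind(fit$X, dosage = g_dosage)
  } else {
    if (is.null(K) || is.null(reads))
      stop("K and reads are required when dosages are missing")
    y <- y[ok]; K <- K[ok, ok, drop = FALSE]; reads <- reads[ok]
    S0 <- diag(sum(ok)) + fit$gamma_g * K + fit$gamma_d * diag(1 / reads)
    U <- chol(S0)
    X <- cbind(fit$X[ok, , drop = FALSE], dosage = g_dosage[ok])
  }
  if (stats::var(X[, "dosage"]) == 0) {
    # zero dosage variance
    return(NULL)
  }
  n <- length(y)
  Xt <- backsolve(U, X, transpose = TRUE)
  yt <- backsolve(U, y, transpose = TRUE)
  XtXi <- solve(crossprod(Xt))
  b <- XtXi %*% crossprod(Xt, yt)
  r <- yt - Xt %*% b
  s2 <- sum(r^2) / (n - ncol(X))
  se <- sqrt(s2 * diag(XtXi))
  j <- ncol(X)
  beta <- b[j]
  list(beta = beta, se = se[j],
       p_nominal = 2 * stats::pt(-abs(beta / se[j]), df = n - ncol(X)),
       n_used = n)
}

# Vectorized scan: z-statistics for every SNP (columns of G) against y, on
# the GLS-whitened scale of `fit`. Missing dosages are mean-imputed here;
# use test_snp for the exact pairwise-complete test of a single SNP.
scan_stats <- function(yt, Gt, Xt, n_covar) {
  # yt, Gt, Xt already whitened; residualize on fixed effects
  Q <- qr.Q(qr(Xt))
  Yc <- yt - Q %*% crossprod(Q, yt)
  Gc <- Gt - Q %*% crossprod(Q, Gt)
  gss <- colSums(Gc^2)
  ok <- gss > 1e-12
  cij <- crossprod(Gc, Yc)                       # S x P
  y2 <- colSums(Yc^2)
  n <- nrow(yt)
  df <- n - n_covar - 1L
  b <- sweep(cij, 1, gss, "/")
  rss <- outer(gss, y2, function(g, s) s) - cij^2 / gss
  se <- sqrt(sweep(rss / df, 1, gss, "/"))
  z <- b / se
  z[!ok, ] <- 0
  list(z = z, beta = b, se = se, ok = ok)
}
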