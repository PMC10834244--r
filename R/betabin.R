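# Beta-binomial core shared across the package.
#
# One parameterization is used everywhere: mean mu in (0,1) and overdispersion
# phi in [0,1), with shape parameters
#   alpha = mu  * (1 - phi) / phi
#   beta  = (1 - mu) * (1 - phi) / phi
# so that Var(k | n) = n mu (1-mu) (1 + (n-1) phi). phi = 0 degenerates to the
# binomial.

#' Beta-binomial density
#'
#' Density of the beta-binomial distribution in the (mean, overdispersion)
#' parameterization used throughout the package.
#'
#' @param x Number of successes.
#' @param size Number of trials.
#' @param mu Mean success probability, in (0,1).
#' @param phi Overdispersion in [0,1); `phi = 0` gives the binomial density.
#' @param log Return log density?
#' @return Density values, recycled over the longest argument.
#' @export
dbetabinom <- function(x, size, mu, phi, log = FALSE) {
  n <- max(length(x), length(size), length(mu), length(phi))
  x <- rep_len(x, n); size <- rep_len(size, n)
  mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  ll <- numeric(n)
  bin <- phi <= 0
  if (any(bin))
    ll[bin] <- stats::dbinom(x[bin], size[bin], mu[bin], log = TRUE)
  if (any(!bin)) {
    a <- mu[!bin] * (1 - phi[!bin]) / phi[!bin]
    b <- (1 - mu[!bin]) * (1 - phi[!bin]) / phi[!bin]
    ll[!bin] <- lchoose(size[!bin], x[!bin]) +
      lbeta(x[!bin] + a, size[!bin] - x[!bin] + b) - lbeta(a, b)
  }
  if (log) ll else exp(ll)
}

#' Beta-binomial random draws
#'
#' @param n Number of draws.
#' @param size Number of trials (recycled).
#' @param mu Mean success probability.
#' @param phi Overdispersion in [0,1); 0 draws binomials.
#' @return Integer vector of counts.
#' @export
rbetabinom <- function(n, size, mu, phi) {
  size <- rep_len(size, n); mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  p <- mu
  od <- phi > 0
  if (any(od)) {
    a <- mu[od] * (1 - phi[od]) / phi[od]
    b <- (1 - mu[od]) * (1 - phi[od]) / phi[od]
    p[od] <- stats::rbeta(sum(od), a, b)
  }
  stats::rbinom(n, size, p)
}

# two-sided Wald p on the t reference; normal when no df remain
wald_p_t <- function(coef, se, df) {
  z <- abs(coef / se)
  if (df >= 1L) 2 * stats::pt(-z, df = df) else 2 * stats::pnorm(-z)
}

betabin_negll <- function(par, k, n, X) {
  nb <- ncol(X)
  eta <- drop(X %*% par[seq_len(nb)])
  mu <- expit(eta)
  phi <- expit(par[nb + 1L])
  val <- suppressWarnings(-sum(dbetabinom(k, n, mu, phi, log = TRUE)))
  if (!is.finite(val)) 1e10 else val   # off-scale steps during optimization
}

#' Fit a beta-binomial regression on the logit scale
#'
#' Maximum-likelihood fit of counts `k` out of `n` with
#' `logit(mu) = X b` and a single overdispersion `phi` shared across
#' observations. Optimization runs on the unconstrained scale
#' `(b, logit(phi))` with multiple starts: from the binomial GLM estimate with
#' a small `phi`, and from `phi = 0.1`. Standard errors come from the inverse
#' observed information at the optimum. Two-sided Wald p-values refer the
#' statistic to the t distribution with `n_obs - n_coef` degrees of freedom
#' (the overdispersion plays the role the residual variance plays in a
#' linear model and does not consume a coefficient degree of freedom); at
#' the handful of donors typical of these tests the normal reference is
#' visibly anti-conservative. When no degrees of freedom remain the normal
#' reference is used.
#'
#' This is the workhorse behind [betabin_ase_test()] (intercept-only model,
#' testing mean allele fraction 0.5) and [betabin_usage_test()] (genotype
#' dosage as covariate, testing for a transcript-usage QTL).
#'
#' @param k Successes per observation (e.g. alt-allele or long-isoform UMIs).
#' @param n Trials per observation (total UMIs); observations with `n = 0`
#'   are dropped.
#' @param X Design matrix (default intercept-only).
#' @return An object of class `"betabin_fit"` with elements `coefficients`,
#'   `se`, `wald_p`, `phi`, `loglik`, `converged`, `fallback` (TRUE when the
#'   reported coefficients come from the binomial GLM because the
#'   beta-binomial optimization failed), `n_obs`.
#' @export
betabin_fit <- function(k, n, X = matrix(1, length(k), 1)) {
  keep <- n > 0
  k <- k[keep]; n <- n[keep]
  X <- X[keep, , drop = FALSE]
  if (length(k) < 1L) stop("no observations with positive totals")
  nb <- ncol(X)
  if (is.null(colnames(X)))
    colnames(X) <- if (nb == 1L) "b0" else c("b0", paste0("b", seq_len(nb - 1L)))

  # binomial GLM start (and fallback)
  glm_fit <- suppressWarnings(
    stats::glm(cbind(k, n - k) ~ X - 1, family = stats::binomial()))
  b_start <- stats::coef(glm_fit)
  b_start[!is.finite(b_start)] <- 0
  starts <- list(c(b_start, logit(1e-3)), c(b_start, logit(0.1)))

  best <- NULL
  for (s in starts) {
    opt <- try(stats::optim(s, betabin_negll, k = k, n = n, X = X,
                            method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }

  if (is.null(best)) {
    sm <- suppressWarnings(summary(glm_fit)$coefficients)
    co <- stats::setNames(sm[, 1], colnames(X))
    se <- stats::setNames(sm[, 2], colnames(X))
    out <- list(coefficients = co, se = se,
                wald_p = wald_p_t(co, se, length(k) - nb),
                phi = 0, loglik = as.numeric(stats::logLik(glm_fit)),
                converged = FALSE, fallback = TRUE, n_obs = length(k))
    class(out) <- "betabin_fit"
    return(out)
  }

  H <- try(stats::optimHess(best$par, betabin_negll, k = k, n = n, X = X),
           silent = TRUE)
  se_all <- rep(NA_real_, nb + 1L)
  if (!inherits(H, "try-error")) {
    Hi <- try(solve(H), silent = TRUE)
    if (!inherits(Hi, "try-error")) {
      v <- diag(Hi)
      se_all <- sqrt(pmax(v, 0))
      se_all[v <= 0] <- NA_real_
    }
  }
  co <- stats::setNames(best$par[seq_len(nb)], colnames(X))
  se <- stats::setNames(se_all[seq_len(nb)], colnames(X))
  # fall back to GLM curvature when the information matrix is singular
  if (any(!is.finite(se))) {
    sm <- suppressWarnings(summary(glm_fit)$coefficients)
    se[!is.finite(se)] <- sm[!is.finite(se), 2]
  }
  out <- list(coefficients = co, se = se,
              wald_p = wald_p_t(co, se, length(k) - nb),
              phi = unname(expit(best$par[nb + 1L])),
              loglik = -best$value,
              converged = best$convergence == 0L,
              fallback = FALSE, n_obs = length(k))
  class(out) <- "betabin_fit"
  out
}

#' @export
print.betabin_fit <- function(x, ...) {
  cat("Beta-binomial regression (logit link)\n")
  cat(sprintf("  observations: %d   phi: %.4g   logLik: %.3f%s\n",
              x$n_obs, x$phi, x$loglik,
              if (!x$converged) "   [not converged]" else ""))
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se,
               `Pr(>|z|)` = x$wald_p)
  print(tab, ...)
  invisible(x)
}

#' @export
coef.betabin_fit <- function(object, ...) object$coefficients

#' @export
logLik.betabin_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1L,
            class = "logLik")
}
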