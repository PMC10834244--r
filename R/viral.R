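# Viral-presence statistics on a cell-by-virus UMI matrix.

#' Donor-level viral presence and cohort prevalence
#'
#' A donor carries a virus when the donor's summed UMIs for that virus reach
#' at least one across any cell type. Prevalence is the fraction of donors
#' carrying the virus, computed per cohort (MS versus non-MS); a virus is
#' retained for testing when it is prevalent in more than `prevalence_min`
#' (default 5%) of either cohort.
#'
#' @param vm Cell-by-virus count matrix (dense or sparse).
#' @param cell_meta Data frame aligned with rows of `vm`: donor, group.
#' @param prevalence_min Retention threshold (default 0.05).
#' @return List with `presence` (donor-by-virus logical matrix),
#'   `prevalence` (virus-by-cohort matrix), `testable` (logical per virus),
#'   `donor_group` (named vector).
#' @export
donor_presence <- function(vm, cell_meta, prevalence_min = 0.05) {
  vm <- as.matrix(vm)
  fd <- factor(cell_meta$donor, levels = sort(unique(cell_meta$donor)))
  sums <- rowsum(vm, fd)
  presence <- sums >= 1
  dgrp <- tapply(cell_meta$group, fd, function(g) g[1])
  is_ms <- dgrp == "MS"
  prev <- cbind(MS = colMeans(presence[is_ms, , drop = FALSE]),
                nonMS = colMeans(presence[!is_ms, , drop = FALSE]))
  testable <- prev[, "MS"] > prevalence_min | prev[, "nonMS"] > prevalence_min
  list(presence = presence, prevalence = prev, testable = testable,
       donor_group = dgrp)
}

# Firth-penalized logistic regression (Jeffreys prior): Newton iterations on
# the adjusted score U = X'(y - p + h (0.5 - p)), h the hat diagonal.
firth_logistic <- function(X, y, max_iter = 100L, tol = 1e-8) {
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    p <- expit(eta)
    wv <- p * (1 - p)
    XW <- X * wv
    Info <- crossprod(X, XW)
    Ii <- tryCatch(solve(Info), error = function(e) NULL)
    if (is.null(Ii)) break
    h <- rowSums((X %*% Ii) * XW)
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- drop(Ii %*% U)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(crossprod(X, X * (expit(drop(X %*% b)) *
                                            (1 - expit(drop(X %*% b))))))))
  list(coef = b, se = se)
}

#' Donor-level viral prevalence regression
#'
#' Per testable virus, a logistic regression
#' `virus_present ~ is_MS + total_UMIs + intercept` with a Wald test on the
#' `is_MS` coefficient, followed by BH FDR across the tested viruses at
#' `fdr_level` (default 10%). `total_UMIs` is the donor's total
#' transcriptome UMI count (sequencing-depth control) unless
#' `depth = "viral"`. Perfect separation is flagged and the reported fit
#' comes from a Firth-penalized fallback. Viruses present in all donors or
#' absent from all are untestable and skipped.
#'
#' @param presence Donor-by-virus logical matrix from [donor_presence()].
#' @param is_ms Logical or 0/1 vector per donor.
#' @param total_umis Per-donor total UMIs.
#' @param testable Optional logical per virus (default all columns).
#' @param fdr_level FDR level for the flags.
#' @return Data frame (virus, coef, se, p, fdr, significant, separated).
#' @export
donor_prevalence_test <- function(presence, is_ms, total_umis,
                                  testable = NULL, fdr_level = 0.10) {
  testable <- testable %||% rep(TRUE, ncol(presence))
  is_ms <- as.numeric(is_ms)
  rows <- list()
  for (v in which(testable)) {
    yv <- as.numeric(presence[, v])
    if (all(yv == 0) || all(yv == 1)) next
    df <- data.frame(y = yv, is_ms = is_ms, total_umis = total_umis)
    fit <- suppressWarnings(stats::glm(y ~ is_ms + total_umis, df,
                                       family = stats::binomial()))
    sep <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 10)
    if (sep) {
      X <- cbind(1, is_ms, scale(total_umis))
      ff <- firth_logistic(X, yv)
      coef_ms <- ff$coef[2]; se_ms <- ff$se[2]
    } else {
      sm <- summary(fit)$coefficients
      coef_ms <- sm["is_ms", 1]; se_ms <- sm["is_ms", 2]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      virus = colnames(presence)[v] %||% paste0("virus", v),
      coef = coef_ms, se = se_ms,
      p = 2 * stats::pnorm(-abs(coef_ms / se_ms)), separated = sep,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$fdr < fdr_level
  res
}

#' Cell-level viral proportion regression
#'
#' The per-donor viral proportion is the fraction of the donor's cells with
#' at least one viral UMI of any virus. The model is
#' `viral_proportion ~ is_MS + log(total_UMIs) + log(total_cells) +
#' intercept`, ordinary least squares with a Wald test on `is_MS`.
#'
#' @param vm Cell-by-virus count matrix.
#' @param cell_meta Data frame aligned to `vm` rows: donor, group, and
#'   `total_umis` (per-cell transcriptome UMIs).
#' @return List (coef, se, p, n_donors, donor_table, degenerate).
#' @export
cell_level_test <- function(vm, cell_meta) {
  vm <- as.matrix(vm)
  any_viral <- rowSums(vm) >= 1
  fd <- factor(cell_meta$donor, levels = sort(unique(cell_meta$donor)))
  prop <- tapply(any_viral, fd, mean)
  ncells <- as.vector(table(fd))
  tot <- tapply(cell_meta$total_umis, fd, sum)
  grp <- tapply(cell_meta$group, fd, function(g) g[1])
  is_ms <- as.numeric(grp == "MS")
  if (length(unique(is_ms)) < 2L || min(table(is_ms)) < 2L)
    stop("need at least 2 donors per group")
  dt <- data.frame(donor = levels(fd), proportion = as.vector(prop),
                   is_ms = is_ms, total_umis_log = log(as.vector(tot)),
                   total_cells_log = log(ncells), stringsAsFactors = FALSE)
  if (all(dt$proportion == 0))
    return(list(coef = 0, se = NA_real_, p = 1, n_donors = nrow(dt),
                donor_table = dt, degenerate = TRUE))
  fit <- stats::lm(proportion ~ is_ms + total_umis_log + total_cells_log,
                   data = dt)
  sm <- summary(fit)$coefficients
  list(coef = sm["is_ms", 1], se = sm["is_ms", 2],
       p = 2 * stats::pnorm(-abs(sm["is_ms", 1] / sm["is_ms", 2])),
       n_donors = nrow(dt), donor_table = dt, degenerate = FALSE)
}
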