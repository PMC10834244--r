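# Downstream statistics on a fitted factor model (factor values Z, factor
# weights W). The factorization itself is consumed, not fit.

#' Variance explained by each factor in one cell type
#'
#' For the cells of the given type, `R2_f = 1 - ||Y - z_f w_f'||^2 / ||Y||^2`
#' on the centered expression matrix the model was fit to. Factors at or
#' above `threshold` (default 1% of variance) are flagged as retained.
#'
#' @param Z Cell-by-factor value matrix.
#' @param W Gene-by-factor weight matrix.
#' @param Y Cell-by-gene centered expression matrix the model was fit to.
#' @param cell_meta Data frame aligned with rows of `Z`/`Y` carrying
#'   `cell_type`.
#' @param cell_type Cell type to evaluate.
#' @param threshold Retention threshold on R-squared (default 0.01).
#' @return Data frame (factor, r2, retained), one row per factor.
#' @export
variance_explained <- function(Z, W, Y, cell_meta, cell_type,
                               threshold = 0.01) {
  if (missing(Y) || is.null(Y))
    stop("the expression matrix the model was fit to must be supplied")
  sel <- cell_meta$cell_type == cell_type
  if (sum(sel) < 2L) stop("need at least 2 cells of type ", cell_type)
  Yc <- Y[sel, , drop = FALSE]
  Zc <- Z[sel, , drop = FALSE]
  ss_tot <- sum(Yc^2)
  r2 <- vapply(seq_len(ncol(Zc)), function(f) {
    1 - sum((Yc - outer(Zc[, f], W[, f]))^2) / ss_tot
  }, 0)
  data.frame(factor = colnames(Z) %||% paste0("factor", seq_len(ncol(Z))),
             r2 = r2, retained = r2 >= threshold, stringsAsFactors = FALSE)
}

#' Donor-level permutation test of factor-disease association
#'
#' The donor value of a factor is the mean factor value over that donor's
#' cells of the tested cell type. The effect is the linear-regression
#' coefficient of the donor mean on the case indicator; the null is built by
#' permuting donor group labels, and the empirical p-value is
#' `(1 + #\{|effect*| >= |effect|\}) / (n_perm + 1)`.
#'
#' @param Z Cell-by-factor matrix.
#' @param cell_meta Data frame aligned with `Z` rows: donor, cell_type,
#'   group.
#' @param factor Factor column (index or name).
#' @param cell_type Cell type whose cells enter the donor means.
#' @param groups Length-2 character vector `(case, control)`.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed.
#' @return List (effect, p, n_case, n_control, donor_means).
#' @export
factor_disease_association <- function(Z, cell_meta, factor, cell_type,
                                       groups = c("MS", "IIH"),
                                       n_perm = 10000L, seed = 1L) {
  sel <- cell_meta$cell_type == cell_type & cell_meta$group %in% groups
  z <- Z[sel, factor]
  don <- cell_meta$donor[sel]
  grp <- cell_meta$group[sel]
  dm <- tapply(z, don, mean)
  dgrp <- tapply(grp, don, function(g) g[1])
  is_case <- as.numeric(dgrp == groups[1])
  if (sum(is_case) < 3L || sum(1 - is_case) < 3L) {
    # fewer than 3 donors in a group
    return(NULL)
  }
  eff <- function(ind) {
    xc <- ind - mean(ind)
    sum(xc * dm) / sum(xc^2)
  }
  obs <- eff(is_case)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) eff(sample(is_case)), 0)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
  list(effect = obs, p = p, n_case = sum(is_case),
       n_control = sum(1 - is_case), donor_means = dm)
}

#' Test several factor/cell-type pairs with BH correction
#'
#' Runs [factor_disease_association()] over the supplied pairs and adjusts
#' the empirical p-values by Benjamini-Hochberg, flagging pairs at
#' `fdr_level` (default 10%).
#'
#' @param Z,cell_meta As in [factor_disease_association()].
#' @param pairs Data frame with columns `factor`, `cell_type`.
#' @param groups,n_perm,seed Passed through.
#' @param fdr_level FDR level for the flags.
#' @return Data frame (factor, cell_type, effect, p, fdr, significant).
#' @export
factor_association_scan <- function(Z, cell_meta, pairs,
                                    groups = c("MS", "IIH"),
                                    n_perm = 10000L, seed = 1L,
                                    fdr_level = 0.10) {
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- factor_disease_association(Z, cell_meta, pairs$factor[i],
                                    pairs$cell_type[i], groups,
                                    n_perm, seed + i)
    if (is.null(a)) return(NULL)
    data.frame(factor = pairs$factor[i], cell_type = pairs$cell_type[i],
               effect = a$effect, p = a$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(NULL)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$fdr < fdr_level
  res
}

#' Regulon enrichment on factor weights
#'
#' The aggregate weight of a transcription factor's regulon in each factor
#' is the matrix product `S = W' T` (plain sum of member weights; a mean
#' option exists for regulon-size comparability). Significance is assessed
#' against a sampling null: for a TF with k targets, k genes are drawn
#' uniformly without replacement from the shared gene universe and the
#' aggregate recomputed, `n_samples` times; the two-sided empirical p is
#' `(1 + #\{|S*| >= |S|\}) / (n_samples + 1)`. TFs with fewer than 3 targets
#' in the universe are dropped.
#'
#' @param W Gene-by-factor weight matrix (rownames = genes).
#' @param Treg Binary gene-by-TF membership matrix (rownames = genes).
#' @param n_samples Null draws (the study setting is 10000).
#' @param seed Integer seed.
#' @param aggregate `"sum"` (the literal matrix product, default) or
#'   `"mean"`.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return List with `score` (factor-by-TF aggregate matrix) and `p`
#'   (empirical p-values, same shape).
#' @export
regulon_enrichment <- function(W, Treg, n_samples = 10000L, seed = 1L,
                               aggregate = c("sum", "mean"),
                               alternative = c("two.sided", "greater")) {
  aggregate <- match.arg(aggregate)
  alternative <- match.arg(alternative)
  universe <- intersect(rownames(W), rownames(Treg))
  if (!length(universe)) stop("empty gene universe intersection")
  W <- W[universe, , drop = FALSE]
  Treg <- Treg[universe, , drop = FALSE]
  sizes <- colSums(Treg)
  keep <- sizes >= 3L
  Treg <- Treg[, keep, drop = FALSE]
  sizes <- sizes[keep]
  S <- crossprod(W, Treg)                 # factor x TF
  if (aggregate == "mean") S <- sweep(S, 2, sizes, "/")

  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  nuniv <- length(universe)
  P <- matrix(NA_real_, nrow(S), ncol(S), dimnames = dimnames(S))
  for (t in seq_len(ncol(Treg))) {
    k <- sizes[t]
    draws <- matrix(0, n_samples, ncol(W))
    for (b in seq_len(n_samples)) {
      idx <- sample.int(nuniv, k)
      draws[b, ] <- colSums(W[idx, , drop = FALSE])
    }
    if (aggregate == "mean") draws <- draws / k
    for (f in seq_len(ncol(W))) {
      if (alternative == "two.sided")
        P[f, t] <- (1 + sum(abs(draws[, f]) >= abs(S[f, t]))) /
          (n_samples + 1)
      else
        P[f, t] <- (1 + sum(draws[, f] >= S[f, t])) / (n_samples + 1)
    }
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  list(score = S, p = P)
}

#' Competitive gene-set test on absolute factor weights
#'
#' Wilcoxon rank-sum test of `|w_gf|` for member versus non-member genes of
#' each set, BH-corrected across sets. Sets overlapping the universe in
#' fewer than 3 genes, or covering the whole universe (no contrast), are
#' skipped.
#'
#' @param W Gene-by-factor weight matrix (rownames = genes).
#' @param gene_sets Named list of character vectors.
#' @param factor Factor column (index or name).
#' @return Data frame (set, n_members, p, fdr); skipped sets absent.
#' @export
gsea_abs_weights <- function(W, gene_sets, factor) {
  w <- abs(W[, factor])
  universe <- rownames(W)
  rows <- lapply(names(gene_sets), function(nm) {
    mem <- universe %in% gene_sets[[nm]]
    if (sum(mem) < 3L || all(mem)) return(NULL)
    p <- stats::wilcox.test(w[mem], w[!mem])$p.value
    data.frame(set = nm, n_members = sum(mem), p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res
}
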