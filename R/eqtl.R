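# cis-eQTL scan: window selection, gene-level permutations, Storey q-values,
# conditional FDR and replication concordance.

#' Select cis SNPs for a gene window
#'
#' SNPs on the gene's chromosome with
#' `start - flank <= pos <= end + flank`, boundaries inclusive.
#'
#' @param window List or one-row data frame with `chrom`, `start`, `end` and
#'   optionally `flank` (default 100000, i.e. 100 kb either side).
#' @param snps SNP table with `id`, `chrom`, `pos`.
#' @param flank Window flank in bp, overriding `window$flank`.
#' @return The subset of `snps` inside the window.
#' @export
cis_snps <- function(window, snps, flank = NULL) {
  flank <- flank %||% window$flank %||% 100000L
  stopifnot(window$start <= window$end, flank >= 0)
  sel <- snps$chrom == window$chrom &
    snps$pos >= window$start - flank & snps$pos <= window$end + flank
  snps[sel, , drop = FALSE]
}

#' Gene-level permutation p-value
#'
#' The observed statistic is the minimum nominal p over the gene's cis SNPs;
#' the null distribution re-computes that minimum with donor labels permuted
#' (the same permutation across all SNPs, preserving cis LD). Permutation is
#' applied to the whitened residuals of the null model (Freedman-Lane style):
#' after transforming by the fitted covariance the residuals are exchangeable
#' under the no-association null, so the permutation stays calibrated in the
#' presence of relatedness and read-depth structure.
#' `p_perm = (1 + #\{null min <= observed min\}) / (n_perm + 1)`, so the
#' smallest attainable value is `1/(n_perm+1)`. The null-model covariance is
#' held fixed from `fit`; missing dosages are mean-imputed for the scan.
#'
#' @param y Donor expression vector.
#' @param G Donor-by-SNP cis dosage matrix.
#' @param fit The `lmm_fit` for this gene.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @return List with `p_perm`, `best_snp` (column index), `beta`, `se`,
#'   `p_nominal` (per-SNP vectors).
#' @export
gene_level_permutation <- function(y, G, fit, n_perm = 1000L, seed = 1L) {
  G <- as.matrix(G)
  for (j in seq_len(ncol(G))) {
    m <- is.na(G[, j])
    if (any(m)) G[m, j] <- mean(G[, j], na.rm = TRUE)
  }
  U <- fit$chol_rel
  n <- length(y)
  yt <- backsolve(U, cbind(y), transpose = TRUE)
  Gt <- backsolve(U, G, transpose = TRUE)
  Xt <- backsolve(U, fit$X, transpose = TRUE)
  obs <- scan_stats(yt, Gt, Xt, ncol(fit$X))
  if (!any(obs$ok)) {
    # no testable cis SNP
    return(NULL)
  }
  z_obs <- abs(obs$z[, 1])
  z_obs[!obs$ok] <- 0
  max_obs <- max(z_obs)

  # whitened residuals are exchangeable under the null: permute those
  Q <- qr.Q(qr(Xt))
  e <- drop(yt - Q %*% crossprod(Q, yt))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  P <- matrix(0, n, n_perm)
  for (k in seq_len(n_perm)) P[, k] <- e[sample.int(n)]
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)

  nullz <- scan_stats(P, Gt, Xt, ncol(fit$X))$z
  nullz[!obs$ok, ] <- 0
  max_null <- apply(abs(nullz), 2, max)
  p_perm <- (1 + sum(max_null >= max_obs)) / (n_perm + 1)
  pn <- 2 * stats::pt(-z_obs, df = n - ncol(fit$X) - 1L)
  pn[!obs$ok] <- NA_real_
  list(p_perm = p_perm, best_snp = which.max(z_obs),
       beta = obs$beta[, 1], se = obs$se[, 1], p_nominal = pn)
}

#' Storey q-values
#'
#' `q_i = min over p_j >= p_i of pi0 * m * p_j / rank(p_j)` with the null
#' proportion estimated at the fixed point `lambda = 0.5`,
#' `pi0 = #\{p > 0.5\} / (0.5 m)`, capped at 1. The fixed-lambda estimator is
#' robust at the small gene counts typical of per-cell-type scans.
#'
#' @param p Vector of p-values in (0,1\].
#' @return Vector of q-values, monotone non-decreasing in `p`.
#' @export
storey_qvalues <- function(p) {
  m <- length(p)
  if (!m) return(numeric(0))
  stopifnot(all(p > 0 & p <= 1))
  pi0 <- min(1, sum(p > 0.5) / (0.5 * m))
  o <- order(p)
  r <- seq_len(m)
  q_sorted <- pi0 * m * p[o] / r
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

#' Conditional FDR via reference-stratified Storey q-values
#'
#' Genes with strong evidence in an external reference study (reference p
#' below `ref_threshold`, by default the Bonferroni point `0.05/|ref|`) form
#' a conditioned stratum within which Storey q-values are computed
#' separately; genes absent from the reference, or outside the stratum, are
#' handled by plain Storey q-values. Both branches are thresholded at
#' `alpha` (default 10%).
#'
#' @param p Gene-level permutation p-values.
#' @param reference_p Reference-study p-values aligned to `p`; `NA` where the
#'   gene is absent from the reference.
#' @param alpha FDR level for the significance flags.
#' @param ref_threshold Reference evidence cutoff; default `0.05 / #matched`.
#' @return Data frame with `q` (within-branch q-value), `method`
#'   (`"cfdr"`/`"storey"`), and `significant`.
#' @export
conditional_fdr <- function(p, reference_p, alpha = 0.10,
                            ref_threshold = NULL) {
  stopifnot(length(p) == length(reference_p))
  matched <- !is.na(reference_p)
  ref_threshold <- ref_threshold %||%
    if (any(matched)) 0.05 / sum(matched) else 0
  cond <- matched & reference_p < ref_threshold
  q <- rep(NA_real_, length(p))
  if (any(cond)) q[cond] <- storey_qvalues(p[cond])
  if (any(!cond)) q[!cond] <- storey_qvalues(p[!cond])
  data.frame(q = q, method = ifelse(cond, "cfdr", "storey"),
             significant = q < alpha, stringsAsFactors = FALSE)
}

#' Replication concordance rate
#'
#' Joins two result sets on (gene, snp) with allele harmonization (the
#' external beta's sign is flipped when its ref/alt assignment is swapped
#' relative to the discovery set). An effect replicates when the direction
#' agrees and the external p is nominally significant (`p < 0.05`); the rate
#' is replicated over joinable pairs, `NA` when nothing joins.
#'
#' @param results_a Discovery results: data frame with gene, snp, beta, and
#'   optionally ref/alt.
#' @param results_b External summaries: gene, snp, beta, p, optionally
#'   ref/alt.
#' @return List with `rate`, `n_joined`, `n_replicated`, and the joined
#'   table.
#' @export
replication_concordance <- function(results_a, results_b) {
  # suffix every non-key column explicitly so p -> p_b even when only one
  # side carries it
  ka <- results_a
  kb <- results_b
  names(ka)[!names(ka) %in% c("gene", "snp")] <-
    paste0(names(ka)[!names(ka) %in% c("gene", "snp")], "_a")
  names(kb)[!names(kb) %in% c("gene", "snp")] <-
    paste0(names(kb)[!names(kb) %in% c("gene", "snp")], "_b")
  j <- merge(ka, kb, by = c("gene", "snp"))
  if (!nrow(j))
    return(list(rate = NA_real_, n_joined = 0L, n_replicated = 0L,
                joined = j))
  beta_b <- j$beta_b
  if (all(c("ref_a", "alt_a", "ref_b", "alt_b") %in% names(j))) {
    swap <- j$ref_a == j$alt_b & j$alt_a == j$ref_b
    beta_b[swap] <- -beta_b[swap]
  }
  rep_ok <- sign(j$beta_a) == sign(beta_b) & j$p_b < 0.05
  list(rate = mean(rep_ok), n_joined = nrow(j),
       n_replicated = sum(rep_ok), joined = cbind(j, replicated = rep_ok))
}

#' Map cis-eQTLs for one cell type
#'
#' For each gene: select cis SNPs within the window that pass the MAF
#' filter, fit the null two-random-effect LMM once, scan all cis SNPs by
#' GLS, and compute the gene-level permutation p-value. Gene-level p-values
#' are then corrected by Storey q-values, or by conditional FDR when a
#' reference is supplied.
#'
#' @param pb A `pseudobulk` object (already aligned to genotyped donors).
#' @param geno A QC-filtered `genotype_table`.
#' @param gene_annot Gene annotation data frame (gene, chrom, start, end).
#' @param K Kinship matrix over all genotyped donors.
#' @param window_bp cis window flank (default 100000).
#' @param maf_min Minimum minor allele frequency (default 0.10).
#' @param n_perm Permutations per gene (default 1000).
#' @param seed Integer seed.
#' @param reference Optional data frame (gene, p) of external summary
#'   statistics for the conditional-FDR branch.
#' @param alpha FDR level (default 0.10).
#' @param covariates Optional donor-level fixed-effect matrix.
#' @return Data frame of class `"eqtl_scan"`: one row per tested gene with
#'   the best cis SNP, effect size, nominal and permutation p-values,
#'   q-value, correction method and significance flag.
#' @export
map_eqtls <- function(pb, geno, gene_annot, K, window_bp = 100000L,
                      maf_min = 0.10, n_perm = 1000L, seed = 1L,
                      reference = NULL, alpha = 0.10, covariates = NULL) {
  donors <- pb$donors
  gidx <- match(donors, geno$donors$donor)
  if (anyNA(gidx)) stop("pseudobulk donors missing from genotypes")
  dos <- geno$dosage[gidx, , drop = FALSE]
  Kd <- K[donors, donors]
  maf <- apply(dos, 2, minor_allele_frequency)
  snp_ok <- !is.na(maf) & maf >= maf_min
  snps <- geno$snps[snp_ok, , drop = FALSE]
  dos <- dos[, snp_ok, drop = FALSE]

  rows <- list()
  for (i in seq_len(nrow(gene_annot))) {
    gene <- gene_annot$gene[i]
    if (!gene %in% colnames(pb$expr)) next
    cis <- cis_snps(gene_annot[i, ], snps, flank = window_bp)
    if (!nrow(cis)) next
    y <- pb$expr[, gene]
    names(y) <- donors
    fit <- fit_null_lmm(y, Kd, pb$total_reads, covariates)
    G <- dos[, cis$id, drop = FALSE]
    pr <- gene_level_permutation(y, G, fit, n_perm = n_perm,
                                 seed = stage_seed(seed + i, "eqtl"))
    if (is.null(pr)) next
    b <- pr$best_snp
    rows[[length(rows) + 1L]] <- data.frame(
      cell_type = pb$cell_type, gene = gene, snp = cis$id[b],
      chrom = cis$chrom[b], pos = cis$pos[b],
      ref = cis$ref[b] %||% NA_character_,
      alt = cis$alt[b] %||% NA_character_,
      beta = pr$beta[b], se = pr$se[b], p_nominal = pr$p_nominal[b],
      p_perm = pr$p_perm, n_donors = length(y), n_cis = nrow(cis),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no testable gene")
  res <- do.call(rbind, rows)
  if (is.null(reference)) {
    res$q_value <- storey_qvalues(res$p_perm)
    res$method <- "storey"
    res$significant <- res$q_value < alpha
  } else {
    ref_p <- reference$p[match(res$gene, reference$gene)]
    cf <- conditional_fdr(res$p_perm, ref_p, alpha = alpha)
    res$q_value <- cf$q
    res$method <- cf$method
    res$significant <- cf$significant
  }
  class(res) <- c("eqtl_scan", "data.frame")
  res
}

#' @export
print.eqtl_scan <- function(x, ...) {
  cat(sprintf("cis-eQTL scan [%s]: %d genes tested, %d significant\n",
              x$cell_type[1], nrow(x), sum(x$significant)))
  NextMethod()
}
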