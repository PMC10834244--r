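# Single-cell normalization and donor-level aggregation.

#' Normalize single-cell counts
#'
#' Two variance-stabilizing schemes selectable by `method`:
#'
#' * `"pearson_nb"` (default): per-gene negative-binomial Pearson residuals.
#'   The expected count of gene g in cell i is `depth_i * pi_g` (a log-depth
#'   offset model with the gene's pooled proportion), the per-gene dispersion
#'   is a method-of-moments estimate regularized by a running-median smooth
#'   over log mean expression, and residuals are clipped at plus/minus the
#'   square root of the number of cells.
#' * `"log_cp10k"`: `log1p` of depth-normalized counts times 1e4.
#'
#' All-zero genes get residual 0 in every cell.
#'
#' A third scheme, `"cp10k"`, returns linearly depth-normalized counts
#' (times 1e4, no log): combined with a log transform after donor averaging
#' it keeps multiplicative genotype effects on their natural log scale,
#' which is the configuration used when planted effect sizes are to be
#' recovered numerically.
#'
#' @param counts Cell-by-gene count matrix (dense or sparse, nonnegative
#'   integers).
#' @param method Normalization scheme.
#' @return Dense cell-by-gene matrix of normalized values.
#' @export
normalize_cells <- function(counts,
                            method = c("pearson_nb", "log_cp10k", "cp10k")) {
  method <- match.arg(method)
  X <- as.matrix(counts)
  if (any(X < 0)) stop("counts must be nonnegative")
  depth <- rowSums(X)
  if (method %in% c("log_cp10k", "cp10k")) {
    sf <- ifelse(depth > 0, 1e4 / depth, 0)
    return(if (method == "cp10k") X * sf else log1p(X * sf))
  }
  n <- nrow(X)
  tot <- sum(depth)
  pi_g <- colSums(X) / ifelse(tot > 0, tot, 1)
  MU <- outer(depth, pi_g)                      # expected counts
  gmean <- colMeans(X)
  nz <- gmean > 0
  # method-of-moments dispersion a in Var = mu + a mu^2, then running-median
  # regularization over log mean expression
  a_raw <- rep(0, ncol(X))
  if (any(nz)) {
    num <- colSums((X - MU)^2 - MU)
    den <- colSums(MU^2)
    a_raw <- ifelse(den > 0, pmax(num / pmax(den, 1e-12), 0), 0)
    ord <- order(log(gmean[nz]))
    sm <- stats::runmed(a_raw[nz][ord], k = min(31L, 2 * (sum(nz) %/% 2) - 1L))
    a_reg <- a_raw
    a_reg[nz][ord] <- sm
    a_raw <- pmax(a_reg, 0)
  }
  V <- MU + sweep(MU^2, 2, a_raw, "*")
  R <- ifelse(V > 0, (X - MU) / sqrt(V), 0)
  clip <- sqrt(n)
  R[R > clip] <- clip
  R[R < -clip] <- -clip
  R[, !nz] <- 0
  dimnames(R) <- dimnames(X)
  R
}

#' Aggregate normalized cells to donor-level pseudobulk
#'
#' For one cell type: the donor value of a gene is the mean of the normalized
#' values over that donor's cells of the type. Donors with fewer than
#' `min_cells` cells of the type are dropped; genes with non-zero
#' pre-normalization expression in fewer than `min_donor_frac` of the
#' retained donors are dropped. The gene-detection filter is applied after
#' the donor filter, per cell type, so donor counts (and power) differ by
#' cell type.
#'
#' @param normed Cell-by-gene normalized matrix from [normalize_cells()].
#' @param counts Cell-by-gene raw counts (used for the detection filter and
#'   read totals).
#' @param cell_meta Data frame with `cell`, `donor`, `cell_type`; rows
#'   aligned with `normed`.
#' @param cell_type Cell type to aggregate.
#' @param min_cells Minimum cells per donor (default 2).
#' @param min_donor_frac Minimum fraction of retained donors in which a gene
#'   must be detected (default 0.10).
#' @param gene_whitelist Optional gene ids to restrict to (e.g.
#'   protein-coding genes).
#' @param transform Transform applied to the donor means after averaging:
#'   `"none"` (default) or `"log1p"` (pairs with `method = "cp10k"` in
#'   [normalize_cells()] to put donor means on the log scale).
#' @return Object of class `"pseudobulk"` with `expr` (donor-by-gene matrix),
#'   `cell_type`, `n_cells` and `total_reads` per donor.
#' @export
aggregate_to_donor <- function(normed, counts, cell_meta, cell_type,
                               min_cells = 2L, min_donor_frac = 0.10,
                               gene_whitelist = NULL,
                               transform = c("none", "log1p")) {
  transform <- match.arg(transform)
  sel <- cell_meta$cell_type == cell_type
  if (!any(sel)) stop("no cells of type ", cell_type)
  normed <- normed[sel, , drop = FALSE]
  counts <- as.matrix(counts)[sel, , drop = FALSE]
  donor <- cell_meta$donor[sel]
  tab <- table(donor)
  keep_donors <- names(tab)[tab >= min_cells]
  if (!length(keep_donors))
    stop("no donor passes the ", min_cells, "-cell filter for ", cell_type)
  keep <- donor %in% keep_donors
  normed <- normed[keep, , drop = FALSE]
  counts <- counts[keep, , drop = FALSE]
  donor <- donor[keep]

  fd <- factor(donor, levels = sort(unique(donor)))
  M <- rowsum(normed, fd) / as.vector(table(fd))
  if (transform == "log1p") M <- log1p(M)
  detected <- rowsum((counts > 0) * 1, fd) > 0
  frac <- colMeans(detected)
  keep_genes <- frac >= min_donor_frac
  if (!is.null(gene_whitelist))
    keep_genes <- keep_genes & colnames(M) %in% gene_whitelist
  structure(list(expr = M[, keep_genes, drop = FALSE],
                 cell_type = cell_type,
                 n_cells = as.vector(table(fd)),
                 total_reads = as.vector(rowsum(rowSums(counts), fd)),
                 donors = levels(fd)),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("pseudobulk [%s]: %d donors x %d genes (median %d cells/donor)\n",
              x$cell_type, nrow(x$expr), ncol(x$expr),
              as.integer(stats::median(x$n_cells))))
  invisible(x)
}

#' Restrict a pseudobulk matrix to genotyped donors
#'
#' Inner join on donor ids; donors without genotypes are excluded with a
#' warning.
#'
#' @param pb A `pseudobulk` object.
#' @param geno A `genotype_table`.
#' @return The `pseudobulk` restricted to shared donors.
#' @export
align_to_genotypes <- function(pb, geno) {
  shared <- intersect(pb$donors, geno$donors$donor)
  dropped <- setdiff(pb$donors, shared)
  if (length(dropped))
    warning(length(dropped), " pseudobulk donor(s) without genotypes dropped")
  idx <- match(shared, pb$donors)
  pb$expr <- pb$expr[idx, , drop = FALSE]
  pb$n_cells <- pb$n_cells[idx]
  pb$total_reads <- pb$total_reads[idx]
  pb$donors <- shared
  pb
}
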