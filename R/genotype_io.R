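# Genotype container, VCF IO, QC filters and kinship.

#' Construct a genotype table
#'
#' Container for donor-by-SNP imputed dosages with per-call posterior
#' probabilities and per-SNP metadata. Coordinates are 1-based inclusive,
#' matching VCF.
#'
#' @param dosage Donor-by-SNP numeric matrix in \[0,2\], `NA` allowed.
#' @param call_posterior Donor-by-SNP matrix in \[0,1\] (probability of the
#'   most likely genotype call).
#' @param snps Data frame with columns id, chrom, pos, ref, alt, r2.
#' @param donors Data frame with at least a `donor` column, or a character
#'   vector of donor ids.
#' @return Object of class `"genotype_table"`.
#' @export
genotype_table <- function(dosage, call_posterior, snps, donors) {
  if (is.character(donors))
    donors <- data.frame(donor = donors, stringsAsFactors = FALSE)
  stopifnot(nrow(dosage) == nrow(donors), ncol(dosage) == nrow(snps))
  if (anyDuplicated(snps$id)) stop("duplicate SNP ids")
  if (any(snps$pos <= 0)) stop("positions must be strictly positive")
  structure(list(dosage = dosage, call_posterior = call_posterior,
                 snps = snps, donors = donors), class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d donors x %d SNPs (%.1f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Write a genotype table as simplified VCF v4.2
#'
#' Emits GT (hard call from rounded dosage), DS (dosage) and GP (genotype
#' posterior spread over the called class) per sample, with the imputation
#' quality in the `R2` INFO field.
#'
#' @param g A `genotype_table`.
#' @param path Output path (plain-text `.vcf`).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation R-squared\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype posterior\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$donors$donor), collapse = "\t")),
             con)
  gt_str <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g$dosage))) {
    ds <- g$dosage[, j]
    gp <- g$call_posterior[, j]
    hard <- pmin(pmax(round(ds), 0), 2)
    rest <- (1 - gp) / 2
    field <- ifelse(is.na(ds), "./.:.:.",
                    sprintf("%s:%.3f:%s", gt_str[hard + 1L], ds,
                            vapply(seq_along(ds), function(i) {
                              p <- rep(rest[i], 3)
                              p[hard[i] + 1L] <- gp[i]
                              sprintf("%.3f,%.3f,%.3f", p[1], p[2], p[3])
                            }, "")))
    writeLines(paste(c(g$snps$chrom[j], g$snps$pos[j], g$snps$id[j],
                       g$snps$ref[j], g$snps$alt[j], ".", "PASS",
                       sprintf("R2=%.4f", g$snps$r2[j]), "GT:DS:GP", field),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF into a genotype table
#'
#' Parses VCF v4.2 via `vcfR`. Dosage comes from the DS FORMAT field when
#' present, otherwise from the alt-allele count of GT. The per-call posterior
#' comes from the maximum GP entry when present, otherwise 1. Multi-allelic
#' sites are skipped with a warning. The imputation quality field name is
#' configurable to cover real-data dialects (R2, INFO, DR2).
#'
#' @param path VCF path.
#' @param r2_field INFO tag carrying the imputation R-squared.
#' @return A `genotype_table`.
#' @export
read_vcf <- function(path, r2_field = "R2") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  if (all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- matrix(vapply(gt, function(s) {
      if (is.na(s) || s %in% c("./.", ".|.")) return(NA_real_)
      sum(as.integer(strsplit(s, "[/|]")[[1]]))
    }, 0), nrow(gt), ncol(gt), dimnames = dimnames(gt))
  }
  gp <- vcfR::extract.gt(v, element = "GP")
  post <- if (all(is.na(gp))) {
    matrix(1, nrow(ds), ncol(ds), dimnames = dimnames(ds))
  } else {
    # posterior of the called genotype: GP entry at the hard-call index
    hard <- pmin(pmax(round(ds), 0), 2)
    p <- vapply(seq_along(gp), function(i) {
      if (is.na(gp[i]) || is.na(hard[i])) return(NA_real_)
      as.numeric(strsplit(gp[i], ",")[[1]])[hard[i] + 1L]
    }, 0)
    matrix(p, nrow(gp), ncol(gp), dimnames = dimnames(gp))
  }
  post[is.na(post)] <- 1
  r2 <- suppressWarnings(as.numeric(vcfR::extract.info(v, r2_field)))
  r2[is.na(r2)] <- 1
  snps <- data.frame(id = fix$ID, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                     r2 = r2, stringsAsFactors = FALSE)
  genotype_table(dosage = t(ds), call_posterior = t(post), snps = snps,
                 donors = colnames(ds))
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of the genotype counts against
#' the expectation from the observed allele frequencies.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return Two-sided p-value, or `NA` when the total is zero.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (is.na(n) || n == 0) return(NA_real_)
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  e <- n * c(p^2, 2 * p * q, q^2)
  o <- c(n_AA, n_Aa, n_aa)
  if (any(e == 0)) return(1)  # monomorphic: trivially in equilibrium
  chi2 <- sum((o - e)^2 / e)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Minor allele frequency from dosages
#'
#' @param dosages Numeric dosages in \[0,2\], `NA` ignored.
#' @return `min(f, 1-f)` with `f = mean(dosage)/2`, or `NA` if all missing.
#' @export
minor_allele_frequency <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) return(NA_real_)
  f <- mean(d) / 2
  min(f, 1 - f)
}

#' Apply genotype quality control
#'
#' Sets individual calls with posterior probability below `posterior_min`
#' to missing, then removes SNPs with imputation R-squared below `r2_min`
#' or a Hardy-Weinberg chi-square p-value below `hwe_alpha` (computed on
#' hard calls, i.e. dosages rounded to the nearest integer). Defaults are
#' the array-imputation QC convention: posterior 0.4, R-squared 0.6,
#' HWE 1e-4. Idempotent.
#'
#' @param g A `genotype_table`.
#' @param posterior_min Minimum per-call posterior probability.
#' @param r2_min Minimum imputation R-squared.
#' @param hwe_alpha HWE p-value cutoff.
#' @return The filtered `genotype_table`.
#' @export
apply_genotype_qc <- function(g, posterior_min = 0.4, r2_min = 0.6,
                              hwe_alpha = 1e-4) {
  stopifnot(posterior_min > 0, posterior_min < 1, r2_min > 0, r2_min < 1,
            hwe_alpha > 0, hwe_alpha < 1)
  dos <- g$dosage
  dos[g$call_posterior < posterior_min] <- NA_real_
  hwe_p <- vapply(seq_len(ncol(dos)), function(j) {
    h <- round(dos[, j])
    hwe_test(sum(h == 0, na.rm = TRUE), sum(h == 1, na.rm = TRUE),
             sum(h == 2, na.rm = TRUE))
  }, 0)
  keep <- g$snps$r2 >= r2_min & (is.na(hwe_p) | hwe_p >= hwe_alpha)
  if (!any(keep)) warning("no SNPs pass QC")
  out <- genotype_table(dosage = dos[, keep, drop = FALSE],
                        call_posterior = g$call_posterior[, keep,
                                                          drop = FALSE],
                        snps = g$snps[keep, , drop = FALSE],
                        donors = g$donors)
  out$snps$hwe_p <- hwe_p[keep]
  out
}

#' SNP summary table
#'
#' @param g A `genotype_table`.
#' @return Data frame (id, chrom, pos, maf, hwe_p, r2).
#' @export
snp_summary <- function(g) {
  maf <- apply(g$dosage, 2, minor_allele_frequency)
  hwe <- g$snps$hwe_p
  if (is.null(hwe))
    hwe <- vapply(seq_len(ncol(g$dosage)), function(j) {
      h <- round(g$dosage[, j])
      hwe_test(sum(h == 0, na.rm = TRUE), sum(h == 1, na.rm = TRUE),
               sum(h == 2, na.rm = TRUE))
    }, 0)
  data.frame(id = g$snps$id, chrom = g$snps$chrom, pos = g$snps$pos,
             maf = unname(maf), hwe_p = hwe, r2 = g$snps$r2,
             stringsAsFactors = FALSE)
}

#' Standardized genetic relationship (kinship) matrix
#'
#' `K = Z Z' / m` with `Z` the column-standardized dosage matrix (missing
#' entries mean-imputed for this computation only) over the `m` SNPs with
#' non-zero variance. Symmetric and positive semi-definite by construction;
#' under the standardized construction the diagonal mean is about 1.
#'
#' @param g A `genotype_table`.
#' @return Donor-by-donor matrix with donor dimnames.
#' @export
compute_kinship <- function(g) {
  if (nrow(g$dosage) < 2L || ncol(g$dosage) < 2L)
    stop("need at least 2 donors and 2 SNPs")
  X <- g$dosage
  for (j in seq_len(ncol(X))) {
    m <- is.na(X[, j])
    if (any(m)) X[m, j] <- mean(X[, j], na.rm = TRUE)
  }
  sdv <- apply(X, 2, stats::sd)
  keep <- !is.na(sdv) & sdv > 0
  X <- X[, keep, drop = FALSE]
  Z <- scale(X)
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(g$donors$donor, g$donors$donor)
  K
}
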