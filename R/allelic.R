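# Allele-specific expression and transcript-usage QTL tests.

#' Choose the most informative SNP per gene
#'
#' When several coding SNPs could report on a gene, the one retained is the
#' SNP with the maximum number of donors that are heterozygous and have at
#' least one UMI covering the SNP; ties break to the smallest genomic
#' position.
#'
#' @param candidates Data frame of candidate SNPs (snp, pos).
#' @param allele_table Allele-count rows for the gene (donor, snp, ref_count,
#'   alt_count), heterozygous donors only.
#' @return The chosen SNP id, or `NULL` when no candidate has an
#'   informative donor.
#' @export
select_informative_snp <- function(candidates, allele_table) {
  info <- vapply(candidates$snp, function(s) {
    rows <- allele_table[allele_table$snp == s, , drop = FALSE]
    length(unique(rows$donor[rows$ref_count + rows$alt_count >= 1]))
  }, 0L)
  if (!any(info > 0L)) {
    # no informative donor for any candidate SNP
    return(NULL)
  }
  best <- which(info == max(info))
  if (length(best) > 1L) best <- best[which.min(candidates$pos[best])]
  candidates$snp[best]
}

#' Beta-binomial test for allele-specific expression
#'
#' Pools each heterozygous donor's UMIs and fits an intercept-only
#' beta-binomial regression of the alternate-allele count on the total,
#' `logit(mu) = b0`, with a single overdispersion shared across donors.
#' Deviation of the mean allele fraction from 0.5 is equivalent to the
#' intercept differing from 0; the p-value is the two-sided Wald test on
#' `b0`. On optimizer failure the binomial GLM estimate is reported with a
#' fallback flag.
#'
#' @param alt Per-donor alternate-allele UMI counts.
#' @param total Per-donor total UMI counts.
#' @param min_donors Minimum informative donors (default 2).
#' @param min_total Minimum pooled UMIs (default 5).
#' @return A `betabin_fit`, or `NULL` when the thresholds are not met.
#' @export
betabin_ase_test <- function(alt, total, min_donors = 2L, min_total = 5L) {
  keep <- total > 0
  if (sum(keep) < min_donors || sum(total) < min_total) {
    # insufficient informative donors or UMIs
    return(NULL)
  }
  betabin_fit(alt[keep], total[keep])
}

#' FDR significance flags for ASE tests
#'
#' Benjamini-Hochberg adjustment with two flag levels: `flag1` at FDR < 0.01
#' and `flag2` at FDR < 0.0001 (so `flag2` implies `flag1`).
#'
#' @param p Wald p-values.
#' @param thresholds Two FDR cutoffs (default `c(0.01, 1e-4)`).
#' @return Data frame (p, fdr, flag1, flag2).
#' @export
ase_fdr_flags <- function(p, thresholds = c(0.01, 1e-4)) {
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, fdr = fdr, flag1 = fdr < thresholds[1],
             flag2 = fdr < thresholds[2])
}

#' Beta-binomial transcript-usage QTL test
#'
#' Aggregates two-isoform transcript-compatible counts to donor level and
#' fits `logit(psi) = b0 + b1 * dosage` by beta-binomial maximum likelihood
#' on (long, long + short) counts, testing for a genetic effect on the
#' long-isoform proportion with a Wald test on `b1`. Also reports the pooled
#' long-isoform share per genotype group.
#'
#' @param table Data frame with columns donor, long_count, short_count,
#'   dosage (per-cell or per-donor rows; aggregated by donor internally).
#' @return List with `fit` (a `betabin_fit`), `b1`, `p`, and
#'   `group_proportions` (pooled long share per dosage 0/1/2), or `NULL`
#'   when fewer than two genotype groups are present.
#' @export
betabin_usage_test <- function(table) {
  agg <- stats::aggregate(cbind(long_count, short_count) ~ donor + dosage,
                          data = table, FUN = sum)
  agg <- agg[agg$long_count + agg$short_count > 0, , drop = FALSE]
  if (length(unique(agg$dosage)) < 2L) {
    # single genotype group
    return(NULL)
  }
  X <- cbind(b0 = 1, b1 = agg$dosage)
  fit <- betabin_fit(agg$long_count, agg$long_count + agg$short_count, X)
  gp <- vapply(0:2, function(d) {
    rows <- agg$dosage == d
    if (!any(rows)) return(NA_real_)
    sum(agg$long_count[rows]) /
      sum(agg$long_count[rows] + agg$short_count[rows])
  }, 0)
  names(gp) <- c("dos0", "dos1", "dos2")
  list(fit = fit, b1 = unname(fit$coefficients["b1"]),
       p = unname(fit$wald_p["b1"]), group_proportions = gp)
}

#' LD between two dosage vectors
#'
#' Squared Pearson correlation of dosages over donors with both calls;
#' used to link ASE SNPs to GWAS variants.
#'
#' @param d1,d2 Dosage vectors.
#' @return r-squared in \[0,1\].
#' @export
dosage_ld_r2 <- function(d1, d2) {
  ok <- !is.na(d1) & !is.na(d2)
  if (sum(ok) < 2L) return(NA_real_)
  stats::cor(d1[ok], d2[ok])^2
}
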