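# Shared fixtures, built in code at test time.

# small cohort config; group sizes scale with n_donors
tiny_sim_config <- function(n_donors = 40L, ...) {
  args <- list(...)
  if (is.null(args$group_sizes)) {
    q <- n_donors %/% 4L
    args$group_sizes <- c(MS = n_donors - 3L * q, OIND = q, NIND = q,
                          IIH = q)
  }
  do.call(sim_config, c(list(n_donors = n_donors), args))
}

# hand-built genotype table for oracle checks
toy_genotypes <- function(n_donors = 5L, n_snps = 10L, seed = 11L) {
  set.seed(seed)
  dos <- matrix(rbinom(n_donors * n_snps, 2, 0.4), n_donors, n_snps,
                dimnames = list(sprintf("D%02d", seq_len(n_donors)),
                                sprintf("s%02d", seq_len(n_snps))))
  genotype_table(
    dosage = dos,
    call_posterior = matrix(1, n_donors, n_snps, dimnames = dimnames(dos)),
    snps = data.frame(id = colnames(dos), chrom = "1",
                      pos = seq_len(n_snps) * 1000L, ref = "A", alt = "G",
                      r2 = 1, stringsAsFactors = FALSE),
    donors = rownames(dos))
}

# independent dense grid-search oracle for the intercept-only beta-binomial
# ML fit (mu, phi); returns the best grid point and its log-likelihood
betabin_grid_oracle <- function(k, n, b0_grid = seq(-2, 2, by = 0.002),
                                phi_grid = seq(1e-4, 0.3, by = 5e-4)) {
  best <- list(ll = -Inf)
  for (phi in phi_grid) {
    mu <- 1 / (1 + exp(-b0_grid))
    ll <- vapply(mu, function(m)
      sum(dbetabinom(k, n, m, phi, log = TRUE)), 0)
    i <- which.max(ll)
    if (ll[i] > best$ll)
      best <- list(ll = ll[i], b0 = b0_grid[i], phi = phi)
  }
  best
}

# exhaustive single-effect posterior over which of p SNPs is causal,
# with the prior effect variance fixed; independent of the IBSS code path
single_effect_posterior_oracle <- function(y, G, v0, sigma2) {
  X <- scale(G)
  y <- y - mean(y)
  d <- colSums(X^2)
  bhat <- drop(crossprod(X, y)) / d
  shat2 <- sigma2 / d
  lbf <- 0.5 * log(shat2 / (shat2 + v0)) +
    0.5 * bhat^2 / shat2 * (v0 / (v0 + shat2))
  w <- exp(lbf - max(lbf))
  w / sum(w)
}
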