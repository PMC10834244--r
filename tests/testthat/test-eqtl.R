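test_that("cis window selection is boundary-inclusive and matches a linear scan", {
  snps <- data.frame(id = sprintf("s%02d", 1:5), chrom = "1",
                     pos = c(899999L, 900000L, 950000L, 1120000L, 1120001L))
  win <- list(chrom = "1", start = 1000000L, end = 1020000L)
  sel <- cis_snps(win, snps, flank = 100000L)
  expect_identical(sel$id, c("s02", "s03", "s04"))  # boundaries included
  # brute-force oracle over a random map
  set.seed(30)
  snps2 <- data.frame(id = sprintf("r%02d", 1:50),
                      chrom = sample(c("1", "2"), 50, replace = TRUE),
                      pos = sample.int(2000000L, 50))
  sel2 <- cis_snps(win, snps2, flank = 100000L)
  brute <- snps2$id[vapply(seq_len(50), function(i) {
    snps2$chrom[i] == "1" && snps2$pos[i] >= 900000 &&
      snps2$pos[i] <= 1120000
  }, TRUE)]
  expect_identical(sel2$id, brute)
})

test_that("permutation p has the 1/(n+1) floor and is seed-reproducible", {
  set.seed(22)
  n <- 60
  g <- rbinom(n, 2, 0.4)
  y <- g * 2 + rnorm(n, 0, 0.5)      # overwhelming signal
  fit <- fit_null_lmm(y, diag(n), reads = rep(1, n))
  pr <- gene_level_permutation(y, cbind(g), fit, n_perm = 1000L, seed = 5L)
  expect_equal(pr$p_perm, 1 / 1001, tolerance = 1e-12)
  pr2 <- gene_level_permutation(y, cbind(g), fit, n_perm = 1000L, seed = 5L)
  expect_identical(pr$p_perm, pr2$p_perm)
})

test_that("with one cis SNP the permutation p approximates the nominal p", {
  set.seed(23)
  n <- 100
  g <- rbinom(n, 2, 0.4)
  y <- 0.22 * g + rnorm(n)
  fit <- fit_null_lmm(y, diag(n), reads = rep(1, n))
  pr <- gene_level_permutation(y, cbind(g), fit, n_perm = 2000L, seed = 9L)
  # the permutation null of the single z-statistic is the exact t
  # reference, which is also the nominal p; allow Monte-Carlo error
  z <- abs(pr$beta[1] / pr$se[1])
  p_t <- 2 * pt(-z, df = n - 2)
  expect_equal(pr$p_nominal[1], p_t, tolerance = 1e-12)
  expect_lt(abs(pr$p_perm - p_t),
            5 * sqrt(p_t * (1 - p_t) / 2000) + 2e-3)
})

test_that("Storey q-values obey closed forms and monotonicity", {
  expect_equal(storey_qvalues(rep(1, 10)), rep(1, 10))
  set.seed(24)
  p <- sort(runif(500))
  q <- storey_qvalues(p)
  expect_true(all(diff(q) >= -1e-12))
  pi0_hat <- min(1, sum(p > 0.5) / (0.5 * 500))
  expect_equal(max(q), min(1, pi0_hat * max(p)), tolerance = 1e-9)
  # uniform null: essentially nothing at q < 0.10 and pi0 near 1
  expect_lt(mean(q < 0.10), 0.01)
  expect_equal(pi0_hat, 1, tolerance = 0.1)
  # hand-checked small case: q_i = min_{p_j >= p_i} pi0 m p_j / rank_j
  p2 <- c(0.01, 0.2, 0.8, 0.9)
  pi0 <- sum(p2 > 0.5) / (0.5 * 4)
  expect_equal(storey_qvalues(p2),
               pmin(1, pi0 * 4 * pmin(p2 / rank(p2),
                                      rev(cummin(rev(p2 / rank(p2)))))),
               tolerance = 1e-12)
})

test_that("conditional FDR routes genes by reference evidence", {
  p <- c(0.001, 0.02, 0.5, 0.9, 0.004)
  # gene 5 absent from the reference -> storey branch
  ref <- c(1e-10, 1e-8, 0.9, 0.8, NA)
  out <- conditional_fdr(p, ref, alpha = 0.10, ref_threshold = 1e-4)
  expect_identical(out$method, c("cfdr", "cfdr", "storey", "storey",
                                 "storey"))
  # all reference p = 1: conditioned stratum empty, equals plain Storey
  out2 <- conditional_fdr(p, rep(1, 5), alpha = 0.10)
  expect_true(all(out2$method == "storey"))
  expect_equal(out2$q, storey_qvalues(p), tolerance = 1e-12)
})

test_that("conditioning on an informative reference increases discoveries", {
  set.seed(26)
  m <- 400
  is_true <- rep(c(TRUE, FALSE), c(80, m - 80))
  p <- ifelse(is_true, rbeta(m, 0.15, 1), runif(m))
  # reference flags most true genes
  ref <- ifelse(is_true & runif(m) < 0.9, 1e-8, runif(m))
  cf <- conditional_fdr(p, ref, alpha = 0.10, ref_threshold = 1e-4)
  plain_q <- storey_qvalues(p)
  expect_gte(sum(cf$significant), sum(plain_q < 0.10))
  fdp <- sum(cf$significant & !is_true) / max(1, sum(cf$significant))
  expect_lte(fdp, 0.15)
})

test_that("replication follows the sign-and-nominal-significance rule", {
  a <- data.frame(gene = c("g1", "g2", "g3"), snp = c("s1", "s2", "s3"),
                  beta = c(1, 1, -1))
  b <- data.frame(gene = c("g1", "g2", "g3"), snp = c("s1", "s2", "s3"),
                  beta = c(0.5, 0.5, 0.7), p = c(0.04, 0.06, 1e-6))
  out <- replication_concordance(a, b)
  # same sign p=0.04 yes; same sign p=0.06 no; opposite sign p=1e-6 no
  expect_equal(out$joined$replicated, c(TRUE, FALSE, FALSE))
  expect_equal(out$rate, 1 / 3)
  # allele harmonization flips the external sign
  a2 <- cbind(a[1, ], ref = "A", alt = "G")
  b2 <- cbind(b[1, ], ref = "G", alt = "A")
  b2$beta <- -0.5
  out2 <- replication_concordance(a2, b2)
  expect_true(out2$joined$replicated)
  expect_true(is.na(replication_concordance(a, b[0, ])$rate))
})

test_that("the scan drives a planted cis-eQTL to the top of its gene", {
  cfg <- tiny_sim_config(n_donors = 80L, n_snps = 100L, n_ld_blocks = 10L,
                         n_genes = 20L, cells_per_donor_range = c(40L, 40L),
                         maf_range = c(0.3, 0.3),
                         planted_eqtls = list(list(gene = 10L, snp = 50L,
                                                   beta = 0.8)),
                         seed = 33L)
  geno <- simulate_genotypes(cfg)
  ex <- simulate_expression(cfg, geno)
  normed <- normalize_cells(ex$counts, method = "cp10k")
  pb <- aggregate_to_donor(normed, ex$counts, ex$cell_meta, "T_CD4",
                           transform = "log1p")
  pb <- align_to_genotypes(pb, geno)
  K <- compute_kinship(geno)
  scan <- map_eqtls(pb, geno, ex$genes, K, n_perm = 200L, seed = 2L)
  hit <- scan[scan$gene == ex$genes$gene[10], ]
  expect_lt(hit$p_perm, 0.05)
  # the best SNP tags the planted block
  planted_block <- geno$snps$block[50]
  expect_equal(geno$snps$block[match(hit$snp, geno$snps$id)], planted_block)
})
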