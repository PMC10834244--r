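test_that("donor presence equals a brute-force summation oracle", {
  set.seed(61)
  meta <- data.frame(cell = sprintf("c%02d", 1:12),
                     donor = rep(c("d1", "d2", "d3"), each = 4),
                     group = rep(c("MS", "IIH", "MS"), each = 4))
  vm <- matrix(rpois(12 * 3, 0.3), 12, 3,
               dimnames = list(meta$cell, c("v1", "v2", "v3")))
  dp <- donor_presence(vm, meta)
  for (d in c("d1", "d2", "d3")) for (v in c("v1", "v2", "v3")) {
    brute <- sum(vm[meta$donor == d, v]) >= 1
    expect_identical(unname(dp$presence[d, v]), brute)
  }
  # all-zero matrix: nothing present, nothing testable
  dp0 <- donor_presence(matrix(0L, 12, 2,
                               dimnames = list(meta$cell, c("a", "b"))),
                        meta)
  expect_false(any(dp0$presence))
  expect_false(any(dp0$testable))
})

test_that("the 5% prevalence filter keys on either cohort", {
  # 33 MS donors (2 carriers = 6.1%) and 20 controls (0 carriers)
  nd <- 53
  meta <- data.frame(cell = seq_len(nd), donor = sprintf("d%02d", 1:nd),
                     group = rep(c("MS", "NIND"), c(33, 20)))
  vm <- matrix(0L, nd, 2, dimnames = list(NULL, c("hit", "zero")))
  vm[1:2, "hit"] <- 1L
  dp <- donor_presence(vm, meta)
  expect_true(dp$testable[["hit"]])     # 6.1% in MS cohort
  expect_false(dp$testable[["zero"]])
  # presence is monotone in added UMIs
  vm2 <- vm
  vm2[3, "hit"] <- 5L
  dp2 <- donor_presence(vm2, meta)
  expect_true(all(dp2$presence[dp$presence]))
})

test_that("prevalence testing is invariant to virus column order", {
  set.seed(62)
  nd <- 60
  meta <- data.frame(cell = seq_len(nd), donor = sprintf("d%02d", 1:nd),
                     group = rep(c("MS", "IIH"), each = 30))
  vm <- matrix(rbinom(nd * 3, 1, 0.3), nd, 3,
               dimnames = list(NULL, c("v1", "v2", "v3")))
  dp <- donor_presence(vm, meta)
  tot <- rexp(nd, 1e-4)
  r1 <- donor_prevalence_test(dp$presence, dp$donor_group == "MS", tot)
  dpr <- donor_presence(vm[, c(3, 1, 2)], meta)
  r2 <- donor_prevalence_test(dpr$presence, dpr$donor_group == "MS", tot)
  expect_equal(r1[order(r1$virus), c("coef", "p")],
               r2[order(r2$virus), c("coef", "p")], ignore_attr = TRUE)
})

test_that("a planted MS log-odds shift is recovered by the logistic model", {
  set.seed(63)
  nd <- 400
  is_ms <- rep(c(1, 0), each = nd / 2)
  tot <- rexp(nd, 1e-4)
  pres <- rbinom(nd, 1, plogis(-2 + 1.5 * is_ms))
  presence <- matrix(pres == 1, nd, 1, dimnames = list(NULL, "v"))
  res <- donor_prevalence_test(presence, is_ms, tot)
  expect_equal(res$coef, 1.5, tolerance = 0.5)
  expect_false(res$separated)
})

test_that("null presence keeps the is_MS coefficient near zero", {
  set.seed(64)
  nd <- 200
  is_ms <- rep(c(1, 0), each = 100)
  presence <- matrix(rbinom(nd, 1, 0.3) == 1, nd, 1,
                     dimnames = list(NULL, "v"))
  res <- donor_prevalence_test(presence, is_ms, rexp(nd, 1e-4))
  expect_gt(res$p, 0.001)
  # untestable when everyone is a carrier
  res_all <- donor_prevalence_test(
    matrix(TRUE, nd, 1, dimnames = list(NULL, "v")), is_ms, rexp(nd, 1e-4))
  expect_null(res_all)
})

test_that("cell-level proportions feed the linear model with donor covariates", {
  set.seed(65)
  nd <- 40; cells_per <- 30
  meta <- data.frame(cell = seq_len(nd * cells_per),
                     donor = rep(sprintf("d%02d", 1:nd), each = cells_per),
                     group = rep(rep(c("MS", "IIH"), each = nd / 2),
                                 each = cells_per),
                     total_umis = rpois(nd * cells_per, 3000))
  # planted +0.1 proportion shift in MS cells
  p_cell <- ifelse(meta$group == "MS", 0.15, 0.05)
  vm <- matrix(rbinom(nd * cells_per, 1, p_cell), ncol = 1,
               dimnames = list(NULL, "v"))
  res <- cell_level_test(vm, meta)
  expect_equal(res$coef, 0.1, tolerance = 0.05)
  expect_lt(res$p, 0.05)
  expect_true(all(res$donor_table$proportion >= 0 &
                    res$donor_table$proportion <= 1))
  expect_equal(res$n_donors - 4, nd - 4)   # residual df = donors - 4
  # degenerate all-zero case
  res0 <- cell_level_test(matrix(0L, nd * cells_per, 1), meta)
  expect_true(res0$degenerate)
  expect_equal(res0$coef, 0)
  expect_equal(res0$p, 1)
})

test_that("the simulated viral matrix carries the planted group effect", {
  cfg <- tiny_sim_config(n_donors = 80L, n_snps = 20L, n_ld_blocks = 4L,
                         n_genes = 10L, cells_per_donor_range = c(50L, 50L),
                         viral_effect = 2, viral_affected = 1L,
                         viral_base_rate = 0.02, seed = 71L)
  geno <- simulate_genotypes(cfg)
  ex <- simulate_expression(cfg, geno)
  fv <- simulate_factors_and_viral(cfg, ex$cell_meta, geno$donors)
  vm <- as.matrix(fv$virus)
  is_ms <- fv$cell_meta$group == "MS"
  rate_ms <- mean(vm[is_ms, 1] > 0)
  rate_other <- mean(vm[!is_ms, 1] > 0)
  expect_gt(rate_ms, rate_other * 2)
  # unaffected viruses stay at the base rate in both cohorts
  expect_equal(mean(vm[is_ms, 2] > 0), mean(vm[!is_ms, 2] > 0),
               tolerance = 0.02)
})
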