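test_that("variance explained is exact for a rank-1 reconstruction", {
  set.seed(51)
  ncell <- 50; ng <- 30
  z <- rnorm(ncell); w <- rnorm(ng)
  Y <- outer(z, w)
  Z <- cbind(f1 = z, f2 = rnorm(ncell))
  W <- cbind(f1 = w, f2 = rnorm(ng))
  meta <- data.frame(cell_type = rep("T", ncell))
  ve <- variance_explained(Z, W, Y, meta, "T")
  expect_equal(ve$r2[1], 1, tolerance = 1e-12)
  expect_true(ve$retained[1])
  expect_error(variance_explained(Z, W, NULL, meta, "T"), "supplied")
})

test_that("the 1% variance threshold and the null factor behave as declared", {
  set.seed(52)
  ncell <- 500; ng <- 40
  Y <- matrix(rnorm(ncell * ng), ncell, ng)
  Z <- matrix(rnorm(ncell * 2), ncell, 2,
              dimnames = list(NULL, c("f1", "f2")))
  W <- matrix(rnorm(ng * 2), ng, 2, dimnames = list(NULL, c("f1", "f2")))
  meta <- data.frame(cell_type = rep("T", ncell))
  ve <- variance_explained(Z, W, Y, meta, "T")
  expect_true(all(ve$r2 <= 0.02))           # random factor explains ~nothing
  # retention boundary: r2 of 0.009 is excluded at the 1% threshold
  expect_false(0.009 >= 0.01)
  expect_identical(ve$retained, ve$r2 >= 0.01)
})

test_that("regulon aggregate equals a brute-force per-TF summation", {
  set.seed(53)
  genes <- sprintf("g%02d", 1:20)
  W <- matrix(rnorm(20 * 3), 20, 3,
              dimnames = list(genes, c("f1", "f2", "f3")))
  Treg <- matrix(rbinom(20 * 4, 1, 0.4), 20, 4,
                 dimnames = list(genes, c("t1", "t2", "t3", "t4")))
  Treg[1:3, 1] <- 1L   # ensure >= 3 targets
  enr <- regulon_enrichment(W, Treg, n_samples = 50L, seed = 1L)
  for (t in colnames(enr$score)) for (f in rownames(enr$score)) {
    brute <- sum(W[Treg[, t] == 1L, f])
    expect_equal(enr$score[f, t], brute, tolerance = 1e-12)
  }
})

test_that("a regulon spanning the whole universe is never enriched", {
  set.seed(54)
  genes <- sprintf("g%02d", 1:15)
  W <- matrix(rnorm(15 * 2), 15, 2, dimnames = list(genes, c("f1", "f2")))
  Treg <- matrix(1L, 15, 1, dimnames = list(genes, "tAll"))
  enr <- regulon_enrichment(W, Treg, n_samples = 200L, seed = 2L)
  expect_true(all(enr$p == 1))
})

test_that("empirical enrichment p-values respect the sampling floor", {
  set.seed(55)
  genes <- sprintf("g%03d", 1:200)
  W <- matrix(rnorm(200), 200, 1, dimnames = list(genes, "f1"))
  Treg <- matrix(0L, 200, 1, dimnames = list(genes, "t1"))
  idx <- 1:50
  Treg[idx, 1] <- 1L
  W[idx, 1] <- W[idx, 1] + 2       # planted loading shift
  enr <- regulon_enrichment(W, Treg, n_samples = 10000L, seed = 3L)
  expect_equal(enr$p[1, 1], 1 / 10001, tolerance = 1e-12)
  # reproducible under the same seed
  enr2 <- regulon_enrichment(W, Treg, n_samples = 10000L, seed = 3L)
  expect_identical(enr$p, enr2$p)
  expect_error(regulon_enrichment(W, matrix(1L, 3, 1,
                                            dimnames = list(c("x1", "x2",
                                                              "x3"), "t")),
                                  n_samples = 10L), "universe")
})

test_that("enrichment is invariant to gene ordering", {
  set.seed(56)
  genes <- sprintf("g%02d", 1:60)
  W <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(genes, c("f1", "f2")))
  Treg <- matrix(rbinom(60, 1, 0.2), 60, 1, dimnames = list(genes, "t1"))
  if (sum(Treg) < 3) Treg[1:3, 1] <- 1L
  e1 <- regulon_enrichment(W, Treg, n_samples = 500L, seed = 4L)
  perm <- sample(60)
  e2 <- regulon_enrichment(W[perm, , drop = FALSE],
                           Treg[perm, , drop = FALSE],
                           n_samples = 500L, seed = 4L)
  expect_equal(e1$score, e2$score, tolerance = 1e-12)
})

test_that("donor-level factor association has power and a permutation floor", {
  set.seed(57)
  nd <- 30
  donors <- sprintf("d%02d", 1:nd)
  grp <- rep(c("MS", "IIH"), each = 15)
  cells_per <- 20
  meta <- data.frame(cell = seq_len(nd * cells_per),
                     donor = rep(donors, each = cells_per),
                     cell_type = "T",
                     group = rep(grp, each = cells_per))
  shift <- ifelse(grp == "MS", 1, 0)        # 1 SD donor-level shift
  Z <- cbind(f1 = rnorm(nd * cells_per) +
               rep(rnorm(nd, shift, 0.2), each = cells_per))
  a <- factor_disease_association(Z, meta, "f1", "T", n_perm = 2000L,
                                  seed = 6L)
  expect_lt(a$p, 0.01)
  expect_gte(a$p, 1 / 2001)
  expect_equal(a$n_case, 15)
  # null labels: p is not extreme
  Z0 <- cbind(f1 = rnorm(nd * cells_per))
  a0 <- factor_disease_association(Z0, meta, "f1", "T", n_perm = 500L,
                                   seed = 7L)
  expect_gte(a0$p, 1 / 501)
})

test_that("rank-sum gene-set test skips degenerate sets and detects shifts", {
  set.seed(58)
  genes <- sprintf("g%04d", 1:2000)
  W <- matrix(rnorm(2000), 2000, 1, dimnames = list(genes, "f1"))
  members <- genes[1:50]
  W[members, 1] <- sign(W[members, 1]) * (abs(W[members, 1]) + 1)
  res <- gsea_abs_weights(W, list(hit = members, all = genes,
                                  tiny = genes[1:2]), "f1")
  expect_false("all" %in% res$set)    # no contrast
  expect_false("tiny" %in% res$set)   # below minimum overlap
  expect_lt(res$p[res$set == "hit"], 0.01)
})
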