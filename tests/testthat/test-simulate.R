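test_that("identical config and seed give bit-identical datasets", {
  cfg <- tiny_sim_config(n_donors = 24L, n_snps = 60L, n_ld_blocks = 10L,
                         n_genes = 20L, cells_per_donor_range = c(5L, 15L),
                         planted_ase = list(list(snp = 10L, mean_af = 0.7,
                                                 phi = 0.02)),
                         planted_usage_qtl = list(
                           list(gene = 5L, snp = 20L,
                                psi = c(0.9, 0.8, 0.7))),
                         seed = 77L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$genotypes$dosage, d2$genotypes$dosage)
  expect_identical(as.matrix(d1$counts), as.matrix(d2$counts))
  expect_identical(d1$allele_counts, d2$allele_counts)
  expect_identical(d1$isoform_counts, d2$isoform_counts)
  expect_identical(d1$factors$W, d2$factors$W)
  expect_identical(as.matrix(d1$factors$virus), as.matrix(d2$factors$virus))
})

test_that("LD blocks control between-SNP dosage correlation", {
  base <- list(n_donors = 500L, n_snps = 40L, n_ld_blocks = 4L,
               n_genes = 5L, n_populations = 1L,
               maf_range = c(0.2, 0.5), seed = 13L)
  g0 <- simulate_genotypes(do.call(tiny_sim_config, c(base, ld_rho = 0)))
  c0 <- cor(g0$dosage)
  expect_lt(max(abs(c0[upper.tri(c0)])), 0.2)
  g9 <- simulate_genotypes(do.call(tiny_sim_config, c(base, ld_rho = 0.95)))
  blk <- g9$snps$block
  within <- abs(cor(g9$dosage)[outer(blk, blk, "==") &
                                 upper.tri(diag(length(blk)))])
  expect_gt(min(within), 0.7)
})

test_that("dosages are hard calls in 0..2 with frequencies near the target", {
  cfg <- tiny_sim_config(n_donors = 400L, n_snps = 50L, n_ld_blocks = 10L,
                         n_genes = 5L, maf_range = c(0.3, 0.3),
                         n_populations = 1L, seed = 21L)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$dosage %in% 0:2))
  f <- colMeans(g$dosage) / 2
  expect_equal(mean(f), 0.3, tolerance = 0.03)
})

test_that("a planted eQTL shows as a dosage slope on donor-mean log expression", {
  cfg <- tiny_sim_config(n_donors = 200L, n_snps = 40L, n_ld_blocks = 8L,
                         n_genes = 100L,
                         cells_per_donor_range = c(150L, 150L),
                         maf_range = c(0.3, 0.3),
                         planted_eqtls = list(list(gene = 10L, snp = 20L,
                                                   beta = 0.5)),
                         seed = 42L)
  geno <- simulate_genotypes(cfg)
  ex <- simulate_expression(cfg, geno)
  sel <- ex$cell_meta$cell_type == "T_CD4"
  cnt <- as.matrix(ex$counts)[sel, ]
  cp <- cnt[, ex$genes$gene[10]] / rowSums(cnt) * 1e4
  dm <- tapply(cp, ex$cell_meta$donor[sel], mean)
  dos <- geno$dosage[names(dm), 20]
  slope <- coef(lm(log1p(dm) ~ dos))[2]
  expect_equal(unname(slope), 0.5, tolerance = 0.15)
})

test_that("without planted effects donor means are uncorrelated with dosage", {
  cfg <- tiny_sim_config(n_donors = 100L, n_snps = 20L, n_ld_blocks = 4L,
                         n_genes = 10L, cells_per_donor_range = c(20L, 20L),
                         seed = 8L)
  geno <- simulate_genotypes(cfg)
  ex <- simulate_expression(cfg, geno)
  cnt <- as.matrix(ex$counts)
  dm <- rowsum(cnt[, 1], ex$cell_meta$donor)
  r <- cor(dm[geno$donors$donor, 1], geno$dosage[, 5])
  expect_lt(abs(r), 0.25)
})

test_that("allele counts cover heterozygotes only with the planted fraction", {
  cfg <- tiny_sim_config(n_donors = 200L, n_snps = 30L, n_ld_blocks = 6L,
                         n_genes = 10L,
                         planted_ase = list(list(snp = 15L, mean_af = 0.7,
                                                 phi = 0.02)),
                         n_ase_null = 2L, seed = 31L)
  geno <- simulate_genotypes(cfg)
  ac <- simulate_allele_counts(cfg, geno)
  snp_id <- geno$snps$id[15]
  rows <- ac[ac$snp == snp_id, ]
  expect_true(all(round(geno$dosage[unique(rows$donor), 15]) == 1L))
  pooled <- sum(rows$alt_count) / sum(rows$alt_count + rows$ref_count)
  expect_equal(pooled, 0.7, tolerance = 0.03)
  # null SNPs pool near balance
  null_rows <- ac[ac$snp != snp_id, ]
  pooled0 <- sum(null_rows$alt_count) /
    sum(null_rows$alt_count + null_rows$ref_count)
  expect_equal(pooled0, 0.5, tolerance = 0.03)
})

test_that("isoform usage decreases monotonically with dosage as planted", {
  cfg <- tiny_sim_config(n_donors = 120L, n_snps = 20L, n_ld_blocks = 4L,
                         n_genes = 10L, cells_per_donor_range = c(20L, 20L),
                         maf_range = c(0.4, 0.5),
                         planted_usage_qtl = list(
                           list(gene = 5L, snp = 10L,
                                psi = c(0.913, 0.83, 0.738))),
                         seed = 17L)
  geno <- simulate_genotypes(cfg)
  ex <- simulate_expression(cfg, geno)
  iso <- simulate_isoform_counts(cfg, geno, ex$cell_meta)
  share <- tapply(iso$long_count, iso$dosage, sum) /
    tapply(iso$long_count + iso$short_count, iso$dosage, sum)
  expect_true(all(diff(share[c("0", "1", "2")]) < 0))
  expect_equal(as.numeric(share[c("0", "1", "2")]), c(0.913, 0.83, 0.738),
               tolerance = 0.02)
})

test_that("zero-total cells contribute nothing to isoform tables", {
  tab <- data.frame(donor = c("a", "a"), dosage = c(1L, 1L),
                    long_count = c(0L, 5L), short_count = c(0L, 5L))
  agg <- stats::aggregate(cbind(long_count, short_count) ~ donor + dosage,
                          data = tab, FUN = sum)
  expect_equal(agg$long_count + agg$short_count, 10L)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(tiny_sim_config(n_donors = 10L,
                               group_sizes = c(MS = 5L, OIND = 2L,
                                               NIND = 2L, IIH = 2L)),
               "sum")
  expect_error(tiny_sim_config(ld_rho = 1), "ld_rho")
  expect_error(tiny_sim_config(planted_eqtls = list(
    list(gene = 1000L, snp = 1L, beta = 1))), "range")
  expect_error(tiny_sim_config(planted_usage_qtl = list(
    list(gene = 1L, snp = 1L, psi = c(0.5, 0.5, 1.2)))), "psi")
  expect_error(tiny_sim_config(planted_ase = list(
    list(snp = 1L, mean_af = 1.2, phi = 0))), "mean_af")
})

test_that("written datasets round-trip through the package readers", {
  cfg <- tiny_sim_config(n_donors = 20L, n_snps = 30L, n_ld_blocks = 5L,
                         n_genes = 10L, cells_per_donor_range = c(5L, 10L),
                         seed = 19L)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  g2 <- read_vcf(file.path(dir, "genotypes.vcf"))
  expect_equal(g2$dosage, round(ds$genotypes$dosage, 3),
               ignore_attr = TRUE)
  m2 <- Matrix::readMM(file.path(dir, "counts.mtx"))
  expect_equal(as.matrix(m2), as.matrix(ds$counts), ignore_attr = TRUE)
  cm <- read.delim(file.path(dir, "cell_meta.tsv"))
  expect_equal(nrow(cm), nrow(ds$cell_meta))
  truth <- yaml::read_yaml(file.path(dir, "ground_truth.yaml"))
  expect_equal(truth$seed, cfg$seed)
})
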