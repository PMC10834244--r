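# csfqtl

Statistical genetics for droplet single-cell RNA-seq cohorts of
cerebrospinal fluid (CSF) immune cells — the setting of case–control
studies of multiple sclerosis (MS) against other neurological diseases,
where ~80 donors contribute a few thousand cells each across a dozen
immune cell types. The package implements the downstream analyses such a
study needs once counts, genotypes and cell annotations exist:

* **Pseudobulk cis-eQTL mapping** per cell type with a two-random-effect
  linear mixed model,
  `cov(y) = σ²_g K + σ²_d diag(1/nᵢ) + σ²_e I`,
  where `K` is the kinship (genetic relatedness) matrix and `nᵢ` each
  donor's read total; REML variance components, GLS association tests,
  gene-level min-p permutation correction (1000 permutations), Storey
  q-values with a conditional-FDR option, and a replication concordance
  rule (same direction, nominal `p < 0.05`).
* **Fine-mapping** of cis signals by the sum-of-single-effects regression
  (L = 10 effects, 95% credible sets, purity filter) with GWAS-variant
  overlap annotation.
* **Allele-specific expression**: per-SNP beta-binomial regression of
  pooled heterozygote allele counts, testing mean allele fraction 0.5
  (Wald test on the intercept), BH flags at FDR 0.01 / 0.0001.
* **Transcript-usage QTLs**: beta-binomial regression of two-isoform
  counts on genotype dosage, `logit(ψ) = b₀ + b₁·dosage`.
* **Factor-model statistics** on a supplied factorization (values `Z`,
  weights `W`): per-factor variance explained with a 1% retention
  threshold, donor-level permutation tests of disease association,
  regulon enrichment as the matrix product `S = Wᵀ T` against 10 000
  size-matched random gene sets, and a competitive |weight| rank-sum
  gene-set test.
* **Viral-presence statistics** on a cell-by-virus UMI matrix: the
  ≥1-UMI presence rule, a 5% cohort prevalence filter, the logistic model
  `present ~ is_MS + total_UMIs` (Firth fallback under separation) and
  the donor-level linear model of viral cell proportions.

A first-class synthetic-data generator (`sim_config()`,
`simulate_dataset()`, `write_dataset()`) produces every input — LD-
structured genotypes with two ancestral populations, negative-binomial
counts with donor random effects, beta-binomial allelic imbalance,
genotype-dependent isoform usage, factor models with planted regulons,
sparse viral UMIs — with planted ground truth for recovery testing.

## Worked example

Simulate a 60-donor cohort with one planted cis-eQTL (gene 10, SNP 70,
β = 0.8 on the log scale, active in CD4 T cells), run QC, pseudobulk and
the scan, then fine-map the hit:

```r
library(csfqtl)

cfg <- sim_config(
  n_donors = 60L,
  group_sizes = c(MS = 25L, OIND = 12L, NIND = 11L, IIH = 12L),
  n_snps = 400L, n_ld_blocks = 40L, n_genes = 60L,
  cells_per_donor_range = c(30L, 80L),
  planted_eqtls = list(list(gene = 10L, snp = 70L, beta = 0.8)),
  seed = 1L)
ds   <- simulate_dataset(cfg)

geno <- apply_genotype_qc(ds$genotypes)   # posterior 0.4, R2 0.6, HWE 1e-4
K    <- compute_kinship(geno)
normed <- normalize_cells(ds$counts, method = "cp10k")
pb   <- aggregate_to_donor(normed, ds$counts, ds$cell_meta, "T_CD4",
                           transform = "log1p")
pb   <- align_to_genotypes(pb, geno)
scan <- map_eqtls(pb, geno, ds$genes, K, n_perm = 1000L, seed = 1L)
head(scan[order(scan$p_perm), ], 3)
```

```
     gene      snp       beta         se      p_perm    q_value significant
 gene0010 snp00070  0.6213336 0.07177907 0.000999001 0.05994006        TRUE
 gene0011 snp00092 -1.0000859 0.24774221 0.007992008 0.19980020       FALSE
 gene0007 snp00054 -0.9172870 0.24675086 0.009990010 0.19980020       FALSE
```

The planted pair tops the scan: the permutation p sits at its floor
`1/1001`, the q-value clears the 10% discovery threshold, and the effect
estimate (0.62) is the planted log-scale β = 0.8 after the expected
attenuation from depth normalization at ~17 cells per donor. Fine-mapping
the gene's cis window pins the signal to a single variant:

```r
y   <- pb$expr[, "gene0010"]
cis <- cis_snps(ds$genes[10, ], geno$snps)
G   <- geno$dosage[match(pb$donors, geno$donors$donor), cis$id]
susie_finemap(y, G)
```

```
susie_fit: 36 SNPs, 1 credible set(s)
  L1: 1 SNP(s), coverage 1.000, purity 1.00
```

`run_demo()` chains every stage — simulation, QC, pseudobulk, eQTL scan,
fine-mapping, ASE, usage QTL, regulon enrichment, viral models — and
prints a recovery report of planted versus detected effects.

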