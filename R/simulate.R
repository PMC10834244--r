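# Synthetic cohort generator.
#
# Emulates the inputs of a CSF single-cell eQTL study: ~80 donors across four
# diagnostic groups (MS, OIND, NIND, IIH), imputed biallelic genotypes with LD
# blocks and two-population structure, negative-binomial UMI counts with donor
# random effects and planted cis-eQTLs, beta-binomial allelic imbalance,
# genotype-dependent two-isoform usage, a factor model with planted regulon
# loading shifts, and a sparse cell-by-virus UMI matrix with a disease effect
# on per-cell presence. All planted truths are returned for recovery testing.

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by the
#' `simulate_*` generators. Defaults describe a cohort of 80 donors in four
#' diagnostic groups (33 MS and 47 others), 2000 LD-structured SNPs, 300
#' genes and 3 cell types, sized so the full pipeline runs in minutes on one
#' CPU.
#'
#' @param n_donors Number of donors.
#' @param group_sizes Named integer vector of donors per diagnostic group;
#'   must sum to `n_donors`.
#' @param n_snps Number of biallelic SNPs.
#' @param n_ld_blocks Number of LD blocks; SNPs are split evenly across
#'   blocks and correlated within block.
#' @param ld_rho Latent within-block correlation of the Gaussian copula,
#'   in \[0,1).
#' @param maf_range Range the per-SNP ancestral allele frequency is drawn
#'   from, within (0, 0.5\].
#' @param n_populations Number of ancestral populations (1 disables
#'   structure).
#' @param pop_fst Balding-Nichols differentiation between populations.
#' @param n_genes Number of genes.
#' @param cell_types Character vector of at least 3 cell-type labels.
#' @param cell_type_probs Sampling probabilities per cell type.
#' @param cells_per_donor_range Range of cells per donor (uniform).
#' @param nb_dispersion Negative-binomial dispersion `a` with
#'   `Var = mu + a mu^2`.
#' @param donor_re_sd SD of the per-donor, per-gene log-scale random effect.
#' @param planted_eqtls List of lists with fields `gene`, `snp`, `beta` and
#'   optional `cell_type` (defaults to the first cell type): cis effects of
#'   one alt-allele dose on log expression, applied in that cell type only.
#' @param planted_ase List of lists with fields `snp`, `mean_af`, `phi`:
#'   allelic imbalance planted at heterozygous donors.
#' @param n_ase_null Number of additional null (balanced) SNPs carried in the
#'   allele-count table.
#' @param planted_usage_qtl List of lists with fields `gene`, `snp`, `psi`
#'   (length-3 long-isoform proportion per dosage 0/1/2).
#' @param usage_phi Beta-binomial overdispersion of per-cell isoform counts.
#' @param n_factors Number of latent factors (the study setting is 30).
#' @param n_tfs Number of transcription factors in the regulon matrix.
#' @param regulon_size Targets per transcription factor.
#' @param planted_regulons List of lists with fields `factor`, `tf`,
#'   `loading_shift`: added to the weights of that TF's targets.
#' @param planted_factor_assoc List of lists with fields `factor`, `shift`:
#'   donor-level factor-value shift for MS donors.
#' @param n_viruses Number of viral sequences.
#' @param viral_base_rate Baseline per-cell presence probability.
#' @param viral_effect Log-odds shift of per-cell viral presence for MS
#'   donors, applied to the viruses in `viral_affected`.
#' @param viral_affected Indices of viruses receiving `viral_effect`.
#' @param seed Integer seed; all generators derive their stream from it.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_donors = 80L,
                       group_sizes = c(MS = 33L, OIND = 16L, NIND = 15L,
                                       IIH = 16L),
                       n_snps = 2000L,
                       n_ld_blocks = 100L,
                       ld_rho = 0.9,
                       maf_range = c(0.05, 0.5),
                       n_populations = 2L,
                       pop_fst = 0.05,
                       n_genes = 300L,
                       cell_types = c("T_CD4", "T_CD8", "B"),
                       cell_type_probs = NULL,
                       cells_per_donor_range = c(50L, 200L),
                       nb_dispersion = 1,
                       donor_re_sd = 0.3,
                       planted_eqtls = list(),
                       planted_ase = list(),
                       n_ase_null = 10L,
                       planted_usage_qtl = list(),
                       usage_phi = 0.02,
                       n_factors = 30L,
                       n_tfs = 20L,
                       regulon_size = 50L,
                       planted_regulons = list(),
                       planted_factor_assoc = list(),
                       n_viruses = 30L,
                       viral_base_rate = 0.005,
                       viral_effect = 0,
                       viral_affected = 1L,
                       seed = 1L) {
  cfg <- list(n_donors = as.integer(n_donors), group_sizes = group_sizes,
              n_snps = as.integer(n_snps),
              n_ld_blocks = as.integer(n_ld_blocks), ld_rho = ld_rho,
              maf_range = maf_range,
              n_populations = as.integer(n_populations), pop_fst = pop_fst,
              n_genes = as.integer(n_genes), cell_types = cell_types,
              cell_type_probs = cell_type_probs %||%
                rep(1 / length(cell_types), length(cell_types)),
              cells_per_donor_range = as.integer(cells_per_donor_range),
              nb_dispersion = nb_dispersion, donor_re_sd = donor_re_sd,
              planted_eqtls = planted_eqtls, planted_ase = planted_ase,
              n_ase_null = as.integer(n_ase_null),
              planted_usage_qtl = planted_usage_qtl, usage_phi = usage_phi,
              n_factors = as.integer(n_factors), n_tfs = as.integer(n_tfs),
              regulon_size = as.integer(regulon_size),
              planted_regulons = planted_regulons,
              planted_factor_assoc = planted_factor_assoc,
              n_viruses = as.integer(n_viruses),
              viral_base_rate = viral_base_rate,
              viral_effect = viral_effect,
              viral_affected = as.integer(viral_affected),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_donors >= 2L, cfg$n_snps >= 1L, cfg$n_genes >= 1L)
  if (sum(cfg$group_sizes) != cfg$n_donors)
    stop("group_sizes must sum to n_donors", call. = FALSE)
  if (cfg$ld_rho < 0 || cfg$ld_rho >= 1)
    stop("ld_rho must be in [0,1)", call. = FALSE)
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must be an increasing pair in (0, 0.5]", call. = FALSE)
  if (length(cfg$cell_types) < 3L)
    stop("at least 3 cell types are required", call. = FALSE)
  if (cfg$cells_per_donor_range[1] < 1L ||
      cfg$cells_per_donor_range[1] > cfg$cells_per_donor_range[2])
    stop("invalid cells_per_donor_range", call. = FALSE)
  for (e in cfg$planted_eqtls) {
    if (e$gene < 1L || e$gene > cfg$n_genes || e$snp < 1L ||
        e$snp > cfg$n_snps)
      stop("planted eQTL indices out of range", call. = FALSE)
    if (!is.null(e$cell_type) && !e$cell_type %in% cfg$cell_types)
      stop("planted eQTL cell type unknown", call. = FALSE)
  }
  for (a in cfg$planted_ase) {
    if (a$snp < 1L || a$snp > cfg$n_snps)
      stop("planted ASE SNP out of range", call. = FALSE)
    if (a$mean_af <= 0 || a$mean_af >= 1)
      stop("mean_af must be in (0,1)", call. = FALSE)
    if (a$phi < 0 || a$phi >= 1)
      stop("phi must be in [0,1)", call. = FALSE)
  }
  for (u in cfg$planted_usage_qtl) {
    if (u$gene < 1L || u$gene > cfg$n_genes || u$snp < 1L ||
        u$snp > cfg$n_snps)
      stop("planted usage-QTL indices out of range", call. = FALSE)
    if (length(u$psi) != 3L || any(u$psi <= 0) || any(u$psi >= 1))
      stop("psi must be a triple in (0,1)", call. = FALSE)
  }
  for (r in cfg$planted_regulons) {
    if (r$factor < 1L || r$factor > cfg$n_factors || r$tf < 1L ||
        r$tf > cfg$n_tfs)
      stop("planted regulon indices out of range", call. = FALSE)
  }
  invisible(cfg)
}

donor_table <- function(cfg) {
  ids <- sprintf("D%03d", seq_len(cfg$n_donors))
  grp <- rep(names(cfg$group_sizes), cfg$group_sizes)
  pop <- rep_len(seq_len(cfg$n_populations), cfg$n_donors)
  data.frame(donor = ids, group = grp, population = pop,
             stringsAsFactors = FALSE)
}

#' Simulate LD-structured donor genotypes
#'
#' Dosages in \{0,1,2\} are produced from a block-wise Gaussian copula: each
#' haplotype draws a latent standard normal with within-block correlation
#' `ld_rho` and carries the alternate allele when the latent value falls below
#' the quantile of the SNP's population allele frequency, so genotypes are in
#' Hardy-Weinberg proportions marginally while dosage correlation tracks the
#' latent correlation. With `n_populations = 2` the per-SNP frequencies
#' diverge between populations by a Balding-Nichols Beta draw at `pop_fst`,
#' which gives the kinship random effect real structure. SNP records carry
#' chromosome, 1-based position, ref/alt alleles, an imputation R-squared and
#' per-call posterior probabilities.
#'
#' @param cfg A [sim_config()] object.
#' @return A `genotype_table` (see [genotype_table()]).
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg$seed, "genotypes"))
  nd <- cfg$n_donors; ns <- cfg$n_snps
  don <- donor_table(cfg)
  block <- rep_len(seq_len(cfg$n_ld_blocks), ns)
  block <- sort(block)

  # one ancestral frequency per LD block: tightly linked variants share
  # their frequency, which keeps within-block dosage correlation close to
  # the latent copula correlation
  f_block <- stats::runif(cfg$n_ld_blocks, cfg$maf_range[1],
                          cfg$maf_range[2])
  f0 <- f_block[block]
  # population-specific frequencies (Balding-Nichols)
  fpop <- matrix(f0, ns, cfg$n_populations)
  if (cfg$n_populations > 1L && cfg$pop_fst > 0) {
    F <- cfg$pop_fst
    for (p in seq_len(cfg$n_populations))
      fpop[, p] <- stats::rbeta(ns, f0 * (1 - F) / F, (1 - f0) * (1 - F) / F)
    fpop[fpop < 1e-4] <- 1e-4
    fpop[fpop > 1 - 1e-4] <- 1 - 1e-4
  }

  rho <- cfg$ld_rho
  hap <- function() {
    # latent: shared block factor + idiosyncratic noise
    u <- stats::rnorm(nd * cfg$n_ld_blocks)
    dim(u) <- c(nd, cfg$n_ld_blocks)
    z <- sqrt(rho) * u[, block, drop = FALSE] +
      sqrt(1 - rho) * matrix(stats::rnorm(nd * ns), nd, ns)
    # per-donor thresholds vary by SNP and population
    thr_mat <- matrix(stats::qnorm(fpop[, don$population]), ns, nd)
    (z < t(thr_mat)) * 1L
  }
  dosage <- hap() + hap()
  dimnames(dosage) <- list(don$donor, sprintf("snp%05d", seq_len(ns)))

  posterior <- matrix(1 - stats::rbeta(nd * ns, 0.3, 30), nd, ns,
                      dimnames = dimnames(dosage))
  low <- stats::runif(nd * ns) < 0.005
  posterior[low] <- stats::runif(sum(low), 0, 0.4)

  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, ns, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), "")
  snps <- data.frame(
    id = colnames(dosage), chrom = "1", pos = seq_len(ns) * 5000L,
    ref = ref, alt = unname(alt),
    r2 = pmin(1, stats::rbeta(ns, 8, 1.2)),
    block = block, stringsAsFactors = FALSE)

  genotype_table(dosage = dosage, call_posterior = posterior, snps = snps,
                 donors = don)
}

gene_annotation <- function(cfg) {
  span <- cfg$n_snps * 5000L
  width <- 20000L
  start <- as.integer(round(seq_len(cfg$n_genes) * span /
                              (cfg$n_genes + 1L)))
  data.frame(gene = sprintf("gene%04d", seq_len(cfg$n_genes)), chrom = "1",
             start = start, end = start + width, stringsAsFactors = FALSE)
}

#' Simulate single-cell UMI counts with planted cis-eQTLs
#'
#' Per-cell counts follow a negative binomial with mean
#' `exp(a_g + b_{donor,g} + beta * dosage + log(depth_cell))`, where the donor
#' random effect `b` is Normal(0, `donor_re_sd`), the per-cell depth factor is
#' lognormal, and planted eQTL effects enter only in their designated cell
#' type. Cells are assigned to donors and cell types per the configuration.
#'
#' @param cfg A [sim_config()] object.
#' @param geno The `genotype_table` from [simulate_genotypes()].
#' @return List with `counts` (sparse cell-by-gene dgCMatrix),
#'   `cell_meta` (data frame: cell, donor, cell_type), `genes` (annotation:
#'   gene, chrom, start, end), and `truth` (per-gene, per-donor log-scale
#'   means in the first cell type).
#' @export
simulate_expression <- function(cfg, geno) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg$seed, "expression"))
  don <- geno$donors
  nd <- nrow(don); ng <- cfg$n_genes
  genes <- gene_annotation(cfg)

  ncell <- sample(seq(cfg$cells_per_donor_range[1],
                      cfg$cells_per_donor_range[2]), nd, replace = TRUE)
  cell_donor <- rep(don$donor, ncell)
  ncells <- length(cell_donor)
  cell_type <- sample(cfg$cell_types, ncells, replace = TRUE,
                      prob = cfg$cell_type_probs)
  depth <- exp(stats::rnorm(ncells, 0, 0.3))

  a_g <- stats::rnorm(ng, log(0.4), 0.8)
  # genes carrying planted cis effects get a well-expressed baseline
  # (about 2 UMIs per cell), as the genes testable for eQTLs in practice do;
  # a multiplicative effect on a nearly-undetected gene is not recoverable
  # at single-cell depths
  for (e in cfg$planted_eqtls) a_g[e$gene] <- log(2)
  b <- matrix(stats::rnorm(nd * ng, 0, cfg$donor_re_sd), nd, ng,
              dimnames = list(don$donor, genes$gene))

  # donor-level log-mean per gene, before cell depth; eQTL effects by cell type
  base_lmu <- sweep(b, 2, a_g, "+")
  lmu_by_type <- rep(list(base_lmu), length(cfg$cell_types))
  names(lmu_by_type) <- cfg$cell_types
  for (e in cfg$planted_eqtls) {
    ct <- e$cell_type %||% cfg$cell_types[1]
    g <- genes$gene[e$gene]
    lmu_by_type[[ct]][, g] <- lmu_by_type[[ct]][, g] +
      e$beta * geno$dosage[don$donor, e$snp]
  }

  di <- match(cell_donor, don$donor)
  counts <- matrix(0L, ncells, ng)
  size <- 1 / cfg$nb_dispersion
  for (ct in cfg$cell_types) {
    idx <- which(cell_type == ct)
    if (!length(idx)) next
    mu <- exp(lmu_by_type[[ct]][di[idx], , drop = FALSE]) * depth[idx]
    counts[idx, ] <- stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = size)
  }
  dimnames(counts) <- list(sprintf("cell%06d", seq_len(ncells)), genes$gene)
  cell_meta <- data.frame(cell = rownames(counts), donor = cell_donor,
                          cell_type = cell_type, stringsAsFactors = FALSE)
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                            "CsparseMatrix"),
       cell_meta = cell_meta, genes = genes,
       truth = list(donor_log_mean = lmu_by_type))
}

#' Simulate per-donor allele counts at heterozygous SNPs
#'
#' For every SNP carried in the table (planted ASE SNPs plus balanced nulls),
#' each donor heterozygous at the SNP contributes, per cell type, a
#' negative-binomial total UMI count and a beta-binomial alternate-allele
#' count with the planted mean allele fraction and overdispersion. Homozygous
#' donors are excluded: allele-specific expression is defined on
#' heterozygotes only. Non-planted SNPs use a balanced mean of 0.5.
#'
#' @param cfg A [sim_config()] object.
#' @param geno The `genotype_table`.
#' @return Data frame with columns donor, snp, gene, cell_type, ref_count,
#'   alt_count.
#' @export
simulate_allele_counts <- function(cfg, geno) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg$seed, "allele"))
  genes <- gene_annotation(cfg)
  planted_idx <- vapply(cfg$planted_ase, `[[`, 0L, "snp")
  null_pool <- setdiff(seq_len(cfg$n_snps), planted_idx)
  null_idx <- sort(sample(null_pool, min(cfg$n_ase_null, length(null_pool))))
  snp_idx <- c(planted_idx, null_idx)
  af <- c(vapply(cfg$planted_ase, `[[`, 0, "mean_af"),
          rep(0.5, length(null_idx)))
  phi <- c(vapply(cfg$planted_ase, `[[`, 0, "phi"),
           rep(0.02, length(null_idx)))

  rows <- list()
  for (k in seq_along(snp_idx)) {
    s <- snp_idx[k]
    het <- which(round(geno$dosage[, s]) == 1L)
    if (!length(het)) next
    # nearest gene hosts the SNP
    gpos <- (genes$start + genes$end) / 2
    gene <- genes$gene[which.min(abs(gpos - geno$snps$pos[s]))]
    for (ct in cfg$cell_types) {
      tot <- stats::rnbinom(length(het), mu = 30, size = 2)
      alt <- rbetabinom(length(het), tot, af[k], phi[k])
      rows[[length(rows) + 1L]] <- data.frame(
        donor = rownames(geno$dosage)[het], snp = geno$snps$id[s],
        gene = gene, cell_type = ct, ref_count = tot - alt, alt_count = alt,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(donor = character(), snp = character(),
                      gene = character(), cell_type = character(),
                      ref_count = integer(), alt_count = integer()))
  do.call(rbind, rows)
}

#' Simulate two-isoform transcript-compatible counts
#'
#' For each planted usage QTL, every cell of a donor draws a Poisson total and
#' a beta-binomial long-isoform count whose mean is the planted long-isoform
#' proportion for that donor's (hard-called) dosage. Cells with zero total
#' contribute nothing downstream.
#'
#' @param cfg A [sim_config()] object.
#' @param geno The `genotype_table`.
#' @param cell_meta Cell metadata from [simulate_expression()].
#' @return Data frame with columns cell, donor, cell_type, gene, snp, dosage,
#'   long_count, short_count.
#' @export
simulate_isoform_counts <- function(cfg, geno, cell_meta) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg$seed, "isoform"))
  genes <- gene_annotation(cfg)
  rows <- list()
  for (u in cfg$planted_usage_qtl) {
    dos <- round(geno$dosage[cell_meta$donor, u$snp])
    psi <- u$psi[dos + 1L]
    tot <- stats::rpois(nrow(cell_meta), 20)
    long <- rbetabinom(nrow(cell_meta), tot, psi, cfg$usage_phi)
    rows[[length(rows) + 1L]] <- data.frame(
      cell = cell_meta$cell, donor = cell_meta$donor,
      cell_type = cell_meta$cell_type, gene = genes$gene[u$gene],
      snp = geno$snps$id[u$snp], dosage = as.integer(dos),
      long_count = long, short_count = tot - long, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(cell = character(), donor = character(),
                      cell_type = character(), gene = character(),
                      snp = character(), dosage = integer(),
                      long_count = integer(), short_count = integer()))
  do.call(rbind, rows)
}

#' Simulate a factor model, regulon matrix and cell-by-virus UMI matrix
#'
#' Factor weights `W` (gene-by-factor) are standard normal except that the
#' targets of each planted regulon receive an added loading shift; factor
#' values `Z` (cell-by-factor) are standard normal with an MS-donor shift for
#' factors carrying a planted disease association. The regulon matrix is a
#' binary gene-by-TF membership. The viral matrix draws per-cell presence
#' from a Bernoulli whose log-odds gain `viral_effect` in MS donors for the
#' affected viruses; present cells carry `1 + Poisson(0.5)` UMIs.
#'
#' @param cfg A [sim_config()] object.
#' @param cell_meta Cell metadata (cell, donor, cell_type).
#' @param donors Donor table with `donor` and `group` columns.
#' @return List with `Z`, `W`, `regulons` (binary gene x TF matrix),
#'   `virus` (sparse cell x virus counts), and `cell_meta` augmented with the
#'   donor's diagnostic group.
#' @export
simulate_factors_and_viral <- function(cfg, cell_meta, donors) {
  validate_sim_config(cfg)
  set.seed(stage_seed(cfg$seed, "factors"))
  genes <- gene_annotation(cfg)$gene
  nf <- cfg$n_factors
  ncells <- nrow(cell_meta)
  grp <- donors$group[match(cell_meta$donor, donors$donor)]
  cm <- cell_meta
  cm$group <- grp

  W <- matrix(stats::rnorm(length(genes) * nf), length(genes), nf,
              dimnames = list(genes, sprintf("factor%02d", seq_len(nf))))
  Treg <- matrix(0L, length(genes), cfg$n_tfs,
                 dimnames = list(genes, sprintf("TF%02d",
                                                seq_len(cfg$n_tfs))))
  for (t in seq_len(cfg$n_tfs))
    Treg[sample(length(genes), min(cfg$regulon_size, length(genes))), t] <- 1L
  for (r in cfg$planted_regulons)
    W[Treg[, r$tf] == 1L, r$factor] <- W[Treg[, r$tf] == 1L, r$factor] +
      r$loading_shift

  Z <- matrix(stats::rnorm(ncells * nf), ncells, nf,
              dimnames = list(cell_meta$cell, colnames(W)))
  is_ms_donor <- donors$group == "MS"
  donor_shift <- stats::rnorm(nrow(donors), 0, 0.3)
  for (a in cfg$planted_factor_assoc) {
    sh <- donor_shift + a$shift * is_ms_donor
    Z[, a$factor] <- Z[, a$factor] + sh[match(cell_meta$donor, donors$donor)]
  }

  set.seed(stage_seed(cfg$seed, "viral"))
  is_ms_cell <- grp == "MS"
  vir <- matrix(0L, ncells, cfg$n_viruses,
                dimnames = list(cell_meta$cell,
                                sprintf("virus%03d", seq_len(cfg$n_viruses))))
  base_lo <- logit(cfg$viral_base_rate)
  for (v in seq_len(cfg$n_viruses)) {
    lo <- base_lo + if (v %in% cfg$viral_affected)
      cfg$viral_effect * is_ms_cell else 0
    pres <- stats::runif(ncells) < expit(lo)
    vir[pres, v] <- 1L + stats::rpois(sum(pres), 0.5)
  }
  list(Z = Z, W = W, regulons = Treg,
       virus = methods::as(Matrix::Matrix(vir, sparse = TRUE),
                           "CsparseMatrix"),
       cell_meta = cm)
}

#' Simulate a complete synthetic dataset
#'
#' Runs every generator in dependency order and bundles the outputs with the
#' ground truth (the planted effect lists plus realized genotypes and
#' per-gene donor means), which is serializable and fully reproducible from
#' the configuration and its seed.
#'
#' @param cfg A [sim_config()] object.
#' @return List of class `"sim_dataset"` with elements `genotypes`, `counts`,
#'   `cell_meta`, `genes`, `allele_counts`, `isoform_counts`, `factors`
#'   (Z/W/regulons/virus) and `truth`.
#' @export
simulate_dataset <- function(cfg) {
  geno <- simulate_genotypes(cfg)
  expr <- simulate_expression(cfg, geno)
  ac <- simulate_allele_counts(cfg, geno)
  iso <- simulate_isoform_counts(cfg, geno, expr$cell_meta)
  fv <- simulate_factors_and_viral(cfg, expr$cell_meta, geno$donors)
  truth <- list(planted_eqtls = cfg$planted_eqtls,
                planted_ase = cfg$planted_ase,
                planted_usage_qtl = cfg$planted_usage_qtl,
                planted_regulons = cfg$planted_regulons,
                planted_factor_assoc = cfg$planted_factor_assoc,
                viral_effect = cfg$viral_effect,
                viral_affected = cfg$viral_affected,
                seed = cfg$seed)
  out <- list(genotypes = geno, counts = expr$counts,
              cell_meta = fv$cell_meta, genes = expr$genes,
              allele_counts = ac, isoform_counts = iso,
              factors = fv, truth = truth)
  class(out) <- "sim_dataset"
  out
}

#' Write a simulated dataset to disk
#'
#' Emits the standard on-disk forms each downstream reader consumes: a
#' simplified VCF v4.2 with GT:DS:GP fields and an `R2` INFO tag, an MTX
#' triplet (matrix + barcodes + features) for the cell-by-gene counts, TSV
#' tables for cell metadata, gene annotation, allele counts, isoform counts
#' and the virus matrix, and a YAML ground-truth file.
#'
#' @param ds A `sim_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(ds$genotypes, file.path(dir, "genotypes.vcf"))
  Matrix::writeMM(ds$counts, file.path(dir, "counts.mtx"))
  writeLines(rownames(ds$counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(ds$counts), file.path(dir, "features.tsv"))
  utils::write.table(ds$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$allele_counts, file.path(dir, "allele_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$isoform_counts, file.path(dir, "isoform_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.matrix(ds$factors$W), file.path(dir, "factor_W.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(as.matrix(ds$factors$Z), file.path(dir, "factor_Z.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(as.matrix(ds$factors$regulons),
                     file.path(dir, "regulons.tsv"), sep = "\t",
                     quote = FALSE)
  Matrix::writeMM(ds$factors$virus, file.path(dir, "virus.mtx"))
  writeLines(colnames(ds$factors$virus), file.path(dir, "virus_names.tsv"))
  yaml::write_yaml(ds$truth, file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}
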