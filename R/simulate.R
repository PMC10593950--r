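#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The generator emulates
#' the data a pathway-partitioned PRS study consumes: LD-blocked biallelic
#' genotypes, GWAS summary statistics with polygenic spike-and-slab effects
#' (optionally enriched inside a target gene set), bilateral continuous
#' imaging-like phenotypes with subject-level correlation, and rare binary
#' psychotic-like-experience (PLE) items with a distress sub-coding.
#'
#' @param n_subjects number of target-sample subjects.
#' @param n_snps total number of SNPs across all chromosomes.
#' @param n_chrom number of chromosomes the SNPs are spread over.
#' @param block_size SNPs per LD block (last block per chromosome may be
#'   truncated).
#' @param rho within-block latent AR(1) correlation, in `[0, 1)`. Across-block
#'   correlation is 0 by construction.
#' @param maf_range length-2 numeric, low/high minor-allele-frequency bounds
#'   in `(0, 0.5]`; per-SNP MAFs are drawn uniformly from this interval.
#' @param n_gwas discovery GWAS sample size used to scale summary-statistic
#'   standard errors (`se = 1/sqrt(2 n maf (1-maf))`).
#' @param prop_causal fraction of SNPs with a nonzero true effect.
#' @param h2_like variance of the nonzero true per-allele effects
#'   (spike-and-slab slab variance).
#' @param set_enrichment multiplier (>= 1) on the causal probability for SNPs
#'   inside the target gene set.
#' @param gamma_set planted standardized effect of the true gene-set PRS on
#'   each continuous phenotype.
#' @param gamma_ple planted log-odds effect (per SD of true set PRS) for the
#'   binary PLE items; defaults to `gamma_set`.
#' @param ple_prevalence target per-item prevalence of the PLE items, in
#'   `(0, 1)`; the logistic intercept is solved numerically to hit it.
#' @param distress_frac fraction of PLE-positive subjects whose most-distress
#'   rating is "distressing" (the rest split neutral/positive).
#' @param icc intraclass correlation of the bilateral phenotypes: share of the
#'   non-genetic, non-covariate variance attributed to the subject-level
#'   random intercept (the rest is hemisphere-specific noise).
#' @param var_covariates share of total phenotype variance explained by the
#'   covariate effects (age, sex, first genetic PC).
#' @param n_ple_items number of binary PLE items (named after the four
#'   classic lifetime items when 4).
#' @param seed integer seed; one global seed expands to fixed per-stage child
#'   seeds so each stage is independently reproducible.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 2000L, n_snps = 2000L, n_chrom = 2L,
                       block_size = 20L, rho = 0.8, maf_range = c(0.05, 0.5),
                       n_gwas = 100000L, prop_causal = 0.1, h2_like = 1e-3,
                       set_enrichment = 1, gamma_set = 0, gamma_ple = NULL,
                       ple_prevalence = 0.02, distress_frac = 0.5,
                       icc = 0.5, var_covariates = 0.1, n_ple_items = 4L,
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), n_snps = as.integer(n_snps),
              n_chrom = as.integer(n_chrom), block_size = as.integer(block_size),
              rho = rho, maf_range = as.numeric(maf_range),
              n_gwas = as.integer(n_gwas), prop_causal = prop_causal,
              h2_like = h2_like, set_enrichment = set_enrichment,
              gamma_set = gamma_set, gamma_ple = gamma_ple %||% gamma_set,
              ple_prevalence = ple_prevalence, distress_frac = distress_frac,
              icc = icc, var_covariates = var_covariates,
              n_ple_items = as.integer(n_ple_items), seed = as.integer(seed))
  .assert(cfg$n_subjects >= 1 && cfg$n_snps >= 1 && cfg$n_chrom >= 1 &&
            cfg$block_size >= 1, "counts must all be >= 1")
  .assert(cfg$rho >= 0 && cfg$rho < 1, "rho must lie in [0, 1)")
  .assert(length(cfg$maf_range) == 2 && cfg$maf_range[1] > 0 &&
            cfg$maf_range[2] <= 0.5 && cfg$maf_range[1] <= cfg$maf_range[2],
          "maf_range must be (low, high) in (0, 0.5]")
  .assert(cfg$prop_causal >= 0 && cfg$prop_causal <= 1,
          "prop_causal must lie in [0, 1]")
  .assert(cfg$h2_like > 0, "h2_like must be > 0")
  .assert(cfg$set_enrichment >= 1, "set_enrichment must be >= 1")
  .assert(is.finite(cfg$gamma_set), "gamma_set must be finite")
  .assert(cfg$ple_prevalence > 0 && cfg$ple_prevalence < 1,
          "ple_prevalence must lie in (0, 1)")
  .assert(cfg$distress_frac >= 0 && cfg$distress_frac <= 1,
          "distress_frac must lie in [0, 1]")
  .assert(cfg$icc >= 0 && cfg$icc <= 1, "icc must lie in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

# unambiguous allele pairs (no A/T, no C/G) so default panels survive QC
.allele_pairs <- matrix(c("A","C", "A","G", "C","A", "C","T",
                          "G","A", "G","T", "T","C", "T","G"),
                        ncol = 2, byrow = TRUE)

#' Simulate LD-blocked biallelic genotypes
#'
#' Dosages are generated from a latent Gaussian AR(1) process per LD block:
#' two independent haploid draws per subject are thresholded at the Gaussian
#' quantile of each SNP's MAF and summed, giving dosages in `{0, 1, 2}` with
#' controllable within-block correlation and independence across blocks.
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes` (n_subjects x n_snps integer dosage matrix,
#'   dosage counts the effect allele `a1`) and `variants` (data.table:
#'   `snp_id, chrom, pos, a1, a2, maf` with strictly increasing positions
#'   within chromosome).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg$seed, "genotypes"))
  n <- cfg$n_subjects; m <- cfg$n_snps; K <- cfg$n_chrom
  per_chrom <- diff(floor(seq(0, m, length.out = K + 1)))
  .assert(all(per_chrom >= 1), "more chromosomes than SNPs")

  snp_id <- sprintf("rs%06d", seq_len(m))
  chrom <- rep(seq_len(K), per_chrom)
  pos <- unlist(lapply(per_chrom, function(mk)
    cumsum(sample(2000:8000, mk, replace = TRUE))), use.names = FALSE)
  maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  ap <- .allele_pairs[sample.int(nrow(.allele_pairs), m, replace = TRUE), ,
                      drop = FALSE]

  G <- matrix(0L, n, m)
  thr <- qnorm(maf)
  idx0 <- 0L
  for (k in seq_len(K)) {
    mk <- per_chrom[k]
    starts <- seq(1L, mk, by = cfg$block_size)
    for (s in starts) {
      B <- min(cfg$block_size, mk - s + 1L)
      cols <- idx0 + s + seq_len(B) - 1L
      Z <- matrix(rnorm(2L * n * B), 2L * n, B)
      if (cfg$rho > 0 && B > 1) {
        w <- sqrt(1 - cfg$rho^2)
        for (j in 2:B) Z[, j] <- cfg$rho * Z[, j - 1] + w * Z[, j]
      }
      H <- Z < rep(thr[cols], each = 2L * n)
      G[, cols] <- H[seq_len(n), , drop = FALSE] +
        H[n + seq_len(n), , drop = FALSE]
    }
    idx0 <- idx0 + mk
  }
  storage.mode(G) <- "integer"
  dimnames(G) <- list(sprintf("S%05d", seq_len(n)), snp_id)
  variants <- data.table(snp_id = snp_id, chrom = as.integer(chrom),
                         pos = as.integer(pos),
                         a1 = ap[, 1], a2 = ap[, 2], maf = maf)
  list(genotypes = G, variants = variants)
}

#' Simulate gene annotation and gene sets
#'
#' Genes tile each chromosome's coordinate span without overlap (a fixed
#' intergenic gap fraction leaves some SNPs unmapped). Named gene sets are
#' drawn from the gene pool, either at random or as a contiguous run of
#' adjacent genes (useful when the planted signal must be genomically
#' clustered, as circular-permutation power experiments require).
#'
#' @param panel output of [simulate_genotypes()].
#' @param cfg a [sim_config()].
#' @param genes_per_chrom genes per chromosome.
#' @param set_sizes integer vector, one entry per gene set.
#' @param set_names optional character names for the sets.
#' @param contiguous if TRUE each set is a run of adjacent genes on one
#'   chromosome.
#' @param gap_frac fraction of each gene slot left intergenic.
#' @return list with `genes` (data.table `gene_id, chrom, start, end`, 1-based
#'   inclusive), `sets` (named list of gene-id vectors) and `membership`
#'   (named list of SNP-id vectors: SNPs inside each set's genes, window 0).
#' @export
simulate_annotation <- function(panel, cfg, genes_per_chrom = 8L,
                                set_sizes = 3L, set_names = NULL,
                                contiguous = FALSE, gap_frac = 0.2) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg$seed, "annotation"))
  v <- panel$variants
  n_sets <- length(set_sizes)
  set_names <- set_names %||% sprintf("set%d", seq_len(n_sets))
  .assert(length(set_names) == n_sets, "set_names length mismatch")

  genes <- rbindlist(lapply(sort(unique(v$chrom)), function(k) {
    span <- max(v$pos[v$chrom == k]) + 1000
    w <- span / genes_per_chrom
    g <- seq_len(genes_per_chrom)
    data.table(gene_id = sprintf("GENE_%d_%02d", k, g), chrom = k,
               start = as.integer(floor((g - 1) * w) + 1),
               end = as.integer(floor((g - 1) * w + (1 - gap_frac) * w)))
  }))
  .assert(all(set_sizes <= nrow(genes)), "set size exceeds gene count")

  sets <- vector("list", n_sets)
  names(sets) <- set_names
  for (i in seq_len(n_sets)) {
    sz <- set_sizes[i]
    if (sz == 0L) {
      sets[[i]] <- character(0)
    } else if (contiguous) {
      start <- sample.int(nrow(genes) - sz + 1L, 1L)
      sets[[i]] <- genes$gene_id[start:(start + sz - 1L)]
    } else {
      sets[[i]] <- sample(genes$gene_id, sz)
    }
  }
  map <- map_snps_to_genes(v, genes, window_kb = 0)
  membership <- lapply(sets, function(gs)
    unique(map$snp_id[map$gene_id %in% gs]))
  list(genes = genes, sets = sets, membership = membership)
}

#' Simulate GWAS summary statistics with spike-and-slab effects
#'
#' True per-allele effects are zero with probability `1 - prop_causal`
#' (multiplied by `set_enrichment`, capped at 1, inside `set_snps`) and
#' Normal(0, `h2_like`) otherwise. Observed effects add sampling noise with
#' the additive-model asymptotic standard error
#' `se = 1/sqrt(2 n_gwas maf (1 - maf))`; p-values are two-sided Wald.
#'
#' @param panel output of [simulate_genotypes()].
#' @param cfg a [sim_config()].
#' @param set_snps SNP ids of the enrichment target set (optional).
#' @param ensure_set_causal if TRUE and `gamma_set != 0`, guarantees at least
#'   one causal SNP inside `set_snps` so the true set PRS is non-degenerate.
#' @return list with `sumstats` (data.table `snp_id, chrom, pos,
#'   effect_allele, other_allele, beta, se, pval, maf`) and `true_betas`
#'   (named numeric, all SNPs).
#' @export
simulate_sumstats <- function(panel, cfg, set_snps = NULL,
                              ensure_set_causal = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg$seed, "sumstats"))
  v <- panel$variants
  .assert(all(v$maf > 0 & v$maf < 1), "maf of 0 or 1 is not allowed")
  m <- nrow(v)
  p_causal <- rep(cfg$prop_causal, m)
  if (!is.null(set_snps))
    p_causal[v$snp_id %in% set_snps] <-
      pmin(1, cfg$prop_causal * cfg$set_enrichment)
  causal <- runif(m) < p_causal
  if (ensure_set_causal && cfg$gamma_set != 0 && length(set_snps) &&
      !any(causal[v$snp_id %in% set_snps])) {
    pick <- sample(which(v$snp_id %in% set_snps), 1L)
    causal[pick] <- TRUE
  }
  beta_true <- ifelse(causal, rnorm(m, 0, sqrt(cfg$h2_like)), 0)
  se <- 1 / sqrt(2 * cfg$n_gwas * v$maf * (1 - v$maf))
  beta_hat <- beta_true + rnorm(m, 0, se)
  pval <- 2 * pnorm(-abs(beta_hat / se))
  ss <- data.table(snp_id = v$snp_id, chrom = v$chrom, pos = v$pos,
                   effect_allele = v$a1, other_allele = v$a2,
                   beta = beta_hat, se = se, pval = pval, maf = v$maf)
  list(sumstats = ss, true_betas = stats::setNames(beta_true, v$snp_id))
}

# solve logistic intercept so that mean(plogis(alpha + eta)) == prev
.solve_intercept <- function(eta, prev) {
  uniroot(function(a) mean(plogis(a + eta)) - prev,
          lower = -40, upper = 40, tol = 1e-10)$root
}

.ple_item_names <- c("conspiracies", "communications", "voices", "visions")

#' Simulate phenotypes, covariates and raw questionnaire responses
#'
#' Continuous phenotypes follow
#' `y = gamma_set * PRS_set_true + covariate effects + subject intercept +
#' hemisphere noise`, emitted as one left and one right row per subject for
#' bilateral phenotypes; variance components are scaled so the total variance
#' is 1, making `gamma_set` a standardized effect. Binary PLE items come from
#' a logistic model whose intercept is solved numerically for the target
#' prevalence; a distress rating is drawn for PLE-positive subjects.
#'
#' @param panel output of [simulate_genotypes()].
#' @param true_betas named true per-allele effects (from
#'   [simulate_sumstats()]).
#' @param set_snps SNP ids defining the true gene set.
#' @param cfg a [sim_config()].
#' @param n_bilateral number of bilateral continuous phenotypes.
#' @param n_global number of unilateral/global continuous phenotypes.
#' @return list with `phenotypes` (long data.table `subject_id, phenotype,
#'   value, hemisphere, modality`), `raw_mhq` (questionnaire responses:
#'   yes/no items plus a distress rating), `covariates` (wide data.table) and
#'   `truth` (ground-truth record, including the standardized true set PRS).
#' @export
simulate_phenotypes <- function(panel, true_betas, set_snps, cfg,
                                n_bilateral = 2L, n_global = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  .assert(is.finite(cfg$gamma_set), "gamma_set non-finite")
  set.seed(child_seed(cfg$seed, "phenotypes"))
  G <- panel$genotypes
  n <- nrow(G)
  subj <- rownames(G)

  in_set <- intersect(colnames(G), set_snps)
  raw_prs <- if (length(in_set))
    as.numeric(G[, in_set, drop = FALSE] %*% true_betas[in_set]) else
      rep(0, n)
  if (sd(raw_prs) > 0) {
    prs <- zscore(raw_prs)
  } else {
    .assert(cfg$gamma_set == 0 && cfg$gamma_ple == 0,
            paste("true set PRS is constant but a nonzero gamma was",
                  "requested; increase prop_causal or set_enrichment"))
    prs <- rep(0, n)
  }

  covs <- data.table(
    subject_id = subj,
    age = round(runif(n, 45, 80), 1),
    sex = rbinom(n, 1L, 0.55),
    array = rbinom(n, 1L, 0.5),
    site = sample(c("site1", "site2", "site3"), n, replace = TRUE),
    head_x = rnorm(n), head_y = rnorm(n), head_z = rnorm(n),
    icv = rnorm(n, 1.5e6, 1.5e5)
  )
  for (j in seq_len(15)) covs[[sprintf("PC%d", j)]] <- rnorm(n)

  # covariate effect built on standardized age/sex/PC1 so its variance share
  # is var_covariates by construction
  c_eff <- sqrt(cfg$var_covariates / 3)
  sex_c <- if (sd(covs$sex) > 0) zscore(covs$sex) else rep(0, n)
  eta_cov <- c_eff * (zscore(covs$age) + sex_c + zscore(covs$PC1))

  resid_var <- 1 - cfg$gamma_set^2 - cfg$var_covariates
  .assert(resid_var > 0, "gamma_set^2 + var_covariates must be < 1")
  var_u <- cfg$icc * resid_var
  var_e <- (1 - cfg$icc) * resid_var

  ph <- list()
  modal_b <- rep(c("volume", "FA"), length.out = max(n_bilateral, 1L))
  for (b in seq_len(n_bilateral)) {
    mu <- cfg$gamma_set * prs + eta_cov + rnorm(n, 0, sqrt(var_u))
    for (h in c("L", "R"))
      ph[[length(ph) + 1L]] <- data.table(
        subject_id = subj,
        phenotype = sprintf("bilat_%s_%d", modal_b[b], b),
        value = mu + rnorm(n, 0, sqrt(var_e)),
        hemisphere = h, modality = modal_b[b])
  }
  for (g in seq_len(n_global)) {
    ph[[length(ph) + 1L]] <- data.table(
      subject_id = subj, phenotype = sprintf("global_FA_%d", g),
      value = cfg$gamma_set * prs + eta_cov + rnorm(n, 0, sqrt(resid_var)),
      hemisphere = NA_character_, modality = "FA")
  }
  phenotypes <- rbindlist(ph)

  # rare binary items: intercept solved for target prevalence
  items <- if (cfg$n_ple_items == 4L) .ple_item_names else
    sprintf("ple_item_%d", seq_len(cfg$n_ple_items))
  eta_ple <- cfg$gamma_ple * prs + 0.1 * zscore(covs$age) + 0.1 * sex_c
  raw <- data.table(subject_id = subj)
  for (it in items) {
    a <- .solve_intercept(eta_ple, cfg$ple_prevalence)
    raw[[it]] <- ifelse(runif(n) < plogis(a + eta_ple), "yes", "no")
  }
  any_ple <- Reduce(`|`, lapply(items, function(it) raw[[it]] == "yes"))
  rating <- rep(NA_character_, n)
  pos <- which(any_ple)
  if (length(pos)) {
    u <- runif(length(pos))
    rating[pos] <- ifelse(u < cfg$distress_frac, "distressing",
                          ifelse(u < cfg$distress_frac +
                                   (1 - cfg$distress_frac) / 2,
                                 "neutral", "positive"))
  }
  raw$distress_rating <- rating

  truth <- list(
    causal_snp_ids = names(true_betas)[true_betas != 0],
    true_betas = true_betas[true_betas != 0],
    set_snps = set_snps,
    gamma_set = cfg$gamma_set, gamma_ple = cfg$gamma_ple,
    covariate_effects = c(age = c_eff, sex = c_eff, PC1 = c_eff),
    prs_set_true = stats::setNames(prs, subj)
  )
  list(phenotypes = phenotypes, raw_mhq = raw, covariates = covs,
       truth = truth)
}

#' Simulate a complete study bundle
#'
#' Convenience wrapper running genotype, annotation, summary-statistic and
#' phenotype simulation in sequence. The first gene set is the enrichment /
#' planted-effect target.
#'
#' @inheritParams simulate_annotation
#' @inheritParams simulate_phenotypes
#' @return list: `config, genotypes, variants, genes, sets, membership,
#'   sumstats, true_betas, phenotypes, raw_mhq, covariates, truth`.
#' @export
simulate_study <- function(cfg, genes_per_chrom = 8L, set_sizes = c(3L, 3L),
                           set_names = NULL, contiguous = FALSE,
                           n_bilateral = 2L, n_global = 1L) {
  panel <- simulate_genotypes(cfg)
  ann <- simulate_annotation(panel, cfg, genes_per_chrom, set_sizes,
                             set_names, contiguous)
  target <- ann$membership[[1]]
  ssim <- simulate_sumstats(panel, cfg, set_snps = target)
  phen <- simulate_phenotypes(panel, ssim$true_betas, target, cfg,
                              n_bilateral, n_global)
  c(list(config = cfg), panel, ann,
    list(sumstats = ssim$sumstats, true_betas = ssim$true_betas),
    phen)
}

#' Write a simulated study bundle to disk
#'
#' Emits the on-disk formats the pipeline reads: genotypes as VCF and PLINK
#' bed/bim/fam, genes as BED (0-based half-open), gene sets as GMT, summary
#' statistics / phenotypes / covariates as TSV, and the ground-truth record
#' as JSON.
#'
#' @param bundle output of [simulate_study()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(bundle$genotypes, bundle$variants, file.path(dir, "genotypes.vcf"))
  write_plink(bundle$genotypes, bundle$variants, file.path(dir, "genotypes"))
  write_gene_bed(bundle$genes, file.path(dir, "genes.bed"))
  write_gmt(bundle$sets, file.path(dir, "gene_sets.gmt"))
  write_sumstats(bundle$sumstats, file.path(dir, "sumstats.tsv"))
  fwrite(bundle$phenotypes, file.path(dir, "phenotypes.tsv"), sep = "\t")
  fwrite(bundle$raw_mhq, file.path(dir, "raw_mhq.tsv"), sep = "\t")
  fwrite(bundle$covariates, file.path(dir, "covariates.tsv"), sep = "\t")
  truth <- bundle$truth
  truth$true_betas <- as.list(truth$true_betas)
  truth$prs_set_true <- as.list(truth$prs_set_true)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
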