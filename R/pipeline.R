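.config_defaults <- function() list(
  inputs = list(sumstats = NULL, genotypes = NULL, genes = NULL,
                gene_sets = NULL, phenotypes = NULL, raw_mhq = NULL,
                covariates = NULL, exclusion_ids = NULL),
  qc = list(maf_min = 0.01, info_min = 0.8),
  annotation = list(window_kb = 0),
  clump = list(r2_thresh = 0.1, window_kb = 250, scope = "global"),
  thresholds = c(0.01, 0.05, 0.1, 0.5, 1),
  primary_threshold = 0.1,
  outliers = list(k = 3),
  fdr = list(alpha = 0.05),
  permutation = list(n_perm = 1000L, all = FALSE),
  seed = 1L,
  out_dir = NULL
)

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML configuration, fills defaults (the five standard p-value
#' thresholds .01/.05/.1/.5/1 with .1 primary among them), rejects unknown
#' keys, checks that every referenced input path exists, and normalizes the
#' threshold list (sorted ascending, with a warning if re-ordered).
#'
#' @param path YAML config file.
#' @return validated config list of class `run_config`.
#' @export
validate_config <- function(path) {
  .assert(file.exists(path), sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  defaults <- .config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  .assert(length(unknown) == 0,
          sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  for (sec in c("inputs", "qc", "annotation", "clump", "outliers", "fdr",
                "permutation")) {
    bad <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    .assert(length(bad) == 0,
            sprintf("unknown key(s) in section '%s': %s", sec,
                    paste(bad, collapse = ", ")))
  }
  cfg <- modifyList(defaults, user)
  for (nm in c("sumstats", "genotypes", "genes", "gene_sets", "phenotypes",
               "covariates")) {
    .assert(!is.null(cfg$inputs[[nm]]),
            sprintf("config must name inputs$%s", nm))
    probe <- cfg$inputs[[nm]]
    if (nm == "genotypes" && !file.exists(probe))
      probe <- paste0(probe, ".bed")      # PLINK prefix
    .assert(file.exists(probe),
            sprintf("input path for '%s' does not exist: %s", nm,
                    cfg$inputs[[nm]]))
  }
  th <- as.numeric(cfg$thresholds)
  .assert(all(is.finite(th)) && all(th > 0 & th <= 1),
          "malformed threshold list")
  if (is.unsorted(th)) {
    warning("thresholds re-ordered ascending")
    th <- sort(th)
  }
  cfg$thresholds <- th
  .assert(cfg$primary_threshold %in% th,
          "primary_threshold must be one of thresholds")
  .assert(cfg$clump$scope %in% c("global", "per-set"), "bad clump scope")
  class(cfg) <- "run_config"
  cfg
}

.read_genotype_input <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) return(read_vcf(path))
  if (file.exists(paste0(path, ".bed"))) return(read_plink(path))
  .assert(grepl("\\.tsv$", path) && file.exists(path),
          sprintf("unrecognized genotype input: %s", path))
  dt <- fread(path)
  G <- as.matrix(dt[, -1])
  rownames(G) <- dt[[1]]
  list(genotypes = G, variants = NULL)
}

#' Run the full pathway-PRS pipeline
#'
#' Executes QC, harmonization, SNP-gene annotation, gene-set partitioning,
#' clumping/thresholding/scoring of set and complement PRSs at every
#' threshold, phenotype derivation (PLE items from raw questionnaire
#' responses when supplied, per-phenotype outlier exclusion, subject
#' filtering), joint association models, per-phenotype BH-FDR, and circular
#' genomic permutation for FDR-significant gene-set associations. All stage
#' outputs are written as plain TSV/JSON under `out_dir` together with a
#' deterministic run manifest.
#'
#' @param cfg a `run_config` from [validate_config()].
#' @return invisibly, a list with the association (`associations`, including
#'   q-values) and permutation tables plus the intermediate objects.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  out_dir <- cfg$out_dir %||% stop("config must set out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(nm, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", nm,
                   conditionMessage(e)), call. = FALSE))
  }

  geno <- stage("genotypes", .read_genotype_input(cfg$inputs$genotypes))
  G <- geno$genotypes
  variants <- geno$variants

  ss_raw <- stage("sumstats", read_sumstats(cfg$inputs$sumstats))
  qc <- stage("qc", qc_sumstats(ss_raw, maf_min = cfg$qc$maf_min,
                                info_min = cfg$qc$info_min))
  write_qc_report(qc$report, file.path(out_dir, "qc_report.json"))
  if (is.null(variants))
    variants <- data.table(snp_id = colnames(G),
                           chrom = qc$sumstats$chrom[
                             match(colnames(G), qc$sumstats$snp_id)],
                           pos = qc$sumstats$pos[
                             match(colnames(G), qc$sumstats$snp_id)],
                           a1 = qc$sumstats$effect_allele[
                             match(colnames(G), qc$sumstats$snp_id)],
                           a2 = qc$sumstats$other_allele[
                             match(colnames(G), qc$sumstats$snp_id)])
  ss <- stage("harmonize", harmonize(qc$sumstats, variants))
  ss <- ss[ss$snp_id %in% colnames(G)]
  .assert(nrow(ss) > 0, "no SNPs shared between summary stats and panel")

  genes <- stage("annotation", read_gene_bed(cfg$inputs$genes))
  sets <- stage("annotation", read_gmt(cfg$inputs$gene_sets))
  snp_map <- stage("annotation",
                   map_snps_to_genes(variants, genes,
                                     window_kb = cfg$annotation$window_kb))
  partition <- stage("annotation",
                     partition_by_geneset(snp_map, sets, ss$snp_id))
  part_dt <- rbindlist(lapply(names(partition), function(nm) data.table(
    set_name = nm,
    snp_id = c(partition[[nm]]$in_set, partition[[nm]]$complement),
    predictor = rep(c("set", "complement"),
                    c(length(partition[[nm]]$in_set),
                      length(partition[[nm]]$complement))))))
  fwrite(part_dt, file.path(out_dir, "partition.tsv"), sep = "\t")

  grid <- stage("scoring",
                build_prs_grid(G, ss, variants, partition,
                               thresholds = cfg$thresholds,
                               r2_thresh = cfg$clump$r2_thresh,
                               window_kb = cfg$clump$window_kb,
                               clump_scope = cfg$clump$scope))
  scores_dt <- rbindlist(lapply(seq_len(nrow(grid$profiles)), function(i) {
    pr <- grid$profiles$profile[[i]]
    data.table(subject_id = pr$subject_id,
               set_name = grid$profiles$set_name[i],
               predictor = pr$predictor, threshold = pr$threshold,
               score = pr$score, n_snps = pr$n_snps_used)
  }))
  fwrite(scores_dt, file.path(out_dir, "scores.tsv"), sep = "\t")
  if (!is.null(grid$clump))
    fwrite(data.table(snp_id = grid$clump$retained, rank =
                        seq_along(grid$clump$retained)),
           file.path(out_dir, "clump.tsv"), sep = "\t")

  phen <- stage("phenotypes",
                as.data.table(fread(cfg$inputs$phenotypes)))
  if ("hemisphere" %in% names(phen))   # blank cells from TSV are NA
    phen$hemisphere[!nzchar(phen$hemisphere)] <- NA_character_
  if (!is.null(cfg$inputs$raw_mhq)) {
    raw <- fread(cfg$inputs$raw_mhq)
    phen <- rbind(phen, derive_ple_items(raw), fill = TRUE)
  }
  covs <- stage("phenotypes", fread(cfg$inputs$covariates))
  if (!is.null(cfg$inputs$exclusion_ids)) {
    excl <- readLines(cfg$inputs$exclusion_ids)
    phen <- filter_subjects(phen, excl)
    covs <- filter_subjects(covs, excl)
  }

  assoc <- stage("association",
                 .associate_all(phen, covs, grid$profiles, cfg))
  fwrite(assoc, file.path(out_dir, "associations.tsv"), sep = "\t")

  assoc$q <- bh_fdr(assoc$p, family_keys = assoc$phenotype)
  fwrite(assoc, file.path(out_dir, "fdr.tsv"), sep = "\t")

  perm_dt <- stage("permutation",
                   .permute_significant(assoc, phen, covs, G, ss, grid,
                                        partition, cfg))
  fwrite(perm_dt, file.path(out_dir, "permutation.tsv"), sep = "\t")

  manifest <- list(
    package_version = as.character(utils::packageVersion("pathprs")),
    seed = cfg$seed, config = unclass(cfg),
    n_subjects = nrow(G), n_snps_harmonized = nrow(ss),
    n_associations = nrow(assoc), n_permutation_runs = nrow(perm_dt))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(associations = assoc, permutation = perm_dt,
                 sumstats = ss, partition = partition, grid = grid,
                 phenotypes = phen, covariates = covs, qc_report = qc$report))
}

.gray_matter_modalities <- c("volume", "cortical", "SA", "thickness",
                             "subcortical")

# one joint fit per phenotype x set x threshold; family chosen from the
# phenotype table's shape (PLE -> logistic, L/R rows -> bilateral-mixed)
.associate_all <- function(phen, covs, profiles, cfg) {
  rows <- list()
  for (ph in unique(phen$phenotype)) {
    sub <- phen[phen$phenotype == ph]
    is_ple <- any(sub$modality == "PLE")
    bilateral <- !is_ple && any(!is.na(sub$hemisphere))
    gray <- any(sub$modality %in% .gray_matter_modalities)
    cov_df <- covariate_frame(covs, family = if (is_ple) "ple" else "imaging",
                              gray_matter = gray)
    if (!is_ple) {
      vals <- sub$value
      mask <- exclude_outliers(vals, k = cfg$outliers$k)
      sub <- sub[mask]
    }
    for (i in seq_len(nrow(profiles))) {
      if (profiles$predictor[i] != "set") next
      set_name <- profiles$set_name[i]
      T <- profiles$threshold[i]
      j <- which(profiles$set_name == set_name &
                   profiles$predictor == "complement" &
                   profiles$threshold == T)
      if (length(j) != 1) next
      prs_s <- profiles$profile[[i]]
      prs_w <- profiles$profile[[j]]
      s <- stats::setNames(prs_s$score, prs_s$subject_id)
      w <- stats::setNames(prs_w$score, prs_w$subject_id)
      res <- if (is_ple) {
        wide <- sub[!is.na(value)]
        idx <- match(wide$subject_id, covs$subject_id)
        fit_logistic_joint(wide$value, s[wide$subject_id],
                           w[wide$subject_id],
                           cov_df[match(wide$subject_id,
                                        cov_df$subject_id),
                                  setdiff(names(cov_df), "subject_id"),
                                  drop = FALSE],
                           phenotype = ph, set_name = set_name,
                           threshold = T)
      } else if (bilateral) {
        suppressWarnings(
          fit_bilateral_joint(sub[, .(subject_id, hemisphere, value)],
                              s, w, cov_df, phenotype = ph,
                              set_name = set_name, threshold = T))
      } else {
        fit_linear_joint(sub$value, s[sub$subject_id], w[sub$subject_id],
                         cov_df[match(sub$subject_id, cov_df$subject_id),
                                setdiff(names(cov_df), "subject_id"),
                                drop = FALSE],
                         phenotype = ph, set_name = set_name,
                         threshold = T)
      }
      rows[[length(rows) + 1L]] <- res
    }
  }
  rbindlist(rows)
}

.permute_significant <- function(assoc, phen, covs, G, ss, grid, partition,
                                 cfg) {
  hits <- assoc[assoc$predictor == "set" &
                  (cfg$permutation$all | assoc$q <= cfg$fdr$alpha), ]
  if (nrow(hits) == 0)
    return(data.table(set_name = character(), phenotype = character(),
                      threshold = numeric(), observed_t = numeric(),
                      empirical_p = numeric(), n_perm = integer(),
                      seed = integer()))
  .assert(!is.null(grid$clump),
          "permutation requires global clump scope")
  out <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i]
    circle <- intersect(grid$clump$retained, select_threshold(ss, h$threshold))
    members <- intersect(circle, partition[[h$set_name]]$in_set)
    sub <- phen[phen$phenotype == h$phenotype]
    is_ple <- any(sub$modality == "PLE")
    bilateral <- !is_ple && any(!is.na(sub$hemisphere))
    gray <- any(sub$modality %in% .gray_matter_modalities)
    cov_df <- covariate_frame(covs, family = if (is_ple) "ple" else "imaging",
                              gray_matter = gray)
    seed_i <- (child_seed(cfg$seed, "permutation") + i) %% .Machine$integer.max
    pr <- if (bilateral) {
      permutation_test(G, ss, circle, members,
                       sub[, .(subject_id, hemisphere, value)],
                       cov_df, model_family = "bilateral-mixed",
                       n_perm = cfg$permutation$n_perm, seed = seed_i)
    } else {
      yv <- sub$value[match(rownames(G), sub$subject_id)]
      cv <- cov_df[match(rownames(G), cov_df$subject_id),
                   setdiff(names(cov_df), "subject_id"), drop = FALSE]
      permutation_test(G, ss, circle, members, yv, cv,
                       model_family = if (is_ple) "logistic" else "linear",
                       n_perm = cfg$permutation$n_perm, seed = seed_i)
    }
    out[[i]] <- data.table(set_name = h$set_name, phenotype = h$phenotype,
                           threshold = h$threshold,
                           observed_t = pr$observed_t,
                           empirical_p = pr$empirical_p,
                           n_perm = pr$n_perm, seed = pr$seed)
  }
  rbindlist(out)
}

#' Reported lifetime PLE item frequencies from a large questionnaire sample
#'
#' Loads the packaged table of lifetime psychotic-like-experience item counts
#' reported for a population mental-health questionnaire sample
#' (n = 119,947) and recomputes each percentage from its count and the
#' sample size, alongside the originally reported (printed) percentage and
#' its decimal precision.
#'
#' @return data.table: `item, count, sample_n, percent_printed, digits,
#'   percent_recomputed` (the last rounded to `digits`), plus
#'   `percent_exact`.
#' @export
mhq_item_frequencies <- function() {
  path <- system.file("extdata", "mhq_item_counts.tsv", package = "pathprs")
  dt <- fread(path)
  dt$percent_exact <- dt$count / dt$sample_n * 100
  dt$percent_recomputed <- round(dt$percent_exact, dt$digits)
  dt[]
}
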