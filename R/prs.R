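#' Greedy LD clumping
#'
#' Iterates SNPs by ascending GWAS p-value (ties broken by chromosome then
#' position) and retains a SNP iff its squared Pearson correlation with every
#' already-retained SNP on the same chromosome within `window_kb` is below
#' `r2_thresh`. r-squared is computed on mean-imputed, mean-centered panel
#' dosages; a zero-variance SNP has r = 0 with everything by convention.
#'
#' @param variants data.table `snp_id, chrom, pos` for the SNPs to clump.
#' @param genotypes dosage matrix with SNP ids as column names (the LD
#'   reference).
#' @param pvals named numeric vector of p-values covering all `variants`.
#' @param r2_thresh LD threshold in `(0, 1]`.
#' @param window_kb physical window in kilobases.
#' @return list of class `clump_result`: `retained` (snp ids in retention
#'   order, i.e. ascending p), `params`, and `absorbed` (data.table
#'   `snp_id, index_snp` recording which retained SNP absorbed each removed
#'   one).
#' @export
ld_clump <- function(variants, genotypes, pvals, r2_thresh = 0.1,
                     window_kb = 250) {
  .assert(r2_thresh > 0 && r2_thresh <= 1, "r2_thresh must lie in (0, 1]")
  .assert(all(variants$snp_id %in% names(pvals)),
          "pvals missing for some variants")
  miss <- setdiff(variants$snp_id, colnames(genotypes))
  .assert(length(miss) == 0,
          sprintf("missing genotype column for SNP(s): %s",
                  paste(head(miss, 3), collapse = ", ")))
  v <- data.table(snp_id = variants$snp_id, chrom = variants$chrom,
                  pos = variants$pos, pval = pvals[variants$snp_id])
  ord <- order(v$pval, v$chrom, v$pos)
  v <- v[ord]

  X <- genotypes[, v$snp_id, drop = FALSE]
  storage.mode(X) <- "double"
  # mean-impute then center; normalize so crossprod gives Pearson r
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    if (anyNA(xj)) xj[is.na(xj)] <- mean(xj, na.rm = TRUE)
    xj <- xj - mean(xj)
    ss <- sqrt(sum(xj^2))
    X[, j] <- if (ss > 0) xj / ss else 0
  }

  w <- window_kb * 1000
  m <- nrow(v)
  retained <- integer(0)
  absorbed <- vector("list", m)
  for (j in seq_len(m)) {
    cand <- retained[v$chrom[retained] == v$chrom[j] &
                       abs(v$pos[retained] - v$pos[j]) <= w]
    if (length(cand)) {
      r2 <- as.numeric(crossprod(X[, cand, drop = FALSE], X[, j]))^2
      if (any(r2 >= r2_thresh)) {
        absorbed[[j]] <- v$snp_id[cand[which.max(r2)]]
        next
      }
    }
    retained <- c(retained, j)
  }
  abs_dt <- data.table(
    snp_id = v$snp_id[!vapply(absorbed, is.null, TRUE)],
    index_snp = unlist(absorbed))
  structure(list(retained = v$snp_id[retained],
                 params = list(r2_thresh = r2_thresh, window_kb = window_kb),
                 absorbed = abs_dt),
            class = "clump_result")
}

#' Select SNPs at a GWAS p-value threshold
#' @param ss summary-statistics table with `snp_id, pval`.
#' @param T threshold in `(0, 1]`; SNPs with `pval <= T` are kept.
#' @return character vector of snp ids.
#' @export
select_threshold <- function(ss, T) {
  .assert(is.numeric(T) && length(T) == 1 && T > 0 && T <= 1,
          "threshold must be a single value in (0, 1]")
  ss$snp_id[ss$pval <= T]
}

#' Compute a polygenic risk score profile
#'
#' `score_i = sum_j beta_j * dosage_ij` over the SNP subset; missing dosages
#' are mean-imputed per SNP. Raw scores are unweighted sums (not averaged per
#' allele count); standardization before modeling makes the choice
#' immaterial for inference.
#'
#' @param genotypes dosage matrix (subjects x SNPs, column names = snp ids).
#' @param ss harmonized summary statistics providing the weights.
#' @param snp_subset snp ids to score (subset of the harmonized universe).
#' @param predictor label for the profile (e.g. "set" or "complement").
#' @param threshold the p-value threshold the subset corresponds to.
#' @return object of class `prs_profile`: list with `subject_id, score,
#'   predictor, threshold, n_snps_used, standardized`.
#' @export
compute_prs <- function(genotypes, ss, snp_subset, predictor = "PRS",
                        threshold = NA_real_) {
  .assert(length(snp_subset) > 0,
          sprintf("empty SNP subset for predictor '%s' at threshold %s",
                  predictor, format(threshold)))
  .assert(all(snp_subset %in% ss$snp_id),
          "snp_subset contains SNPs absent from the summary statistics")
  .assert(all(snp_subset %in% colnames(genotypes)),
          "snp_subset contains SNPs absent from the genotype panel")
  beta <- stats::setNames(ss$beta, ss$snp_id)[snp_subset]
  X <- genotypes[, snp_subset, drop = FALSE]
  storage.mode(X) <- "double"
  if (anyNA(X))
    for (j in which(colSums(is.na(X)) > 0)) {
      xj <- X[, j]
      xj[is.na(xj)] <- mean(xj, na.rm = TRUE)
      X[, j] <- xj
    }
  score <- as.numeric(X %*% beta)
  structure(list(subject_id = rownames(genotypes), score = score,
                 predictor = predictor, threshold = threshold,
                 n_snps_used = length(snp_subset), standardized = FALSE),
            class = "prs_profile")
}

#' @export
print.prs_profile <- function(x, ...) {
  cat(sprintf("<prs_profile> %s @ T=%s: %d subjects, %d SNPs%s\n",
              x$predictor, format(x$threshold), length(x$score),
              x$n_snps_used,
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' Standardize a PRS profile to z-scores
#'
#' Sample mean 0, sample SD 1 (n - 1 denominator).
#'
#' @param profile a `prs_profile`.
#' @return the profile with standardized scores.
#' @export
standardize_profile <- function(profile) {
  stopifnot(inherits(profile, "prs_profile"))
  .assert(sd(profile$score) > 0,
          sprintf("constant scores for predictor '%s': cannot standardize",
                  profile$predictor))
  profile$score <- zscore(profile$score)
  profile$standardized <- TRUE
  profile
}

#' Pearson correlation of two PRS profiles
#' @param profile_a,profile_b `prs_profile` objects over the same subjects.
#' @return correlation in `[-1, 1]`.
#' @export
correlate_profiles <- function(profile_a, profile_b) {
  .assert(identical(profile_a$subject_id, profile_b$subject_id),
          "profiles cover different subjects")
  .assert(sd(profile_a$score) > 0 && sd(profile_b$score) > 0,
          "constant profile: correlation undefined")
  cor(profile_a$score, profile_b$score)
}

#' Build the full PRS grid for a gene-set partition
#'
#' Clumps once (globally by default), then for each p-value threshold and
#' each gene set scores the set SNPs and the complement SNPs among the
#' clumped, thresholded list. With `clump_scope = "per-set"` the set and
#' complement lists are instead clumped separately before thresholding.
#'
#' @param genotypes dosage matrix.
#' @param ss harmonized summary statistics.
#' @param variants panel variant table.
#' @param partition output of [partition_by_geneset()].
#' @param thresholds numeric vector of p-value thresholds.
#' @param r2_thresh,window_kb clumping parameters.
#' @param clump_scope "global" (default) or "per-set".
#' @param standardize z-score each profile?
#' @return list with `clump` (the global `clump_result`, or NULL for
#'   per-set scope) and `profiles`, a data.table
#'   `set_name, predictor, threshold, profile` (list column), plus
#'   `n_snps_used` per cell. Cells whose SNP list is empty are dropped with
#'   a warning.
#' @export
build_prs_grid <- function(genotypes, ss, variants, partition,
                           thresholds = c(0.01, 0.05, 0.1, 0.5, 1),
                           r2_thresh = 0.1, window_kb = 250,
                           clump_scope = c("global", "per-set"),
                           standardize = TRUE) {
  clump_scope <- match.arg(clump_scope)
  pv <- stats::setNames(ss$pval, ss$snp_id)
  vv <- variants[variants$snp_id %in% ss$snp_id]

  clump_global <- NULL
  if (clump_scope == "global")
    clump_global <- ld_clump(vv, genotypes, pv, r2_thresh, window_kb)

  rows <- list()
  for (set_name in names(partition)) {
    part <- partition[[set_name]]
    for (pred in c("set", "complement")) {
      members <- if (pred == "set") part$in_set else part$complement
      if (clump_scope == "global") {
        pool <- intersect(clump_global$retained, members)
      } else {
        vsub <- vv[vv$snp_id %in% members]
        pool <- if (nrow(vsub)) ld_clump(vsub, genotypes, pv, r2_thresh,
                                         window_kb)$retained else character(0)
      }
      for (T in thresholds) {
        keep <- intersect(pool, select_threshold(ss, T))
        if (length(keep) == 0) {
          warning(sprintf(
            "no SNPs for set '%s' predictor '%s' at threshold %g",
            set_name, pred, T))
          next
        }
        prof <- compute_prs(genotypes, ss, keep, predictor = pred,
                            threshold = T)
        if (standardize) prof <- standardize_profile(prof)
        rows[[length(rows) + 1L]] <- data.table(
          set_name = set_name, predictor = pred, threshold = T,
          n_snps_used = prof$n_snps_used, profile = list(prof))
      }
    }
  }
  list(clump = clump_global, profiles = rbindlist(rows))
}
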