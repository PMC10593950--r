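#' @importFrom lmerTest lmer
NULL

.as_score <- function(x) {
  if (inherits(x, "prs_profile")) stats::setNames(x$score, x$subject_id)
  else x
}

.assoc_row <- function(phenotype, predictor, set_name, threshold, est,
                       model_family) {
  data.table(phenotype = phenotype, predictor = predictor,
             set_name = set_name, threshold = threshold,
             beta_std = est[["beta"]], se = est[["se"]],
             stat = est[["stat"]], p = est[["p"]], n = est[["n"]],
             model_family = model_family)
}

# listwise deletion across all model inputs, with a message when rows drop
.complete_rows <- function(...) {
  parts <- list(...)
  ok <- Reduce(`&`, lapply(parts, function(p) {
    if (is.null(p)) return(TRUE)
    if (is.data.frame(p)) complete.cases(p) else !is.na(p)
  }))
  if (!all(ok)) message(sprintf("dropping %d incomplete case(s)", sum(!ok)))
  ok
}

#' Joint linear association of a phenotype with set and complement PRSs
#'
#' Ordinary least squares of the z-scored outcome on the z-scored gene-set
#' PRS and z-scored whole-genome-complement PRS plus covariates (covariates
#' stay on their native scale; their scaling does not affect the PRS
#' effects). Returns standardized effects for both PRSs.
#'
#' @param y continuous outcome (numeric vector).
#' @param prs_set,prs_wg PRS scores (`prs_profile` or numeric vectors,
#'   aligned with `y`).
#' @param covariates optional data.frame of covariates, same row order.
#' @param phenotype,set_name,threshold labels carried into the result.
#' @return data.table with two AssociationResult rows (predictor "set" and
#'   "complement"): `phenotype, predictor, set_name, threshold, beta_std,
#'   se, stat, p, n, model_family`.
#' @export
fit_linear_joint <- function(y, prs_set, prs_wg, covariates = NULL,
                             phenotype = "y", set_name = NA_character_,
                             threshold = NA_real_) {
  s <- .as_score(prs_set); w <- .as_score(prs_wg)
  ok <- .complete_rows(y, s, w, covariates)
  y <- y[ok]; s <- s[ok]; w <- w[ok]
  cov_df <- if (!is.null(covariates)) as.data.frame(covariates)[ok, ,
                                                                drop = FALSE]
  df <- data.frame(.y = zscore(y), prs_set = zscore(s), prs_wg = zscore(w))
  if (!is.null(cov_df)) df <- cbind(df, cov_df)
  n <- nrow(df)
  p_design <- 1L + 2L + if (is.null(cov_df)) 0L else ncol(cov_df)
  .assert(n > p_design,
          sprintf("too few cases (%d) for %d-parameter model", n, p_design))
  fit <- lm(.y ~ ., data = df)
  aliased <- names(coef(fit))[is.na(coef(fit))]
  .assert(length(aliased) == 0,
          sprintf("rank-deficient design; collinear column(s): %s",
                  paste(aliased, collapse = ", ")))
  co <- summary(fit)$coefficients
  out <- rbind(
    .assoc_row(phenotype, "set", set_name, threshold,
               c(beta = co["prs_set", 1], se = co["prs_set", 2],
                 stat = co["prs_set", 3], p = co["prs_set", 4], n = n),
               "linear"),
    .assoc_row(phenotype, "complement", set_name, threshold,
               c(beta = co["prs_wg", 1], se = co["prs_wg", 2],
                 stat = co["prs_wg", 3], p = co["prs_wg", 4], n = n),
               "linear"))
  out
}

#' Joint bilateral mixed-model association
#'
#' For bilateral phenotypes (one left and one right measurement per subject):
#' linear mixed model with a subject-level random intercept, hemisphere as a
#' within-subject fixed covariate, and both PRSs plus covariates as fixed
#' effects; fitted by REML. The outcome (over all rows) and both PRSs are
#' z-scored. Zero between-subject variance is a valid boundary fit.
#' Subjects without exactly one L and one R row are dropped with a warning.
#'
#' @param y_long data.table `subject_id, hemisphere, value`.
#' @param prs_set,prs_wg PRS scores named by subject id (or `prs_profile`).
#' @param covariates optional data.frame with one row per subject and a
#'   `subject_id` column.
#' @inheritParams fit_linear_joint
#' @return data.table with two AssociationResult rows
#'   (model_family "bilateral-mixed"; `n` = number of subjects).
#' @export
fit_bilateral_joint <- function(y_long, prs_set, prs_wg, covariates = NULL,
                                phenotype = "y", set_name = NA_character_,
                                threshold = NA_real_) {
  y_long <- as.data.table(y_long)
  cnt <- y_long[, .N, by = subject_id]
  bad <- cnt$subject_id[cnt$N != 2L]
  two_hemi <- y_long[, length(unique(hemisphere)) == 2L, by = subject_id]
  bad <- union(bad, two_hemi$subject_id[!two_hemi$V1])
  if (length(bad)) {
    warning(sprintf("dropping %d subject(s) without exactly one L and one R row",
                    length(bad)))
    y_long <- y_long[!subject_id %in% bad]
  }
  s <- .as_score(prs_set); w <- .as_score(prs_wg)
  .assert(!is.null(names(s)) && !is.null(names(w)),
          "bilateral fit needs subject-named PRS scores")
  dat <- data.table(subject_id = y_long$subject_id,
                    hemisphere = y_long$hemisphere,
                    .y = y_long$value,
                    prs_set = s[y_long$subject_id],
                    prs_wg = w[y_long$subject_id])
  if (!is.null(covariates)) {
    cov_dt <- as.data.table(covariates)
    .assert("subject_id" %in% names(cov_dt),
            "covariates for bilateral fits need a subject_id column")
    dat <- merge(dat, cov_dt, by = "subject_id", sort = FALSE)
  }
  dat <- dat[complete.cases(dat)]
  keep <- dat[, .N, by = subject_id][N == 2L, subject_id]
  dat <- dat[subject_id %in% keep]
  .assert(nrow(dat) > 0, "no complete bilateral cases")
  dat[, `:=`(.y = zscore(.y), prs_set = zscore(prs_set),
             prs_wg = zscore(prs_wg))]
  covs <- setdiff(names(dat), c("subject_id", "hemisphere", ".y",
                                "prs_set", "prs_wg"))
  form <- stats::as.formula(paste(
    ".y ~ hemisphere + prs_set + prs_wg",
    if (length(covs)) paste("+", paste(covs, collapse = " + ")) else "",
    "+ (1 | subject_id)"))
  fit <- suppressMessages(lmerTest::lmer(form, data = dat, REML = TRUE))
  co <- coef(summary(fit))
  n_subj <- length(unique(dat$subject_id))
  rbind(
    .assoc_row(phenotype, "set", set_name, threshold,
               c(beta = co["prs_set", "Estimate"],
                 se = co["prs_set", "Std. Error"],
                 stat = co["prs_set", "t value"],
                 p = co["prs_set", "Pr(>|t|)"], n = n_subj),
               "bilateral-mixed"),
    .assoc_row(phenotype, "complement", set_name, threshold,
               c(beta = co["prs_wg", "Estimate"],
                 se = co["prs_wg", "Std. Error"],
                 stat = co["prs_wg", "t value"],
                 p = co["prs_wg", "Pr(>|t|)"], n = n_subj),
               "bilateral-mixed"))
}

#' Joint logistic association for binary phenotypes
#'
#' Maximum-likelihood logistic regression of a binary outcome on both
#' z-scored PRSs plus covariates; the reported effect is the log-odds change
#' per SD of PRS with its Wald z and two-sided p. Complete separation (or
#' non-convergence) raises an error rather than returning a silently
#' divergent fit.
#'
#' @param y binary outcome in `{0, 1}` (NAs dropped listwise).
#' @inheritParams fit_linear_joint
#' @return data.table with two AssociationResult rows
#'   (model_family "logistic").
#' @export
fit_logistic_joint <- function(y, prs_set, prs_wg, covariates = NULL,
                               phenotype = "y", set_name = NA_character_,
                               threshold = NA_real_) {
  s <- .as_score(prs_set); w <- .as_score(prs_wg)
  ok <- .complete_rows(y, s, w, covariates)
  y <- y[ok]; s <- s[ok]; w <- w[ok]
  .assert(all(y %in% c(0, 1)), "outcome must be binary in {0, 1}")
  .assert(length(unique(y)) == 2,
          "outcome has a single class: logistic fit undefined")
  df <- data.frame(.y = y, prs_set = zscore(s), prs_wg = zscore(w))
  if (!is.null(covariates))
    df <- cbind(df, as.data.frame(covariates)[ok, , drop = FALSE])
  n <- nrow(df)
  sep_flag <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(wn) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(wn)))
        sep_flag <<- TRUE
      invokeRestart("muffleWarning")
    })
  .assert(fit$converged, "logistic fit did not converge")
  co <- summary(fit)$coefficients
  if (sep_flag && any(abs(co[c("prs_set", "prs_wg"), 1]) > 10))
    stop("complete separation detected in logistic fit", call. = FALSE)
  rbind(
    .assoc_row(phenotype, "set", set_name, threshold,
               c(beta = co["prs_set", 1], se = co["prs_set", 2],
                 stat = co["prs_set", 3], p = co["prs_set", 4], n = n),
               "logistic"),
    .assoc_row(phenotype, "complement", set_name, threshold,
               c(beta = co["prs_wg", 1], se = co["prs_wg", 2],
                 stat = co["prs_wg", 3], p = co["prs_wg", 4], n = n),
               "logistic"))
}

#' Default covariate sets per model family
#'
#' Imaging models adjust for age, age squared, sex, 15 genetic PCs, scan
#' site, the three MRI head-position coordinates and genotype array, with
#' intracranial volume added for gray-matter phenotypes; PLE (logistic)
#' models use the reduced set age, sex, 15 PCs and array.
#'
#' @param covariates wide covariate data.table (as produced by
#'   [simulate_phenotypes()]).
#' @param family "imaging" or "ple".
#' @param gray_matter include the ICV column (imaging family only)?
#' @param include_age2 include the age-squared term (imaging family).
#' @return data.frame of model-ready covariates (factors for site), with a
#'   `subject_id` column retained.
#' @export
covariate_frame <- function(covariates, family = c("imaging", "ple"),
                            gray_matter = FALSE, include_age2 = TRUE) {
  family <- match.arg(family)
  cv <- as.data.table(covariates)
  pcs <- grep("^PC\\d+$", names(cv), value = TRUE)
  out <- data.table(subject_id = cv$subject_id, age = cv$age, sex = cv$sex)
  if (family == "imaging") {
    if (include_age2) out$age2 <- cv$age^2
    out <- cbind(out, cv[, ..pcs])
    out$site <- factor(cv$site)
    out$head_x <- cv$head_x; out$head_y <- cv$head_y; out$head_z <- cv$head_z
    out$array <- cv$array
    if (gray_matter) out$icv <- cv$icv
  } else {
    out <- cbind(out, cv[, ..pcs])
    out$array <- cv$array
  }
  as.data.frame(out)
}
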