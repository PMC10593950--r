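#' Derive binary PLE items and the distress contrast
#'
#' Converts raw questionnaire responses into four binary lifetime
#' psychotic-like-experience items plus a distress variable. Distress is 1
#' for subjects reporting at least one PLE whose distress rating is
#' "distressing", 0 for subjects reporting no PLE at all, and missing for
#' subjects whose PLEs were rated neutral or positive — i.e. the contrast is
#' distressing-PLE reporters versus non-reporters. With
#' `distress_contrast = "vs-any"` neutral/positive reporters are coded 0
#' instead of missing.
#'
#' @param raw_responses data.table with `subject_id`, one yes/no column per
#'   item (any of `conspiracies, communications, voices, visions` present are
#'   used) and a `distress_rating` column in
#'   `{distressing, neutral, positive, NA}`.
#' @param distress_contrast `"vs-none"` (default, as described above) or
#'   `"vs-any"`.
#' @return long data.table `subject_id, phenotype, value, hemisphere,
#'   modality` with modality "PLE"; values 0/1/NA.
#' @export
derive_ple_items <- function(raw_responses,
                             distress_contrast = c("vs-none", "vs-any")) {
  distress_contrast <- match.arg(distress_contrast)
  raw_responses <- as.data.table(raw_responses)
  for (cl in names(raw_responses))   # blank cells (TSV round-trip) are NA
    if (is.character(raw_responses[[cl]]))
      raw_responses[[cl]][!nzchar(raw_responses[[cl]])] <- NA_character_
  items <- intersect(.ple_item_names, names(raw_responses))
  .assert(length(items) >= 1, "no recognized PLE item columns")
  for (it in items) {
    vals <- raw_responses[[it]]
    bad <- !(vals %in% c("yes", "no") | is.na(vals))
    .assert(!any(bad), sprintf("unknown response code in item '%s': %s",
                               it, vals[bad][1]))
  }
  rating <- raw_responses$distress_rating
  .assert(all(rating %in% c("distressing", "neutral", "positive") |
                is.na(rating)),
          "unknown distress rating code")

  out <- rbindlist(lapply(items, function(it) data.table(
    subject_id = raw_responses$subject_id, phenotype = it,
    value = as.numeric(raw_responses[[it]] == "yes"),
    hemisphere = NA_character_, modality = "PLE")))

  any_ple <- Reduce(`|`, lapply(items, function(it)
    raw_responses[[it]] == "yes"))
  distress <- rep(NA_real_, nrow(raw_responses))
  distress[!any_ple] <- 0
  distress[any_ple & !is.na(rating) & rating == "distressing"] <- 1
  if (distress_contrast == "vs-any")
    distress[any_ple & is.na(distress)] <- 0
  rbind(out, data.table(subject_id = raw_responses$subject_id,
                        phenotype = "distress", value = distress,
                        hemisphere = NA_character_, modality = "PLE"))
}

#' First-principal-component composite of correlated measures
#'
#' Standardizes the columns, takes scores on the first unrotated principal
#' component, scales them to mean 0 / SD 1 and fixes the sign so the scores
#' correlate positively with the subject-wise mean of the standardized
#' measures (the PC sign is otherwise arbitrary and downstream effect signs
#' depend on it).
#'
#' @param measures numeric matrix, subjects x measures (>= 2 columns,
#'   complete cases; row names = subject ids).
#' @return named numeric vector of composite scores with attribute
#'   `var_explained` (share of variance on PC1).
#' @export
derive_composite_pc <- function(measures) {
  measures <- as.matrix(measures)
  .assert(ncol(measures) >= 2, "composite PC requires >= 2 measures")
  .assert(all(complete.cases(measures)), "composite PC requires complete cases")
  sds <- apply(measures, 2, sd)
  .assert(all(sds > 0), sprintf("constant column: %s",
                                colnames(measures)[which(sds == 0)[1]]))
  Z <- scale(measures)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1]
  if (cor(scores, rowMeans(Z)) < 0) scores <- -scores
  out <- zscore(scores)
  names(out) <- rownames(measures)
  attr(out, "var_explained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  out
}

#' Lobar and global sums of regional values
#'
#' Sums region-of-interest values into lobar aggregates per hemisphere, plus
#' a per-hemisphere global sum over all ROIs.
#'
#' @param roi_values data.table `subject_id, roi, hemisphere, value`.
#' @param lobe_map data.table `roi, lobe` assigning each ROI to a lobe.
#' @return long data.table `subject_id, phenotype, value, hemisphere,
#'   modality` with phenotypes `<lobe>_sum` and `global_sum`.
#' @export
derive_lobar_sums <- function(roi_values, lobe_map) {
  missing_roi <- setdiff(lobe_map$roi, unique(roi_values$roi))
  .assert(length(missing_roi) == 0,
          sprintf("ROI(s) in lobe map absent from data: %s",
                  paste(head(missing_roi, 3), collapse = ", ")))
  dt <- merge(as.data.table(roi_values), as.data.table(lobe_map), by = "roi")
  lobar <- dt[, .(value = sum(value)), by = .(subject_id, hemisphere, lobe)]
  lobar <- data.table(subject_id = lobar$subject_id,
                      phenotype = paste0(lobar$lobe, "_sum"),
                      value = lobar$value, hemisphere = lobar$hemisphere,
                      modality = "cortical")
  glob <- as.data.table(roi_values)[, .(value = sum(value)),
                                    by = .(subject_id, hemisphere)]
  glob <- data.table(subject_id = glob$subject_id, phenotype = "global_sum",
                     value = glob$value, hemisphere = glob$hemisphere,
                     modality = "cortical")
  rbind(lobar, glob)
}

#' Mean +/- k SD outlier inclusion mask
#'
#' Single-pass exclusion of values more than `k` sample standard deviations
#' from the sample mean (no iterative re-estimation). Scope is the caller's
#' choice: pass a single phenotype's values for per-phenotype exclusion, or
#' a modality-level PC composite (see [derive_composite_pc()]) for
#' modality-global exclusion.
#'
#' @param values numeric vector (names preserved in the mask).
#' @param k SD multiplier (default 3).
#' @return logical inclusion mask (TRUE = keep), with attribute
#'   `n_excluded`.
#' @export
exclude_outliers <- function(values, k = 3) {
  s <- sd(values, na.rm = TRUE)
  .assert(is.finite(s) && s > 0, "SD is zero: outlier exclusion undefined")
  mu <- mean(values, na.rm = TRUE)
  mask <- abs(values - mu) <= k * s
  mask[is.na(mask)] <- TRUE          # missing values are not excluded here
  attr(mask, "n_excluded") <- sum(!mask)
  mask
}

#' Remove listed subjects from a table
#' @param table data.table with a `subject_id` column.
#' @param exclusion_ids subject ids to drop (possibly empty).
#' @return filtered table.
#' @export
filter_subjects <- function(table, exclusion_ids) {
  if (length(exclusion_ids) == 0) return(table)
  table[!table$subject_id %in% exclusion_ids, ]
}
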