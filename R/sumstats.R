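#' Read GWAS summary statistics from TSV
#'
#' Parses a header-ed TSV into the package's internal column layout. Either a
#' BETA or an OR column must be present; odds ratios are converted to the
#' log-odds scale at read time (`beta = log(OR)`) so a single effect scale is
#' used internally. Alleles are upper-cased. No filtering is applied here.
#'
#' @param path TSV file with header.
#' @param column_map named character vector mapping internal fields
#'   (`snp_id, chrom, pos, effect_allele, other_allele, beta, or, se, pval,
#'   info, maf`) to file column names. Defaults follow the common
#'   SNP/CHR/BP/A1/A2/BETA/OR/SE/P/INFO/MAF convention.
#' @return data.table with columns `snp_id, chrom, pos, effect_allele,
#'   other_allele, beta, se, pval` and, when present in the file, `info` and
#'   `maf`.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  defaults <- c(snp_id = "SNP", chrom = "CHR", pos = "BP",
                effect_allele = "A1", other_allele = "A2", beta = "BETA",
                or = "OR", se = "SE", pval = "P", info = "INFO", maf = "MAF")
  map <- defaults
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  raw <- fread(path, header = TRUE)

  need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "se", "pval")
  for (f in need)
    .assert(map[[f]] %in% names(raw),
            sprintf("required column '%s' (field %s) missing from %s",
                    map[[f]], f, path))
  has_beta <- map[["beta"]] %in% names(raw)
  has_or <- map[["or"]] %in% names(raw)
  .assert(has_beta || has_or,
          sprintf("neither effect column '%s' nor '%s' found in %s",
                  map[["beta"]], map[["or"]], path))

  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    .assert(!any(is.na(v) & !is.na(x)),
            sprintf("unparseable numeric value in column %s", what))
    v
  }
  ss <- data.table(
    snp_id = as.character(raw[[map[["snp_id"]]]]),
    chrom = raw[[map[["chrom"]]]],
    pos = as.integer(raw[[map[["pos"]]]]),
    effect_allele = toupper(as.character(raw[[map[["effect_allele"]]]])),
    other_allele = toupper(as.character(raw[[map[["other_allele"]]]])),
    beta = if (has_beta) num(raw[[map[["beta"]]]], map[["beta"]]) else
      log(num(raw[[map[["or"]]]], map[["or"]])),
    se = num(raw[[map[["se"]]]], map[["se"]]),
    pval = num(raw[[map[["pval"]]]], map[["pval"]]))
  if (map[["info"]] %in% names(raw))
    ss$info <- num(raw[[map[["info"]]]], map[["info"]])
  if (map[["maf"]] %in% names(raw))
    ss$maf <- num(raw[[map[["maf"]]]], map[["maf"]])
  .assert(all(ss$pval > 0 & ss$pval <= 1),
          "p-values must lie in (0, 1]")
  ss[]
}

.ambiguous <- function(a1, a2)
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")

#' Quality-control summary statistics
#'
#' Applies, in order: duplicate removal (all copies of a duplicated snp_id
#' are dropped — the correct record cannot be adjudicated), strand-ambiguous
#' A/T and C/G removal, MAF filtering and INFO filtering (the latter two only
#' when the columns exist). The report reconciles exactly:
#' input = retained + sum(removed).
#'
#' @param ss summary statistics from [read_sumstats()].
#' @param maf_min minimum minor-allele frequency.
#' @param info_min minimum imputation INFO score.
#' @param drop_ambiguous drop strand-ambiguous SNPs?
#' @param drop_duplicates drop duplicated snp_ids?
#' @return list with `sumstats` (filtered table) and `report` (list of class
#'   `qc_report`: n_input, n_duplicate, n_ambiguous, n_maf, n_info,
#'   n_retained).
#' @export
qc_sumstats <- function(ss, maf_min = 0.01, info_min = 0.8,
                        drop_ambiguous = TRUE, drop_duplicates = TRUE) {
  n_input <- nrow(ss)
  rep <- list(n_input = n_input, n_duplicate = 0L, n_ambiguous = 0L,
              n_maf = 0L, n_info = 0L)
  if (drop_duplicates) {
    dup_ids <- unique(ss$snp_id[duplicated(ss$snp_id)])
    keep <- !(ss$snp_id %in% dup_ids)
    rep$n_duplicate <- sum(!keep)
    ss <- ss[keep]
  }
  if (drop_ambiguous) {
    amb <- .ambiguous(ss$effect_allele, ss$other_allele)
    rep$n_ambiguous <- sum(amb)
    ss <- ss[!amb]
  }
  if (!is.null(ss$maf)) {
    low <- pmin(ss$maf, 1 - ss$maf) < maf_min
    rep$n_maf <- sum(low)
    ss <- ss[!low]
  }
  if (!is.null(ss$info)) {
    low <- ss$info < info_min
    rep$n_info <- sum(low)
    ss <- ss[!low]
  }
  rep$n_retained <- nrow(ss)
  .assert(rep$n_retained > 0, "no SNPs survive summary-statistics QC")
  stopifnot(rep$n_input == rep$n_retained + rep$n_duplicate +
              rep$n_ambiguous + rep$n_maf + rep$n_info)
  class(rep) <- "qc_report"
  list(sumstats = ss[], report = rep)
}

#' Write a QC report as JSON
#' @param report a `qc_report`.
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}

#' Harmonize summary statistics against a genotype panel
#'
#' Matching is by snp_id. SNPs absent from the panel are dropped. Records
#' whose alleles equal the panel's but swapped have their effect negated and
#' alleles swapped, so the output effect allele always matches the panel's
#' `a1`. Records whose allele sets differ from the panel's are dropped.
#' Position disagreements are reported as a warning only (build-version
#' drift is common; identity is carried by the snp_id).
#'
#' @param ss QC'd summary statistics.
#' @param variants panel variant table (`snp_id, chrom, pos, a1, a2`).
#' @return harmonized summary statistics, allele order matching the panel.
#' @export
harmonize <- function(ss, variants) {
  m <- merge(ss, variants[, .(snp_id, panel_pos = pos, a1, a2)],
             by = "snp_id", sort = FALSE)
  if (nrow(m) == 0) return(ss[0])
  mismatch_pos <- sum(m$pos != m$panel_pos, na.rm = TRUE)
  if (mismatch_pos > 0)
    warning(sprintf("%d SNPs matched by id but disagree on position",
                    mismatch_pos))
  aligned <- m$effect_allele == m$a1 & m$other_allele == m$a2
  flipped <- m$effect_allele == m$a2 & m$other_allele == m$a1
  m <- m[aligned | flipped]
  flip <- m$effect_allele == m$a2 & m$other_allele == m$a1
  m[flip, beta := -beta]
  m[, `:=`(effect_allele = a1, other_allele = a2,
           panel_pos = NULL, a1 = NULL, a2 = NULL)]
  m[]
}
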