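#' Benjamini-Hochberg q-values within declared families
#'
#' Applies BH step-up FDR control independently inside each family (e.g. one
#' family per phenotype, members = all gene sets x predictors x thresholds).
#'
#' @param pvals numeric p-values in `(0, 1]`.
#' @param family_keys optional vector (same length) assigning each p-value to
#'   a family; NULL treats all p-values as one family.
#' @return numeric q-values, aligned with `pvals`.
#' @export
bh_fdr <- function(pvals, family_keys = NULL) {
  .assert(length(pvals) > 0, "empty p-value family")
  .assert(all(pvals > 0 & pvals <= 1), "p-values must lie in (0, 1]")
  if (is.null(family_keys)) return(p.adjust(pvals, method = "BH"))
  .assert(length(family_keys) == length(pvals),
          "family_keys length mismatch")
  q <- numeric(length(pvals))
  for (idx in split(seq_along(pvals), family_keys))
    q[idx] <- p.adjust(pvals[idx], method = "BH")
  q
}

#' Rotate a membership vector around the genome circle
#'
#' `rotated[i] = membership[(i - k) mod N]` over the position-ordered SNP
#' circle; the member count is preserved (rotation is a bijection).
#'
#' @param membership logical/0-1 vector ordered by (chrom, pos).
#' @param k offset, `0 <= k < length(membership)`.
#' @return rotated membership vector.
#' @export
circular_rotate <- function(membership, k) {
  N <- length(membership)
  .assert(length(k) == 1 && k >= 0 && k < N, "offset k must satisfy 0 <= k < N")
  if (k == 0) return(membership)
  membership[((seq_len(N) - 1 - k) %% N) + 1]
}

# exact OLS t for the set-PRS term via Frisch-Waugh-Lovell residualization:
# identical to the full joint fit (estimate, se, df) at a fraction of the cost
.fwl_t <- function(ry, rs, rw, df_resid) {
  X <- cbind(rs, rw)
  XtX <- crossprod(X)
  Xty <- crossprod(X, ry)
  b <- solve(XtX, Xty)
  rss <- sum(ry^2) - sum(b * Xty)
  sigma2 <- rss / df_resid
  se <- sqrt(sigma2 * solve(XtX)[1, 1])
  as.numeric(b[1] / se)
}

#' Circular genomic permutation test for a gene-set association
#'
#' Generates the null by rotating the gene-set membership around the
#' position-ordered circle of clumped, thresholded SNPs: each rotation keeps
#' every SNP's GWAS weight and the local LD structure intact but reassigns
#' which contiguous stretch of the genome counts as "the set". For each of
#' `n_perm` distinct nonzero offsets the set and complement PRSs are rebuilt
#' from the same weights, the same joint model is refitted, and the set-PRS
#' t (or z) statistic recorded. The empirical p-value is
#' `(r + 1) / (n_perm + 1)` with `r` = number of null statistics at least as
#' extreme (two-sided, on |t|) as the observed one.
#'
#' @param genotypes dosage matrix.
#' @param ss harmonized summary statistics (weights, positions).
#' @param clumped_snps snp ids of the post-clumping, post-thresholding
#'   universe the rotation operates on.
#' @param membership snp ids of the gene set within `clumped_snps` (or a
#'   logical vector aligned with the position-ordered circle).
#' @param y outcome: numeric vector (linear/logistic, aligned with genotype
#'   rows) or a long bilateral table for the mixed family.
#' @param covariates optional covariate data.frame (see the fit functions).
#' @param model_family "linear", "bilateral-mixed" or "logistic".
#' @param n_perm number of rotations (must be < number of SNPs on the
#'   circle).
#' @param seed RNG seed for offset sampling.
#' @return object of class `permutation_result`: `observed_t, null_t,
#'   offsets, empirical_p, n_perm, seed, n_snps, set_size,
#'   n_degenerate_redrawn`.
#' @export
permutation_test <- function(genotypes, ss, clumped_snps, membership, y,
                             covariates = NULL,
                             model_family = c("linear", "bilateral-mixed",
                                              "logistic"),
                             n_perm = 1000L, seed = 1L) {
  model_family <- match.arg(model_family)
  sub <- ss[ss$snp_id %in% clumped_snps]
  sub <- sub[order(sub$chrom, sub$pos)]
  N <- nrow(sub)
  .assert(N >= 2, "need at least 2 SNPs on the circle")
  .assert(n_perm < N,
          sprintf("cannot draw %d distinct nonzero offsets from %d SNPs",
                  n_perm, N))
  mvec <- if (is.logical(membership)) {
    .assert(length(membership) == N, "logical membership length mismatch")
    membership
  } else sub$snp_id %in% membership
  .assert(any(mvec) && !all(mvec),
          "membership must be a proper nonempty subset of the circle")

  beta <- stats::setNames(sub$beta, sub$snp_id)
  X <- genotypes[, sub$snp_id, drop = FALSE]
  storage.mode(X) <- "double"
  if (anyNA(X))
    for (j in which(colSums(is.na(X)) > 0)) {
      xj <- X[, j]; xj[is.na(xj)] <- mean(xj, na.rm = TRUE); X[, j] <- xj
    }
  C <- sweep(X, 2L, beta, `*`)      # per-SNP score contributions
  total <- rowSums(C)

  set.seed(seed)
  pool <- sample(seq_len(N - 1L))   # candidate nonzero offsets, random order
  offsets <- integer(0)
  n_degenerate <- 0L

  score_pair <- function(mv) {
    s <- as.numeric(C %*% mv)
    list(s = s, w = total - s)
  }
  obs <- score_pair(mvec)
  .assert(sd(obs$s) > 0 && sd(obs$w) > 0,
          "observed set or complement score is constant")

  fit_t <- switch(model_family,
    linear = local({
      ok <- .complete_rows(y, covariates)
      yv <- zscore(y[ok])
      D0 <- if (is.null(covariates))
        matrix(1, sum(ok), 1) else
          model.matrix(~ ., data = as.data.frame(covariates)[ok, ,
                                                             drop = FALSE])
      qr0 <- qr(D0)
      ry <- qr.resid(qr0, yv)
      df_resid <- sum(ok) - qr0$rank - 2L
      .assert(df_resid >= 1, "not enough residual degrees of freedom")
      function(sc) {
        rs <- qr.resid(qr0, zscore(sc$s[ok]))
        rw <- qr.resid(qr0, zscore(sc$w[ok]))
        .fwl_t(ry, rs, rw, df_resid)
      }
    }),
    `bilateral-mixed` = function(sc) {
      subj <- rownames(genotypes)
      res <- fit_bilateral_joint(y, stats::setNames(sc$s, subj),
                                 stats::setNames(sc$w, subj), covariates)
      res[res$predictor == "set", stat]
    },
    logistic = function(sc) {
      res <- fit_logistic_joint(y, sc$s, sc$w, covariates)
      res[res$predictor == "set", stat]
    })

  observed_t <- fit_t(obs)
  null_t <- numeric(n_perm)
  i <- 0L; p_idx <- 0L
  while (i < n_perm) {
    p_idx <- p_idx + 1L
    .assert(p_idx <= length(pool),
            "offset pool exhausted by degenerate rotations")
    k <- pool[p_idx]
    sc <- score_pair(circular_rotate(mvec, k))
    if (sd(sc$s) == 0 || sd(sc$w) == 0) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    i <- i + 1L
    offsets[i] <- k
    null_t[i] <- fit_t(sc)
  }
  if (n_degenerate > 0)
    message(sprintf("%d degenerate rotation(s) redrawn", n_degenerate))

  r <- sum(abs(null_t) >= abs(observed_t))
  structure(list(observed_t = observed_t, null_t = null_t,
                 offsets = offsets,
                 empirical_p = (r + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed, n_snps = N,
                 set_size = sum(mvec),
                 n_degenerate_redrawn = n_degenerate),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> observed t = %.3f, empirical p = %.4g (%d rotations, circle of %d SNPs, set size %d)\n",
    x$observed_t, x$empirical_p, x$n_perm, x$n_snps, x$set_size))
  invisible(x)
}
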