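# Independent oracles, coded from the definitions (not from the package
# implementation), plus small fixture builders used across test files.

library(data.table)

# Brute-force greedy clumping: full correlation matrix, explicit loop over
# SNPs in ascending-p order (ties: chrom, pos), retain iff r^2 with every
# retained SNP on the same chromosome within the window is < r2_thresh.
oracle_clump <- function(variants, genotypes, pvals, r2_thresh = 0.1,
                         window_kb = 250) {
  v <- data.frame(snp_id = variants$snp_id, chrom = variants$chrom,
                  pos = variants$pos, pval = pvals[variants$snp_id])
  v <- v[order(v$pval, v$chrom, v$pos), ]
  X <- genotypes[, v$snp_id, drop = FALSE]
  storage.mode(X) <- "double"
  for (j in seq_len(ncol(X))) {
    xj <- X[, j]
    if (anyNA(xj)) xj[is.na(xj)] <- mean(xj, na.rm = TRUE)
    X[, j] <- xj
  }
  sds <- apply(X, 2, sd)
  R <- suppressWarnings(cor(X))
  R[is.na(R)] <- 0            # zero-variance SNPs: r = 0 by convention
  w <- window_kb * 1000
  retained <- character(0)
  for (j in seq_len(nrow(v))) {
    ok <- TRUE
    for (r in retained) {
      ri <- which(v$snp_id == r)
      if (v$chrom[ri] == v$chrom[j] && abs(v$pos[ri] - v$pos[j]) <= w &&
          R[v$snp_id[j], r]^2 >= r2_thresh) { ok <- FALSE; break }
    }
    if (ok) retained <- c(retained, v$snp_id[j])
  }
  retained
}

# Benjamini-Hochberg step-up from the closed form:
# q_(i) = min_{j >= i} p_(j) * m / j, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Random clumping instance: small panel with some duplicated/correlated
# columns so nontrivial absorptions occur.
random_clump_instance <- function(n_snps = 30, n_subj = 60) {
  m <- n_snps
  chrom <- sort(sample(1:2, m, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(idx)
    sort(sample.int(5e5, length(idx)))), use.names = FALSE)
  G <- matrix(rbinom(n_subj * m, 2, 0.3), n_subj, m)
  # inject LD: some columns copy a neighbour (exact or noisy)
  for (j in which(runif(m) < 0.4 & seq_len(m) > 1)) {
    src <- j - 1
    G[, j] <- if (runif(1) < 0.5) G[, src] else
      pmin(2L, pmax(0L, G[, src] + rbinom(n_subj, 1, 0.15)))
  }
  ids <- sprintf("s%03d", seq_len(m))
  colnames(G) <- ids
  list(variants = data.table(snp_id = ids, chrom = chrom, pos = pos),
       genotypes = G,
       pvals = setNames(runif(m), ids))
}

# Small simulated study used by several files.
tiny_study <- function(seed = 11, gamma_set = 0, n = 300, m = 300, ...) {
  cfg <- sim_config(n_subjects = n, n_snps = m, n_chrom = 2,
                    gamma_set = gamma_set, seed = seed, ...)
  simulate_study(cfg, genes_per_chrom = 6, set_sizes = c(2, 2))
}

expect_setequal_chr <- function(a, b) expect_setequal(as.character(a),
                                                      as.character(b))
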