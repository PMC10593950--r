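test_that("clumping retains everything when SNPs are uncorrelated", {
  set.seed(1)
  n <- 200
  ids <- sprintf("s%d", 1:4)
  G <- sapply(1:4, function(i) rbinom(n, 2, 0.5))
  colnames(G) <- ids
  v <- data.table(snp_id = ids, chrom = 1L, pos = c(100L, 200L, 300L, 400L))
  # r2_thresh = 1 means only perfect correlation clumps; random SNPs survive
  res <- ld_clump(v, G, setNames(c(0.4, 0.1, 0.3, 0.2), ids), r2_thresh = 1)
  expect_setequal_chr(res$retained, ids)
  expect_equal(res$retained[1], "s2")          # ascending-p order
})

test_that("perfectly correlated pair keeps only the smaller p", {
  set.seed(2)
  x <- rbinom(100, 2, 0.4)
  G <- cbind(s1 = x, s2 = x)
  v <- data.table(snp_id = c("s1", "s2"), chrom = 1L, pos = c(100L, 500L))
  res <- ld_clump(v, G, c(s1 = 0.2, s2 = 0.01))
  expect_equal(res$retained, "s2")
  expect_equal(res$absorbed$snp_id, "s1")
  expect_equal(res$absorbed$index_snp, "s2")
  # out of window: both kept despite r2 = 1
  v_far <- data.table(snp_id = c("s1", "s2"), chrom = 1L,
                      pos = c(100L, 100L + 251 * 1000L))
  expect_setequal_chr(ld_clump(v_far, G, c(s1 = 0.2, s2 = 0.01))$retained,
                      c("s1", "s2"))
})

test_that("clumping matches the brute-force greedy oracle on random instances", {
  set.seed(3)
  for (i in 1:25) {
    inst <- random_clump_instance(n_snps = sample(5:50, 1))
    for (r2 in c(0.1, 0.5)) {
      got <- ld_clump(inst$variants, inst$genotypes, inst$pvals,
                      r2_thresh = r2, window_kb = 100)
      want <- oracle_clump(inst$variants, inst$genotypes, inst$pvals,
                           r2_thresh = r2, window_kb = 100)
      expect_identical(got$retained, want)
    }
  }
})

test_that("clumping validates its inputs", {
  inst <- random_clump_instance(10)
  expect_error(ld_clump(inst$variants, inst$genotypes, inst$pvals,
                        r2_thresh = 0), "r2_thresh")
  expect_error(ld_clump(inst$variants,
                        inst$genotypes[, -1, drop = FALSE], inst$pvals),
               "missing genotype column")
})

test_that("p-value thresholding counts and errors are exact", {
  ss <- data.table(snp_id = sprintf("s%d", 1:7),
                   pval = c(0.005, 0.02, 0.1, 0.2, 0.5, 0.9, 1))
  expect_setequal_chr(select_threshold(ss, 1), ss$snp_id)
  expect_setequal_chr(select_threshold(ss, 0.1), c("s1", "s2", "s3"))
  expect_error(select_threshold(ss, 0), "threshold")
  expect_error(select_threshold(ss, 1.5), "threshold")
})

test_that("scoring equals the dot-product oracle and handles missingness", {
  G <- matrix(c(0, 1, 2, 2, 0, 1), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  ss <- data.table(snp_id = c("s1", "s2"), beta = c(0.5, -1),
                   pval = c(0.1, 0.1))
  pr <- compute_prs(G, ss, c("s1", "s2"))
  expect_equal(pr$score, as.numeric(G %*% c(0.5, -1)))
  expect_equal(pr$n_snps_used, 2L)
  # all-zero weights give all-zero scores
  ss0 <- data.table::copy(ss)[, beta := 0]
  expect_equal(compute_prs(G, ss0, c("s1", "s2"))$score, rep(0, 3))
  # single SNP with beta 1: score equals the dosage
  ss1 <- data.table::copy(ss)[, beta := 1]
  expect_equal(compute_prs(G, ss1, "s1")$score, as.numeric(G[, "s1"]))
  # missing dosages are mean-imputed per SNP
  Gna <- G; Gna["b", "s1"] <- NA
  pr_na <- compute_prs(Gna, ss, c("s1", "s2"))
  expect_equal(pr_na$score[2], mean(c(0, 2)) * 0.5 + 0 * -1)
  expect_error(compute_prs(G, ss, character(0), predictor = "set",
                           threshold = 0.1), "set.*0.1")
})

test_that("standardization follows the n-1 closed form and is idempotent", {
  mk <- function(sc) structure(
    list(subject_id = letters[seq_along(sc)], score = sc, predictor = "p",
         threshold = 1, n_snps_used = 1L, standardized = FALSE),
    class = "prs_profile")
  z <- standardize_profile(mk(c(1, 3)))
  expect_equal(z$score, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  z2 <- standardize_profile(mk(rnorm(50)))
  expect_equal(standardize_profile(z2)$score, z2$score, tolerance = 1e-12)
  expect_error(standardize_profile(mk(rep(2, 5))), "constant")
})

test_that("profile correlation matches the closed form", {
  set.seed(4)
  mk <- function(sc) structure(
    list(subject_id = sprintf("i%d", seq_along(sc)), score = sc,
         predictor = "p", threshold = 1, n_snps_used = 1L,
         standardized = FALSE), class = "prs_profile")
  a <- mk(rnorm(30)); b <- mk(rnorm(30))
  expect_equal(correlate_profiles(a, a), 1)
  neg <- mk(-a$score)
  expect_equal(correlate_profiles(a, neg), -1)
  expect_equal(correlate_profiles(a, b), cor(a$score, b$score))
  expect_error(correlate_profiles(a, mk(rnorm(10))), "different subjects")
})

test_that("set plus complement equals the universe score exactly", {
  b <- tiny_study(seed = 19)
  ss <- b$sumstats
  map <- map_snps_to_genes(b$variants, b$genes, 0)
  part <- partition_by_geneset(map, b$sets, ss$snp_id)
  grid <- build_prs_grid(b$genotypes, ss, b$variants, part,
                         thresholds = c(0.1, 1), standardize = FALSE)
  for (i in which(grid$profiles$predictor == "set")) {
    T <- grid$profiles$threshold[i]
    nm <- grid$profiles$set_name[i]
    j <- which(grid$profiles$set_name == nm &
                 grid$profiles$predictor == "complement" &
                 grid$profiles$threshold == T)
    universe_T <- intersect(grid$clump$retained, select_threshold(ss, T))
    full <- compute_prs(b$genotypes, ss, universe_T)
    expect_equal(grid$profiles$profile[[i]]$score +
                   grid$profiles$profile[[j]]$score,
                 full$score, tolerance = 1e-12)
    expect_equal(grid$profiles$profile[[i]]$n_snps_used +
                   grid$profiles$profile[[j]]$n_snps_used,
                 full$n_snps_used)
  }
})

test_that("scores are invariant to SNP ordering", {
  b <- tiny_study(seed = 23, n = 100, m = 80)
  ss <- b$sumstats
  snps <- sample(ss$snp_id, 30)
  a <- compute_prs(b$genotypes, ss, snps)$score
  c2 <- compute_prs(b$genotypes, ss, rev(snps))$score
  expect_equal(a, c2, tolerance = 1e-12)
})
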