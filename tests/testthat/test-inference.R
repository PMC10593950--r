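test_that("BH q-values follow the step-up closed form", {
  expect_equal(bh_fdr(0.03), 0.03)                       # m = 1
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))                             # worked step-up case
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("families are processed independently", {
  p <- c(0.01, 0.5, 0.01, 0.9)
  keys <- c("a", "a", "b", "b")
  q <- bh_fdr(p, keys)
  expect_equal(q[1:2], bh_fdr(p[1:2]))
  expect_equal(q[3:4], bh_fdr(p[3:4]))
  # changing family b leaves family a untouched
  q2 <- bh_fdr(c(0.01, 0.5, 1e-8, 1e-7), keys)
  expect_equal(q2[1:2], q[1:2])
})

test_that("BH matches the oracle and never violates q >= p on random instances", {
  set.seed(20)
  for (i in 1:50) {
    m <- sample(1:100, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
  }
})

test_that("circular rotation shifts membership and conserves the count", {
  m <- c(1, 0, 0)
  expect_equal(circular_rotate(m, 0), m)
  expect_equal(circular_rotate(m, 1), c(0, 1, 0))
  expect_equal(circular_rotate(m, 2), c(0, 0, 1))
  expect_error(circular_rotate(m, 3), "offset")
  expect_error(circular_rotate(m, -1), "offset")
  set.seed(21)
  mm <- runif(40) < 0.3
  for (k in sample(0:39, 8))
    expect_equal(sum(circular_rotate(mm, k)), sum(mm))
  # rotations compose: k1 then k2 equals k1 + k2 (mod N)
  expect_equal(circular_rotate(circular_rotate(mm, 7), 9),
               circular_rotate(mm, 16))
})

perm_fixture <- function(seed = 22, gamma = 0, n = 400, m = 400) {
  cfg <- sim_config(n_subjects = n, n_snps = m, n_chrom = 2,
                    gamma_set = gamma, set_enrichment = 4,
                    prop_causal = 0.15, seed = seed)
  b <- simulate_study(cfg, genes_per_chrom = 6, set_sizes = 2,
                      contiguous = TRUE, n_bilateral = 0, n_global = 1)
  cl <- ld_clump(b$variants, b$genotypes,
                 setNames(b$sumstats$pval, b$sumstats$snp_id))
  circle <- intersect(cl$retained, select_threshold(b$sumstats, 1))
  members <- intersect(circle, b$membership[[1]])
  ph <- b$phenotypes[phenotype == "global_FA_1"]
  y <- ph$value[match(rownames(b$genotypes), ph$subject_id)]
  covs <- covariate_frame(b$covariates)[, -1]
  list(b = b, circle = circle, members = members, y = y, covs = covs)
}

test_that("permutation empirical p respects the (r+1)/(n+1) bounds", {
  fx <- perm_fixture(seed = 23, gamma = 0.5)
  pr <- permutation_test(fx$b$genotypes, fx$b$sumstats, fx$circle,
                         fx$members, fx$y, fx$covs, "linear",
                         n_perm = 49, seed = 1)
  expect_gt(pr$empirical_p, 0)
  expect_lte(pr$empirical_p, 1)
  expect_length(pr$null_t, 49)
  expect_length(unique(pr$offsets), 49)
  expect_false(any(pr$offsets == 0))
  if (all(abs(pr$null_t) < abs(pr$observed_t)))
    expect_equal(pr$empirical_p, 1 / 50)
  # determinism under the seed
  pr2 <- permutation_test(fx$b$genotypes, fx$b$sumstats, fx$circle,
                          fx$members, fx$y, fx$covs, "linear",
                          n_perm = 49, seed = 1)
  expect_identical(pr2$null_t, pr$null_t)
  expect_identical(pr2$empirical_p, pr$empirical_p)
})

test_that("permutation linear t matches a full joint refit", {
  fx <- perm_fixture(seed = 24, gamma = 0.3)
  pr <- permutation_test(fx$b$genotypes, fx$b$sumstats, fx$circle,
                         fx$members, fx$y, fx$covs, "linear",
                         n_perm = 5, seed = 2)
  ss <- fx$b$sumstats[fx$b$sumstats$snp_id %in% fx$circle]
  full <- fit_linear_joint(
    fx$y,
    compute_prs(fx$b$genotypes, ss, intersect(fx$circle, fx$members))$score,
    compute_prs(fx$b$genotypes, ss, setdiff(fx$circle, fx$members))$score,
    fx$covs)
  expect_equal(pr$observed_t, full[full$predictor == "set", stat],
               tolerance = 1e-8)
})

test_that("permutation rejects impossible requests", {
  fx <- perm_fixture(seed = 25)
  expect_error(
    permutation_test(fx$b$genotypes, fx$b$sumstats, fx$circle, fx$members,
                     fx$y, fx$covs, "linear",
                     n_perm = length(fx$circle), seed = 1),
    "distinct nonzero offsets")
  expect_error(
    permutation_test(fx$b$genotypes, fx$b$sumstats, fx$circle,
                     fx$circle, fx$y, fx$covs, "linear", n_perm = 5,
                     seed = 1),
    "proper nonempty subset")
})

test_that("permutation runs for logistic and mixed families", {
  cfg <- sim_config(n_subjects = 500, n_snps = 200, n_chrom = 2,
                    gamma_set = 0.3, set_enrichment = 4, prop_causal = 0.2,
                    ple_prevalence = 0.15, seed = 26)
  b <- simulate_study(cfg, genes_per_chrom = 5, set_sizes = 2,
                      contiguous = TRUE, n_bilateral = 1, n_global = 0)
  cl <- ld_clump(b$variants, b$genotypes,
                 setNames(b$sumstats$pval, b$sumstats$snp_id))
  circle <- intersect(cl$retained, select_threshold(b$sumstats, 1))
  members <- intersect(circle, b$membership[[1]])
  covs_ple <- covariate_frame(b$covariates, "ple")[, -1]
  yb <- as.numeric(b$raw_mhq$voices == "yes")
  pr_log <- permutation_test(b$genotypes, b$sumstats, circle, members,
                             yb, covs_ple, "logistic", n_perm = 9, seed = 3)
  expect_length(pr_log$null_t, 9)
  ph <- b$phenotypes[grepl("^bilat", phenotype)]
  pr_mix <- permutation_test(b$genotypes, b$sumstats, circle, members,
                             ph[, .(subject_id, hemisphere, value)], NULL,
                             "bilateral-mixed", n_perm = 5, seed = 4)
  expect_length(pr_mix$null_t, 5)
  expect_gt(pr_mix$empirical_p, 0)
})
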