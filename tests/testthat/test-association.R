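test_that("linear joint fit recovers the perfect-fit limit", {
  set.seed(8)
  n <- 200
  s <- rnorm(n); w <- rnorm(n)
  res <- fit_linear_joint(s, s, w)
  expect_equal(res[res$predictor == "set", beta_std], 1, tolerance = 1e-6)
  expect_equal(res[res$predictor == "complement", beta_std], 0,
               tolerance = 1e-6)
})

test_that("linear fit errors on saturated or collinear designs", {
  s <- c(1, 2, 3); w <- c(2, 1, 3)
  expect_error(fit_linear_joint(c(1, 2, 4), s, w), "too few cases")
  set.seed(9)
  s2 <- rnorm(50)
  expect_error(fit_linear_joint(rnorm(50), s2, s2), "collinear")
})

test_that("linear t equals beta/se and p matches the t tail", {
  set.seed(10)
  n <- 120
  s <- rnorm(n); w <- 0.3 * s + rnorm(n)
  covs <- data.frame(c1 = rnorm(n), c2 = rnorm(n))
  y <- 0.2 * s + rnorm(n)
  res <- fit_linear_joint(y, s, w, covs)
  p_design <- 1 + 2 + 2
  for (i in 1:2) {
    expect_equal(res$stat[i], res$beta_std[i] / res$se[i], tolerance = 1e-10)
    expect_equal(res$p[i], 2 * pt(-abs(res$stat[i]), df = n - p_design),
                 tolerance = 1e-10)
  }
  expect_true(all(res$p > 0 & res$p <= 1))
})

test_that("joint betas equal marginal betas for orthogonalized predictors", {
  set.seed(11)
  n <- 500
  s <- rnorm(n)
  w0 <- rnorm(n)
  w <- resid(lm(w0 ~ s))           # exactly orthogonal to s
  y <- 0.3 * scale(s)[, 1] + 0.1 * scale(w)[, 1] + rnorm(n)
  joint <- fit_linear_joint(y, s, w)
  marg_s <- coef(lm(scale(y)[, 1] ~ scale(s)[, 1]))[2]
  marg_w <- coef(lm(scale(y)[, 1] ~ scale(w)[, 1]))[2]
  expect_equal(joint[joint$predictor == "set", beta_std], as.numeric(marg_s),
               tolerance = 1e-8)
  expect_equal(joint[joint$predictor == "complement", beta_std],
               as.numeric(marg_w), tolerance = 1e-8)
})

make_bilateral <- function(n = 300, gamma = 0.15, icc = 0.5, seed = 12) {
  set.seed(seed)
  subj <- sprintf("s%d", 1:n)
  s <- rnorm(n); w <- rnorm(n)
  resid_var <- 1 - gamma^2
  u <- rnorm(n, 0, sqrt(icc * resid_var))
  eL <- rnorm(n, 0, sqrt((1 - icc) * resid_var))
  eR <- rnorm(n, 0, sqrt((1 - icc) * resid_var))
  mu <- gamma * s + u
  y_long <- data.table(subject_id = rep(subj, 2),
                       hemisphere = rep(c("L", "R"), each = n),
                       value = c(mu + eL, mu + eR))
  list(y_long = y_long, s = setNames(s, subj), w = setNames(w, subj))
}

test_that("bilateral fit collapses to pooled OLS when between-subject variance is 0", {
  d <- make_bilateral(n = 250, gamma = 0.2, icc = 0, seed = 13)
  fit <- fit_bilateral_joint(d$y_long, d$s, d$w)
  y <- zscore_oracle <- (d$y_long$value - mean(d$y_long$value)) /
    sd(d$y_long$value)
  ols <- lm(y ~ d$y_long$hemisphere + scale(d$s[d$y_long$subject_id])[, 1] +
              scale(d$w[d$y_long$subject_id])[, 1])
  expect_equal(fit[fit$predictor == "set", beta_std],
               as.numeric(coef(ols)[3]), tolerance = 0.02)
})

test_that("bilateral fit with identical hemispheres equals subject-mean OLS", {
  d <- make_bilateral(n = 250, gamma = 0.2, icc = 1, seed = 14)
  fit <- fit_bilateral_joint(d$y_long, d$s, d$w)
  means <- d$y_long[, .(value = mean(value)), by = subject_id]
  ym <- (means$value - mean(means$value)) / sd(means$value)
  ols <- lm(ym ~ scale(d$s[means$subject_id])[, 1] +
              scale(d$w[means$subject_id])[, 1])
  # the stacked z-scoring uses the pooled SD, identical here since L = R
  expect_equal(fit[fit$predictor == "set", beta_std],
               as.numeric(coef(ols)[2]), tolerance = 0.02)
})

test_that("bilateral fit drops subjects lacking a hemisphere pair", {
  d <- make_bilateral(n = 50, seed = 15)
  y_bad <- d$y_long[-1]                   # first subject loses its L row
  expect_warning(fit <- fit_bilateral_joint(y_bad, d$s, d$w), "dropping")
  expect_equal(fit$n[1], 49)
})

test_that("logistic joint fit validates the outcome and reports z-scale stats", {
  set.seed(16)
  n <- 2000
  s <- rnorm(n); w <- rnorm(n)
  eta <- -3 + 0.5 * s
  y <- rbinom(n, 1, plogis(eta))
  res <- fit_logistic_joint(y, s, w)
  expect_equal(res$model_family, rep("logistic", 2))
  expect_equal(res$stat, res$beta_std / res$se, tolerance = 1e-10)
  expect_error(fit_logistic_joint(rep(0, n), s, w), "single class")
  expect_error(fit_logistic_joint(c(y[1:10], 2), rnorm(11), rnorm(11)),
               "binary")
})

test_that("logistic fit flags complete separation instead of diverging", {
  set.seed(17)
  s <- c(rnorm(20, -4), rnorm(20, 4))
  y <- rep(c(0, 1), each = 20)
  expect_error(fit_logistic_joint(y, s, rnorm(40)), "separation")
})

test_that("covariate sets per family match the modeling protocol", {
  cfg <- sim_config(n_subjects = 20, n_snps = 30, seed = 18)
  b <- simulate_study(cfg, genes_per_chrom = 4, set_sizes = 2)
  img <- covariate_frame(b$covariates, "imaging", gray_matter = TRUE)
  expect_setequal(names(img),
                  c("subject_id", "age", "age2", "sex", sprintf("PC%d", 1:15),
                    "site", "head_x", "head_y", "head_z", "array", "icv"))
  img_wm <- covariate_frame(b$covariates, "imaging", gray_matter = FALSE)
  expect_false("icv" %in% names(img_wm))
  ple <- covariate_frame(b$covariates, "ple")
  expect_setequal(names(ple),
                  c("subject_id", "age", "sex", sprintf("PC%d", 1:15),
                    "array"))
})

test_that("null PRS coefficients are calibrated in the logistic model", {
  set.seed(19)
  covered <- 0L
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    n <- 400
    s <- rnorm(n); w <- rnorm(n)
    y <- rbinom(n, 1, 0.15)               # outcome independent of both PRSs
    res <- tryCatch(fit_logistic_joint(y, s, w), error = function(e) NULL)
    if (is.null(res)) next
    b <- res[res$predictor == "set", ]
    if (abs(b$beta_std) <= 3 * b$se) covered <- covered + 1L
  }
  expect_gte(covered / n_rep, 0.9)
})
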