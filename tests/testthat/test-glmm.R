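test_that("collapsed and expanded binomial fits are likelihood-equivalent", {
  des <- factorial_design(5, 5, 30, c(dam = 0.6, sire = 0.15,
                                      dam_sire = 0.15),
                          family = "binomial", link = "logit")
  dat <- simulate_factorial(des, seed = 7)
  spec <- model_spec("response", family = "binomial", link = "logit")
  f1 <- fit_glmm(dat, spec)
  f2 <- fit_glmm(dat, spec, collapse = FALSE)
  expect_equal(f1$variance_estimates, f2$variance_estimates,
               tolerance = 1e-3)
  expect_equal(f1$log_likelihood, f2$log_likelihood, tolerance = 1e-5)
  expect_equal(f1$n_obs, nrow(dat))
})

test_that("count-pair input matches the expanded binary fit", {
  counts <- make_count_table(n_fam = 12, seed = 5)
  expanded <- expand_binary(counts, "alive", "dead")
  f_cnt <- fit_glmm(counts, model_spec("alive", family = "binomial",
                                       failures = "dead"))
  f_bin <- fit_glmm(expanded, model_spec("status", family = "binomial"))
  expect_equal(f_cnt$variance_estimates, f_bin$variance_estimates,
               tolerance = 1e-4)
  expect_equal(f_cnt$log_likelihood, f_bin$log_likelihood, tolerance = 1e-5)
  expect_equal(f_cnt$n_obs, nrow(expanded))
})

test_that("null binary data give near-zero component estimates", {
  n_seed <- 50
  est <- matrix(NA_real_, n_seed, 3)
  des <- factorial_design(11, 11, 30, c(dam = 0, sire = 0, dam_sire = 0),
                          family = "binomial", link = "logit")
  spec <- model_spec("response", family = "binomial")
  for (i in seq_len(n_seed)) {
    dat <- simulate_factorial(des, seed = 8000 + i)
    f <- fit_glmm(dat, spec)
    est[i, ] <- f$variance_estimates[c("dam", "sire", "dam_sire")]
  }
  expect_true(all(colMeans(est) < 0.02))
})

test_that("logit and probit fits preserve the component rank order", {
  des <- factorial_design(8, 8, 60, c(dam = 0.9, sire = 0.3,
                                      dam_sire = 0.1),
                          family = "binomial", link = "logit")
  dat <- simulate_factorial(des, seed = 17)
  fl <- fit_glmm(dat, model_spec("response", family = "binomial",
                                 link = "logit"))
  fp <- fit_glmm(dat, model_spec("response", family = "binomial",
                                 link = "probit"))
  pl <- decompose(fl)$percent[c("dam", "sire", "dam_sire")]
  pp <- decompose(fp)$percent[c("dam", "sire", "dam_sire")]
  expect_equal(order(pl), order(pp))
})

test_that("relabeling 0/1 flips the intercept but not the components", {
  des <- factorial_design(6, 6, 40, c(dam = 0.5, sire = 0.2,
                                      dam_sire = 0.2),
                          family = "binomial", link = "logit")
  dat <- simulate_factorial(des, seed = 23)
  spec <- model_spec("response", family = "binomial")
  f1 <- fit_glmm(dat, spec)
  dat2 <- dat
  dat2$response <- 1L - dat2$response
  f2 <- fit_glmm(dat2, spec)
  expect_equal(f1$variance_estimates, f2$variance_estimates,
               tolerance = 5e-3)
  expect_equal(unname(f1$fixed_estimates[1]),
               -unname(f2$fixed_estimates[1]), tolerance = 5e-3)
})

test_that("overdispersion machinery detects (only) real overdispersion", {
  # clean poisson: OLRE variance near zero, test non-significant
  des <- factorial_design(8, 8, 20, c(dam = 0.3, sire = 0.1,
                                      dam_sire = 0.1),
                          family = "poisson", link = "log", intercept = 1)
  dat <- simulate_factorial(des, seed = 31)
  qp <- model_spec("response", family = "quasipoisson")
  clean <- overdispersion_test(dat, qp)
  expect_lt(clean$olre_variance, 0.05)
  expect_gt(clean$p_value, 0.05)

  # lognormal extra-noise multiplier on the rate: strongly significant
  set.seed(32)
  dat2 <- dat
  dat2$response <- rpois(nrow(dat2),
                         exp(1 + rnorm(nrow(dat2), 0, 0.7)))
  over <- overdispersion_test(dat2, qp)
  expect_lt(over$p_value, 0.05)
  expect_gt(over$olre_variance, 0.05)
})

test_that("binary responses are rejected by the quasi-families", {
  d <- data.frame(dam = rep(c("a", "b"), 10), sire = rep(c("x", "y"), 10),
                  status = rep(0:1, 10))
  expect_error(
    fit_glmm(d, model_spec("status", family = "quasibinomial")),
    "no overdispersion with binary data")
  expect_error(
    overdispersion_test(d, model_spec("status", family = "binomial")),
    "quasibinomial or quasipoisson")
})

test_that("poisson/log fits populate the random-effects-only intercept", {
  des <- factorial_design(6, 6, 20, c(dam = 0.3, sire = 0.1,
                                      dam_sire = 0.1),
                          family = "poisson", link = "log", intercept = 1,
                          fixed = c(x = 0.3))
  dat <- simulate_factorial(des, seed = 37)
  f <- fit_glmm(dat, model_spec("response", family = "poisson",
                                fixed = "x"))
  expect_false(is.null(f$intercept_only_beta0))
  rv <- residual_variance(f)
  expect_equal(rv, log(1 / exp(f$intercept_only_beta0) + 1))
  # without fixed effects the model's own intercept is beta0
  f0 <- fit_glmm(dat, model_spec("response", family = "poisson"))
  expect_equal(f0$intercept_only_beta0, unname(f0$fixed_estimates[1]))
  expect_equal(f$intercept_only_beta0, f0$intercept_only_beta0,
               tolerance = 0.05)
})

test_that("binomial parameter recovery at small scale", {
  n_seed <- 30
  est <- matrix(NA_real_, n_seed, 3)
  des <- factorial_design(8, 8, 100, c(dam = 0.62, sire = 0.16,
                                       dam_sire = 0.16),
                          family = "binomial", link = "logit")
  spec <- model_spec("response", family = "binomial")
  for (i in seq_len(n_seed)) {
    dat <- simulate_factorial(des, seed = 9000 + i)
    f <- fit_glmm(dat, spec)
    est[i, ] <- f$variance_estimates[c("dam", "sire", "dam_sire")]
  }
  truth <- c(0.62, 0.16, 0.16)
  mc_se <- apply(est, 2, sd) / sqrt(n_seed)
  # sire and interaction are close to unbiased; the dam component carries
  # the deterministic ML few-levels + Laplace downward bias (~ truth/n_dam
  # and more; see the methods vignette), so only its magnitude is checked
  expect_true(all(abs(colMeans(est)[2:3] - truth[2:3]) <
                    3 * mc_se[2:3] + 0.02))
  expect_lt(abs(mean(est[, 1]) - truth[1]), 0.3 * truth[1])
  expect_gt(mean(est[, 1]), 0.5 * truth[1])
})
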