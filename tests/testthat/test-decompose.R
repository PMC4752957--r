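test_that("latent-scale residual constants are exact", {
  expect_identical(residual_variance(family = "binomial", link = "probit"),
                   1)
  expect_identical(residual_variance(family = "poisson", link = "sqrt"),
                   0.25)
  expect_equal(residual_variance(family = "binomial", link = "logit"),
               pi^2 / 3)
  expect_equal(residual_variance(family = "poisson", link = "log",
                                 beta0 = 0), log(2))
  # quasi-families inherit their base family's rule
  expect_equal(residual_variance(family = "quasibinomial", link = "logit"),
               pi^2 / 3)
  expect_error(residual_variance(family = "binomial", link = "log"),
               "unsupported")
  expect_error(residual_variance(family = "poisson", link = "log"),
               "beta0")
})

test_that("fixed-group variance is the n-1 variance of X beta", {
  X <- cbind(1, c(0, 1, 0, 1))
  expect_equal(fixed_group_variance(X, c(0, 2)), var(c(0, 2, 0, 2)))
  expect_equal(fixed_group_variance(X, c(0, 2)), 4 / 3)
  expect_equal(fixed_group_variance(matrix(1, 4, 1), 3), 0)  # intercept only
  expect_equal(fixed_group_variance(X, c(0, 0)), 0)
  expect_error(fixed_group_variance(X, c(1, 2, 3)), "shape error")
  # weighted computation equals the expanded equivalent
  Xw <- cbind(1, c(0, 1))
  w <- c(3, 2)
  Xe <- cbind(1, c(0, 0, 0, 1, 1))
  expect_equal(fixed_group_variance(Xw, c(1, 2), weights = w),
               fixed_group_variance(Xe, c(1, 2)))
})

test_that("decomposition identities hold for direct component input", {
  d <- variance_decomposition(c(dam = 1, sire = 1, dam_sire = 1,
                                residual = 1))
  expect_equal(d$total, 4)
  expect_equal(unname(d$derived_raw), c(4, 4, 0))
  expect_equal(unname(d$percent), rep(25, 4))
  expect_equal(unname(d$derived_percent), c(100, 100, 0))

  z <- variance_decomposition(c(dam = 0.3, sire = 0, dam_sire = 0.1,
                                residual = 1))
  expect_equal(unname(z$derived_raw["additive"]), 0)
  expect_equal(unname(z$derived_raw["maternal"]), unname(z$raw["dam"]))
})

test_that("worked-example percentages are internally consistent", {
  d <- variance_decomposition(c(dam = 0.6224, sire = 0.1609,
                                dam_sire = 0.1609, residual = pi^2 / 3))
  expect_equal(unname(d$percent["dam"]), 14.7, tolerance = 0.01)
  expect_equal(unname(d$percent["sire"]), 3.8, tolerance = 0.01)
  expect_equal(unname(d$percent["dam_sire"]), 3.8, tolerance = 0.01)
  printed <- c(additive = 15.0, nonadditive = 15.1, maternal = 11.0)
  expect_true(all(abs(d$derived_percent - printed) <= 0.3))
})

test_that("percentages sum to 100 and respect scale equivariance", {
  set.seed(5)
  for (i in 1:10) {
    raw <- setNames(runif(5), c("dam", "sire", "dam_sire", "fixed_group",
                                "residual"))
    d <- variance_decomposition(raw)
    expect_equal(sum(d$percent), 100, tolerance = 1e-9)
  }
  dat <- make_gaussian_factorial(5, 5, 8, 0.4, 0.1, 0.1, 1, seed = 71)
  d1 <- decompose(fit_lmm(dat, model_spec("y")))
  dat$y <- 3 * dat$y
  d2 <- decompose(fit_lmm(dat, model_spec("y")))
  expect_equal(d2$raw, 9 * d1$raw, tolerance = 1e-3)
  expect_equal(d2$percent, d1$percent, tolerance = 1e-3)
})

test_that("negative maternal variance is reported, never clipped", {
  d <- variance_decomposition(c(dam = 0.1, sire = 0.4, dam_sire = 0.1,
                                residual = 1))
  expect_lt(d$derived_raw["maternal"], 0)
  expect_equal(unname(d$derived_raw["maternal"]), -0.3)
})

test_that("zero total variance is flagged degenerate with zero percents", {
  d <- variance_decomposition(c(dam = 0, sire = 0, dam_sire = 0,
                                residual = 0))
  expect_true(d$degenerate)
  expect_true(all(d$percent == 0))
  expect_true(all(d$derived_percent == 0))
})

test_that("decompose wires model fields into the table", {
  des <- factorial_design(5, 5, 40, c(dam = 0.5, sire = 0.2,
                                      dam_sire = 0.2),
                          family = "binomial", link = "logit")
  dat <- simulate_factorial(des, seed = 73)
  f <- fit_glmm(dat, model_spec("response", family = "binomial"))
  d <- decompose(f)
  expect_equal(unname(d$raw["residual"]), pi^2 / 3)
  expect_equal(unname(d$derived_raw["additive"]),
               4 * unname(f$variance_estimates["sire"]))
  expect_equal(unname(d$derived_raw["nonadditive"]),
               4 * unname(f$variance_estimates["dam_sire"]))
  expect_equal(unname(d$derived_raw["maternal"]),
               unname(f$variance_estimates["dam"] -
                        f$variance_estimates["sire"]))
  expect_equal(sum(d$raw), d$total)
})
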