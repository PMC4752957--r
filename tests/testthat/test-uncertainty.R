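make_small_design <- function(seed = 91) {
  des <- factorial_design(5, 5, 4, c(dam = 0.5, sire = 0.2, dam_sire = 0.2,
                                     residual = 1), replicates = 2)
  simulate_factorial(des, seed = seed)
}

test_that("stratified resampling reproduces stratum sizes exactly", {
  dat <- make_small_design()
  rs <- resample_by_replicate(dat, iterations = 4, seed = 1)
  expect_equal(nrow(rs), 4 * nrow(dat))
  for (it in 1:4) {
    chunk <- rs[rs$.iteration == it, ]
    expect_equal(table(chunk$family, chunk$replicate),
                 table(dat$family, dat$replicate))
  }
  rs_f <- resample_by_family(dat, iterations = 3, seed = 2)
  expect_equal(as.vector(table(rs_f$.iteration)),
               rep(nrow(dat), 3))
})

test_that("resampling is seed-reproducible and seed-sensitive", {
  dat <- make_small_design()
  a <- resample_by_family(dat, 5, seed = 42)
  b <- resample_by_family(dat, 5, seed = 42)
  c <- resample_by_family(dat, 5, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a$response, c$response))
})

test_that("a singleton stratum is duplicated every iteration", {
  d <- data.frame(dam = c("a", "a", "b", "b"), sire = c("x", "y", "x", "y"),
                  y = 1:4)
  rs <- resample_by_family(d, 10, seed = 3)
  expect_true(all(tapply(rs$y, rs$family, function(v) length(unique(v))) == 1))
})

test_that("per-stratum shards are written and merge to the full set", {
  dat <- make_small_design()
  dir <- withr::local_tempdir()
  rs <- resample_by_family(dat, 2, seed = 9, dir = dir)
  files <- list.files(dir, pattern = "^resample_")
  expect_equal(length(files), nlevels(droplevels(dat$family)) + 1L)
  merged <- read_table_csv(file.path(dir, "resample_merged.csv"))
  expect_equal(nrow(merged), nrow(rs))
})

test_that("fit_resampled returns one row per requested iteration", {
  dat <- make_small_design()
  rs <- resample_by_family(dat, 12, seed = 5)
  cm <- fit_resampled(rs, model_spec("response"), start = 2, end = 11,
                      engine = "ems")
  expect_equal(nrow(cm), 10L)
  expect_equal(cm$iteration, 2:11)
  # raw base components sum to the total on every row
  base <- cm$dam + cm$sire + cm$dam_sire + cm$fixed_group + cm$residual
  expect_equal(base, cm$total, tolerance = 1e-9)
  expect_equal(cm$additive, 4 * cm$sire)
  expect_equal(cm$maternal, cm$dam - cm$sire)
})

test_that("ems and lme4 engines agree on resampled fits", {
  dat <- make_small_design()
  rs <- resample_by_family(dat, 3, seed = 6)
  spec <- model_spec("response")
  cm_ems <- fit_resampled(rs, spec, engine = "ems")
  cm_lme <- fit_resampled(rs, spec, engine = "lme4")
  # EMS equals REML only at interior solutions: when a moment estimate is
  # truncated at zero the REML optimum redistributes the other components,
  # so boundary rows are excluded from the comparison
  interior <- apply(cm_ems[c("dam", "sire", "dam_sire")], 1,
                    function(v) all(v > 0.02))
  expect_gt(sum(interior), 0)
  for (cl in c("dam", "sire", "dam_sire", "residual")) {
    expect_equal(cm_ems[[cl]][interior], cm_lme[[cl]][interior],
                 tolerance = 1e-4)
  }
})

test_that("degenerate resampling reproduces the observed components", {
  # singleton family-by-replicate strata: resampling must return the data
  d <- expand.grid(dam = sprintf("D%d", 1:4), sire = sprintf("S%d", 1:4),
                   replicate = c("R1", "R2"))
  set.seed(8)
  d$y <- rnorm(nrow(d))
  rs <- resample_by_replicate(d, 3, seed = 10)
  spec <- model_spec("y")
  cm <- fit_resampled(rs, spec)
  obs <- decompose(fit_lmm(d, spec))
  for (cl in c("dam", "sire", "residual")) {
    expect_equal(cm[[cl]], rep(unname(obs$raw[cl]), 3), tolerance = 1e-6)
  }
  expect_equal(cm$total, rep(obs$total, 3), tolerance = 1e-6)
})

test_that("bootstrap component means track the observed components", {
  dat <- simulate_factorial(
    factorial_design(6, 6, 10, c(dam = 0.5, sire = 0.2, dam_sire = 0.2,
                                 residual = 1)), seed = 92)
  rs <- resample_by_family(dat, 200, seed = 93)
  cm <- fit_resampled(rs, model_spec("response"), engine = "ems")
  obs <- fit_ems(dat, "response")$variance_estimates
  r <- 10
  # dam and sire refit means track the observed values; residual (and the
  # interaction, which absorbs the shift) carry the O(1/r) within-stratum
  # resampling bias E[boot MS_E] = (r-1)/r MS_E
  for (cl in c("dam", "sire")) {
    mc_se <- sd(cm[[cl]]) / sqrt(nrow(cm))
    expect_lt(abs(mean(cm[[cl]]) - obs[cl]), max(10 * mc_se, 0.05))
  }
  for (cl in c("dam_sire", "residual")) {
    mc_se <- sd(cm[[cl]]) / sqrt(nrow(cm))
    expect_lt(abs(mean(cm[[cl]]) - obs[cl]),
              obs["residual"] / r + 10 * mc_se + 0.02)
  }
})

test_that("definition-7 quantiles drive the bootstrap intervals", {
  cm <- fake_component_matrix(1:1000)
  iv <- ci_bootstrap_t(cm, level = 95)
  row <- iv$raw[iv$raw$component == "dam", ]
  expect_equal(row$lower, 25.975)
  expect_equal(row$center, 500.5)
  expect_equal(row$upper, 975.025)

  const <- ci_bootstrap_t(fake_component_matrix(rep(7, 200)))
  crow <- const$raw[const$raw$component == "dam", ]
  expect_equal(unname(unlist(crow[-1])), c(7, 7, 7))
})

test_that("BCa with zero bias and acceleration equals the percentile CI", {
  # bootstrap symmetric about the observed value -> median fraction 0.5;
  # symmetric jackknife deviations -> acceleration 0
  x <- c(seq(-1, -0.001, length.out = 500), seq(0.001, 1, length.out = 500))
  cm <- fake_component_matrix(5 + x, total = rep(10, 1000))
  jk <- fake_component_matrix(5 + c(-0.2, -0.1, 0.1, 0.2),
                              total = rep(10, 4))
  obs <- data.frame(iteration = 1, dam = 5, total = 10)
  plain <- ci_bootstrap_t(cm, level = 95)
  bca <- ci_bootstrap_t(cm, level = 95, observed = obs, jack = jk)
  expect_equal(bca$raw, plain$raw, tolerance = 1e-12)
  expect_equal(bca$correction, "BCa")
  expect_error(ci_bootstrap_t(cm, observed = obs, bca = TRUE),
               "configuration error")
})

test_that("group comparison implements the one-tailed proportion rule", {
  a <- fake_component_matrix(rep(2, 1000))
  b <- fake_component_matrix(rep(1, 1000))
  expect_equal(compare_groups(a, b, "dam")$p_value, 0)

  alt <- fake_component_matrix(1000 + rep(c(1, -1), 500))
  base <- fake_component_matrix(rep(1000, 1000))
  expect_equal(compare_groups(alt, base, "dam")$p_value, 0.5)

  set.seed(14)
  diffs <- c(-abs(rnorm(49)), abs(rnorm(951)))[sample(1000)]
  g1 <- fake_component_matrix(rep(0, 1000))
  g2 <- fake_component_matrix(-diffs)
  res <- compare_groups(g1, g2, "dam")
  expect_equal(res$p_value, 0.049)
  expect_equal(res$n_less, 49)

  expect_error(compare_groups(fake_component_matrix(1:5),
                              fake_component_matrix(1:6), "dam"),
               "equal iteration counts")
  expect_warning(self <- compare_groups(a, a, "dam"), "tied")
  expect_equal(self$p_value, 0)
  expect_equal(self$ties, 1000)
})

test_that("jackknife fits honor delete-one and delete-d row counts", {
  des <- factorial_design(5, 5, 4, c(dam = 0.5, sire = 0.2, dam_sire = 0.2,
                                     residual = 1))
  dat <- simulate_factorial(des, seed = 95)   # N = 100
  spec <- model_spec("response")
  jk1 <- jackknife_fit(dat, spec, d = 1)
  expect_equal(nrow(jk1), 100L)
  expect_equal(attr(jk1, "d"), 1L)
  # delete-one means stay within O(1/N) of the observed components
  obs <- decompose(fit_lmm(dat, spec))
  for (cl in c("dam", "sire", "dam_sire", "residual")) {
    expect_lt(abs(mean(jk1[[cl]]) - obs$raw[cl]), 10 / nrow(dat))
  }

  dat105 <- rbind(dat, dat[1:5, ])           # N = 105, d = 10 -> 10 rows
  jk10 <- jackknife_fit(dat105, spec, d = 10, seed = 96)
  expect_equal(nrow(jk10), 10L)
  expect_equal(attr(jk10, "N"), 105L)
  expect_error(jackknife_fit(dat, spec, d = 100), "usage error")
})

test_that("jackknife intervals use pseudo-values with M = N/d df", {
  # statistic = sample mean: pseudo-values equal the raw observations
  set.seed(15)
  x <- rnorm(25, 10, 2)
  loo <- vapply(seq_along(x), function(i) mean(x[-i]), numeric(1))
  mat <- fake_component_matrix(loo, total = loo, d = 1L, N = 25L)
  obs <- data.frame(iteration = 1, dam = mean(x), total = mean(x))
  iv <- ci_jackknife(mat, obs, level = 95)
  row <- iv$raw[iv$raw$component == "dam", ]
  expect_equal(row$center, mean(x), tolerance = 1e-12)
  # sd(pseudo) = sd(x) exactly, half-width = t(.975, df=N) * sd/sqrt(N)
  expect_equal(row$upper - row$lower,
               2 * qt(0.975, df = 25) * sd(x) / sqrt(25), tolerance = 1e-12)
  expect_equal(iv$df, 25)

  # delete-d df bookkeeping: N = 1000, d = 10 -> df = 100
  mat2 <- fake_component_matrix(rep(1, 100), d = 10L, N = 1000L)
  obs2 <- data.frame(iteration = 1, dam = 1, total = 1)
  expect_equal(ci_jackknife(mat2, obs2)$df, 100)

  # all leave-outs equal to observed -> degenerate interval at observed
  mat3 <- fake_component_matrix(rep(3, 50), d = 1L, N = 50L)
  obs3 <- data.frame(iteration = 1, dam = 3, total = 3)
  iv3 <- ci_jackknife(mat3, obs3)
  r3 <- iv3$raw[iv3$raw$component == "dam", ]
  expect_equal(unname(unlist(r3[-1])), c(3, 3, 3))

  expect_error(ci_jackknife(mat3, NULL), "configuration error")
})
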