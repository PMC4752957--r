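#' Likelihood-ratio test for a single random effect
#'
#' Compares the full model against a reduced model with the named random
#' term deleted, keeping the fixed structure identical. The test statistic
#' is `max(0, 2 * (logLik_full - logLik_reduced))`, referred to a
#' chi-squared distribution with 1 degree of freedom. Because the null
#' value of a variance lies on the boundary of the parameter space, this
#' reference is conservative; it is used as-is and not corrected.
#' `delta_AIC` and `delta_BIC` are reduced-minus-full criterion values.
#'
#' For Gaussian specs the comparison is carried out on the scale requested
#' by `scale` (`"REML"` or `"ML"`, defaulting to the spec's method);
#' nonnormal models always use ML.
#'
#' @param data an [observation_table()] (or coercible data frame).
#' @param spec a [model_spec()].
#' @param term the random term to test: `"dam"`, `"sire"`, `"dam:sire"`, an
#'   extra random term, or `"olre"` for quasi-families.
#' @param scale likelihood scale for Gaussian models.
#' @return a one-row data frame of class `vc_lrt`: `term`, `chi_sq`, `df`,
#'   `p_value`, `delta_AIC`, `delta_BIC`, `scale`.
#' @export
lrt_random <- function(data, spec, term, scale = NULL) {
  prep <- prepare_frame(data, spec)
  lrt_random_prepared(prep, term, scale)
}

# LRT p-values for several random terms, fitting the full model once
lrt_pvalues <- function(prep, terms, fast = TRUE) {
  method <- if (prep$spec$family == "gaussian") prep$spec$method else "ML"
  full <- fit_engine(prep, method = method, fast = fast)
  ll_full <- as.numeric(stats::logLik(full$fit))
  vapply(terms, function(tm) {
    col <- term_to_column(tm)
    red <- fit_engine(prep, rand_cols = setdiff(prep$rand_cols, col),
                      method = method, fast = fast)
    chi <- max(0, 2 * (ll_full - as.numeric(stats::logLik(red$fit))))
    stats::pchisq(chi, df = 1, lower.tail = FALSE)
  }, numeric(1))
}

lrt_random_prepared <- function(prep, term, scale = NULL, fast = FALSE) {
  spec <- prep$spec
  method <- if (spec$family == "gaussian") {
    scale %||% spec$method
  } else "ML"
  col <- term_to_column(term)
  olre_term <- identical(term, "olre")
  if (olre_term && !prep$olre) {
    stop("term `olre` requires a quasibinomial/quasipoisson spec",
         call. = FALSE)
  }
  if (!olre_term && !col %in% prep$rand_cols) {
    stop("`", term, "` is not a random term of this model spec",
         call. = FALSE)
  }
  full <- fit_engine(prep, method = method, fast = fast)
  reduced <- tryCatch(
    fit_engine(prep,
               rand_cols = if (olre_term) prep$rand_cols else
                 setdiff(prep$rand_cols, col),
               method = method,
               olre = prep$olre && !olre_term,
               fast = fast),
    error = function(e) {
      stop("test error: reduced model (without `", term,
           "`) failed to fit: ", conditionMessage(e), call. = FALSE)
    })
  ll_full <- as.numeric(stats::logLik(full$fit))
  ll_red <- as.numeric(stats::logLik(reduced$fit))
  chi <- max(0, 2 * (ll_full - ll_red))
  k_full <- attr(stats::logLik(full$fit), "df")
  n <- prep$n_obs
  # reduced model has one fewer variance parameter
  delta_aic <- (-2 * ll_red + 2 * (k_full - 1)) - (-2 * ll_full + 2 * k_full)
  delta_bic <- (-2 * ll_red + (k_full - 1) * log(n)) -
    (-2 * ll_full + k_full * log(n))
  structure(data.frame(
    term = term, chi_sq = chi, df = 1L,
    p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
    delta_AIC = delta_aic, delta_BIC = delta_bic,
    scale = method, stringsAsFactors = FALSE
  ), class = c("vc_lrt", "data.frame"))
}

#' Test overdispersion via the observation-level random effect
#'
#' Fits the quasi-family model with and without its observation-level
#' random effect (OLRE) by ML and compares them with a likelihood-ratio
#' test on 1 degree of freedom. A significant test indicates
#' overdispersion of the proportion or count response. Binary data cannot
#' be overdispersed and are rejected.
#'
#' @inheritParams lrt_random
#' @param spec a [model_spec()] with family `"quasibinomial"` (count-pair
#'   response) or `"quasipoisson"`.
#' @return a list with `olre_variance`, `chi_sq` and `p_value`.
#' @export
overdispersion_test <- function(data, spec) {
  if (!is_quasi(spec)) {
    stop("overdispersion_test requires a quasibinomial or quasipoisson spec",
         call. = FALSE)
  }
  prep <- prepare_frame(data, spec)
  test <- lrt_random_prepared(prep, "olre")
  with_olre <- fit_engine(prep)
  vc <- lme4::VarCorr(with_olre$fit)
  list(olre_variance = as.numeric(vc[[".olre"]][1L, 1L]),
       chi_sq = test$chi_sq, p_value = test$p_value)
}

#' Parametric-bootstrap test for a fixed effect
#'
#' Likelihood-ratio tests are unreliable for fixed effects in mixed models
#' (the denominator degrees of freedom are ill-defined), so the null
#' distribution of the ML likelihood-ratio chi-squared statistic is built
#' by simulation: `n_sim` response vectors are drawn from the ML-fitted
#' null (term-deleted) model, both models are refitted to each, and the
#' bootstrap p-value is `(1 + #(chi_sim >= chi_obs)) / (n_sim + 1)` (never
#' exactly zero). The analytic LRT p-value is reported alongside as an
#' approximation.
#'
#' @inheritParams lrt_random
#' @param term the fixed-effect term to delete under the null.
#' @param n_sim number of parametric-bootstrap simulations (>= 99).
#' @param seed optional integer seed; per-simulation sub-seeds are spawned
#'   from it.
#' @return a list of class `vc_pb`: `term`, `chi_sq_observed`,
#'   `p_parametric_bootstrap`, `n_sim`, `n_failed`, `p_LRT`, `delta_AIC`,
#'   `delta_BIC`.
#' @export
pb_fixed <- function(data, spec, term, n_sim = 500, seed = NULL) {
  if (!term %in% spec$fixed) {
    stop("`", term, "` is not a fixed term of this model spec", call. = FALSE)
  }
  if (n_sim < 99) stop("`n_sim` must be at least 99", call. = FALSE)
  spec_ml <- spec; spec_ml$method <- "ML"
  null_spec <- spec_ml; null_spec$fixed <- setdiff(spec$fixed, term)
  prep_full <- prepare_frame(data, spec_ml)
  prep_null <- prepare_frame(data, null_spec)
  full <- fit_engine(prep_full, method = "ML")
  null <- fit_engine(prep_null, method = "ML")
  ll_full <- as.numeric(stats::logLik(full$fit))
  ll_null <- as.numeric(stats::logLik(null$fit))
  chi_obs <- max(0, 2 * (ll_full - ll_null))
  k_full <- attr(stats::logLik(full$fit), "df")
  k_null <- attr(stats::logLik(null$fit), "df")
  df <- k_full - k_null
  n <- prep_full$n_obs
  delta_aic <- (-2 * ll_null + 2 * k_null) - (-2 * ll_full + 2 * k_full)
  delta_bic <- (-2 * ll_null + k_null * log(n)) -
    (-2 * ll_full + k_full * log(n))
  sims <- with_seed(seed, stats::simulate(null$fit, nsim = n_sim))
  chi_sim <- rep(NA_real_, n_sim)
  for (i in seq_len(n_sim)) {
    chi_sim[i] <- tryCatch({
      y_star <- sims[[i]]
      f1 <- suppressWarnings(suppressMessages(lme4::refit(full$fit, y_star)))
      f0 <- suppressWarnings(suppressMessages(lme4::refit(null$fit, y_star)))
      max(0, 2 * (as.numeric(stats::logLik(f1)) -
                    as.numeric(stats::logLik(f0))))
    }, error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(chi_sim))
  if (n_failed > 0.1 * n_sim) {
    stop("test error: ", n_failed, " of ", n_sim,
         " bootstrap refits failed", call. = FALSE)
  }
  ok <- chi_sim[!is.na(chi_sim)]
  p_pb <- (1 + sum(ok >= chi_obs)) / (length(ok) + 1)
  structure(list(
    term = term, chi_sq_observed = chi_obs,
    p_parametric_bootstrap = p_pb, n_sim = length(ok), n_failed = n_failed,
    p_LRT = stats::pchisq(chi_obs, df = df, lower.tail = FALSE),
    df = df, delta_AIC = delta_aic, delta_BIC = delta_bic
  ), class = "vc_pb")
}

#' Full observed-data analysis of a factorial design
#'
#' Convenience wrapper reproducing the usual single-call analysis: fits the
#' model, decomposes the variance, and runs the likelihood-ratio test for
#' every random term (including the OLRE for quasi-families).
#'
#' @inheritParams lrt_random
#' @return a list of class `vc_analysis` with `fit`, `decomposition`, and
#'   `random_tests` (one row per random term).
#' @export
analyze_factorial <- function(data, spec) {
  prep <- prepare_frame(data, spec)
  eng <- fit_engine(prep)
  fit <- extract_fit(eng, prep, if (spec$family == "gaussian") spec$method
                     else "ML")
  terms <- c(spec$random, spec$extra_random, if (is_quasi(spec)) "olre")
  tests <- do.call(rbind, lapply(terms, function(tm) {
    lrt_random_prepared(prep, tm)
  }))
  structure(list(fit = fit, decomposition = decompose(fit),
                 random_tests = tests),
            class = "vc_analysis")
}

#' @export
print.vc_analysis <- function(x, ...) {
  print(x$decomposition)
  cat("\nRandom-effect likelihood-ratio tests (df = 1)\n")
  tab <- x$random_tests
  tab$chi_sq <- signif(tab$chi_sq, 4)
  tab$p_value <- signif(tab$p_value, 4)
  tab$delta_AIC <- signif(tab$delta_AIC, 4)
  tab$delta_BIC <- signif(tab$delta_BIC, 4)
  print(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}
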