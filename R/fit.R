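# Model preparation and fitting. All fits go through prepare_frame() +
# fit_engine() so that observed fits, LRT refits, bootstrap/jackknife refits
# and power simulations share one code path.

# Build the internal model frame. For binomial data without an
# observation-level random effect, Bernoulli rows sharing every model
# variable are collapsed to (successes, failures) counts: the likelihood
# differs from the individual-level one only by a binomial-coefficient
# constant, which is subtracted from every reported log-likelihood so all
# likelihoods stay on the individual (Bernoulli) scale and cancel exactly
# in likelihood-ratio tests.
prepare_frame <- function(data, spec, collapse = TRUE) {
  data <- as_observation_table(data)
  rand_cols <- random_columns(spec)
  fixed_vars <- if (length(spec$fixed)) {
    all.vars(stats::reformulate(spec$fixed))
  } else character(0)
  need <- unique(c(rand_cols, fixed_vars))
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("model column(s) not found in data: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if ("dam" %in% rand_cols && nlevels(droplevels(data$dam)) < 2L ||
      "sire" %in% rand_cols && nlevels(droplevels(data$sire)) < 2L) {
    stop("design error: at least 2 dams and 2 sires are required",
         call. = FALSE)
  }
  if (!spec$response %in% names(data)) {
    stop("response column `", spec$response, "` not found", call. = FALSE)
  }
  y <- data[[spec$response]]
  if (anyNA(y)) stop("response contains missing values", call. = FALSE)

  fam <- base_family(spec)
  response_kind <- "numeric"
  if (fam == "binomial") {
    if (!is.null(spec$failures)) {
      check_count_cols(data, c(spec$response, spec$failures))
      response_kind <- "counts"
    } else {
      if (!all(y %in% c(0, 1))) {
        stop("binomial response must be 0/1 at the individual level ",
             "(or supply `failures` for count pairs)", call. = FALSE)
      }
      response_kind <- "binary"
    }
  } else if (fam == "poisson") {
    if (!all(is_wholenumber(y)) || any(y < 0)) {
      stop("poisson response must be non-negative integer counts",
           call. = FALSE)
    }
  } else if (!is.numeric(y)) {
    stop("gaussian response must be numeric", call. = FALSE)
  }

  olre <- is_quasi(spec)
  if (olre && response_kind == "binary") {
    stop("usage error: there is no overdispersion with binary data; ",
         "use family = \"binomial\"", call. = FALSE)
  }

  loglik_const <- 0
  model_cols <- unique(c(rand_cols, fixed_vars))
  if (response_kind == "counts") {
    frame <- data[, model_cols, drop = FALSE]
    frame$.succ <- as.integer(round(data[[spec$response]]))
    frame$.fail <- as.integer(round(data[[spec$failures]]))
    keep <- frame$.succ + frame$.fail > 0L
    frame <- frame[keep, , drop = FALSE]
    loglik_const <- sum(lchoose(frame$.succ + frame$.fail, frame$.succ))
    n_obs <- sum(frame$.succ + frame$.fail)
    lhs <- "cbind(.succ, .fail)"
    weights <- frame$.succ + frame$.fail
  } else if (response_kind == "binary" && collapse) {
    key <- do.call(paste, c(data[model_cols], list(sep = "\r")))
    first <- !duplicated(key)
    frame <- data[first, model_cols, drop = FALSE]
    succ <- rowsum(as.numeric(y), key)
    n <- rowsum(rep(1, length(y)), key)
    ord <- match(key[first], rownames(succ))
    frame$.succ <- as.integer(succ[ord, 1L])
    frame$.fail <- as.integer(n[ord, 1L] - succ[ord, 1L])
    loglik_const <- sum(lchoose(frame$.succ + frame$.fail, frame$.succ))
    n_obs <- nrow(data)
    lhs <- "cbind(.succ, .fail)"
    weights <- frame$.succ + frame$.fail
  } else {
    frame <- data[, model_cols, drop = FALSE]
    frame$.response <- y
    n_obs <- nrow(data)
    lhs <- ".response"
    weights <- rep(1, nrow(frame))
  }
  for (col in model_cols) {
    if (col %in% c("dam", "sire", "family", "replicate") ||
        col %in% if (length(spec$extra_random)) spec$extra_random else character(0)) {
      frame[[col]] <- droplevels(factor(frame[[col]]))
    }
  }
  if (olre) frame$.olre <- factor(seq_len(nrow(frame)))
  rownames(frame) <- NULL
  list(frame = frame, lhs = lhs, spec = spec, loglik_const = loglik_const,
       n_obs = n_obs, weights = weights, rand_cols = rand_cols,
       fixed_terms = spec$fixed, olre = olre)
}

build_formula <- function(prep, rand_cols = prep$rand_cols,
                          include_fixed = TRUE, olre = prep$olre) {
  fixed <- if (include_fixed && length(prep$fixed_terms)) {
    prep$fixed_terms
  } else "1"
  rand <- sprintf("(1 | %s)", rand_cols)
  if (olre) rand <- c(rand, "(1 | .olre)")
  stats::as.formula(paste(prep$lhs, "~", paste(c(fixed, rand), collapse = " + ")),
                    env = parent.frame())
}

# One lme4 fit; returns the merMod plus convergence metadata.
fit_engine <- function(prep, rand_cols = prep$rand_cols, include_fixed = TRUE,
                       method = prep$spec$method, olre = prep$olre,
                       fast = FALSE) {
  form <- build_formula(prep, rand_cols, include_fixed, olre)
  msgs <- character(0)
  handler <- function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  fam <- base_family(prep$spec)
  fit <- withCallingHandlers({
    if (fam == "gaussian") {
      # bobyqa: measurably closer to the EMS solution on balanced designs
      # than the default nloptwrap, and faster
      ctrl <- lme4::lmerControl(
        optimizer = "bobyqa",
        check.conv.singular = "ignore",
        calc.derivs = !fast)
      lme4::lmer(form, data = prep$frame, REML = method == "REML",
                 control = ctrl)
    } else {
      ctrl <- lme4::glmerControl(
        optimizer = "bobyqa",
        check.conv.singular = "ignore",
        calc.derivs = !fast)
      famobj <- if (fam == "binomial") {
        stats::binomial(link = prep$spec$link)
      } else {
        stats::poisson(link = prep$spec$link)
      }
      lme4::glmer(form, data = prep$frame, family = famobj, control = ctrl)
    }
  }, warning = handler)
  opt_ok <- isTRUE(fit@optinfo$conv$opt == 0)
  lme4_msgs <- fit@optinfo$conv$lme4$messages
  list(fit = fit, messages = c(msgs, unlist(lme4_msgs)),
       converged = opt_ok && !length(lme4_msgs))
}

extract_fit <- function(eng, prep, method) {
  fit <- eng$fit
  spec <- prep$spec
  vc <- lme4::VarCorr(fit)
  grp <- names(vc)
  est <- stats::setNames(vapply(vc, function(v) as.numeric(v[1L, 1L]),
                                numeric(1)), grp)
  olre_variance <- if (".olre" %in% grp) unname(est[".olre"]) else NULL
  est <- est[setdiff(grp, ".olre")]
  # order components: dam, sire, dam_sire, extras
  labels <- vapply(names(est), component_label, character(1))
  names(est) <- labels
  want <- c("dam", "sire", "dam_sire")
  est <- c(est[intersect(want, labels)], est[setdiff(labels, want)])
  if (base_family(spec) == "gaussian") {
    est <- c(est, residual = stats::sigma(fit)^2)
  }
  beta <- lme4::fixef(fit)
  X <- lme4::getME(fit, "X")
  xb <- as.numeric(X %*% beta)
  fgv <- if (length(beta) > 1L) weighted_var(xb, prep$weights) else 0
  k <- length(beta) + length(est) + length(olre_variance)
  ll <- as.numeric(stats::logLik(fit)) - prep$loglik_const
  beta0 <- NULL
  if (base_family(spec) == "poisson" && spec$link == "log") {
    if (length(beta) > 1L) {
      eng0 <- fit_engine(prep, include_fixed = FALSE, fast = TRUE)
      beta0 <- unname(lme4::fixef(eng0$fit)[1L])
    } else {
      beta0 <- unname(beta[1L])
    }
  }
  structure(list(
    variance_estimates = est,
    olre_variance = olre_variance,
    fixed_estimates = beta,
    fixed_group_variance = fgv,
    log_likelihood = ll,
    n_parameters = k,
    n_obs = prep$n_obs,
    method = method,
    converged = eng$converged,
    messages = eng$messages,
    family = spec$family,
    link = spec$link,
    intercept_only_beta0 = beta0,
    spec = spec,
    prep = prep,
    merMod = fit
  ), class = "vc_fit")
}

#' Fit a Gaussian linear mixed model for a factorial mating design
#'
#' Fits the standard model with crossed random intercepts for dam, sire and
#' dam-by-sire (plus any `extra_random` terms and `fixed` terms in the
#' spec) by REML or ML, and returns the variance-component estimates.
#' Variance parameters are constrained non-negative; estimates at the
#' boundary are reported as exact zeros.
#'
#' @param data an [observation_table()] (or coercible data frame).
#' @param spec a [model_spec()] with `family = "gaussian"`.
#' @return an object of class `vc_fit` with elements `variance_estimates`
#'   (named vector: dam, sire, dam_sire, extras, residual),
#'   `fixed_estimates`, `log_likelihood`, `n_parameters`, `n_obs`,
#'   `method`, `converged`, and the underlying `merMod` fit.
#' @seealso [fit_glmm()], [decompose()], [lrt_random()]
#' @export
fit_lmm <- function(data, spec) {
  if (spec$family != "gaussian") {
    stop("fit_lmm requires a gaussian spec; use fit_glmm for ",
         spec$family, call. = FALSE)
  }
  prep <- prepare_frame(data, spec)
  eng <- fit_engine(prep)
  extract_fit(eng, prep, spec$method)
}

#' Fit a binomial or Poisson generalized linear mixed model
#'
#' Fits the factorial model for nonnormal phenotypes by the Laplace
#' approximation to the marginal likelihood (ML only). Quasi-binomial and
#' quasi-Poisson specs add an observation-level random effect (OLRE) whose
#' variance absorbs, and tests for, overdispersion. For Poisson models with
#' the log link, an intercept-plus-random-effects-only refit supplies the
#' `intercept_only_beta0` used by the latent-scale residual variance.
#'
#' Binary rows that share every model variable are internally collapsed to
#' binomial counts; this is likelihood-equivalent (the binomial-coefficient
#' constant is removed so the reported log-likelihood is on the
#' individual-observation scale) and much faster on large designs. Set
#' `collapse = FALSE` to fit the expanded rows directly.
#'
#' @inheritParams fit_lmm
#' @param spec a [model_spec()] with a binomial/quasibinomial or
#'   poisson/quasipoisson family.
#' @param collapse collapse identical Bernoulli rows to binomial counts
#'   (default `TRUE`; has no effect on estimates).
#' @return a `vc_fit` (see [fit_lmm()]) with additional fields
#'   `olre_variance` (quasi-families) and `intercept_only_beta0`
#'   (poisson/log).
#' @export
fit_glmm <- function(data, spec, collapse = TRUE) {
  if (spec$family == "gaussian") {
    stop("fit_glmm requires a nonnormal spec; use fit_lmm for gaussian",
         call. = FALSE)
  }
  prep <- prepare_frame(data, spec, collapse = collapse)
  eng <- fit_engine(prep)
  extract_fit(eng, prep, "ML")
}

# family-dispatching fit used by resampling and power loops
fit_vc <- function(data, spec, ...) {
  if (spec$family == "gaussian") fit_lmm(data, spec) else fit_glmm(data, spec, ...)
}

#' Information criteria for a fitted variance-component model
#'
#' `AIC = -2 l + 2 k` and `BIC = -2 l + k log(n)`, where `k` counts all
#' fixed-effect coefficients plus all variance parameters (residual
#' included for Gaussian models) and `n` is the number of observations.
#'
#' @param model a `vc_fit` from [fit_lmm()] or [fit_glmm()], or any list
#'   with elements `log_likelihood`, `n_parameters`, `n_obs`.
#' @return a list with `AIC`, `BIC` and `logLik`.
#' @export
information_criteria <- function(model) {
  ll <- model$log_likelihood
  k <- model$n_parameters
  n <- model$n_obs
  list(AIC = -2 * ll + 2 * k, BIC = -2 * ll + k * log(n), logLik = ll)
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("Variance-component fit: %s(%s), %s%s\n", x$family, x$link,
              x$method, if (x$converged) "" else " [NOT CONVERGED]"))
  est <- x$variance_estimates
  tab <- data.frame(component = names(est), variance = unname(est))
  if (!is.null(x$olre_variance)) {
    tab <- rbind(tab, data.frame(component = "olre",
                                 variance = x$olre_variance))
  }
  print(tab, row.names = FALSE)
  ic <- information_criteria(x)
  cat(sprintf("logLik %.3f  AIC %.2f  BIC %.2f  (n = %d, k = %d)\n",
              ic$logLik, ic$AIC, ic$BIC, x$n_obs, x$n_parameters))
  invisible(x)
}

# Vectorized EMS core for a complete balanced factorial. `fi` must equal
# (di - 1) * ns + si. Returns the four truncated moment estimates.
ems_core <- function(y, di, si, fi, nd, ns, r) {
  csum <- rowsum(y, fi)
  cellm <- matrix(csum / r, nrow = ns)  # [sire, dam]
  grand <- mean(y)
  dmean <- colMeans(cellm)
  smean <- rowMeans(cellm)
  ss_e <- sum(y * y) - r * sum(cellm * cellm)
  inter <- cellm - matrix(smean, ns, nd) -
    matrix(dmean, ns, nd, byrow = TRUE) + grand
  ms_e <- ss_e / (nd * ns * (r - 1))
  ms_ds <- r * sum(inter * inter) / ((nd - 1) * (ns - 1))
  ms_d <- ns * r * sum((dmean - grand)^2) / (nd - 1)
  ms_s <- nd * r * sum((smean - grand)^2) / (ns - 1)
  c(dam = max(0, (ms_d - ms_ds) / (ns * r)),
    sire = max(0, (ms_s - ms_ds) / (nd * r)),
    dam_sire = max(0, (ms_ds - ms_e) / r),
    residual = ms_e)
}

#' Closed-form moment estimator for balanced Gaussian factorials
#'
#' Expected-mean-squares (ANOVA) estimator of the dam, sire, dam-by-sire
#' and residual variances for a balanced complete factorial with equal
#' family sizes and no fixed effects beyond the intercept. Negative moment
#' solutions are truncated at zero. On balanced data the interior solution
#' coincides with REML; this engine is orders of magnitude faster than an
#' iterative fit and is used as the fast path for large resampling loops
#' ([fit_resampled()] with `engine = "ems"`).
#'
#' @param data an [observation_table()] (or coercible data frame) forming a
#'   complete, balanced factorial.
#' @param response name of the numeric response column.
#' @return a list of class `vc_fit_ems` with `variance_estimates`
#'   (dam, sire, dam_sire, residual) and design metadata.
#' @export
fit_ems <- function(data, response) {
  data <- as_observation_table(data)
  y <- data[[response]]
  if (is.null(y) || !is.numeric(y)) {
    stop("numeric response column `", response, "` required", call. = FALSE)
  }
  dam <- droplevels(factor(data$dam)); sire <- droplevels(factor(data$sire))
  nd <- nlevels(dam); ns <- nlevels(sire)
  di <- as.integer(dam); si <- as.integer(sire)
  fi <- (di - 1L) * ns + si
  sizes <- tabulate(fi, nbins = nd * ns)
  if (any(sizes == 0L) || length(unique(sizes)) != 1L) {
    stop("fit_ems requires a complete balanced factorial ",
         "(equal family sizes, no empty cells)", call. = FALSE)
  }
  r <- sizes[1L]
  if (r < 2L) stop("fit_ems requires at least 2 observations per family",
                   call. = FALSE)
  est <- ems_core(y, di, si, fi, nd, ns, r)
  structure(list(
    variance_estimates = est,
    olre_variance = NULL,
    fixed_estimates = c(`(Intercept)` = mean(y)),
    fixed_group_variance = 0,
    log_likelihood = NA_real_,
    n_parameters = 5L,
    n_obs = length(y),
    method = "EMS",
    converged = TRUE,
    messages = character(0),
    family = "gaussian",
    link = "identity",
    intercept_only_beta0 = NULL
  ), class = c("vc_fit_ems", "vc_fit"))
}
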