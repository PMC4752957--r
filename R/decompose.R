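#' Latent-scale residual variance of a fitted model
#'
#' Nonnormal mixed models have no estimated residual variance; a
#' distribution-specific constant is assigned to the link-scale residual
#' instead: `pi^2/3` for binomial errors with the logit link, `1` for the
#' probit link, `0.25` for Poisson errors with the square-root link, and
#' `log(1/exp(beta0) + 1)` for Poisson errors with the log link, where
#' `beta0` is the intercept of the model containing only the random
#' effects. Gaussian models return their estimated residual variance.
#'
#' @param model a `vc_fit`; alternatively supply `family`, `link` (and
#'   `beta0` for poisson/log) directly.
#' @param family,link error structure, when no model is given.
#'   Quasi-families use their base family's rule.
#' @param beta0 random-effects-only model intercept (poisson/log only).
#' @return the residual variance on the latent (link) scale.
#' @examples
#' residual_variance(family = "binomial", link = "logit")   # pi^2 / 3
#' residual_variance(family = "poisson", link = "sqrt")     # 0.25
#' @export
residual_variance <- function(model = NULL, family = NULL, link = NULL,
                              beta0 = NULL) {
  if (!is.null(model)) {
    family <- model$family
    link <- model$link
    beta0 <- model$intercept_only_beta0
    if (base_family_name(family) == "gaussian") {
      return(unname(model$variance_estimates["residual"]))
    }
  }
  if (is.null(family) || is.null(link)) {
    stop("supply a fitted model or a family/link pair", call. = FALSE)
  }
  fam <- base_family_name(family)
  key <- paste(fam, link)
  switch(key,
    "gaussian identity" = stop(
      "gaussian residual variance is estimated, not a constant; ",
      "pass the fitted model", call. = FALSE),
    "binomial logit" = pi^2 / 3,
    "binomial probit" = 1,
    "poisson sqrt" = 0.25,
    "poisson log" = {
      if (is.null(beta0)) {
        stop("poisson/log residual variance requires `beta0` (the ",
             "intercept of the random-effects-only model)", call. = FALSE)
      }
      log(1 / exp(beta0) + 1)
    },
    stop("unsupported family/link pair: ", family, "/", link, call. = FALSE)
  )
}

base_family_name <- function(family) {
  switch(family,
         gaussian = "gaussian",
         binomial = , quasibinomial = "binomial",
         poisson = , quasipoisson = "poisson",
         stop("unknown family: ", family, call. = FALSE))
}

#' Variance attributable to the fixed effects as a single group
#'
#' Computes the variance (denominator `n - 1`, frequency-weighted when
#' `weights` are replication counts) of the fixed-effect contributions to
#' the linear predictor, `X %*% beta`. The intercept only shifts the
#' predictor by a constant, so its inclusion does not change the result; an
#' intercept-only model has fixed-group variance 0.
#'
#' @param design_matrix the fixed-effects design matrix `X`.
#' @param estimates the fixed-effect coefficient vector `beta`.
#' @param weights optional replication counts per row (used when rows are
#'   collapsed binomial counts).
#' @return a single non-negative number.
#' @export
fixed_group_variance <- function(design_matrix, estimates, weights = NULL) {
  design_matrix <- as.matrix(design_matrix)
  if (ncol(design_matrix) != length(estimates)) {
    stop("shape error: design matrix has ", ncol(design_matrix),
         " columns but ", length(estimates), " estimates supplied",
         call. = FALSE)
  }
  xb <- as.numeric(design_matrix %*% estimates)
  if (length(xb) < 2L) return(0)
  weighted_var(xb, weights)
}

#' Construct a variance decomposition from raw components
#'
#' Builds the full raw/percentage decomposition, including the derived
#' additive genetic (`V_A = 4 V_S`), nonadditive genetic
#' (`V_N = 4 V_DxS`) and maternal (`V_M = V_D - V_S`) components, from a
#' named vector of raw variance components. `V_M` may be negative and is
#' reported as-is. The total is the sum of all raw components and is the
#' denominator of every percentage, so the derived percentages (which
#' re-use the sire and interaction variances) can sum to more than 100.
#'
#' @param raw named numeric vector of non-derived variance components;
#'   recognized names include `dam`, `sire`, `dam_sire`, `residual`,
#'   `fixed_group`, `olre` and any extra random terms.
#' @return an object of class `vc_decomposition` with elements `raw`,
#'   `percent`, `derived_raw`, `derived_percent`, `total` and `degenerate`
#'   (TRUE when the total is zero, in which case percentages are defined
#'   as 0).
#' @export
variance_decomposition <- function(raw) {
  if (is.null(names(raw)) || any(!nzchar(names(raw)))) {
    stop("`raw` must be a fully named numeric vector", call. = FALSE)
  }
  raw <- unlist(raw)
  total <- sum(raw)
  degenerate <- total <= 0
  pct <- if (degenerate) raw * 0 else 100 * raw / total
  g <- function(nm) if (nm %in% names(raw)) unname(raw[nm]) else 0
  derived <- c(additive = 4 * g("sire"),
               nonadditive = 4 * g("dam_sire"),
               maternal = g("dam") - g("sire"))
  dpct <- if (degenerate) derived * 0 else 100 * derived / total
  structure(list(raw = raw, percent = pct, derived_raw = derived,
                 derived_percent = dpct, total = total,
                 degenerate = degenerate),
            class = "vc_decomposition")
}

#' Decompose a fitted model into raw and percentage variance components
#'
#' Extracts dam, sire, dam-by-sire, extra random-term, fixed-group,
#' observation-level (overdispersion) and residual variance components from
#' a fitted model, forms the phenotypic total as their sum, and derives the
#' additive genetic, nonadditive genetic and maternal components. For
#' nonnormal models the residual is the latent-scale constant of
#' [residual_variance()].
#'
#' @param model a `vc_fit` from [fit_lmm()], [fit_glmm()] or [fit_ems()].
#' @return a `vc_decomposition`; see [variance_decomposition()].
#' @export
decompose <- function(model) {
  est <- model$variance_estimates
  est <- est[setdiff(names(est), "residual")]
  raw <- c(est,
           if (!is.null(model$olre_variance)) c(olre = model$olre_variance),
           fixed_group = model$fixed_group_variance %||% 0,
           residual = residual_variance(model))
  variance_decomposition(raw)
}

#' @export
print.vc_decomposition <- function(x, digits = 4, ...) {
  tab <- as.data.frame(x)
  tab$raw <- signif(tab$raw, digits)
  tab$percent <- round(tab$percent, 1)  # display rounding only
  cat("Variance decomposition\n")
  print(tab, row.names = FALSE)
  if (x$degenerate) cat("(degenerate: total variance is zero)\n")
  invisible(x)
}

#' @export
as.data.frame.vc_decomposition <- function(x, ...) {
  data.frame(
    component = c(names(x$raw), "total", names(x$derived_raw)),
    raw = c(unname(x$raw), x$total, unname(x$derived_raw)),
    percent = c(unname(x$percent), if (x$degenerate) 0 else 100,
                unname(x$derived_percent)),
    stringsAsFactors = FALSE
  )
}

# flat named vector used to build component-matrix rows
decomposition_row <- function(dec) {
  c(dec$raw, total = dec$total, dec$derived_raw)
}
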