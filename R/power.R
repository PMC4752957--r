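#' Specify a factorial design for simulation and power analysis
#'
#' States the world to simulate: an `n_dam x n_sire` complete factorial
#' with a given number of offspring per family, zero-mean normal dam, sire
#' and dam-by-sire effects with the stated variances on the latent (link)
#' scale, and a Gaussian, binomial or Poisson response.
#'
#' @param n_dam,n_sire numbers of dams and sires (>= 2).
#' @param n_offspring offspring per family (total across replicates).
#' @param components named list/vector of latent-scale variances: `dam`,
#'   `sire`, `dam_sire`, and `residual` (Gaussian only); extra random
#'   sources may be added via `extras`.
#' @param family,link error structure, as in [model_spec()].
#' @param intercept latent-scale intercept; default 0 (success probability
#'   0.5 for binomial, unit rate for Poisson with log link).
#' @param replicates number of replicates per family; `n_offspring` must
#'   divide evenly across them.
#' @param fixed optional named numeric vector of slopes; for each entry a
#'   standard-normal individual-level covariate of that name is generated
#'   and its slope applied.
#' @param extras optional named list of extra random sources, each
#'   `list(variance =, n_levels =)`; levels are assigned cyclically across
#'   rows (e.g. tray or tank positions).
#' @return an object of class `factorial_design`.
#' @export
factorial_design <- function(n_dam, n_sire, n_offspring, components,
                             family = "gaussian", link = NULL,
                             intercept = 0, replicates = 1L,
                             fixed = NULL, extras = NULL) {
  family <- match.arg(family, names(VALID_LINKS))
  link <- link %||% VALID_LINKS[[family]][1L]
  if (!link %in% VALID_LINKS[[family]]) {
    stop("configuration error: link `", link, "` invalid for family `",
         family, "`", call. = FALSE)
  }
  if (n_dam < 2L || n_sire < 2L) {
    stop("`n_dam` and `n_sire` must be >= 2", call. = FALSE)
  }
  components <- unlist(components)
  need <- c("dam", "sire", "dam_sire")
  if (base_family_name(family) == "gaussian") need <- c(need, "residual")
  miss <- setdiff(need, names(components))
  if (length(miss)) {
    stop("missing component variance(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(components < 0)) stop("variances must be >= 0", call. = FALSE)
  if (n_offspring %% replicates != 0L) {
    stop("`n_offspring` must divide evenly across `replicates`",
         call. = FALSE)
  }
  structure(list(n_dam = as.integer(n_dam), n_sire = as.integer(n_sire),
                 n_offspring = as.integer(n_offspring),
                 components = components, family = family, link = link,
                 intercept = intercept, replicates = as.integer(replicates),
                 fixed = fixed, extras = extras),
            class = "factorial_design")
}

#' Simulate offspring records from a factorial design
#'
#' Draws independent dam, sire and dam-by-sire effects from zero-mean
#' normal distributions with the design's variances, adds the intercept
#' and any fixed-effect contributions on the latent scale, and samples the
#' response: Gaussian adds normal residuals; binomial and Poisson
#' transform through the inverse link and draw from the response
#' distribution. The result is bit-reproducible for a fixed seed. The
#' latent effect draws are attached as `attr(, "effects")` for
#' calibration checks.
#'
#' @param design a [factorial_design()].
#' @param seed optional integer seed.
#' @return an [observation_table()] with
#'   `n_dam * n_sire * n_offspring` rows and a `response` column.
#' @export
simulate_factorial <- function(design, seed = NULL) {
  with_seed(seed, {
    nd <- design$n_dam; ns <- design$n_sire; noff <- design$n_offspring
    cmp <- design$components
    dam_lv <- sprintf("D%03d", seq_len(nd))
    sire_lv <- sprintf("S%03d", seq_len(ns))
    dam <- rep(dam_lv, each = ns * noff)
    sire <- rep(rep(sire_lv, each = noff), nd)
    dam_eff <- stats::rnorm(nd, 0, sqrt(cmp[["dam"]]))
    sire_eff <- stats::rnorm(ns, 0, sqrt(cmp[["sire"]]))
    fam_eff <- stats::rnorm(nd * ns, 0, sqrt(cmp[["dam_sire"]]))
    fam_idx <- rep(seq_len(nd * ns), each = noff)
    eta <- design$intercept +
      dam_eff[rep(seq_len(nd), each = ns * noff)] +
      sire_eff[rep(rep(seq_len(ns), each = noff), nd)] +
      fam_eff[fam_idx]
    n <- length(eta)
    out <- data.frame(dam = dam, sire = sire, stringsAsFactors = FALSE)
    if (design$replicates > 1L) {
      out$replicate <- rep(rep(sprintf("R%d", seq_len(design$replicates)),
                               each = noff / design$replicates), nd * ns)
    }
    effects <- list(dam = dam_eff, sire = sire_eff, dam_sire = fam_eff)
    if (!is.null(design$extras)) {
      for (nm in names(design$extras)) {
        ex <- design$extras[[nm]]
        lev <- rep_len(seq_len(ex$n_levels), n)
        eff <- stats::rnorm(ex$n_levels, 0, sqrt(ex$variance))
        eta <- eta + eff[lev]
        out[[nm]] <- sprintf("%s%03d", toupper(substr(nm, 1, 1)), lev)
        effects[[nm]] <- eff
      }
    }
    if (!is.null(design$fixed)) {
      for (nm in names(design$fixed)) {
        x <- stats::rnorm(n)
        eta <- eta + design$fixed[[nm]] * x
        out[[nm]] <- x
      }
    }
    fam <- base_family_name(design$family)
    linkinv <- stats::make.link(design$link)$linkinv
    out$response <- switch(fam,
      gaussian = eta + stats::rnorm(n, 0, sqrt(cmp[["residual"]])),
      binomial = stats::rbinom(n, 1L, linkinv(eta)),
      poisson = stats::rpois(n, linkinv(eta)))
    tab <- observation_table(out,
                             replicate = if (design$replicates > 1L)
                               "replicate" else NULL)
    attr(tab, "effects") <- effects
    tab
  })
}

#' Simulation-based power analysis of variance components
#'
#' For each of `n_sim` simulations, data are generated from the design,
#' the model is fitted, and each random term's likelihood-ratio p-value is
#' computed; power per term is the proportion of p-values below `alpha`.
#' Fixed-effect terms, when present in the spec, are tested by the
#' parametric bootstrap when `n_pb_sim > 0` (expensive) and by the
#' analytic ML LRT otherwise.
#'
#' @param design a [factorial_design()].
#' @param n_sim number of simulated data sets (the reference configuration
#'   uses 500; a warning is issued below that, an error below 50).
#' @param alpha significance level.
#' @param spec optional [model_spec()]; defaults to the standard model
#'   matching the design's family, link and fixed effects.
#' @param seed optional integer seed; per-simulation sub-seeds are spawned
#'   from it.
#' @param n_pb_sim parametric-bootstrap simulations per fixed term (0 =
#'   use the analytic LRT p-value).
#' @return a list of class `vc_power`: `power` (data frame with `term`,
#'   `power`, `n_significant`, `n_sim`), `alpha`, `n_failed`, `notes`.
#' @export
power_analysis <- function(design, n_sim = 100, alpha = 0.05, spec = NULL,
                           seed = NULL, n_pb_sim = 0) {
  if (n_sim < 50) stop("`n_sim` must be >= 50", call. = FALSE)
  if (n_sim < 500) {
    message("note: n_sim = ", n_sim,
            " (the reference configuration uses 500 simulations)")
  }
  spec <- spec %||% model_spec(
    "response", family = design$family, link = design$link,
    method = if (design$family == "gaussian") "REML" else "ML",
    extra_random = names(design$extras %||% list()),
    fixed = names(design$fixed %||% list()))
  terms <- c(spec$random, spec$extra_random)
  fixed_terms <- spec$fixed
  seeds <- spawn_seeds(seed %||% sample.int(1e6, 1), n_sim)
  pvals <- matrix(NA_real_, n_sim, length(terms) + length(fixed_terms),
                  dimnames = list(NULL, c(terms, fixed_terms)))
  n_failed <- 0L
  for (i in seq_len(n_sim)) {
    res <- tryCatch({
      dat <- simulate_factorial(design, seed = seeds[i])
      prep <- prepare_frame(dat, spec)
      row <- lrt_pvalues(prep, terms, fast = TRUE)
      if (length(fixed_terms)) {
        row <- c(row, vapply(fixed_terms, function(tm) {
          if (n_pb_sim > 0) {
            pb_fixed(dat, spec, tm, n_sim = n_pb_sim,
                     seed = seeds[i])$p_parametric_bootstrap
          } else {
            pb_lrt_p(dat, spec, tm)
          }
        }, numeric(1)))
      }
      row
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else pvals[i, ] <- res
  }
  if (n_failed > 0.1 * n_sim) {
    stop("power error: ", n_failed, " of ", n_sim, " simulated fits failed",
         call. = FALSE)
  }
  ok <- stats::complete.cases(pvals)
  n_ok <- sum(ok)
  nsig <- colSums(pvals[ok, , drop = FALSE] < alpha)
  structure(list(
    power = data.frame(term = colnames(pvals),
                       power = unname(nsig) / n_ok,
                       n_significant = unname(nsig), n_sim = n_ok,
                       stringsAsFactors = FALSE),
    alpha = alpha, n_failed = n_failed,
    notes = sprintf("random terms: LRT (%s); fixed terms: %s",
                    spec$method,
                    if (n_pb_sim > 0) "parametric bootstrap" else "ML LRT")
  ), class = "vc_power")
}

# analytic ML LRT p-value for a fixed term (fast path inside power loops)
pb_lrt_p <- function(data, spec, term) {
  spec_ml <- spec; spec_ml$method <- "ML"
  null_spec <- spec_ml; null_spec$fixed <- setdiff(spec$fixed, term)
  f1 <- fit_vc(data, spec_ml)
  f0 <- fit_vc(data, null_spec)
  chi <- max(0, 2 * (f1$log_likelihood - f0$log_likelihood))
  df <- length(f1$fixed_estimates) - length(f0$fixed_estimates)
  stats::pchisq(chi, df = max(1L, df), lower.tail = FALSE)
}

#' @export
print.vc_power <- function(x, ...) {
  cat(sprintf("Power analysis (alpha = %g; %s)\n", x$alpha, x$notes))
  print(x$power, row.names = FALSE)
  if (x$n_failed > 0) cat(x$n_failed, "simulated fits failed\n")
  invisible(x)
}
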