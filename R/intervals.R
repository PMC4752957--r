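# Confidence intervals from component matrices.

matrix_component_cols <- function(mat) {
  setdiff(names(mat), "iteration")
}

# non-derived columns whose raw values sum to the total
base_component_cols <- function(mat) {
  setdiff(matrix_component_cols(mat),
          c("total", "additive", "nonadditive", "maternal"))
}

# convert every row's components to percentages of that row's total
percent_matrix <- function(mat) {
  cols <- matrix_component_cols(mat)
  if (!"total" %in% cols) {
    stop("component matrix has no `total` column; cannot form percentages",
         call. = FALSE)
  }
  out <- mat
  tot <- mat$total
  for (cl in setdiff(cols, "total")) out[[cl]] <- 100 * mat[[cl]] / tot
  out$total <- ifelse(tot > 0, 100, 0)
  out
}

# observed values (raw and percent) as named vectors aligned to `cols`
observed_values <- function(observed, cols) {
  if (inherits(observed, "vc_decomposition")) {
    raw <- c(observed$raw, total = observed$total, observed$derived_raw)
    pct <- c(observed$percent, total = 100, observed$derived_percent)
  } else if (is.data.frame(observed) && nrow(observed) == 1L) {
    raw <- unlist(observed[setdiff(names(observed), "iteration")])
    pct <- 100 * raw / raw[["total"]]
    pct[["total"]] <- 100
  } else {
    stop("`observed` must be a vc_decomposition or a one-row data frame ",
         "with the component-matrix columns", call. = FALSE)
  }
  list(raw = raw[intersect(cols, names(raw))],
       percent = pct[intersect(cols, names(pct))])
}

bca_probs <- function(x, obs, jack, probs) {
  b <- length(x)
  if (all(x == obs)) return(probs)  # constant column (e.g. percent total)
  frac <- sum(x < obs) / b
  if (frac <= 0 || frac >= 1) {
    # observed value outside the bootstrap distribution: bias constant is
    # infinite; fall back to the uncorrected probabilities with a warning
    warning("BCa bias constant undefined for a component ",
            "(observed value outside the bootstrap distribution); ",
            "uncorrected quantiles used")
    return(probs)
  }
  z0 <- stats::qnorm(frac)
  dev <- mean(jack) - jack
  denom <- sum(dev^2)^1.5
  a <- if (denom > 0) sum(dev^3) / (6 * denom) else 0
  zp <- stats::qnorm(probs)
  stats::pnorm(z0 + (z0 + zp) / (1 - a * (z0 + zp)))
}

#' Bootstrap-t (and BCa) confidence intervals for variance components
#'
#' Extracts, per component, the lower limit, median and upper limit of the
#' bootstrap distribution at the requested confidence level, using the
#' Hyndman-Fan definition-7 (linear interpolation) quantile. Intervals are
#' produced on the raw scale and on the percentage scale, where every
#' component of a row is first converted to a percentage of that row's
#' total variance.
#'
#' When the bootstrap median is far from the observed value, the BCa
#' correction of the interval limits can be requested by supplying both
#' the observed decomposition (bias correction) and a delete-one jackknife
#' component matrix (acceleration correction). With zero bias and zero
#' acceleration BCa reduces exactly to the uncorrected interval. The
#' reported center remains the plain bootstrap median.
#'
#' @param matrix a `component_matrix` from [fit_resampled()].
#' @param level confidence level as a percentage (default 95).
#' @param observed optional `vc_decomposition` of the observed data
#'   (required for BCa).
#' @param jack optional delete-one jackknife `component_matrix` (required
#'   for BCa).
#' @param bca apply the BCa correction; defaults to TRUE when both
#'   `observed` and `jack` are supplied.
#' @return a list of class `vc_intervals` with data frames `raw` and
#'   `percent` (columns `component`, `lower`, `center`, `upper`), plus
#'   `level`, `center_kind = "median"` and `correction`.
#' @export
ci_bootstrap_t <- function(matrix, level = 95, observed = NULL, jack = NULL,
                           bca = !is.null(observed) && !is.null(jack)) {
  if (bca && (is.null(observed) || is.null(jack))) {
    stop("configuration error: BCa requires both `observed` and `jack`",
         call. = FALSE)
  }
  cols <- matrix_component_cols(matrix)
  usable <- sum(stats::complete.cases(matrix[cols]))
  if (usable < 100) {
    warning("only ", usable, " usable bootstrap rows; ",
            ">= 100 are recommended")
  }
  alpha <- 1 - level / 100
  probs <- c(alpha / 2, 1 - alpha / 2)
  obs <- if (!is.null(observed)) observed_values(observed, cols)
  jk <- if (!is.null(jack)) list(raw = jack, percent = percent_matrix(jack))
  scales <- list(raw = matrix, percent = percent_matrix(matrix))
  result <- lapply(names(scales), function(sc) {
    mat <- scales[[sc]]
    rows <- lapply(cols, function(cl) {
      x <- mat[[cl]][!is.na(mat[[cl]])]
      ctr <- quantile_hf7(x, 0.5)
      pr <- probs
      if (bca && cl %in% names(obs[[sc]])) {
        pr <- bca_probs(x, obs[[sc]][[cl]], jk[[sc]][[cl]][!is.na(jk[[sc]][[cl]])],
                        probs)
      }
      lims <- quantile_hf7(x, pr)
      data.frame(component = cl, lower = lims[1L], center = ctr,
                 upper = lims[2L], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  names(result) <- names(scales)
  structure(list(raw = result$raw, percent = result$percent, level = level,
                 center_kind = "median",
                 correction = if (bca) "BCa" else "none"),
            class = "vc_intervals")
}

#' Jackknife confidence intervals from pseudo-values
#'
#' For each variance component, pseudo-values are formed from the observed
#' estimate and each leave-out refit as `M * theta_obs - (M - 1) *
#' theta_(-block)`, with `M = N / d`. The interval is the pseudo-value mean
#' plus/minus `t(alpha/2, df = M)` times the standard error of the
#' pseudo-values (`M` degrees of freedom, taken literally as `N/d`, not
#' `M - 1`). The percentage scale converts every jackknife row (and the
#' observed values) to percentages of the row total before pseudo-value
#' computation.
#'
#' @param matrix a `component_matrix` from [jackknife_fit()].
#' @param observed the observed-data `vc_decomposition` (required: the
#'   pseudo-values are anchored at the observed component values).
#' @param level confidence level as a percentage.
#' @param d,N deletion block size and total observations; default to the
#'   attributes recorded by [jackknife_fit()].
#' @return a `vc_intervals` (see [ci_bootstrap_t()]) with
#'   `center_kind = "pseudo-value mean"`.
#' @export
ci_jackknife <- function(matrix, observed, level = 95,
                         d = attr(matrix, "d"), N = attr(matrix, "N")) {
  if (is.null(observed)) {
    stop("configuration error: the observed variance components are ",
         "required to compute pseudo-values", call. = FALSE)
  }
  if (is.null(d) || is.null(N)) {
    stop("`d` and `N` must be supplied when `matrix` does not carry them",
         call. = FALSE)
  }
  cols <- matrix_component_cols(matrix)
  obs <- observed_values(observed, cols)
  alpha <- 1 - level / 100
  M <- N / d
  scales <- list(raw = matrix,
                 percent = if ("total" %in% cols) percent_matrix(matrix))
  result <- lapply(names(scales), function(sc) {
    mat <- scales[[sc]]
    if (is.null(mat)) return(NULL)
    rows <- lapply(intersect(cols, names(obs[[sc]])), function(cl) {
      x <- mat[[cl]][!is.na(mat[[cl]])]
      pseudo <- M * obs[[sc]][[cl]] - (M - 1) * x
      ctr <- mean(pseudo)
      se <- stats::sd(pseudo) / sqrt(length(pseudo))
      if (!is.finite(se)) se <- 0
      half <- stats::qt(1 - alpha / 2, df = M) * se
      data.frame(component = cl, lower = ctr - half, center = ctr,
                 upper = ctr + half, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  names(result) <- names(scales)
  structure(list(raw = result$raw, percent = result$percent, level = level,
                 center_kind = "pseudo-value mean", correction = "none",
                 df = M),
            class = "vc_intervals")
}

#' @export
print.vc_intervals <- function(x, ...) {
  cat(sprintf("%g%% confidence intervals (center: %s%s)\n", x$level,
              x$center_kind,
              if (x$correction != "none") paste0(", ", x$correction) else ""))
  cat("Raw scale:\n")
  print(x$raw, row.names = FALSE, digits = 4)
  if (!is.null(x$percent)) {
    cat("Percentage of total variance:\n")
    pr <- x$percent
    pr[-1] <- round(pr[-1], 1)
    print(pr, row.names = FALSE)
  }
  invisible(x)
}

#' Pairwise comparison of a variance component between two groups
#'
#' Given two bootstrap component matrices with equal iteration counts
#' (paired by iteration number), the difference is taken per iteration and
#' the proportion of differences below zero -- or above zero, whichever is
#' smaller -- serves as a one-tailed p-value for a group difference. With
#' 1000 iterations, fewer than 50 differences on one side declares
#' significance at alpha = 5%. Ties (exact zero differences) contribute to
#' neither count and are reported; comparing a matrix against itself
#' therefore returns p = 0 with every pair tied, flagged by the tie count.
#'
#' @param matrix_a,matrix_b `component_matrix` objects with equal row
#'   counts.
#' @param component column to compare (e.g. `"additive"`).
#' @return a list of class `vc_comparison`: `p_value`, `n_less`,
#'   `n_greater`, `ties`, `n`.
#' @export
compare_groups <- function(matrix_a, matrix_b, component) {
  if (nrow(matrix_a) != nrow(matrix_b)) {
    stop("usage error: the two groups must have equal iteration counts",
         call. = FALSE)
  }
  if (!component %in% names(matrix_a) || !component %in% names(matrix_b)) {
    stop("component `", component, "` not present in both matrices",
         call. = FALSE)
  }
  diffs <- matrix_a[[component]] - matrix_b[[component]]
  keep <- !is.na(diffs)
  diffs <- diffs[keep]
  n <- length(diffs)
  n_less <- sum(diffs < 0)
  n_greater <- sum(diffs > 0)
  ties <- n - n_less - n_greater
  if (ties > 0) {
    warning(ties, " tied difference(s) contribute to neither count")
  }
  structure(list(p_value = min(n_less, n_greater) / n,
                 n_less = n_less, n_greater = n_greater,
                 ties = ties, n = n),
            class = "vc_comparison")
}

#' @export
print.vc_comparison <- function(x, ...) {
  cat(sprintf(
    "One-tailed bootstrap comparison: p = %.4g (%d below, %d above, %d ties, n = %d)\n",
    x$p_value, x$n_less, x$n_greater, x$ties, x$n))
  invisible(x)
}
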