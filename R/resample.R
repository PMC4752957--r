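# Bootstrap resampling and per-iteration refitting.

resample_strata <- function(data, strata, iterations, seed, dir = NULL,
                            by_label = "stratum") {
  if (iterations < 1L) stop("`iterations` must be >= 1", call. = FALSE)
  idx_by_stratum <- split(seq_len(nrow(data)), strata, drop = TRUE)
  if (any(lengths(idx_by_stratum) == 0L)) {
    stop("validation error: empty ", by_label, " stratum", call. = FALSE)
  }
  n <- nrow(data)
  picks <- with_seed(seed, {
    lapply(seq_len(iterations), function(it) {
      unlist(lapply(idx_by_stratum, function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
    })
  })
  out <- data[unlist(picks, use.names = FALSE), , drop = FALSE]
  out$.iteration <- rep(seq_len(iterations), each = n)
  rownames(out) <- NULL
  if (!is.null(dir)) {
    # mirror the per-stratum shard workflow: one CSV per stratum, then the
    # merged data set
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    src_stratum <- as.character(strata)[unlist(picks, use.names = FALSE)]
    for (s in unique(src_stratum)) {
      utils::write.csv(
        out[src_stratum == s, , drop = FALSE],
        file.path(dir,
                  paste0("resample_", gsub("[^A-Za-z0-9_.-]", "_", s), ".csv")),
        row.names = FALSE)
    }
    utils::write.csv(out, file.path(dir, "resample_merged.csv"),
                     row.names = FALSE)
  }
  attr(out, "iterations") <- iterations
  class(out) <- unique(c("vc_resample", class(out)))
  out
}

#' Bootstrap resample observations within family-by-replicate strata
#'
#' For each iteration, observations are resampled with replacement within
#' every replicate-within-family stratum until the stratum's original size
#' is reproduced, so each iteration has exactly the original number of
#' rows and the design structure is preserved. The stacked result carries
#' an `.iteration` index column.
#'
#' @param data an [observation_table()] with a `replicate` column.
#' @param iterations number of bootstrap iterations (typically 1000).
#' @param seed optional integer seed for reproducibility.
#' @param dir optional directory: when given, one CSV per stratum plus the
#'   merged data set are written there (the on-disk workflow for very large
#'   designs); the merged in-memory data set is returned either way.
#' @return a data frame of class `vc_resample` with
#'   `nrow(data) * iterations` rows.
#' @export
resample_by_replicate <- function(data, iterations, seed = NULL, dir = NULL) {
  data <- as_observation_table(data)
  if (is.null(data$replicate)) {
    stop("`data` has no replicate column; use resample_by_family()",
         call. = FALSE)
  }
  strata <- interaction(data$family, data$replicate, drop = TRUE)
  resample_strata(data, strata, iterations, seed, dir,
                  by_label = "family x replicate")
}

#' Bootstrap resample observations within family strata
#'
#' As [resample_by_replicate()], with families as the strata.
#'
#' @inheritParams resample_by_replicate
#' @export
resample_by_family <- function(data, iterations, seed = NULL, dir = NULL) {
  data <- as_observation_table(data)
  resample_strata(data, droplevels(data$family), iterations, seed, dir,
                  by_label = "family")
}

component_matrix_columns <- function(spec) {
  c("dam", "sire", "dam_sire",
    vapply(spec$extra_random, component_label, character(1)),
    if (is_quasi(spec)) "olre",
    "fixed_group", "residual", "total",
    "additive", "nonadditive", "maternal")
}

fit_component_row <- function(data, spec, engine, fast = TRUE) {
  fit <- if (engine == "ems") {
    fit_ems(data, spec$response)
  } else if (spec$family == "gaussian") {
    prep <- prepare_frame(data, spec)
    extract_fit(fit_engine(prep, fast = fast), prep, spec$method)
  } else {
    prep <- prepare_frame(data, spec)
    extract_fit(fit_engine(prep, fast = fast), prep, "ML")
  }
  decomposition_row(decompose(fit))
}

#' Refit the model to every iteration of a resampled data set
#'
#' Applies a common model to each bootstrap iteration and collects the raw
#' variance components (dam, sire, dam-by-sire, any extras, fixed group,
#' residual), the total, and the derived additive, nonadditive and
#' maternal components, one row per model iteration. Iterations whose fit
#' fails are recorded as missing rows (with the reason retained in
#' `attr(, "failures")`) and excluded from downstream quantiles.
#'
#' @param resampled a `vc_resample` from [resample_by_replicate()] or
#'   [resample_by_family()].
#' @param spec a [model_spec()].
#' @param start,end first and last model iteration to fit (defaults: all).
#' @param engine `"lme4"` (default) or `"ems"`, the closed-form
#'   expected-mean-squares estimator of [fit_ems()] (balanced Gaussian
#'   designs only; stratified resampling preserves balance).
#' @return a data frame of class `component_matrix` with one row per
#'   iteration and an `iteration` column.
#' @export
fit_resampled <- function(resampled, spec, start = 1L, end = NULL,
                          engine = c("lme4", "ems")) {
  engine <- match.arg(engine)
  if (is.null(resampled$.iteration)) {
    stop("`resampled` must carry an .iteration column ",
         "(see resample_by_family)", call. = FALSE)
  }
  end <- end %||% max(resampled$.iteration)
  if (start > end) stop("`start` must be <= `end`", call. = FALSE)
  cols <- component_matrix_columns(spec)
  its <- start:end
  rows <- matrix(NA_real_, nrow = length(its), ncol = length(cols),
                 dimnames = list(NULL, cols))
  failures <- list()
  chunks <- split(seq_len(nrow(resampled)), resampled$.iteration)
  if (engine == "ems") {
    # vectorized fast path: stratified resampling preserves the design, so
    # integer design codes are extracted once for the whole stacked set
    if (spec$family != "gaussian" || length(spec$fixed) ||
        length(spec$extra_random)) {
      stop("engine = \"ems\" supports the standard gaussian model only",
           call. = FALSE)
    }
    dam <- droplevels(factor(resampled$dam))
    sire <- droplevels(factor(resampled$sire))
    nd <- nlevels(dam); ns <- nlevels(sire)
    di_all <- as.integer(dam); si_all <- as.integer(sire)
    fi_all <- (di_all - 1L) * ns + si_all
    y_all <- resampled[[spec$response]]
    first <- chunks[[as.character(its[1L])]]
    sizes <- tabulate(fi_all[first], nbins = nd * ns)
    if (any(sizes == 0L) || length(unique(sizes)) != 1L || sizes[1L] < 2L) {
      stop("engine = \"ems\" requires a complete balanced factorial",
           call. = FALSE)
    }
    r <- sizes[1L]
    for (j in seq_along(its)) {
      ix <- chunks[[as.character(its[j])]]
      est <- ems_core(y_all[ix], di_all[ix], si_all[ix], fi_all[ix],
                      nd, ns, r)
      dec <- variance_decomposition(c(est["dam"], est["sire"],
                                      est["dam_sire"], fixed_group = 0,
                                      residual = unname(est["residual"])))
      row <- decomposition_row(dec)
      rows[j, names(row)] <- row
    }
  } else {
    for (j in seq_along(its)) {
      it <- its[j]
      dat <- resampled[chunks[[as.character(it)]], , drop = FALSE]
      row <- tryCatch(fit_component_row(dat, spec, engine),
                      error = function(e) conditionMessage(e))
      if (is.character(row)) {
        failures[[as.character(it)]] <- row
      } else {
        rows[j, names(row)] <- row
      }
    }
  }
  if (length(failures) == length(its)) {
    stop("pipeline error: every resampled fit failed; first reason: ",
         failures[[1L]], call. = FALSE)
  }
  out <- data.frame(iteration = its, rows, check.names = FALSE)
  attr(out, "failures") <- failures
  attr(out, "spec") <- spec
  class(out) <- unique(c("component_matrix", class(out)))
  out
}

#' Jackknife refitting of a factorial model
#'
#' Delete-one (default) or delete-d jackknife: for `d = 1` each observation
#' is left out in turn, in original row order; for `d > 1` the rows are
#' shuffled once (using `seed`) and `floor(N / d)` sequential blocks of
#' size `d` are deleted in turn. One variance-component row is produced per
#' refit. Deleting rows unbalances the design, so the lme4 engine is
#' always used.
#'
#' @inheritParams fit_resampled
#' @param data an [observation_table()] (or coercible data frame).
#' @param d block size of deleted observations.
#' @param seed seed for the delete-d shuffle.
#' @return a `component_matrix` with `N` rows (`d = 1`) or `floor(N/d)`
#'   rows, carrying attributes `d` and `N` used by [ci_jackknife()].
#' @export
jackknife_fit <- function(data, spec, d = 1L, seed = NULL) {
  data <- as_observation_table(data)
  n <- nrow(data)
  if (d < 1L) stop("`d` must be >= 1", call. = FALSE)
  if (d >= n) stop("usage error: `d` must be smaller than the number of ",
                   "observations", call. = FALSE)
  m <- if (d == 1L) n else floor(n / d)
  if (m < 10L) warning("fewer than 10 jackknife groups (N/d = ", m, ")")
  ord <- if (d == 1L) seq_len(n) else with_seed(seed, sample.int(n))
  cols <- component_matrix_columns(spec)
  rows <- matrix(NA_real_, nrow = m, ncol = length(cols),
                 dimnames = list(NULL, cols))
  failures <- list()
  for (j in seq_len(m)) {
    drop_idx <- ord[((j - 1L) * d + 1L):(j * d)]
    dat <- data[-drop_idx, , drop = FALSE]
    row <- tryCatch(fit_component_row(dat, spec, engine = "lme4"),
                    error = function(e) conditionMessage(e))
    if (is.character(row)) failures[[as.character(j)]] <- row
    else rows[j, names(row)] <- row
  }
  if (length(failures) == m) {
    stop("pipeline error: every jackknife fit failed; first reason: ",
         failures[[1L]], call. = FALSE)
  }
  out <- data.frame(iteration = seq_len(m), rows, check.names = FALSE)
  attr(out, "failures") <- failures
  attr(out, "spec") <- spec
  attr(out, "d") <- as.integer(d)
  attr(out, "N") <- n
  class(out) <- unique(c("component_matrix", class(out)))
  out
}
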