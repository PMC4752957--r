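# JSON serialization of fit, decomposition, test and interval results.

#' Serialize an analysis object to JSON
#'
#' Supported objects: `vc_fit`, `vc_decomposition`, `vc_analysis`,
#' `vc_intervals`, `vc_power`. The merMod internals of fits are not
#' serialized; the summary carries the variance table, fixed-effect table,
#' logLik/AIC/BIC and convergence metadata.
#'
#' @param x an analysis object.
#' @param path optional output path; when given the JSON is written there.
#' @return the JSON string, invisibly when `path` is given.
#' @export
vc_json <- function(x, path = NULL) {
  lst <- vc_json_list(x)
  js <- jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

vc_json_list <- function(x) {
  if (inherits(x, "vc_decomposition")) {
    return(list(
      raw = as.list(x$raw), percent = as.list(x$percent),
      derived_raw = as.list(x$derived_raw),
      derived_percent = as.list(x$derived_percent),
      total = x$total, degenerate = x$degenerate))
  }
  if (inherits(x, "vc_fit")) {
    ic <- information_criteria(x)
    return(list(
      family = x$family, link = x$link, method = x$method,
      variance_estimates = as.list(x$variance_estimates),
      olre_variance = x$olre_variance,
      fixed_estimates = as.list(x$fixed_estimates),
      fixed_group_variance = x$fixed_group_variance,
      logLik = ic$logLik, AIC = ic$AIC, BIC = ic$BIC,
      n_obs = x$n_obs, n_parameters = x$n_parameters,
      converged = x$converged,
      messages = as.list(x$messages %||% character(0)),
      intercept_only_beta0 = x$intercept_only_beta0))
  }
  if (inherits(x, "vc_analysis")) {
    return(list(fit = vc_json_list(x$fit),
                decomposition = vc_json_list(x$decomposition),
                random_tests = x$random_tests))
  }
  if (inherits(x, "vc_intervals")) {
    return(list(level = x$level, center_kind = x$center_kind,
                correction = x$correction, raw = x$raw,
                percent = x$percent))
  }
  if (inherits(x, "vc_power")) {
    return(list(alpha = x$alpha, power = x$power, n_failed = x$n_failed,
                notes = x$notes))
  }
  stop("no JSON serializer for class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}
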