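VALID_LINKS <- list(
  gaussian = "identity",
  binomial = c("logit", "probit"),
  quasibinomial = c("logit", "probit"),
  poisson = c("log", "sqrt"),
  quasipoisson = c("log", "sqrt")
)

#' Specify the variance-component model for a factorial analysis
#'
#' Describes the response, error structure, estimation method and model
#' terms for fitting a full factorial mating design. The standard random
#' structure is dam + sire + dam-by-sire; position/block/other random
#' intercepts are added through `extra_random` and covariates or factors
#' through `fixed`.
#'
#' The quasi-families model overdispersion of proportion or count data by an
#' observation-level random effect (OLRE); they are invalid for binary
#' responses, which cannot be overdispersed.
#'
#' @param response name of the response column. For binomial data this is
#'   either a 0/1 individual-level column or, together with `failures`, a
#'   successes-count column.
#' @param family error structure: `"gaussian"`, `"binomial"`,
#'   `"quasibinomial"`, `"poisson"` or `"quasipoisson"`.
#' @param link link function; defaults to the family's canonical link
#'   (identity, logit, log). Binomial families also accept `"probit"`,
#'   Poisson families `"sqrt"`.
#' @param method `"REML"` (default) or `"ML"`; Gaussian only. Nonnormal
#'   models are always fitted by maximum likelihood (Laplace approximation).
#' @param random random intercept terms; default
#'   `c("dam", "sire", "dam:sire")`. `"dam:sire"` refers to the `family`
#'   column of the observation table.
#' @param extra_random names of additional random-intercept columns (e.g.
#'   tray, cell, block).
#' @param fixed character vector of fixed-effect terms (column names,
#'   optionally with interactions in formula syntax).
#' @param failures for binomial/quasibinomial count-pair input, the name of
#'   the failures-count column.
#' @param alpha significance level used by downstream tests; default 0.05.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(response, family = "gaussian", link = NULL,
                       method = c("REML", "ML"),
                       random = c("dam", "sire", "dam:sire"),
                       extra_random = character(0), fixed = character(0),
                       failures = NULL, alpha = 0.05) {
  family <- match.arg(family, names(VALID_LINKS))
  link <- link %||% VALID_LINKS[[family]][1L]
  if (!link %in% VALID_LINKS[[family]]) {
    stop("link `", link, "` is not valid for family `", family, "` ",
         "(valid: ", paste(VALID_LINKS[[family]], collapse = ", "), ")",
         call. = FALSE)
  }
  method <- match.arg(method)
  if (family != "gaussian") method <- "ML"
  if (!is.character(response) || length(response) != 1L) {
    stop("`response` must be a single column name", call. = FALSE)
  }
  if (!is.null(failures) && !family %in% c("binomial", "quasibinomial")) {
    stop("`failures` applies only to binomial/quasibinomial families",
         call. = FALSE)
  }
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1)) {
    stop("`alpha` must be a single value in (0, 1)", call. = FALSE)
  }
  structure(list(
    response = response, family = family, link = link, method = method,
    random = random, extra_random = as.character(extra_random),
    fixed = as.character(fixed), failures = failures, alpha = alpha
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model spec: %s(%s), %s\n", x$family, x$link, x$method))
  cat("  response:", x$response,
      if (!is.null(x$failures)) paste0("/ ", x$failures, " (count pair)"),
      "\n")
  cat("  random:", paste(c(x$random, x$extra_random), collapse = " + "), "\n")
  if (length(x$fixed)) cat("  fixed:", paste(x$fixed, collapse = " + "), "\n")
  invisible(x)
}

# all random terms as data-frame column names ("dam:sire" -> "family")
random_columns <- function(spec) {
  cols <- vapply(c(spec$random, spec$extra_random), function(tm) {
    if (tm %in% c("dam:sire", "dam_sire", "family")) "family" else tm
  }, character(1))
  unname(cols)
}

# map a data column name back to the component label used in outputs
component_label <- function(col) {
  if (col == "family") "dam_sire" else col
}

# reverse: accept user-facing term names for deletion tests
term_to_column <- function(term) {
  if (term %in% c("dam:sire", "dam_sire", "family")) "family" else term
}

is_quasi <- function(spec) spec$family %in% c("quasibinomial", "quasipoisson")

base_family <- function(spec) {
  switch(spec$family,
         gaussian = "gaussian",
         binomial = , quasibinomial = "binomial",
         poisson = , quasipoisson = "poisson")
}
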