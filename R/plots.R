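# Base-graphics visualization of component distributions and intervals.

open_device <- function(path, format = c("png", "svg"), width = 7,
                        height = 5) {
  format <- match.arg(format)
  if (is.null(path)) return(FALSE)
  if (format == "png") {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = 150)
  } else {
    grDevices::svg(path, width = width, height = height)
  }
  TRUE
}

check_ylim <- function(ymin, ymax, yunit) {
  if (!is.null(ymin) && !is.null(ymax) && ymin >= ymax) {
    stop("validation error: ymin must be smaller than ymax", call. = FALSE)
  }
  if (!is.null(yunit) && yunit <= 0) {
    stop("validation error: yunit must be positive", call. = FALSE)
  }
}

#' Bar graph of variance-component confidence intervals
#'
#' One shaded bar per component, topped at the interval center (bootstrap
#' median or jackknife pseudo-value mean), with error bars spanning the
#' confidence limits. Several interval sets (e.g. different traits or
#' groups) can be drawn as labelled clusters in one figure.
#'
#' @param intervals a `vc_intervals`, or a named list of them for grouped
#'   clusters.
#' @param scale `"raw"` or `"percent"`.
#' @param components components to draw; the additive, nonadditive and
#'   maternal set by default.
#' @param ymin,ymax,yunit y-axis minimum, maximum and tick increment.
#' @param cex_ylab axis label size.
#' @param path output image path (default: draw on the active device).
#' @param format `"png"` or `"svg"`.
#' @return the plotted table of centers and limits, invisibly.
#' @export
bar_plot <- function(intervals, scale = c("percent", "raw"),
                     components = c("additive", "nonadditive", "maternal"),
                     ymin = NULL, ymax = NULL, yunit = NULL, cex_ylab = 1,
                     path = NULL, format = "png") {
  scale <- match.arg(scale)
  check_ylim(ymin, ymax, yunit)
  groups <- if (inherits(intervals, "vc_intervals")) {
    list(trait = intervals)
  } else intervals
  tabs <- lapply(groups, function(iv) {
    tab <- iv[[scale]]
    miss <- setdiff(components, tab$component)
    if (length(miss)) {
      stop("plotting error: interval set lacks component(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    tab[match(components, tab$component), , drop = FALSE]
  })
  centers <- do.call(cbind, lapply(tabs, function(t) t$center))
  lowers <- do.call(cbind, lapply(tabs, function(t) t$lower))
  uppers <- do.call(cbind, lapply(tabs, function(t) t$upper))
  dev <- open_device(path, format)
  if (dev) on.exit(grDevices::dev.off())
  ylim <- c(ymin %||% min(0, lowers), ymax %||% max(uppers) * 1.05)
  mids <- graphics::barplot(centers, beside = TRUE,
                            names.arg = names(groups),
                            col = c("grey30", "grey60", "grey85"),
                            ylim = ylim,
                            ylab = if (scale == "percent")
                              "% of phenotypic variance" else "variance",
                            cex.lab = cex_ylab, xpd = FALSE,
                            yaxt = if (is.null(yunit)) "s" else "n")
  if (!is.null(yunit)) {
    graphics::axis(2, at = seq(ylim[1], ylim[2], by = yunit))
  }
  nonzero <- uppers > lowers  # zero-length error bars are legitimate
  if (any(nonzero)) {
    graphics::arrows(mids[nonzero], lowers[nonzero], mids[nonzero],
                     uppers[nonzero], angle = 90, code = 3, length = 0.05)
  }
  graphics::legend("topright", legend = components,
                   fill = c("grey30", "grey60", "grey85"), bty = "n")
  invisible(list(centers = centers, lowers = lowers, uppers = uppers))
}

#' Boxplots of bootstrap or jackknife component distributions
#'
#' Per-component boxes with the median bar, the 25th/75th-quartile box,
#' whiskers, and outlier dots beyond 1.5 times the interquartile range.
#' Quartiles use the definition-7 (linear interpolation) quantile.
#'
#' @param matrix a `component_matrix`, or a named list of them for grouped
#'   clusters.
#' @inheritParams bar_plot
#' @return the boxplot statistics, invisibly.
#' @export
box_plot <- function(matrix, scale = c("percent", "raw"),
                     components = c("additive", "nonadditive", "maternal"),
                     ymin = NULL, ymax = NULL, yunit = NULL, cex_ylab = 1,
                     path = NULL, format = "png") {
  scale <- match.arg(scale)
  check_ylim(ymin, ymax, yunit)
  groups <- if (is.data.frame(matrix)) list(trait = matrix) else matrix
  values <- list()
  for (g in names(groups)) {
    mat <- groups[[g]]
    if (!nrow(mat)) stop("plotting error: empty component matrix",
                         call. = FALSE)
    if (nrow(mat) < 5L) warning("fewer than 5 rows; boxplot is unstable")
    mat <- if (scale == "percent") percent_matrix(mat) else mat
    for (cl in components) {
      if (!cl %in% names(mat)) {
        stop("plotting error: component matrix lacks `", cl, "`",
             call. = FALSE)
      }
      values[[paste(g, cl, sep = ".")]] <- mat[[cl]][!is.na(mat[[cl]])]
    }
  }
  # boxplot statistics from definition-7 quartiles (not Tukey hinges),
  # outliers beyond 1.5 * IQR
  stat_list <- lapply(values, function(x) {
    q <- quantile_hf7(x, c(0.25, 0.5, 0.75))
    iqr <- q[3L] - q[1L]
    lo <- min(x[x >= q[1L] - 1.5 * iqr])
    hi <- max(x[x <= q[3L] + 1.5 * iqr])
    list(stats = c(lo, q[1L], q[2L], q[3L], hi),
         conf = q[2L] + c(-1.58, 1.58) * iqr / sqrt(length(x)),
         out = x[x < q[1L] - 1.5 * iqr | x > q[3L] + 1.5 * iqr])
  })
  z <- list(
    stats = vapply(stat_list, `[[`, numeric(5), "stats"),
    n = vapply(values, length, numeric(1)),
    conf = vapply(stat_list, `[[`, numeric(2), "conf"),
    out = unlist(lapply(stat_list, `[[`, "out")),
    group = rep(seq_along(stat_list),
                vapply(stat_list, function(s) length(s$out), integer(1))),
    names = names(values)
  )
  dev <- open_device(path, format)
  if (dev) on.exit(grDevices::dev.off())
  rng <- range(unlist(values))
  ylim <- c(ymin %||% rng[1], ymax %||% rng[2])
  graphics::bxp(z, ylim = ylim,
                boxfill = rep(c("grey30", "grey60", "grey85"),
                              length(groups)),
                las = 2, cex.axis = 0.7, outpch = 16, outcex = 0.5,
                ylab = if (scale == "percent")
                  "% of phenotypic variance" else "variance",
                cex.lab = cex_ylab,
                yaxt = if (is.null(yunit)) "s" else "n")
  if (!is.null(yunit)) {
    graphics::axis(2, at = seq(ylim[1], ylim[2], by = yunit))
  }
  invisible(z)
}
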