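#' Standardize a data frame of offspring records for factorial analysis
#'
#' Binds the design identifier columns of a full factorial (North Carolina
#' II) data set to canonical names. The returned table has factor columns
#' `dam`, `sire`, `family` (the dam-by-sire combination) and, when supplied,
#' `replicate`; every other column is carried through untouched. Identifier
#' labels are treated as opaque: no numeric coercion is performed, so a dam
#' labelled "1" never collides with a sire labelled "1".
#'
#' When no family column is supplied, `family` is derived as the
#' dam-by-sire interaction (`<dam>:<sire>`). A supplied family column is
#' checked for consistency: each (dam, sire) pair must map to exactly one
#' family label.
#'
#' @param data a data frame with one row per individual offspring (or per
#'   replicate when the response is a count pair).
#' @param dam,sire names of the dam and sire identifier columns.
#' @param family optional name of the family identifier column.
#' @param replicate optional name of the replicate identifier column.
#' @return a data frame of class `observation_table`.
#' @export
observation_table <- function(data, dam = "dam", sire = "sire",
                              family = NULL, replicate = NULL) {
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  need <- c(dam, sire, family, replicate)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("column(s) not found in `data`: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- data
  ren <- c(dam = dam, sire = sire)
  if (!is.null(family)) ren <- c(ren, family = family)
  if (!is.null(replicate)) ren <- c(ren, replicate = replicate)
  names(out)[match(ren, names(out))] <- names(ren)
  for (col in c("dam", "sire")) {
    if (anyNA(out[[col]])) {
      stop("missing values in identifier column `", col, "`", call. = FALSE)
    }
    out[[col]] <- factor(out[[col]])
  }
  if (is.null(family)) {
    out$family <- factor(paste(as.character(out$dam), as.character(out$sire),
                               sep = ":"))
  } else {
    out$family <- factor(out$family)
    key <- paste(as.character(out$dam), as.character(out$sire), sep = "\r")
    if (anyNA(out$family)) {
      stop("missing values in identifier column `family`", call. = FALSE)
    }
    n_fam_per_pair <- tapply(as.character(out$family), key,
                             function(f) length(unique(f)))
    if (any(n_fam_per_pair > 1L)) {
      stop("a (dam, sire) pair maps to more than one family label",
           call. = FALSE)
    }
  }
  if (!is.null(replicate)) out$replicate <- factor(out$replicate)
  class(out) <- unique(c("observation_table", class(out)))
  out
}

as_observation_table <- function(data) {
  if (inherits(data, "observation_table")) return(data)
  observation_table(data,
                    family = if ("family" %in% names(data)) "family" else NULL,
                    replicate = if ("replicate" %in% names(data)) "replicate" else NULL)
}

#' Summarize and validate the factorial structure of a design
#'
#' Reports the number of dams, sires and families, the family sizes, and
#' which dam-by-sire cells are absent. A complete n x n factorial has every
#' pairwise combination represented.
#'
#' @param data an [observation_table()] (or coercible data frame).
#' @return a list with elements `n_dam`, `n_sire`, `n_family`,
#'   `family_sizes` (named integer vector), `missing_cells` (data frame of
#'   absent dam/sire pairs) and `complete` (logical).
#' @export
validate_design <- function(data) {
  data <- as_observation_table(data)
  n_dam <- nlevels(droplevels(data$dam))
  n_sire <- nlevels(droplevels(data$sire))
  if (n_dam < 2L || n_sire < 2L) {
    stop("design error: at least 2 dams and 2 sires are required to ",
         "identify dam, sire, and dam-by-sire variance components",
         call. = FALSE)
  }
  tab <- table(droplevels(data$dam), droplevels(data$sire))
  absent <- which(tab == 0L, arr.ind = TRUE)
  missing_cells <- data.frame(dam = rownames(tab)[absent[, 1L]],
                              sire = colnames(tab)[absent[, 2L]],
                              stringsAsFactors = FALSE)
  fam_sizes <- table(droplevels(data$family))
  structure(list(
    n_dam = n_dam,
    n_sire = n_sire,
    n_family = length(fam_sizes),
    family_sizes = stats::setNames(as.integer(fam_sizes), names(fam_sizes)),
    missing_cells = missing_cells,
    complete = nrow(missing_cells) == 0L
  ), class = "design_summary")
}

#' @export
print.design_summary <- function(x, ...) {
  cat(sprintf("Factorial design: %d dams x %d sires, %d families (%s)\n",
              x$n_dam, x$n_sire, x$n_family,
              if (x$complete) "complete" else
                sprintf("incomplete, %d empty cells", nrow(x$missing_cells))))
  cat(sprintf("Family sizes: min %d, median %s, max %d\n",
              min(x$family_sizes), format(stats::median(x$family_sizes)),
              max(x$family_sizes)))
  invisible(x)
}

check_count_cols <- function(counts, cols) {
  miss <- setdiff(cols, names(counts))
  if (length(miss)) {
    stop("count column(s) not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in cols) {
    v <- counts[[col]]
    if (!all(is_wholenumber(v)) || any(v < 0)) {
      stop("column `", col, "` must contain non-negative integer counts",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Expand replicate-level survival counts to individual binary records
#'
#' Converts a table with one row per family (or family-replicate) holding
#' the number of offspring in two outcome categories -- e.g. alive and dead
#' -- into a table with one row per offspring and a binary `status` column.
#' Analyzing such data at the individual level avoids underestimating the
#' phenotypic variance relative to replicate-level proportions.
#'
#' Row order is deterministic: input rows are processed in order, and within
#' each row every `status = 1` record precedes the `status = 0` records.
#'
#' @param counts a data frame of counts (one row per family/replicate).
#' @param one_column name of the column counted as `status = 1` (e.g. alive).
#' @param zero_column name of the column counted as `status = 0` (e.g. dead).
#' @param copy_columns columns to duplicate onto every emitted row; defaults
#'   to all columns other than the two count columns.
#' @return a data frame with `sum(counts[[one_column]] + counts[[zero_column]])`
#'   rows and a new integer column `status`.
#' @examples
#' expand_binary(data.frame(dam = "D1", sire = "S1", alive = 2, dead = 1),
#'               "alive", "dead")
#' @export
expand_binary <- function(counts, one_column, zero_column,
                          copy_columns = NULL) {
  check_count_cols(counts, c(one_column, zero_column))
  if (is.null(copy_columns)) {
    copy_columns <- setdiff(names(counts), c(one_column, zero_column))
  } else {
    miss <- setdiff(copy_columns, names(counts))
    if (length(miss)) {
      stop("copy column(s) not found: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  ones <- as.integer(round(counts[[one_column]]))
  zeros <- as.integer(round(counts[[zero_column]]))
  idx <- rep.int(seq_len(nrow(counts)), ones + zeros)
  status <- unlist(mapply(function(a, b) c(rep.int(1L, a), rep.int(0L, b)),
                          ones, zeros, SIMPLIFY = FALSE), use.names = FALSE)
  out <- counts[idx, copy_columns, drop = FALSE]
  out$status <- as.integer(status %||% integer(0))
  rownames(out) <- NULL
  out
}

#' Expand multi-category offspring counts to individual coded records
#'
#' Generalization of [expand_binary()]: several count columns are mapped to
#' numeric codes, and one row per counted offspring is emitted with the code
#' in a new `status` column. Emission order is deterministic: input row
#' order, then `value_map` order within each row.
#'
#' @param counts a data frame of counts.
#' @param value_map a named numeric vector; names are count-column names,
#'   values the numeric code assigned to offspring counted in that column.
#'   Codes must be unique.
#' @param copy_columns columns to duplicate onto every emitted row; defaults
#'   to all columns not named in `value_map`.
#' @return a data frame with one row per counted offspring.
#' @examples
#' expand_multi(data.frame(dam = "D1", sire = "S1", eyed = 1, hatched = 2,
#'                         dead = 1),
#'              c(dead = 0, eyed = 1, hatched = 2))
#' @export
expand_multi <- function(counts, value_map, copy_columns = NULL) {
  if (length(value_map) == 0L) {
    stop("`value_map` must name at least one count column", call. = FALSE)
  }
  if (is.null(names(value_map)) || any(!nzchar(names(value_map)))) {
    stop("`value_map` must be a named numeric vector", call. = FALSE)
  }
  if (anyDuplicated(value_map)) {
    stop("duplicate codes in `value_map`", call. = FALSE)
  }
  check_count_cols(counts, names(value_map))
  if (is.null(copy_columns)) {
    copy_columns <- setdiff(names(counts), names(value_map))
  }
  cnt <- as.matrix(counts[names(value_map)])
  storage.mode(cnt) <- "integer"
  idx <- rep.int(seq_len(nrow(counts)), rowSums(cnt))
  status <- unlist(lapply(seq_len(nrow(counts)),
                          function(i) rep.int(unname(value_map), cnt[i, ])),
                   use.names = FALSE)
  out <- counts[idx, copy_columns, drop = FALSE]
  out$status <- status %||% numeric(0)
  rownames(out) <- NULL
  out
}

#' Read a delimited table of observations or counts
#'
#' Thin wrapper around [utils::read.csv()] (UTF-8, header row required)
#' used by the command-line pipeline.
#'
#' @param path path to a CSV file.
#' @return a data frame.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, header = TRUE, fileEncoding = "UTF-8",
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a table as CSV
#'
#' @param x a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
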