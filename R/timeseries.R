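#' Concentration time-series container
#'
#' A `sm_timeseries` holds measured concentrations for `n` species at `T`
#' time points, optionally partitioned into independent condition segments
#' (e.g. replicate experiments or perturbation conditions). Within each
#' condition segment the time stamps must be strictly increasing; different
#' segments are treated as independent throughout the package (gradients and
#' likelihood contributions are computed per segment and pooled).
#'
#' @param values numeric matrix, time points in rows and species in columns.
#' @param times numeric vector of time stamps (hours), one per row.
#' @param species character vector of species names; defaults to the column
#'   names of `values`.
#' @param condition vector of per-row condition labels; a single condition is
#'   assumed when omitted.
#'
#' @return An object of class `sm_timeseries` with fields `times`, `values`,
#'   `species` and `condition`.
#' @export
timeseries <- function(values, times, species = colnames(values),
                       condition = NULL) {
  values <- as.matrix(values)
  if (is.null(species)) species <- paste0("x", seq_len(ncol(values)))
  if (length(times) != nrow(values))
    stop("`times` must have one entry per row of `values`")
  if (is.null(condition)) condition <- rep("c1", length(times))
  if (length(condition) != length(times))
    stop("`condition` must have one entry per row of `values`")
  condition <- as.character(condition)
  for (cid in unique(condition)) {
    tt <- times[condition == cid]
    if (any(diff(tt) <= 0))
      stop("times must be strictly increasing within condition '", cid, "'")
  }
  colnames(values) <- species
  structure(
    list(times = as.numeric(times), values = values,
         species = species, condition = condition),
    class = "sm_timeseries"
  )
}

#' @export
print.sm_timeseries <- function(x, ...) {
  cat("<sm_timeseries> ", length(x$times), " time points, ",
      length(x$species), " species, ",
      length(unique(x$condition)), " condition(s)\n", sep = "")
  cat("  species: ", paste(x$species, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.sm_timeseries <- function(x) dim(x$values)

#' Indices of the rows belonging to each condition segment
#' @noRd
segment_indices <- function(ts) {
  split(seq_along(ts$times), ts$condition)[unique(ts$condition)]
}

#' Read a concentration time series from a delimited text file
#'
#' Expects a header row naming the columns, a time column (default `time`),
#' one column per species, and an optional condition column splitting the rows
#' into independent segments. Comma and tab delimiters are auto-detected.
#'
#' @param path path to the file.
#' @param time_col name of the time column.
#' @param condition_col name of the condition column, if present.
#' @param sep field delimiter; `NULL` (default) auto-detects `,` vs tab.
#' @param strict if `TRUE`, negative concentrations are an error instead of a
#'   warning.
#' @return An [timeseries()] object.
#' @export
read_timeseries <- function(path, time_col = "time", condition_col = "condition",
                            sep = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!time_col %in% names(df))
    stop("format error: no time column '", time_col, "' in ", path)
  condition <- if (condition_col %in% names(df)) df[[condition_col]] else NULL
  keep <- setdiff(names(df), c(time_col, condition_col))
  if (length(keep) == 0L) stop("format error: no species columns in ", path)
  vals <- as.matrix(df[keep])
  storage.mode(vals) <- "double"
  if (any(vals < 0, na.rm = TRUE)) {
    msg <- "negative concentrations present"
    if (strict) stop(msg) else warning(msg)
  }
  timeseries(vals, times = df[[time_col]], species = keep,
             condition = condition)
}

#' Write a concentration time series to a delimited text file
#'
#' Inverse of [read_timeseries()]; round trips are lossless at the printed
#' precision (17 significant digits).
#'
#' @param ts an [timeseries()] object.
#' @param path output path.
#' @param sep field delimiter.
#' @export
write_timeseries <- function(ts, path, sep = "\t") {
  df <- data.frame(time = ts$times, check.names = FALSE)
  if (length(unique(ts$condition)) > 1L) df$condition <- ts$condition
  df <- cbind(df, as.data.frame(ts$values, check.names = FALSE))
  ok <- tryCatch({
    utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                       path, sep = sep, quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed writing '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Rescale each species to minimum 0 and mean 1
#'
#' Per species: subtract the minimum (so the smallest value becomes 0), then
#' divide by the post-shift mean (so the mean becomes 1). This is the
#' normalization applied to the synthetic regressor data before inference;
#' it is idempotent.
#'
#' @param ts an [timeseries()] object; every species needs at least two
#'   distinct values.
#' @return A normalized [timeseries()] object.
#' @export
normalize_series <- function(ts) {
  vals <- ts$values
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j] - min(vals[, j])
    m <- mean(v)
    if (m == 0)
      stop("degenerate series: species '", ts$species[j], "' is constant")
    vals[, j] <- v / m
  }
  timeseries(vals, ts$times, ts$species, ts$condition)
}

#' Estimated temporal-derivative container
#'
#' Holds the gradient estimates \eqn{y_i(t_j)} used as the regression response
#' of the gradient-matching model. Same layout as the source time series.
#'
#' @param values numeric matrix of derivative estimates (concentration/hour).
#' @param times numeric vector of time stamps.
#' @param species species names.
#' @param condition per-row condition labels.
#' @param method `"numerical"` or `"analytical"` provenance tag.
#' @return An object of class `sm_gradients`.
#' @export
gradient_set <- function(values, times, species = colnames(values),
                         condition = NULL, method = c("numerical", "analytical")) {
  method <- match.arg(method)
  ts <- timeseries(values, times, species, condition)
  structure(
    list(times = ts$times, values = ts$values, species = ts$species,
         condition = ts$condition, method = method),
    class = "sm_gradients"
  )
}

#' @export
print.sm_gradients <- function(x, ...) {
  cat("<sm_gradients> (", x$method, ") ", length(x$times), " time points, ",
      length(x$species), " species\n", sep = "")
  invisible(x)
}
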