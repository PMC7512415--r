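#' Construct a labelled time series
#'
#' Light container for a physiological time series: an ordered vector of
#' amplitude samples (e.g. body temperature in degrees Celsius, one sample
#' per minute) together with an identifier and an optional binary class
#' label (0 = healthy, 1 = patient).
#'
#' @param samples Numeric vector of finite amplitude samples, in time order.
#' @param series_id Character scalar identifying the series.
#' @param class_label Optional class label, `0`, `1` or `NA`.
#' @return An object of class `time_series`: a list with elements
#'   `samples`, `series_id` and `class_label`.
#' @examples
#' ts <- time_series(sin(1:100), series_id = "demo", class_label = 0)
#' length(ts$samples)
#' @export
time_series <- function(samples, series_id = "series", class_label = NA) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop_short_series("a time series needs at least one sample")
  }
  if (!all(is.finite(samples))) {
    stop_parse(sprintf(
      "series '%s' contains %d non-finite sample(s)",
      series_id, sum(!is.finite(samples))
    ))
  }
  if (!is.na(class_label) && !class_label %in% c(0, 1)) {
    stop_parse("class_label must be 0, 1 or NA")
  }
  structure(
    list(
      samples = samples,
      series_id = as.character(series_id)[1],
      class_label = if (is.na(class_label)) NA_integer_ else as.integer(class_label)
    ),
    class = "time_series"
  )
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf(
    "<time_series '%s'> L = %d, class = %s, range = [%.4g, %.4g]\n",
    x$series_id, length(x$samples),
    if (is.na(x$class_label)) "NA" else x$class_label,
    min(x$samples), max(x$samples)
  ))
  invisible(x)
}

# Accept either a time_series or a bare numeric vector everywhere.
as_samples <- function(x) {
  if (inherits(x, "time_series")) x$samples else as.numeric(x)
}

series_id_of <- function(x, default = "series") {
  if (inherits(x, "time_series")) x$series_id else default
}

#' Z-score normalization of a time series
#'
#' Centres the series to mean zero and scales it to unit population
#' standard deviation (divisor `L`, not `L - 1`). With tolerance `r`
#' expressed as a fraction of the series SD, running the amplitude-based
#' entropy estimators on a normalized series makes `r` an absolute
#' threshold equal to that fraction.
#'
#' @param ts A `time_series` or numeric vector with at least two samples.
#' @return Object of the same type with normalized samples; order and
#'   length preserved.
#' @examples
#' normalize_series(c(0, 2))  # -1, 1
#' @export
normalize_series <- function(ts) {
  x <- as_samples(ts)
  if (length(x) < 2L) {
    stop_short_series("normalization needs at least two samples")
  }
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  if (sd_pop == 0) {
    stop_degenerate("zero variance: constant series cannot be normalized")
  }
  z <- (x - mu) / sd_pop
  if (inherits(ts, "time_series")) {
    ts$samples <- z
    ts
  } else {
    z
  }
}

#' Read raw time series from a plain-text or CSV file
#'
#' Two dialects are accepted: a single-column plain-text file (one sample
#' per line, no header) holding one series, and a CSV file with a header
#' row holding one series per column. Row order is time order.
#'
#' @param path File path.
#' @param class_label Class label attached to every series read (default `NA`).
#' @return A list of [time_series()] objects (length one for plain text).
#' @export
read_series <- function(path, class_label = NA) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, check.names = FALSE)
    if (nrow(df) == 0L) stop_parse(sprintf("no samples in %s", path))
    lapply(names(df), function(nm) {
      col <- df[[nm]]
      if (!is.numeric(col)) {
        stop_parse(sprintf("column '%s' of %s is not numeric", nm, path))
      }
      time_series(col, series_id = nm, class_label = class_label)
    })
  } else {
    txt <- readLines(path, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) == 0L) stop_parse(sprintf("no samples in %s", path))
    val <- suppressWarnings(as.numeric(txt))
    if (anyNA(val)) {
      stop_parse(sprintf(
        "non-numeric sample at line %d of %s", which(is.na(val))[1], path
      ))
    }
    id <- sub("\\.[^.]*$", "", basename(path))
    list(time_series(val, series_id = id, class_label = class_label))
  }
}

#' Write a set of series as a multi-column CSV
#'
#' Inverse of the CSV dialect of [read_series()]: one column per series,
#' header = series ids. Series of unequal length are padded with empty
#' cells. Class labels are not stored in the series file; use
#' [write_cohort()] to keep a labels sidecar.
#'
#' @param series_list List of `time_series` objects.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_series_csv <- function(series_list, path) {
  stopifnot(length(series_list) >= 1L)
  lens <- vapply(series_list, function(s) length(as_samples(s)), integer(1))
  L <- max(lens)
  cols <- lapply(series_list, function(s) {
    x <- as_samples(s)
    c(x, rep(NA_real_, L - length(x)))
  })
  names(cols) <- vapply(seq_along(series_list), function(i) {
    series_id_of(series_list[[i]], default = paste0("s", i))
  }, character(1))
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
    row.names = FALSE, na = ""
  )
  invisible(path)
}
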