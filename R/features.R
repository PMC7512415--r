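#' Construct and validate a feature table
#'
#' The modelling dataset: one row per subject with the three entropy
#' features and a binary class label (0 = healthy, 1 = febrile patient).
#'
#' @param df Data frame with columns `id`, `apen`, `pe`, `sampen`, `class`.
#' @return A `feature_table` (a validated data frame).
#' @export
feature_table <- function(df) {
  required <- c("id", "apen", "pe", "sampen", "class")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop_parse(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0L) stop_parse("no records")
  for (col in c("apen", "pe", "sampen")) {
    v <- df[[col]]
    if (!is.numeric(v) || !all(is.finite(v))) {
      bad <- if (is.numeric(v)) which(!is.finite(v))[1] else 1L
      stop_parse(sprintf("non-numeric or non-finite value in column '%s', row %d", col, bad))
    }
  }
  cls <- df[["class"]]
  if (!all(cls %in% c(0, 1))) {
    stop_parse(sprintf(
      "non-binary class value '%s' in row %d",
      cls[!cls %in% c(0, 1)][1], which(!cls %in% c(0, 1))[1]
    ))
  }
  out <- data.frame(
    id = df$id,
    apen = as.numeric(df$apen),
    pe = as.numeric(df$pe),
    sampen = as.numeric(df$sampen),
    class = as.integer(cls),
    stringsAsFactors = FALSE
  )
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Class counts of a feature table
#' @param ft A [feature_table()].
#' @return Named integer vector `c(n0 = ..., n1 = ...)`.
#' @export
class_counts <- function(ft) {
  c(n0 = sum(ft$class == 0L), n1 = sum(ft$class == 1L))
}

#' Bundled reference feature table (30-record temperature cohort)
#'
#' Entropy features of 30 body-temperature records (8-hour daytime
#' intervals sampled once per minute): 16 healthy individuals (class 0)
#' and 14 febrile inpatients (class 1). Features are approximate entropy
#' and sample entropy at `m = 1`, `r = 0.25` and permutation entropy at
#' `m = 8` (bits). The values are shipped verbatim as published for this
#' cohort, including one duplicated class-0 row (records 1 and 15); the
#' raw recordings themselves are not public and the feature values are
#' not regenerable from data in this package.
#'
#' @return A [feature_table()] with 30 rows.
#' @examples
#' ft <- reference_features()
#' class_counts(ft)
#' @export
reference_features <- function() {
  path <- system.file("extdata", "temperature_entropy_features.csv",
    package = "tempentropy", mustWork = TRUE
  )
  read_feature_csv(path)
}

#' Read / write a feature table as CSV
#'
#' The CSV schema has header columns `id`, `apen`, `pe`, `sampen`,
#' `class`; a write followed by a read reproduces the table exactly.
#'
#' @param path CSV file path.
#' @return `read_feature_csv()` returns a [feature_table()];
#'   `write_feature_csv()` returns `path` invisibly.
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) stop_parse(sprintf("file not found: %s", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop_parse(sprintf("cannot parse %s: %s", path, conditionMessage(e)))
  )
  if (nrow(df) == 0L) stop_parse("no records")
  feature_table(df)
}

#' @rdname read_feature_csv
#' @param ft A [feature_table()].
#' @export
write_feature_csv <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  utils::write.csv(as.data.frame(ft), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compute the entropy feature table of a labelled series set
#'
#' Bridges raw time series to the modelling dataset: evaluates ApEn,
#' SampEn and PE for every series with the study defaults (ApEn and
#' SampEn at `m = 1`, `r = 0.25` on z-scored series; PE at `m = 8`,
#' `tau = 1`) and assembles one feature row per series. Every series must
#' carry a binary class label. Deterministic: identical inputs give
#' identical tables.
#'
#' @param series_list List of labelled [time_series()] objects.
#' @param apen_m,apen_r ApEn embedding dimension and tolerance.
#' @param sampen_m,sampen_r SampEn embedding dimension and tolerance.
#' @param pe_m,pe_tau PE pattern order and delay.
#' @param normalize Z-score series before the amplitude-based measures.
#' @param sampen_mode SampEn convention, see [sample_entropy()].
#' @return A [feature_table()] with one row per series.
#' @examples
#' cohort <- generate_cohort(n0 = 4, n1 = 4, master_seed = 1)
#' compute_features(cohort)
#' @export
compute_features <- function(series_list,
                             apen_m = 1L, apen_r = 0.25,
                             sampen_m = 1L, sampen_r = 0.25,
                             pe_m = 8L, pe_tau = 1L,
                             normalize = TRUE, sampen_mode = "literal") {
  if (length(series_list) == 0L) stop_parse("empty series set")
  rows <- lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    if (!inherits(s, "time_series") || is.na(s$class_label)) {
      stop_parse(sprintf("series %d has no class label", i))
    }
    wrap <- function(expr) {
      tryCatch(expr, error = function(e) {
        stop_tempentropy(
          sprintf("series '%s': %s", s$series_id, conditionMessage(e)),
          class(e)[1]
        )
      })
    }
    data.frame(
      id = s$series_id,
      apen = wrap(approximate_entropy(s, apen_m, apen_r, normalize)),
      pe = wrap(permutation_entropy(s, pe_m, pe_tau)),
      sampen = wrap(sample_entropy(s, sampen_m, sampen_r, normalize, sampen_mode)),
      class = s$class_label,
      stringsAsFactors = FALSE
    )
  })
  feature_table(do.call(rbind, rows))
}
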