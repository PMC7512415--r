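# Amplitude-based regularity statistics (ApEn, SampEn) and the
# ordinality-based permutation entropy. ApEn/SampEn compare length-m
# embedded templates under the Chebyshev (max-difference) distance; PE
# compares the rank order of the samples inside each window and is
# therefore blind to amplitude.

# Chebyshev match matrix between all length-m templates of x.
# Entry [i, j] is TRUE when max_k |x[i+k] - x[j+k]| is below r.
# strict = TRUE counts a match only when the distance is strictly
# below r; many public implementations use <=, hence the flag.
chebyshev_matches <- function(x, m, r, strict = TRUE) {
  n <- length(x) - m + 1L
  idx <- seq_len(n)
  d <- abs(outer(x[idx], x[idx], "-"))
  if (m > 1L) {
    for (k in seq_len(m - 1L)) {
      d <- pmax(d, abs(outer(x[idx + k], x[idx + k], "-")))
    }
  }
  if (strict) d < r else d <= r
}

check_entropy_args <- function(x, m, r = NULL) {
  if (!all(is.finite(x))) stop_parse("series contains non-finite samples")
  if (m < 1L) stop_parse("embedding dimension m must be >= 1")
  if (!is.null(r) && r <= 0) stop_parse("tolerance r must be > 0")
}

#' Approximate entropy (ApEn)
#'
#' Regularity statistic of Pincus: the log-decrease in the fraction of
#' amplitude-similar templates when the embedding length grows from `m` to
#' `m + 1`. For each of the `L - m + 1` templates of length `m`, the
#' fraction `C_i^m(r)` of templates within Chebyshev distance `r`
#' (self-matches included) is computed; `Phi^m(r)` is the average of
#' `log C_i^m(r)` (natural log), and
#' `ApEn(m, r, L) = Phi^m(r) - Phi^{m+1}(r)`.
#'
#' With `normalize = TRUE` (default) the series is z-scored first, so `r`
#' is a fraction of the series standard deviation; results are then
#' invariant under positive rescaling of the amplitudes.
#'
#' @param ts A `time_series` or numeric vector, length `L >= m + 2`.
#' @param m Embedding dimension (window length), positive integer.
#' @param r Tolerance; a fraction of the series SD when `normalize = TRUE`,
#'   an absolute amplitude threshold otherwise.
#' @param normalize Z-score the series before embedding (default `TRUE`).
#' @param strict Count a match when the distance is strictly below `r`
#'   (default); `FALSE` uses `<=` for comparability with tools that do.
#' @return A single non-negative (up to floating error) numeric value.
#' @seealso [sample_entropy()], [permutation_entropy()]
#' @examples
#' set.seed(1)
#' approximate_entropy(rnorm(200), m = 1, r = 0.25)
#' @export
approximate_entropy <- function(ts, m = 1L, r = 0.25, normalize = TRUE,
                                strict = TRUE) {
  x <- as_samples(ts)
  m <- as.integer(m)
  check_entropy_args(x, m, r)
  L <- length(x)
  if (L <= m + 1L) {
    stop_short_series(sprintf("ApEn needs L >= m + 2 (got L = %d, m = %d)", L, m))
  }
  if (normalize) x <- normalize_series(x)
  phi <- function(mm) {
    M <- chebyshev_matches(x, mm, r, strict)
    # self-match (diagonal) guarantees C_i > 0, so the log is finite
    mean(log(rowMeans(M)))
  }
  phi(m) - phi(m + 1L)
}

#' Sample entropy (SampEn)
#'
#' Bias-reduced variant of [approximate_entropy()] that excludes
#' self-matches: `SampEn(m, r, L) = -log(Phi^{m+1}(r) / Phi^m(r))`, where
#' `Phi` is now the plain (not log-) average of the per-template match
#' fractions.
#'
#' Two conventions are provided. `mode = "literal"` evaluates the match
#' fractions over all `L - m + 1` templates of each length, with inner
#' denominator `L - m`, applying the same formulas to the `m` and `m + 1`
#' passes. `mode = "canonical"` is the Richman-Moorman convention: both
#' passes restrict to the first `L - m` templates so that every length-m
#' template has a length-(m+1) continuation, and the statistic equals
#' `-log(A / B)` with `A`, `B` the (m+1)- and m-level match-pair counts.
#' The two agree closely for long series but differ at small `L`.
#'
#' @inheritParams approximate_entropy
#' @param mode `"literal"` (default) or `"canonical"`; see Details.
#' @return A single finite numeric value.
#' @section Errors: when no template pair matches at tolerance `r` at
#'   either length, the statistic is undefined and a typed
#'   `tempentropy_undefined_entropy` error is signalled (never a silent
#'   `NaN`).
#' @examples
#' set.seed(1)
#' sample_entropy(rnorm(200), m = 1, r = 0.25)
#' sample_entropy(rnorm(200), m = 2, r = 0.2, mode = "canonical")
#' @export
sample_entropy <- function(ts, m = 1L, r = 0.25, normalize = TRUE,
                           mode = c("literal", "canonical"), strict = TRUE) {
  x <- as_samples(ts)
  m <- as.integer(m)
  mode <- match.arg(mode)
  check_entropy_args(x, m, r)
  L <- length(x)
  if (L <= m + 1L) {
    stop_short_series(sprintf("SampEn needs L >= m + 2 (got L = %d, m = %d)", L, m))
  }
  if (normalize) x <- normalize_series(x)

  if (mode == "literal") {
    phi <- function(mm) {
      M <- chebyshev_matches(x, mm, r, strict)
      # exclude the self-match on the diagonal; inner denominator L - mm
      mean((rowSums(M) - 1) / (L - mm))
    }
    phi_m <- phi(m)
    phi_m1 <- phi(m + 1L)
  } else {
    n <- L - m # number of templates with a length-(m+1) continuation
    Mm <- chebyshev_matches(x, m, r, strict)[seq_len(n), seq_len(n), drop = FALSE]
    Mm1 <- chebyshev_matches(x, m + 1L, r, strict)
    phi_m <- (sum(Mm) - n) / (n * (n - 1))
    phi_m1 <- (sum(Mm1) - n) / (n * (n - 1))
  }
  if (phi_m <= 0 || phi_m1 <= 0) {
    stop_undefined_entropy(sprintf(
      "no template matches at tolerance r = %g: SampEn undefined", r
    ))
  }
  -log(phi_m1 / phi_m)
}

#' Ordinal pattern distribution of a time series
#'
#' Slides a window of `m` samples (delay `tau` between successive window
#' elements) along the series and records, for each window, the
#' permutation that re-assembles its samples in ascending order. Ties are
#' broken by temporal order of appearance (stable ranking: the earlier
#' sample keeps the lower rank), a necessary convention for quantized
#' signals such as clinical temperature records. Probabilities are
#' relative frequencies over all `L - (m - 1) * tau` windows.
#'
#' @param ts A `time_series` or numeric vector, length `L >= m`
#'   (more precisely `L >= (m - 1) * tau + 1`).
#' @param m Window length (pattern order), integer `>= 2`.
#' @param tau Embedding delay, positive integer; `tau = 1` (default) uses
#'   the original time scale.
#' @return An object of class `ordinal_distribution`: list with `counts`
#'   (named integer vector; names are the zero-based permutation indices
#'   joined by `-`), `probabilities`, `n_windows`, `m` and `tau`.
#' @examples
#' ordinal_pattern_counts(c(4, 7, 9, 10, 6, 11, 3), m = 2)
#' @export
ordinal_pattern_counts <- function(ts, m, tau = 1L) {
  x <- as_samples(ts)
  m <- as.integer(m)
  tau <- as.integer(tau)
  if (m < 2L) stop_parse("ordinal patterns need m >= 2")
  if (tau < 1L) stop_parse("embedding delay tau must be >= 1")
  if (!all(is.finite(x))) stop_parse("series contains non-finite samples")
  L <- length(x)
  n_win <- L - (m - 1L) * tau
  if (n_win < 1L) {
    stop_short_series(sprintf(
      "series too short for ordinal patterns: L = %d, m = %d, tau = %d", L, m, tau
    ))
  }
  offs <- seq(0L, by = tau, length.out = m)
  pats <- vapply(seq_len(n_win), function(t) {
    w <- x[t + offs]
    # order() with radix method is stable: tied samples keep time order
    paste(order(w, method = "radix") - 1L, collapse = "-")
  }, character(1))
  counts <- table(pats)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(
    list(
      counts = counts,
      probabilities = counts / n_win,
      n_windows = n_win,
      m = m,
      tau = tau
    ),
    class = "ordinal_distribution"
  )
}

#' @export
print.ordinal_distribution <- function(x, ...) {
  cat(sprintf(
    "<ordinal_distribution> m = %d, tau = %d, %d windows, %d distinct patterns\n",
    x$m, x$tau, x$n_windows, length(x$counts)
  ))
  print(x$counts)
  invisible(x)
}

#' Permutation entropy (PE)
#'
#' Shannon entropy, in bits, of the ordinal pattern distribution of
#' [ordinal_pattern_counts()]: `PE(m, L) = -sum p * log2 p` over patterns
#' with nonzero probability. PE depends only on the ordering of samples,
#' so it is exactly invariant under strictly increasing amplitude
#' transforms, and is bounded by `log2(min(m!, n_windows))`.
#'
#' @inheritParams ordinal_pattern_counts
#' @return Entropy in bits, a single value in `[0, log2(min(m!, n_windows))]`.
#' @examples
#' permutation_entropy(c(4, 7, 9, 10, 6, 11, 3), m = 2) # ~0.9183 bits
#' permutation_entropy(1:50, m = 4) # 0: a monotone series has one pattern
#' @export
permutation_entropy <- function(ts, m, tau = 1L) {
  dist <- ordinal_pattern_counts(ts, m, tau)
  p <- dist$probabilities
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Entropy parameter sweep over a set of series
#'
#' Evaluates one estimator over a grid of embedding dimensions (and, for
#' the amplitude-based measures, tolerances) for every series. Estimator
#' errors (e.g. undefined SampEn at a tight tolerance) are recorded per
#' cell in the `error` column rather than aborting the sweep.
#'
#' @param series_list List of `time_series` objects or numeric vectors.
#' @param measure One of `"apen"`, `"sampen"`, `"pe"`.
#' @param m_values Integer vector of embedding dimensions.
#' @param r_values Numeric vector of tolerances (ignored for `"pe"`).
#' @param tau Embedding delay for `"pe"` (default 1).
#' @param normalize,strict,mode Passed to the estimators.
#' @return A tidy data frame with columns `series_id`, `measure`, `m`,
#'   `r`, `value`, `error` (`NA` when the cell evaluated cleanly).
#' @examples
#' set.seed(7)
#' xs <- replicate(3, rnorm(120), simplify = FALSE)
#' entropy_sweep(xs, "apen", m_values = 1:2, r_values = c(0.2, 0.25))
#' @export
entropy_sweep <- function(series_list, measure = c("apen", "sampen", "pe"),
                          m_values, r_values = NA_real_, tau = 1L,
                          normalize = TRUE, strict = TRUE, mode = "literal") {
  measure <- match.arg(measure)
  if (length(series_list) == 0L) stop_parse("empty series set")
  if (length(m_values) == 0L) stop_parse("empty m grid")
  if (measure == "pe") r_values <- NA_real_
  if (measure != "pe" && all(is.na(r_values))) stop_parse("empty r grid")

  grid <- expand.grid(
    s = seq_along(series_list), m = as.integer(m_values), r = r_values,
    KEEP.OUT.ATTRS = FALSE
  )
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- series_list[[grid$s[i]]]
    m <- grid$m[i]
    r <- grid$r[i]
    res <- tryCatch(
      switch(measure,
        apen = approximate_entropy(s, m, r, normalize, strict),
        sampen = sample_entropy(s, m, r, normalize, mode, strict),
        pe = permutation_entropy(s, m, tau)
      ),
      error = function(e) e
    )
    data.frame(
      series_id = series_id_of(s, default = paste0("s", grid$s[i])),
      measure = measure,
      m = m,
      r = r,
      value = if (inherits(res, "error")) NA_real_ else res,
      error = if (inherits(res, "error")) conditionMessage(res) else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
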