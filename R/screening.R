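#' Pairwise correlation screen of the entropy measures
#'
#' Before any measure pair enters a joint classifier, their redundancy is
#' assessed: Pearson correlation of each pair of feature columns pooled
#' over both classes, with the two-sided p-value of the correlation
#' t-test on `n - 2` degrees of freedom. A strongly correlated pair
#' (ApEn and SampEn in practice) carries redundant information and should
#' not share a model.
#'
#' @param ft A [feature_table()] with at least 3 records.
#' @return Object of class `correlation_screen`: list with symmetric
#'   matrices `r` and `p` over `apen`, `pe`, `sampen`, and `n`, the
#'   number of records used.
#' @examples
#' correlation_screen(reference_features())
#' @export
correlation_screen <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  n <- nrow(ft)
  if (n < 3L) stop_parse("correlation screen needs at least 3 records")
  measures <- c("apen", "pe", "sampen")
  for (mcol in measures) {
    if (stats::var(ft[[mcol]]) == 0) {
      stop_degenerate(sprintf("zero variance in column '%s': correlation undefined", mcol))
    }
  }
  r <- diag(3)
  p <- matrix(NA_real_, 3, 3)
  dimnames(r) <- dimnames(p) <- list(measures, measures)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      ct <- stats::cor.test(ft[[measures[i]]], ft[[measures[j]]],
        method = "pearson", alternative = "two.sided"
      )
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  structure(list(r = r, p = p, n = n), class = "correlation_screen")
}

#' @export
print.correlation_screen <- function(x, ...) {
  cat(sprintf("<correlation_screen> n = %d\nPearson r:\n", x$n))
  print(round(x$r, 4))
  cat("two-sided p:\n")
  print(round(x$p, 4))
  invisible(x)
}

#' Measure pairs admissible for a joint model
#'
#' A pair of measures may share a logistic model only when their
#' correlation is not significant: a pair is excluded when its
#' correlation-test p-value falls below `p_threshold`. On the reference
#' cohort at the default 0.05 this admits PE+ApEn and PE+SampEn and
#' excludes ApEn+SampEn.
#'
#' @param screen A [correlation_screen()].
#' @param p_threshold Significance level below which a pair is considered
#'   correlated, hence excluded (default 0.05).
#' @return A list of length-2 character vectors, one per admissible pair.
#' @examples
#' admissible_pairs(correlation_screen(reference_features()))
#' @export
admissible_pairs <- function(screen, p_threshold = 0.05) {
  stopifnot(inherits(screen, "correlation_screen"))
  measures <- rownames(screen$r)
  out <- list()
  for (i in 1:2) {
    for (j in (i + 1):3) {
      if (!(screen$p[i, j] < p_threshold)) {
        out[[length(out) + 1L]] <- c(measures[i], measures[j])
      }
    }
  }
  out
}

#' Export a correlation screen as CSV matrices
#'
#' Writes the `r` and `p` matrices side by side in long form:
#' columns `measure_a`, `measure_b`, `r`, `p`.
#'
#' @param screen A [correlation_screen()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_screen_csv <- function(screen, path) {
  measures <- rownames(screen$r)
  rows <- list()
  for (i in 1:2) {
    for (j in (i + 1):3) {
      rows[[length(rows) + 1L]] <- data.frame(
        measure_a = measures[i], measure_b = measures[j],
        r = screen$r[i, j], p = screen$p[i, j]
      )
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
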