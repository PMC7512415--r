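#' Paired leave-one-out validation
#'
#' Held-out assessment for small two-class cohorts: each fold removes
#' one class-0 and one class-1 record, refits the logistic model on the
#' remaining `n - 2` records, and predicts the held-out pair at the
#' classification threshold. With unequal class sizes no single 1:1
#' pairing covers every record symmetrically, so the default scheme
#' enumerates all `n0 * n1` (class-0, class-1) pairs; a `"cyclic"`
#' scheme (record k of each class, the smaller class recycled) is
#' available for comparison.
#'
#' Because each record is held out many times under the all-pairs
#' scheme, two aggregates are reported: the average over all held-out
#' predictions (`accuracy_prediction`) and the average of per-record
#' correctness rates (`accuracy_record`).
#'
#' @param ft A [feature_table()] with at least two records per class.
#' @param predictors Predictor subset, as in [fit_logistic()].
#' @param threshold Classification threshold (default 0.5).
#' @param scheme `"all_pairs"` (default) or `"cyclic"`.
#' @return Object of class `loo_result`: list with `folds` (data frame:
#'   fold, record id, class-1 probability, predicted, true, correct),
#'   `n_folds`, `accuracy_prediction`, `accuracy_record`,
#'   `per_record` (data frame id, times_tested, times_correct), and
#'   `n_separation_warnings`.
#' @examples
#' res <- leave_pair_out(reference_features(), "pe")
#' res$accuracy_prediction
#' @export
leave_pair_out <- function(ft, predictors, threshold = 0.5,
                           scheme = c("all_pairs", "cyclic")) {
  stopifnot(inherits(ft, "feature_table"))
  scheme <- match.arg(scheme)
  i0 <- which(ft$class == 0L)
  i1 <- which(ft$class == 1L)
  if (length(i0) < 2L || length(i1) < 2L) {
    stop_parse("leave-pair-out needs at least two records per class")
  }
  pairs <- if (scheme == "all_pairs") {
    expand.grid(a = i0, b = i1, KEEP.OUT.ATTRS = FALSE)
  } else {
    k <- max(length(i0), length(i1))
    data.frame(
      a = i0[((seq_len(k) - 1L) %% length(i0)) + 1L],
      b = i1[((seq_len(k) - 1L) %% length(i1)) + 1L]
    )
  }

  n_sep <- 0L
  rows <- vector("list", nrow(pairs))
  for (f in seq_len(nrow(pairs))) {
    hold <- c(pairs$a[f], pairs$b[f])
    train <- feature_table(as.data.frame(ft)[-hold, , drop = FALSE])
    fit <- withCallingHandlers(
      fit_logistic(train, predictors),
      warning = function(w) {
        n_sep <<- n_sep + 1L
        invokeRestart("muffleWarning")
      }
    )
    p <- predict_probability(fit, as.data.frame(ft)[hold, , drop = FALSE])
    pred <- as.integer(p > threshold)
    rows[[f]] <- data.frame(
      fold = f,
      id = ft$id[hold],
      probability = p,
      predicted = pred,
      true = ft$class[hold],
      correct = pred == ft$class[hold],
      stringsAsFactors = FALSE
    )
  }
  folds <- do.call(rbind, rows)
  rownames(folds) <- NULL

  per_record <- do.call(rbind, lapply(unique(ft$id), function(id) {
    sub <- folds[folds$id == id, , drop = FALSE]
    data.frame(
      id = id,
      times_tested = nrow(sub),
      times_correct = sum(sub$correct),
      stringsAsFactors = FALSE
    )
  }))
  tested <- per_record$times_tested > 0L
  structure(
    list(
      folds = folds,
      n_folds = nrow(pairs),
      accuracy_prediction = 100 * mean(folds$correct),
      accuracy_record = 100 * mean(
        per_record$times_correct[tested] / per_record$times_tested[tested]
      ),
      per_record = per_record,
      n_separation_warnings = n_sep
    ),
    class = "loo_result"
  )
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf(
    "<loo_result> %d folds; held-out accuracy %.2f%% (per prediction), %.2f%% (per record)\n",
    x$n_folds, x$accuracy_prediction, x$accuracy_record
  ))
  if (x$n_separation_warnings > 0L) {
    cat(sprintf("%d fold(s) raised separation warnings\n", x$n_separation_warnings))
  }
  invisible(x)
}

#' Export a leave-pair-out report as CSV
#'
#' @param loo A [leave_pair_out()] result.
#' @param path Output CSV path (one row per held-out prediction).
#' @return Invisibly, `path`.
#' @export
write_loo_csv <- function(loo, path) {
  stopifnot(inherits(loo, "loo_result"))
  utils::write.csv(loo$folds, path, row.names = FALSE)
  invisible(path)
}
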