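# Logistic classifiers of class membership from entropy features, with
# the full diagnostic panel: per-coefficient Wald tests and odds ratios,
# deviance, Cox-Snell and Nagelkerke pseudo-R2, AIC, confusion summaries
# at a probability threshold, and the empirical ROC curve / AUC.

#' Null deviance of an intercept-only binary classifier
#'
#' Closed form of `-2LL` for the model that predicts the class-1 base
#' rate for every record:
#' `2 * (n0 * log((n0 + n1) / n0) + n1 * log((n0 + n1) / n1))`.
#'
#' @param n0,n1 Class counts, both `>= 1`.
#' @return The null deviance (natural-log scale).
#' @examples
#' null_deviance(16, 14) # ~41.455
#' @export
null_deviance <- function(n0, n1) {
  if (n0 < 1 || n1 < 1) stop_parse("both classes must be non-empty")
  n <- n0 + n1
  2 * (n0 * log(n / n0) + n1 * log(n / n1))
}

#' Fit a logistic classifier on entropy features
#'
#' Maximum-likelihood logistic regression of the class label (1 =
#' patient) on up to two entropy features, fitted by iteratively
#' reweighted least squares (deviance-change tolerance 1e-8, at most 50
#' iterations), with no regularization. Standard errors come from the
#' inverse observed information; per-coefficient p-values from the Wald
#' statistic `(b / SE)^2` against chi-squared with 1 df (equivalent to
#' the two-sided z test). Likelihood-ratio p-values per predictor are
#' also exposed (`lr_p`) but Wald is the default reading.
#'
#' Pseudo-R2: Cox-Snell `1 - exp((D_model - D_null) / n)` and Nagelkerke
#' (Cox-Snell rescaled by its ceiling `1 - exp(-D_null / n)`).
#' `AIC = D_model + 2 * (q + 1)` with `q` the number of predictors.
#'
#' @param ft A [feature_table()] containing both classes.
#' @param predictors Character vector, a subset of
#'   `c("apen", "sampen", "pe")` of length 0 (intercept-only), 1 or 2.
#' @return Object of class `logistic_fit`: list with `coefficients` (data
#'   frame: term, estimate, std_error, wald, df, p_value, lr_p, exp_b),
#'   `deviance`, `null_deviance`, `r2_cox_snell`, `r2_nagelkerke`, `aic`,
#'   `predictors`, `n`, `n0`, `n1`, `converged`, `separation`, and the
#'   underlying `glm` object.
#' @section Separation: quasi- or complete separation (diverging
#'   coefficients / fitted probabilities of 0 or 1) is flagged in
#'   `$separation` with a warning; the maximum-iterations result is
#'   still returned.
#' @examples
#' fit <- fit_logistic(reference_features(), "pe")
#' fit$coefficients
#' @export
fit_logistic <- function(ft, predictors) {
  stopifnot(inherits(ft, "feature_table"))
  allowed <- c("apen", "sampen", "pe")
  predictors <- as.character(predictors)
  if (length(predictors) > 2L) stop_parse("at most two predictors are supported")
  if (!all(predictors %in% allowed)) {
    stop_parse(paste0("unknown predictor(s): ",
      paste(setdiff(predictors, allowed), collapse = ", ")))
  }
  counts <- class_counts(ft)
  if (any(counts == 0L)) stop_parse("both classes must be present to fit")

  fml <- if (length(predictors) == 0L) {
    stats::as.formula("class ~ 1")
  } else {
    stats::as.formula(paste("class ~", paste(predictors, collapse = " + ")))
  }
  separation <- FALSE
  m <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(),
      data = as.data.frame(ft),
      control = stats::glm.control(epsilon = 1e-8, maxit = 50)
    ),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
        conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  # glm converges quietly under complete separation once the deviance
  # plateaus; fitted probabilities at the 0/1 boundary give it away
  if (!separation &&
    (!m$converged || any(m$fitted.values < 1e-8 | m$fitted.values > 1 - 1e-8))) {
    separation <- TRUE
  }
  if (separation) {
    warning(sprintf(
      "possible quasi/complete separation for predictors {%s}; coefficients may diverge",
      paste(predictors, collapse = ", ")
    ), call. = FALSE)
  }

  est <- stats::coef(m)
  se <- sqrt(diag(stats::vcov(m)))
  wald <- (est / se)^2
  p_wald <- stats::pchisq(wald, df = 1, lower.tail = FALSE)

  # likelihood-ratio p per predictor (deviance change on removal)
  lr_p <- rep(NA_real_, length(est))
  names(lr_p) <- names(est)
  for (pr in predictors) {
    reduced <- setdiff(predictors, pr)
    fml_r <- if (length(reduced) == 0L) "class ~ 1" else paste("class ~", reduced)
    m_r <- suppressWarnings(stats::glm(stats::as.formula(fml_r),
      family = stats::binomial(),
      data = as.data.frame(ft),
      control = stats::glm.control(epsilon = 1e-8, maxit = 50)
    ))
    lr_p[pr] <- stats::pchisq(m_r$deviance - m$deviance, df = 1, lower.tail = FALSE)
  }

  n <- nrow(ft)
  d_null <- null_deviance(counts["n0"], counts["n1"])
  d_model <- m$deviance
  r2_cs <- 1 - exp((d_model - d_null) / n)
  r2_nk <- r2_cs / (1 - exp(-d_null / n))
  q <- length(predictors)

  coef_tab <- data.frame(
    term = names(est),
    estimate = unname(est),
    std_error = unname(se),
    wald = unname(wald),
    df = 1L,
    p_value = unname(p_wald),
    lr_p = unname(lr_p),
    exp_b = unname(exp(est)),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      coefficients = coef_tab,
      deviance = d_model,
      null_deviance = unname(d_null),
      r2_cox_snell = r2_cs,
      r2_nagelkerke = r2_nk,
      aic = d_model + 2 * (q + 1),
      predictors = predictors,
      n = n,
      n0 = unname(counts["n0"]),
      n1 = unname(counts["n1"]),
      converged = m$converged,
      separation = separation,
      glm = m
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, digits = 4, ...) {
  cat(sprintf(
    "<logistic_fit> class ~ %s  (n = %d: %d/%d)\n",
    if (length(x$predictors)) paste(x$predictors, collapse = " + ") else "1",
    x$n, x$n0, x$n1
  ))
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  cat(sprintf(
    "-2LL %.5f (null %.5f)  Cox-Snell R2 %.3f  Nagelkerke R2 %.3f  AIC %.5f\n",
    x$deviance, x$null_deviance, x$r2_cox_snell, x$r2_nagelkerke, x$aic
  ))
  if (x$separation) cat("warning: possible separation\n")
  invisible(x)
}

#' Class-1 probability under a fitted logistic model
#'
#' Evaluates the logistic transform of the linear predictor at one or
#' more records.
#'
#' @param fit A [fit_logistic()] result.
#' @param newdata A [feature_table()], data frame, or named list/vector
#'   providing the fit's predictor columns.
#' @return Numeric vector of probabilities in (0, 1).
#' @examples
#' fit <- fit_logistic(reference_features(), "pe")
#' predict_probability(fit, list(pe = 9.096728))
#' @export
predict_probability <- function(fit, newdata) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  miss <- setdiff(fit$predictors, names(newdata))
  if (length(miss) > 0L) {
    stop_parse(paste0("missing predictor value(s): ", paste(miss, collapse = ", ")))
  }
  b <- fit$coefficients$estimate
  eta <- rep(b[1], nrow(newdata))
  for (k in seq_along(fit$predictors)) {
    eta <- eta + b[k + 1] * as.numeric(newdata[[fit$predictors[k]]])
  }
  stats::plogis(eta)
}

#' Confusion summary at a probability threshold
#'
#' Classifies each record as 1 when its fitted probability strictly
#' exceeds `threshold` (a probability exactly at the threshold
#' classifies as 0) and tabulates agreement with the observed classes.
#' Following the convention of this cohort's literature, "sensitivity"
#' is the percentage of class-0 records classified correctly and
#' "specificity" the percentage of class-1 records.
#'
#' @param fit A [fit_logistic()] result.
#' @param ft Feature table to classify (defaults to the data the model
#'   was fitted on).
#' @param threshold Probability threshold (default 0.5).
#' @return Object of class `confusion_summary`: list with `counts` (2x2
#'   matrix, observed x predicted), `sensitivity`, `specificity`,
#'   `accuracy` (all percentages), `threshold`, `misclassified_ids`.
#' @examples
#' confusion_summary(fit_logistic(reference_features(), "pe"))
#' @export
confusion_summary <- function(fit, ft = NULL, threshold = 0.5) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (is.null(ft)) ft <- feature_table(fit$glm$data)
  p <- predict_probability(fit, ft)
  pred <- as.integer(p > threshold)
  obs <- ft$class
  counts <- matrix(0L, 2, 2, dimnames = list(
    observed = c("0", "1"), predicted = c("0", "1")
  ))
  for (k in seq_along(obs)) {
    counts[obs[k] + 1L, pred[k] + 1L] <- counts[obs[k] + 1L, pred[k] + 1L] + 1L
  }
  structure(
    list(
      counts = counts,
      sensitivity = 100 * counts["0", "0"] / sum(counts["0", ]),
      specificity = 100 * counts["1", "1"] / sum(counts["1", ]),
      accuracy = 100 * sum(diag(counts)) / sum(counts),
      threshold = threshold,
      misclassified_ids = ft$id[pred != obs]
    ),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> threshold %g\n", x$threshold))
  print(x$counts)
  cat(sprintf(
    "class 0 correct %.1f%%  class 1 correct %.1f%%  total %.1f%%\n",
    x$sensitivity, x$specificity, x$accuracy
  ))
  invisible(x)
}

#' Empirical ROC curve and AUC of a fitted classifier
#'
#' Sweeps the classification threshold over all fitted scores and
#' records the (FPR, TPR) operating points, with class 1 as positive.
#' The AUC is the area under this empirical curve, which equals the
#' Mann-Whitney rank statistic: the probability that a random class-1
#' score exceeds a random class-0 score, ties counted half.
#'
#' @param fit A [fit_logistic()] result.
#' @param ft Feature table to score (defaults to the training data).
#' @return Object of class `roc_summary`: list with `points` (data frame
#'   `threshold`, `fpr`, `tpr`, ordered from (0,0) to (1,1)) and `auc`.
#' @examples
#' roc_auc(fit_logistic(reference_features(), "pe"))$auc
#' @export
roc_auc <- function(fit, ft = NULL) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (is.null(ft)) ft <- feature_table(fit$glm$data)
  if (length(unique(ft$class)) < 2L) stop_parse("both classes must be present")
  scores <- predict_probability(fit, ft)
  y <- ft$class
  # thresholds descending so the curve runs (0,0) -> (1,1); predict 1 when
  # score > threshold, matching confusion_summary()
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pts <- data.frame(
    threshold = th,
    fpr = vapply(th, function(t) mean(scores[y == 0] > t), numeric(1)),
    tpr = vapply(th, function(t) mean(scores[y == 1] > t), numeric(1))
  )
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_summary")
}

#' @export
print.roc_summary <- function(x, ...) {
  cat(sprintf("<roc_summary> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Rank models by AIC
#'
#' Orders fitted classifiers by ascending AIC; the first row is the
#' preferred model among those compared.
#'
#' @param fits List of [fit_logistic()] results on the same table.
#' @return Data frame with columns `model`, `deviance`, `aic`, ascending
#'   in `aic`.
#' @examples
#' ft <- reference_features()
#' compare_models(list(fit_logistic(ft, "pe"), fit_logistic(ft, c("pe", "apen"))))
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "logistic_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L, all(vapply(fits, inherits, logical(1), "logistic_fit")))
  out <- data.frame(
    model = vapply(fits, function(f) {
      if (length(f$predictors)) paste(f$predictors, collapse = "+") else "(intercept)"
    }, character(1)),
    deviance = vapply(fits, `[[`, numeric(1), "deviance"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$aic), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a fit report as CSV
#'
#' Writes the coefficient table (one row per term) followed by a summary
#' block (deviance, pseudo-R2, AIC) to two CSV files with suffixes
#' `_coefficients.csv` and `_summary.csv`.
#'
#' @param fit A [fit_logistic()] result.
#' @param stem Output path stem (without suffix).
#' @return Invisibly, the two paths written.
#' @export
write_fit_csv <- function(fit, stem) {
  stopifnot(inherits(fit, "logistic_fit"))
  p1 <- paste0(stem, "_coefficients.csv")
  p2 <- paste0(stem, "_summary.csv")
  utils::write.csv(fit$coefficients, p1, row.names = FALSE)
  utils::write.csv(data.frame(
    model = paste(fit$predictors, collapse = "+"),
    deviance = fit$deviance,
    null_deviance = fit$null_deviance,
    r2_cox_snell = fit$r2_cox_snell,
    r2_nagelkerke = fit$r2_nagelkerke,
    aic = fit$aic,
    n = fit$n
  ), p2, row.names = FALSE)
  invisible(c(p1, p2))
}
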