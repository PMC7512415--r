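test_that("the PE-only classifier reproduces the published coefficient panel", {
  fit <- fit_logistic(fixture_table(), "pe")
  co <- fit$coefficients
  b1 <- co[co$term == "pe", ]
  b0 <- co[co$term == "(Intercept)", ]

  expect_equal(b1$estimate, 3.704, tolerance = 0.005 / 3.704)
  expect_equal(b0$estimate, -32.202, tolerance = 0.05 / 32.202)
  expect_equal(b1$std_error, 1.395, tolerance = 0.005)
  expect_equal(b1$wald, 7.050, tolerance = 0.02)
  expect_equal(b1$exp_b, 40.598, tolerance = 0.1)
  expect_lt(abs(b1$p_value - 0.008), 5e-4)

  expect_lt(abs(fit$deviance - 24.031), 0.01)
  expect_lt(abs(fit$r2_cox_snell - 0.441), 1e-3)
  expect_lt(abs(fit$r2_nagelkerke - 0.588), 1e-3)
  expect_lt(abs(fit$aic - 28.03126), 0.01)
})

test_that("the bivariate PE + ApEn classifier reproduces the published fit", {
  fit <- fit_logistic(fixture_table(), c("pe", "apen"))
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "pe"], 3.433, tolerance = 0.01)
  expect_equal(co$estimate[co$term == "apen"], -12.806, tolerance = 0.01)
  expect_equal(co$estimate[co$term == "(Intercept)"], -24.940, tolerance = 0.01)
  # the printed features carry 6-decimal rounding; the refitted deviance
  # lands within 0.025 of the published 14.813
  expect_lt(abs(fit$deviance - 14.813), 0.025)
})

test_that("an intercept-only fit on balanced classes gives log-odds zero", {
  ft <- feature_table(data.frame(
    id = 1:16, apen = runif(16), pe = runif(16), sampen = runif(16),
    class = rep(c(0, 1), each = 8)
  ))
  fit <- fit_logistic(ft, character(0))
  expect_equal(fit$coefficients$estimate, 0, tolerance = 1e-10)
  expect_equal(fit$deviance, fit$null_deviance)
})

test_that("single-class or malformed predictor requests are refused", {
  ft <- fixture_table()
  one <- feature_table(as.data.frame(ft)[ft$class == 0, ])
  expect_error(fit_logistic(one, "pe"), "both classes")
  expect_error(fit_logistic(ft, c("pe", "apen", "sampen")), "at most two")
  expect_error(fit_logistic(ft, "temperature"), "unknown predictor")
})

test_that("null deviance follows the closed form", {
  n0 <- 16
  n1 <- 14
  expect_equal(
    null_deviance(n0, n1),
    2 * (n0 * log(30 / n0) + n1 * log(30 / n1))
  )
  # symmetric case: 2 * 2k * ln 2
  for (k in c(3, 8, 50)) expect_equal(null_deviance(k, k), 4 * k * log(2))
  expect_error(null_deviance(10, 0), "non-empty")

  # the closed form matches glm's intercept-only deviance and, combined
  # with the fitted deviance, the published pseudo-R2 pair
  fit <- fit_logistic(fixture_table(), "pe")
  expect_equal(fit$null_deviance, null_deviance(16, 14), tolerance = 1e-9)
  expect_lt(abs(1 - exp((24.031 - null_deviance(16, 14)) / 30) - 0.441), 1e-3)
})

test_that("diagnostic identities hold exactly on every model", {
  ft <- fixture_table()
  specs <- list("pe", "sampen", "apen", c("pe", "sampen"), c("pe", "apen"))
  for (spec in specs) {
    fit <- fit_logistic(ft, spec)
    co <- fit$coefficients
    expect_equal(co$wald, (co$estimate / co$std_error)^2, tolerance = 1e-12)
    expect_equal(co$exp_b, exp(co$estimate), tolerance = 1e-12)
    expect_equal(fit$aic, fit$deviance + 2 * (length(spec) + 1), tolerance = 1e-12)
    expect_gte(fit$r2_cox_snell, 0)
    expect_lte(fit$r2_cox_snell, fit$r2_nagelkerke)
    expect_lte(fit$r2_nagelkerke, 1)
    expect_equal(fit$deviance, fit$glm$deviance, tolerance = 1e-12)
  }
})

test_that("the fitted deviance attains the grid-search likelihood minimum", {
  # tiny table, one predictor with three distinct values: an exhaustive
  # zoomed grid search over (b0, b1) must not beat the IRLS optimum
  ft <- feature_table(data.frame(
    id = 1:12,
    apen = rep(c(0.1, 0.3, 0.5), 4),
    pe = rep(8, 12),
    sampen = rep(0.2, 12),
    # each predictor level carries both classes, so the MLE is finite
    class = c(1, 1, 0, 1, 0, 1, 0, 0, 1, 1, 0, 0)
  ))
  fit <- fit_logistic(ft, "apen")

  deviance_at <- function(b0, b1) {
    eta <- b0 + b1 * ft$apen
    p <- 1 / (1 + exp(-eta))
    -2 * sum(ft$class * log(p) + (1 - ft$class) * log(1 - p))
  }
  centre <- c(0, 0)
  width <- 20
  best <- Inf
  for (zoom in 1:8) {
    b0s <- seq(centre[1] - width, centre[1] + width, length.out = 41)
    b1s <- seq(centre[2] - 2 * width, centre[2] + 2 * width, length.out = 41)
    grid <- expand.grid(b0 = b0s, b1 = b1s)
    dev <- mapply(deviance_at, grid$b0, grid$b1)
    best <- min(dev)
    centre <- unlist(grid[which.min(dev), ])
    width <- width / 8
  }
  expect_equal(fit$deviance, best, tolerance = 1e-6)
  expect_lte(fit$deviance, best + 1e-6)
})

test_that("predicted probabilities match the published per-record values", {
  fit <- fit_logistic(fixture_table(), "pe")
  expect_equal(predict_probability(fit, list(pe = 9.096728)), 0.8161, tolerance = 0.001)
  expect_lt(abs(predict_probability(fit, list(pe = 7.045437)) - 0.0022), 0.0005)

  # a record placed exactly at the decision boundary scores 0.5
  b <- fit$coefficients$estimate
  expect_equal(predict_probability(fit, list(pe = -b[1] / b[2])), 0.5)

  expect_error(predict_probability(fit, list(apen = 0.3)), "missing predictor")
})

test_that("confusion summaries reproduce the published per-class accuracies", {
  ft <- fixture_table()
  cs_pe <- confusion_summary(fit_logistic(ft, "pe"))
  expect_identical(unname(cs_pe$counts["0", ]), c(14L, 2L))
  expect_identical(unname(cs_pe$counts["1", ]), c(3L, 11L))
  expect_lt(abs(cs_pe$sensitivity - 87.5), 0.05)
  expect_lt(abs(cs_pe$specificity - 78.6), 0.05)
  expect_lt(abs(cs_pe$accuracy - 83.3), 0.05)

  cs_joint <- confusion_summary(fit_logistic(ft, c("pe", "apen")))
  expect_identical(unname(diag(cs_joint$counts)), c(15L, 13L))
  expect_lt(abs(cs_joint$accuracy - 93.3), 0.05)

  # perfectly separated scores classify perfectly
  sep <- feature_table(data.frame(
    id = 1:10, apen = c(rep(0.9, 5), rep(0.05, 5)), pe = c(rep(7, 5), rep(10, 5)),
    sampen = c(rep(0.8, 5), rep(0.05, 5)), class = rep(c(0, 1), each = 5)
  ))
  fit_sep <- suppressWarnings(fit_logistic(sep, "pe"))
  cs_sep <- confusion_summary(fit_sep, sep)
  expect_equal(cs_sep$accuracy, 100)
  expect_true(fit_sep$separation)
})

test_that("threshold semantics are strict and monotone", {
  ft <- fixture_table()
  fit <- fit_logistic(ft, "pe")
  # a probability exactly at the threshold classifies as class 0
  p <- predict_probability(fit, ft)
  at <- confusion_summary(fit, ft, threshold = max(p))
  expect_identical(sum(at$counts[, "1"]), 0L)

  # raising the threshold never increases the predicted-1 count
  n_pos <- vapply(
    seq(0, 1, by = 0.05),
    function(th) sum(confusion_summary(fit, ft, th)$counts[, "1"]),
    integer(1)
  )
  expect_true(all(diff(n_pos) <= 0))
})

test_that("ROC/AUC equals the pairwise rank oracle and published value", {
  ft <- fixture_table()
  fit <- fit_logistic(ft, "pe")
  roc <- roc_auc(fit)
  expect_equal(roc$auc, 0.87, tolerance = 0.005)
  expect_equal(roc$auc, oracle_auc(predict_probability(fit, ft), ft$class),
    tolerance = 1e-12
  )
  # curve is monotone from (0,0) to (1,1)
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
  expect_equal(unlist(roc$points[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc$points[nrow(roc$points), c("fpr", "tpr")]), c(fpr = 1, tpr = 1))

  for (spec in list("sampen", "apen", c("pe", "sampen"), c("pe", "apen"))) {
    f <- fit_logistic(ft, spec)
    expect_equal(
      roc_auc(f)$auc,
      oracle_auc(predict_probability(f, ft), ft$class),
      tolerance = 1e-12
    )
  }
})

test_that("ROC/AUC agrees with pROC on the reference fits", {
  skip_if_not_installed("pROC")
  ft <- fixture_table()
  for (spec in list("pe", c("pe", "apen"))) {
    fit <- fit_logistic(ft, spec)
    scores <- predict_probability(fit, ft)
    ref <- as.numeric(pROC::auc(pROC::roc(ft$class, scores, quiet = TRUE)))
    expect_equal(roc_auc(fit)$auc, ref, tolerance = 1e-10)
  }
})

test_that("degenerate score sets hit the AUC tie conventions", {
  ft <- feature_table(data.frame(
    id = 1:8, apen = runif(8), pe = c(1, 2, 3, 4, 11, 12, 13, 14),
    sampen = runif(8), class = rep(c(0, 1), each = 4)
  ))
  fit <- suppressWarnings(fit_logistic(ft, "pe"))
  expect_equal(roc_auc(fit, ft)$auc, 1)

  flat <- feature_table(data.frame(
    id = 1:8, apen = runif(8), pe = rep(5, 8), sampen = runif(8),
    class = rep(c(0, 1), each = 4)
  ))
  # constant predictor: every score identical, AUC is 0.5 by half-credit
  fit_flat <- fit_logistic(flat, character(0))
  expect_equal(roc_auc(fit_flat, flat)$auc, 0.5)
})

test_that("AIC ranking orders the five reference models as published", {
  ft <- fixture_table()
  fits <- list(
    fit_logistic(ft, "pe"),
    fit_logistic(ft, "apen"),
    fit_logistic(ft, "sampen"),
    fit_logistic(ft, c("pe", "apen")),
    fit_logistic(ft, c("pe", "sampen"))
  )
  rank <- compare_models(fits)
  expect_identical(
    rank$model,
    c("pe+apen", "pe+sampen", "pe", "apen", "sampen")
  )
  # the three AIC values the printed features reproduce at 0.01
  expect_lt(abs(rank$aic[rank$model == "pe"] - 28.03126), 0.01)
  expect_lt(abs(rank$aic[rank$model == "sampen"] - 34.79841), 0.01)
  expect_lt(abs(rank$aic[rank$model == "pe+sampen"] - 21.39607), 0.01)

  expect_identical(nrow(compare_models(fits[1])), 1L)
  # equal-q models: AIC difference equals deviance difference
  d <- compare_models(fits[1:3])
  expect_equal(diff(d$aic), diff(d$deviance), tolerance = 1e-12)
})
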