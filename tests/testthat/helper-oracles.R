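# Independent brute-force oracles: literal double-loop evaluations of the
# estimator definitions, written without reference to the package's
# vectorized implementations. Only usable at small L.

oracle_apen <- function(x, m, r) {
  L <- length(x)
  phi <- function(mm) {
    n <- L - mm + 1
    logC <- numeric(n)
    for (i in seq_len(n)) {
      cnt <- 0L
      for (j in seq_len(n)) {
        d <- 0
        for (k in 0:(mm - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d < r) cnt <- cnt + 1L
      }
      logC[i] <- log(cnt / n)
    }
    mean(logC)
  }
  phi(m) - phi(m + 1)
}

# literal convention: all L-mm+1 templates per pass, inner denominator L-mm
oracle_sampen_literal <- function(x, m, r) {
  L <- length(x)
  phi <- function(mm) {
    n <- L - mm + 1
    Ci <- numeric(n)
    for (i in seq_len(n)) {
      cnt <- 0L
      for (j in seq_len(n)) {
        if (j == i) next
        d <- 0
        for (k in 0:(mm - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d < r) cnt <- cnt + 1L
      }
      Ci[i] <- cnt / (L - mm)
    }
    mean(Ci)
  }
  pm <- phi(m)
  pm1 <- phi(m + 1)
  if (pm <= 0 || pm1 <= 0) return(NA_real_)
  -log(pm1 / pm)
}

# Richman-Moorman convention: both passes over the first L-m templates
oracle_sampen_canonical <- function(x, m, r) {
  L <- length(x)
  n <- L - m
  count_pairs <- function(mm) {
    cnt <- 0L
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j == i) next
        d <- 0
        for (k in 0:(mm - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d < r) cnt <- cnt + 1L
      }
    }
    cnt
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1)
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

# pairwise-comparison AUC: P(score1 > score0), ties counted half
oracle_auc <- function(scores, y) {
  s0 <- scores[y == 0]
  s1 <- scores[y == 1]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s0) * length(s1))
}

fixture_table <- function() reference_features()
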