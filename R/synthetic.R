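# Seeded generator of surrogate two-class temperature cohorts. The
# clinical recordings behind the reference feature table are not public,
# so end-to-end tests of the raw-series -> features -> classifier path
# run on these surrogates. The generative family is deliberately simple:
# baseline + circadian sinusoid + smoothed AR(1) noise, plus (for the
# febrile class) slow fever-like ramps and a small white jitter. The two
# levers decouple the features: amplitude irregularity *relative to the
# series SD* drives ApEn/SampEn, while the fine-scale ordinal diversity
# of the jitter drives PE without contributing visible amplitude.

#' Configuration of the surrogate temperature generator
#'
#' Defaults describe an 8-hour recording sampled once per minute
#' (`length = 480`). All amplitudes are in degrees Celsius.
#'
#' @param length Number of samples, `>= 50`.
#' @param baseline Baseline temperature level.
#' @param circadian_amplitude Amplitude of the slow circadian sinusoid.
#' @param circadian_period Period of that sinusoid in samples (minutes);
#'   default one day.
#' @param ar_phi AR(1) coefficient of the noise component, in `[0, 1)`.
#' @param ar_sd Innovation SD of the AR(1) noise.
#' @param smooth_halfwidth Half-width (samples) of the moving-average
#'   smoother applied to the noise; larger values give ordinally
#'   smoother traces (fewer distinct rank patterns).
#' @param ramp_count Number of fever-like ramps (0 for the healthy class).
#' @param ramp_amplitude Peak height of each ramp.
#' @param ramp_rise,ramp_fall Rise and fall time constants in samples.
#' @param jitter_sd SD of white measurement jitter added last (not
#'   smoothed); tiny relative to the ramps, it enriches ordinal patterns
#'   without affecting amplitude-based regularity.
#' @param series_cv Between-subject heterogeneity: `ar_sd`, `jitter_sd`
#'   and `ramp_amplitude` are multiplied per series by a lognormal
#'   factor with this log-scale SD (0 disables it). Without it every
#'   series of a class would share one regime and the two feature
#'   clouds would separate completely, unlike real cohorts.
#' @return A validated list of class `cohort_config`.
#' @seealso [healthy_config()], [febrile_config()], [generate_series()]
#' @export
cohort_config <- function(length = 480L,
                          baseline = 36.9,
                          circadian_amplitude = 0.25,
                          circadian_period = 1440L,
                          ar_phi = 0.85,
                          ar_sd = 0.06,
                          smooth_halfwidth = 4L,
                          ramp_count = 0L,
                          ramp_amplitude = 0.9,
                          ramp_rise = 40,
                          ramp_fall = 120,
                          jitter_sd = 0,
                          series_cv = 0.45) {
  cfg <- list(
    length = as.integer(length), baseline = baseline,
    circadian_amplitude = circadian_amplitude,
    circadian_period = as.integer(circadian_period),
    ar_phi = ar_phi, ar_sd = ar_sd,
    smooth_halfwidth = as.integer(smooth_halfwidth),
    ramp_count = as.integer(ramp_count), ramp_amplitude = ramp_amplitude,
    ramp_rise = ramp_rise, ramp_fall = ramp_fall,
    jitter_sd = jitter_sd, series_cv = series_cv
  )
  if (cfg$length < 50L) stop_parse("length must be >= 50")
  if (cfg$ar_phi < 0 || cfg$ar_phi >= 1) stop_parse("ar_phi must be in [0, 1)")
  for (fld in c("circadian_amplitude", "ar_sd", "ramp_amplitude", "jitter_sd")) {
    if (cfg[[fld]] < 0) stop_parse(sprintf("%s must be >= 0", fld))
  }
  if (cfg$series_cv < 0) stop_parse("series_cv must be >= 0")
  if (cfg$smooth_halfwidth < 0L) stop_parse("smooth_halfwidth must be >= 0")
  if (cfg$ramp_count < 0L) stop_parse("ramp_count must be >= 0")
  if (cfg$ramp_rise <= 0 || cfg$ramp_fall <= 0) stop_parse("ramp time constants must be > 0")
  structure(cfg, class = "cohort_config")
}

#' Default class-0 (healthy) generator configuration
#'
#' Circadian drift plus smoothed autocorrelated noise, no fever ramps:
#' the noise supplies most of the series SD, so amplitude-based
#' regularity (ApEn/SampEn) is comparatively high, while the smoothing
#' keeps the ordinal pattern repertoire modest (lower PE).
#' @return A [cohort_config()].
#' @export
healthy_config <- function() {
  cohort_config(
    ar_sd = 0.06,
    ar_phi = 0.85,
    smooth_halfwidth = 3L,
    jitter_sd = 0.006
  )
}

#' Default class-1 (febrile) generator configuration
#'
#' The same backbone plus slow high-amplitude fever ramps, weaker
#' autocorrelated noise and a small white measurement jitter. The ramps
#' dominate the series SD, so relative amplitude irregularity — hence
#' ApEn/SampEn — drops, while the unsmoothed jitter diversifies the
#' fine-scale rank patterns and raises PE.
#' @return A [cohort_config()].
#' @export
febrile_config <- function() {
  cohort_config(
    baseline = 37.6,
    ar_phi = 0.85,
    ar_sd = 0.035,
    smooth_halfwidth = 4L,
    ramp_count = 2L,
    ramp_amplitude = 1.0,
    ramp_rise = 40,
    ramp_fall = 120,
    jitter_sd = 0.010
  )
}

# centred moving average with reflected edges; h = 0 is a no-op
moving_average <- function(x, h) {
  if (h == 0L) return(x)
  n <- length(x)
  h <- min(h, n)
  pad <- c(rev(x[seq_len(h)]), x, rev(x[seq.int(n - h + 1L, n)]))
  k <- rep(1 / (2 * h + 1), 2 * h + 1)
  as.numeric(stats::filter(pad, k, sides = 2))[(h + 1):(h + n)]
}

#' Generate one surrogate temperature series
#'
#' Deterministic given `(config, class_label, seed)`. The RNG state of
#' the session is left untouched.
#'
#' @param config A [cohort_config()].
#' @param class_label 0 or 1, attached to the series.
#' @param seed Integer seed for this series.
#' @param series_id Identifier (default derived from class and seed).
#' @return A [time_series()].
#' @examples
#' s <- generate_series(febrile_config(), class_label = 1, seed = 7)
#' @export
generate_series <- function(config, class_label = 0L, seed = 1L,
                            series_id = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!class_label %in% c(0, 1)) stop_parse("class_label must be 0 or 1")
  if (is.null(series_id)) {
    series_id <- sprintf("c%d_seed%d", as.integer(class_label), as.integer(seed))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  # per-subject regime: lognormal multipliers on the stochastic amplitudes
  fac <- if (config$series_cv > 0) {
    exp(stats::rnorm(3, 0, config$series_cv))
  } else {
    c(1, 1, 1)
  }
  config$ar_sd <- config$ar_sd * fac[1]
  config$jitter_sd <- config$jitter_sd * fac[2]
  config$ramp_amplitude <- config$ramp_amplitude * fac[3]

  L <- config$length
  t <- seq_len(L) - 1
  phase <- stats::runif(1, 0, config$circadian_period)
  circ <- config$circadian_amplitude *
    sin(2 * pi * (t + phase) / config$circadian_period)

  burn <- 100L
  innov <- stats::rnorm(L + burn, 0, config$ar_sd)
  ar <- as.numeric(stats::filter(innov, config$ar_phi, method = "recursive"))
  ar <- ar[(burn + 1):(burn + L)]
  noise <- moving_average(ar, config$smooth_halfwidth)

  ramps <- numeric(L)
  if (config$ramp_count > 0L && config$ramp_amplitude > 0) {
    onsets <- sort(stats::runif(config$ramp_count, -config$ramp_fall, L))
    for (o in onsets) {
      s <- t - o
      shape <- ifelse(s >= 0, exp(-s / config$ramp_fall) - exp(-s / config$ramp_rise), 0)
      peak <- max(shape)
      if (peak > 0) ramps <- ramps + config$ramp_amplitude * shape / peak
    }
  }

  jitter <- if (config$jitter_sd > 0) stats::rnorm(L, 0, config$jitter_sd) else 0

  time_series(
    config$baseline + circ + noise + ramps + jitter,
    series_id = series_id,
    class_label = class_label
  )
}

#' Generate a labelled two-class surrogate cohort
#'
#' Per-series seeds are drawn deterministically from `master_seed`, so a
#' cohort is a pure function of `(config0, config1, n0, n1, master_seed)`.
#'
#' @param config0,config1 Class-0 and class-1 [cohort_config()]s
#'   (defaults [healthy_config()] and [febrile_config()]).
#' @param n0,n1 Number of series per class (defaults 16 and 14, the
#'   reference cohort sizes).
#' @param master_seed Integer master seed.
#' @return List of `n0 + n1` labelled [time_series()] objects (class 0
#'   first).
#' @examples
#' cohort <- generate_cohort(n0 = 3, n1 = 3, master_seed = 42)
#' vapply(cohort, function(s) s$class_label, integer(1))
#' @export
generate_cohort <- function(config0 = healthy_config(),
                            config1 = febrile_config(),
                            n0 = 16L, n1 = 14L, master_seed = 1L) {
  if (n0 < 1L || n1 < 1L) stop_parse("n0 and n1 must be >= 1")
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max - 1L, n0 + n1)
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }

  out <- vector("list", n0 + n1)
  for (i in seq_len(n0)) {
    out[[i]] <- generate_series(config0, 0L, seeds[i],
      series_id = sprintf("h%02d", i)
    )
  }
  for (j in seq_len(n1)) {
    out[[n0 + j]] <- generate_series(config1, 1L, seeds[n0 + j],
      series_id = sprintf("p%02d", j)
    )
  }
  out
}

#' Write a cohort as a series CSV plus a labels CSV
#'
#' The series file uses the multi-column CSV dialect of [read_series()];
#' the labels file has columns `id`, `class`.
#'
#' @param cohort List of labelled [time_series()] objects.
#' @param series_path,labels_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, series_path, labels_path) {
  write_series_csv(cohort, series_path)
  labels <- data.frame(
    id = vapply(cohort, function(s) s$series_id, character(1)),
    class = vapply(cohort, function(s) s$class_label, integer(1))
  )
  utils::write.csv(labels, labels_path, row.names = FALSE)
  invisible(c(series_path, labels_path))
}

#' Read a cohort written by [write_cohort()]
#'
#' @param series_path,labels_path Paths written by [write_cohort()].
#' @return List of labelled [time_series()] objects.
#' @export
read_cohort <- function(series_path, labels_path) {
  series <- read_series(series_path)
  labels <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  if (!all(c("id", "class") %in% names(labels))) {
    stop_parse("labels file needs columns id, class")
  }
  lapply(series, function(s) {
    hit <- match(s$series_id, labels$id)
    if (is.na(hit)) stop_parse(sprintf("no label for series '%s'", s$series_id))
    s$class_label <- as.integer(labels$class[hit])
    s
  })
}
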