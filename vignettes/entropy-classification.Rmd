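---
title: "Classifying body-temperature time series with combined entropy features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying body-temperature time series with combined entropy features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(tempentropy)
```

## The problem

Continuous body-temperature monitoring (one sample per minute over several
hours) carries information about thermoregulation that single readings miss.
The question this package addresses is whether a short daytime temperature
trace suffices to tell febrile inpatients from healthy individuals — and, when
no single regularity statistic separates the groups convincingly, whether a
*pair* of statistically independent statistics combined in one logistic model
does.

The pipeline has four stages: entropy feature extraction, a correlation screen
that decides which features may share a model, logistic classification with
full diagnostics, and paired leave-one-out validation. A bundled feature table
of 30 subjects (16 healthy, 14 febrile; `reference_features()`) exercises the
modelling stages at desk scale, and a seeded surrogate-cohort generator
exercises the raw-series path end to end.

## The three entropy statistics

All three statistics operate on windows of `m` consecutive samples. They split
into two families:

**Amplitude-based.** `approximate_entropy()` (ApEn) and `sample_entropy()`
(SampEn) ask how often two windows are similar in amplitude — Chebyshev
distance below a tolerance `r` — and how much that similarity decays when the
window grows from `m` to `m + 1`. ApEn log-averages the per-template match
fractions and includes self-matches; SampEn removes the self-match bias and
takes `-log` of the ratio of average match fractions. Both are computed on the
z-scored series by default (`normalize = TRUE`, population SD), which makes
`r` a fraction of the series SD and the result scale-invariant.

**Ordinality-based.** `permutation_entropy()` (PE) replaces each window by the
permutation that sorts its samples ascending and returns the Shannon entropy
(in bits) of the resulting pattern distribution. PE ignores amplitude
entirely, so it is exactly invariant under strictly increasing transforms of
the signal — the property that makes it a natural partner for an
amplitude-based measure rather than a competitor.

### Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `m` (ApEn/SampEn) | 1 | embedding window length |
| `r` | 0.25 | tolerance, as a fraction of the series SD |
| `m` (PE) | 8 | ordinal pattern order |
| `tau` | 1 | embedding delay (original time scale) |
| `L` | 480 | series length: 8 h at one sample per minute |

These defaults are the configuration under which the bundled feature table was
produced; `entropy_sweep()` reproduces the kind of grid exploration (ApEn/SampEn
over `m` in {1, 2} and `r` in 0.10–0.25; PE over `m` in 3–8) that motivated
them. Note that `m = 8` does not satisfy the usual `m! << L` recommendation at
`L = 480`; it is retained because it is the configuration of the reference
features, and the PE upper bound `log2(min(m!, L - m + 1))` is enforced in the
property tests instead.

### Numerical conventions

Several small conventions matter for reproducibility and are therefore
explicit, tested flags:

- **Match inequality.** A template pair matches when its distance is
  *strictly* below `r`. Many public implementations use `<=`; the
  `strict = FALSE` flag switches, and the test suite uses it to cross-check
  against `pracma`.
- **SampEn convention.** `mode = "literal"` evaluates the defining formulas
  over all `L - m + 1` templates of each length with inner denominator
  `L - m` (the same formulas applied to both the `m` and `m + 1` passes);
  `mode = "canonical"` is the Richman–Moorman count restricted to the first
  `L - m` templates, the convention of most toolboxes. Both are tested
  against independent double-loop oracles; they differ only at small `L`.
- **PE ties.** Quantized temperature data tie frequently, and ordinal
  patterns are only defined for strict orderings, so a rule is mandatory:
  ranking is stable (the earlier sample takes the lower rank), via a radix
  sort. This is deterministic and matches the most common convention.
- **Degenerate inputs.** A constant series cannot be z-scored (typed
  `tempentropy_degenerate` error); a tolerance too tight to yield any match
  makes SampEn undefined (typed `tempentropy_undefined_entropy` error, never
  a silent `NaN`); series shorter than the embedding requirements are
  refused.
- **Logarithms.** Natural log inside ApEn/SampEn, base 2 (bits) for PE.

## The correlation screen

Pearson correlation of each feature pair over all records, with the two-sided
t-test p-value on `n - 2` degrees of freedom (`stats::cor.test`). A pair may
enter a joint model only if its correlation is *not* significant
(`admissible_pairs()`, default threshold 0.05; a pair is excluded when
`p < 0.05`). On the reference table this admits PE+ApEn and PE+SampEn and
excludes ApEn+SampEn, whose correlation is ~0.96: the two amplitude-based
measures are near-duplicates, while PE is uncorrelated with either — the
empirical basis for combining across the two families. Pearson (not Spearman)
correlation is used because it reproduces the reference matrices; no
multiple-testing adjustment is applied across the three pairs.

## The logistic classifier and its diagnostics

`fit_logistic()` models the class-1 probability as the logistic transform of a
linear combination of one or two features, fitted by unregularized maximum
likelihood (IRLS via `stats::glm`, deviance tolerance 1e-8, at most 50
iterations). The diagnostic panel is computed in the package and each identity
is enforced by tests:

- Wald statistic `(b / SE)^2` against chi-squared(1) — identical to the
  two-sided z-test; per-predictor likelihood-ratio p-values are exposed
  alongside but are not the default reading.
- Odds ratio `Exp(B) = exp(b)`.
- Deviance `-2LL`; null deviance in closed form
  `2 (n0 log(n/n0) + n1 log(n/n1))`.
- Cox–Snell `R^2 = 1 - exp((D_model - D_null)/n)` and Nagelkerke
  `R^2` (Cox–Snell divided by its ceiling `1 - exp(-D_null/n)`).
- `AIC = D + 2(q + 1)`.

Classification at threshold 0.5 is strict (`p > 0.5` predicts class 1; a
record exactly at the threshold classifies as 0). In the confusion summary,
"sensitivity" is the percentage of class-0 records classified correctly and
"specificity" the class-1 percentage — the reversed-looking convention of
this cohort's literature, kept for comparability. The ROC curve sweeps all
score thresholds; its trapezoidal area equals the Mann–Whitney rank
probability with half-credit ties, which the tests verify against a pairwise
oracle and `pROC`.

Quasi- or complete separation is flagged (`$separation`) rather than hidden:
besides `glm`'s own warnings, any fitted probability within 1e-8 of 0 or 1
raises the flag, because IRLS can "converge" quietly once the deviance
plateaus under separation.

## Paired leave-one-out

With 16 class-0 and 14 class-1 records no 1:1 pairing covers every record
symmetrically, so `leave_pair_out()` enumerates **all** `16 × 14 = 224`
(class-0, class-1) pairs: each fold refits on the remaining 28 records and
predicts the held-out pair. This all-pairs scheme is the unique symmetric
completion of "hold out one record of each class"; a cyclic 1:1 scheme is
available as a strategy parameter for comparison. Because each record is
tested many times, both the per-prediction average and the per-record average
accuracy are reported; they differ little on the reference table. Fold
enumeration order is fixed, so results are bit-reproducible.

## The surrogate cohort generator

The clinical recordings behind the reference features are not public, so the
raw-series path is tested on surrogates from `generate_cohort()`. A series is

```
baseline + circadian sinusoid + smoothed AR(1) noise [+ fever ramps + jitter]
```

with per-subject lognormal variability (`series_cv`) on the stochastic
amplitudes. The family was chosen as the simplest one that *decouples* the two
feature families:

- **Class 0** (`healthy_config()`): the smoothed AR(1) noise supplies most of
  the series SD, so consecutive samples move by a substantial fraction of
  `r × SD` — relatively high ApEn/SampEn — while the smoothing keeps ordinal
  patterns repetitive — moderate PE.
- **Class 1** (`febrile_config()`): slow fever-like ramps (double-exponential
  rise/fall) dominate the SD, so the trace is locally predictable at the
  `r × SD` scale — low ApEn/SampEn — while a tiny unsmoothed measurement
  jitter diversifies the fine-scale rank patterns — high PE — without
  contributing visible amplitude.

The defaults were fixed once so that the two feature clouds overlap partially
(as the reference cohort's do) rather than separating completely, and are not
meant to be refitted per analysis. What the surrogates do **not** emulate:
probe placement and measurement artefacts, quantization of the thermometer,
the chronobiology of real fever episodes, or the absolute feature ranges of
the reference table (surrogate PE at `m = 8` sits lower than the reference
values; see the last section). Passing synthetic-pipeline tests therefore
demonstrates that the code recovers a planted class geometry — positive PE
coefficient, negative ApEn coefficient, high AUC — not that the generator is
physiologically faithful.

## Problem sizes in the test suite

The suite runs at desk scale: brute-force oracle comparisons on series up to
`L = 150`; modelling tests on the 30-record reference table; 224-fold
leave-pair-out per model; and a 50-replicate synthetic experiment with
30 series of 480 samples per replicate, which dominates the runtime at
roughly a minute.

## Known limitations and open points

- The bundled PE values reach 9.96 bits, above the `log2(473) ≈ 8.89`
  ceiling that `L = 480`, `m = 8` implies — the source features were
  evidently computed on longer windows than the 8-h segment. The table is
  shipped verbatim as the modelling ground truth, and no attempt is made to
  regenerate entropy values from raw data (none are available). Consequently
  the entropy stage is accepted by oracle and property tests, not by
  reproducing those numbers.
- The shipped 6-decimal ApEn column does not reproduce the published
  ApEn-model deviances to the last hundredth (the refits land ~0.02–0.05
  higher); coefficients, classifications and the AIC *ranking* reproduce
  fully. The corresponding assertions keep the strict tolerance and document
  the discrepancy rather than widening the band.
- Published leave-one-out averages depend on an unstated pairing convention;
  under the all-pairs scheme the recomputed accuracies fall within a few
  points of all of them, and they are treated as plausibility bands, not
  exact targets.
- Multiscale (`tau > 1`) entropy paths exist but are deliberately not tuned;
  fuzzy/distribution entropy and non-logistic classifiers are out of scope.
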