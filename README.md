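# tempentropy

Entropy features and logistic classification of body-temperature time series.

## The problem

Short continuous temperature recordings (one sample per minute over a few
hours) separate febrile inpatients from healthy individuals only marginally
when a single regularity statistic is used. `tempentropy` implements the
alternative: extract one **amplitude-based** regularity statistic (approximate
entropy ApEn, or its bias-reduced variant, sample entropy SampEn) and one
**ordinality-based** statistic (permutation entropy PE), verify by a
correlation screen that the two carry independent information, and combine
them as joint predictors of a logistic classifier,

```
p(z) = exp(b0 + b1 z1 + b2 z2) / (1 + exp(b0 + b1 z1 + b2 z2)),
```

where `z1`, `z2` are entropy features and `p(z)` the probability that a record
comes from a patient (class 1). The package computes the full diagnostic
panel — standard errors, Wald statistics, odds ratios `Exp(B)`, deviance
`-2LL`, Cox–Snell and Nagelkerke pseudo-R², AIC, ROC/AUC, confusion summaries
— plus paired leave-one-out validation (all class-0 × class-1 hold-out pairs),
and ships:

- `reference_features()` — a 30-subject feature table (16 healthy /
  14 febrile) from a published body-temperature monitoring cohort, the
  modelling ground truth;
- the three entropy estimators with explicit, tested numerical conventions
  (strict `< r` matching, literal vs canonical SampEn, stable PE
  tie-breaking), a parameter-sweep helper, and raw-series CSV ingest;
- `generate_cohort()` — a seeded surrogate generator of two-class 8-h
  temperature traces for end-to-end testing;
- a command-line front end
  (`system.file("cli", "tempentropy.R", package = "tempentropy")`) with
  `features`, `analyze`, `simulate` and `fixture-export` subcommands.

## Worked example

```r
library(tempentropy)
ft <- reference_features()

correlation_screen(ft)
#> <correlation_screen> n = 30
#> Pearson r:
#>           apen      pe  sampen
#> apen    1.0000 -0.2366  0.9601
#> pe     -0.2366  1.0000 -0.1342
#> sampen  0.9601 -0.1342  1.0000
#> two-sided p:
#>          apen     pe sampen
#> apen       NA 0.2082 0.0000
#> pe     0.2082     NA 0.4795
#> sampen 0.0000 0.4795     NA
```

ApEn and SampEn are nearly collinear (r = 0.96, p < 1e-4) and must not share
a model; PE is uncorrelated with both (p = 0.21, 0.48), so PE+ApEn and
PE+SampEn are admissible joint models. The best of them:

```r
fit <- fit_logistic(ft, c("pe", "apen"))
fit
#> <logistic_fit> class ~ pe + apen  (n = 30: 16/14)
#>         term estimate std_error   wald df p_value   lr_p  exp_b
#>  (Intercept) -24.9990   13.7310 3.3147  1  0.0687     NA  0.000
#>           pe   3.4396    1.6050 4.5926  1  0.0321 0.0003 31.176
#>         apen -12.8086    6.4682 3.9214  1  0.0477  0.0024  0.000
#> -2LL 14.83332 (null 41.45540)  Cox-Snell R2 0.588  Nagelkerke R2 0.786  AIC 20.83332

confusion_summary(fit)
#> <confusion_summary> threshold 0.5
#>         predicted
#> observed  0  1
#>        0 15  1
#>        1  1 13
#> class 0 correct 93.8%  class 1 correct 92.9%  total 93.3%

roc_auc(fit)$auc
#> [1] 0.9554

leave_pair_out(ft, c("pe", "apen"))
#> <loo_result> 224 folds; held-out accuracy 88.17% (per prediction), 88.27% (per record)
```

Read: higher PE raises the fitted fever probability (odds ratio ~31 per bit),
higher ApEn lowers it; the joint model classifies 28/30 records correctly
in-sample (93.3%), versus 83.3% for the best single feature, and holds 88% on
224 leave-pair-out refits — the synergy of combining an ordinal with an
amplitude measure. `compare_models()` confirms PE+ApEn has the minimum AIC of
the five candidate models.

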