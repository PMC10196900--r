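# bingesense

Predicting imminent, same-day binge-drinking events (BDEs) from passively
sensed smartphone data.

## What this package is for

Digital just-in-time interventions for risky drinking need to know *when*
support will matter: in the hours before a drinking occasion starts, not
after.  `bingesense` implements an end-to-end pipeline that takes raw
phone sensor streams (GPS, accelerometer, call/SMS logs, screen and app
events, battery, Wi-Fi) plus twice-weekly self-reported drinking logs and
builds three-class predictors of the upcoming day class — non-drinking
(N), low-risk drinking (D, 1–3 drinks for women / 1–4 for men), or binge
(BDE, ≥4 / ≥5 drinks) — at a configurable lead time before onset.

The modelling core follows the standard mobile-sensing design: sensor
data are cut into 15-minute epochs; an **analysis window** of *w* hours of
features ending *d* hours before (pseudo-)onset — the **prediction
distance** — forms one instance, so

```
features( [onset − (w+d), onset − d) )  →  P(N), P(D), P(BDE)
```

with `w ∈ {1,3,6,9,12}` and `d ∈ {1,3,6}` searched per day class (weekday
vs weekend).  Seventy behavioral features are computed per window,
including GPS mobility metrics — radius of gyration
`r_g = sqrt(mean(dist(p_i, centroid)^2))`, location entropy
`H = −Σ p_c log p_c` over significant-place dwell, location variance,
Lomb–Scargle circadian movement — alongside accelerometer magnitude
statistics, communication counts, device-use and Wi-Fi features.  Class
imbalance is handled with SMOTE on the training side only; models
(gradient boosting by default; random forest, decision tree, SVM and
multinomial logistic are also wrapped) are tuned by seeded random search
under 10-fold cross-validation and scored by accuracy, macro-F1, Cohen's
kappa and per-class precision/recall/F1 against a day-of-week baseline.
A Shapley/PDP explanation layer reports which features drive BDE
predictions and produces a privacy-coarsened location-probability map.

Because raw sensor data of this kind are not publicly deposited, the
package ships a first-class seeded cohort generator
(`simulate_cohort()`) calibrated to the reference study's event mix,
BDE day-of-week and onset-hour distributions, with a planted,
recoverable behavioral signal; every stage of the pipeline is tested
against it.

## Worked example

```r
library(bingesense)

# a planted-signal cohort: 75 participants, 14 weeks, seed 7
pl <- run_pipeline(config = signal_recovery_config(), seed = 7,
                   day_classes = "weekend", algorithms = "xgboost",
                   search_trials = 20, explain = TRUE)

pl$grid$grid[, .(model_id, accuracy, macro_f1, kappa, bde_f1, baseline_macro_f1)]
#>       model_id  accuracy  macro_f1     kappa    bde_f1 baseline_macro_f1
#> 1:  WEXGB-W1D1 0.8421053 0.8005449 0.7483217 0.6902655         0.2211055
#> 2:  WEXGB-W3D1 0.9172932 0.8896270 0.8673858 0.8173913         0.2211055
#> 3:  WEXGB-W6D1 0.8834586 0.8464706 0.8140364 0.7540984         0.2211055
#> 4:  WEXGB-W9D1 0.8984962 0.8646447 0.8376215 0.7719298         0.2211055
#> 5: WEXGB-W12D1 0.8796992 0.8391936 0.8062284 0.7339450         0.2211055
#> 6:  WEXGB-W3D3 0.8759398 0.8372877 0.8011508 0.7321429         0.2211055
#> 7:  WEXGB-W3D6 0.6052632 0.5729569 0.3405582 0.5833333         0.2211055

pl$explanations$weekend$importance[1:5]
#>              feature importance
#> 1:       hour_of_day  0.7205498
#> 2:     dwell_place_1  0.5058320
#> 3:      time_at_home  0.4823696
#> 4:           lon_std  0.3141088
#> 5: location_variance  0.2687100
```

Reading this output: the best weekend cell uses a 3-hour window at a
1-hour prediction distance (`WEXGB-W3D1`), reaching macro-F1 0.89 where
the day-of-week baseline manages 0.22 — the planted behavioral signal is
recovered.  The attribution ranking surfaces the planted channels: the
hour of day at prediction time, home-dwelling structure, and the
travel-spread family (location variance, coordinate dispersion, radius of
gyration and their correlates share the credit), mirroring the
qualitative finding that time of day plus GPS-derived travel extent carry
most of the predictive signal for binge events.

## Command line

A thin CLI over the same functions lives at `inst/cli/bingesense`:

```sh
Rscript inst/cli/bingesense simulate --seed 7 --out fixtures/
Rscript inst/cli/bingesense build    --in fixtures/ --seed 1 --out build/
Rscript inst/cli/bingesense train    --in build/    --seed 1 --out models/
Rscript inst/cli/bingesense explain  --in models/   --out explain/
```

See the methods vignette (`vignettes/methods.Rmd`) for the model,
feature definitions, generator mechanism, numerical choices, and known
limitations.
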