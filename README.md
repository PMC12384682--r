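# wardtrig

Ambient environmental triggers of agitation subtypes on dementia care wards.

Agitation is among the most burdensome behavioural symptoms of dementia, and
clinical frameworks (the progressively lowered stress threshold, the unmet
needs model) suggest it is partly driven by the immediate environment —
over- or understimulation by light and sound. `wardtrig` implements, as a
tested and reusable pipeline, an analysis that quantifies those triggers on
a momentary basis: nurses rate agitation nine times a day with the
Pittsburgh Agitation Scale under an experience-sampling schedule, fixed
sensors record light (lux), sound (leqDBA) and temperature (°C) per room,
a location trace says which room the patient was in, and the question is
whether the environment in the window **33 to 12 minutes before** a rating
predicts agitation — and whether the *motor* and *verbal* subtypes respond
to different modalities (lower mean light for motor agitation, higher sound
variability for verbal agitation).

The package is aimed at researchers in ambient sensing / digital
phenotyping for dementia care who want to run, extend or stress-test this
kind of analysis without access to clinical data.

## What it computes

For survey *j* of patient *i* and binary outcome *y* (overall, motor or
verbal agitation from binarized PAS scores), the core model is a
random-intercept binomial GLMM

    logit P(y_ij = 1) = x_ij' beta + b_i,     b_i ~ N(0, sigma_b^2)

fitted by direct maximization of the marginal likelihood with adaptive
Gauss–Hermite quadrature (25 nodes; Laplace as the fast option). The
covariates are the time-of-day group ([8,12), [12,16), [16,20), [20,8)),
the majority-room group of the pre-survey window, and descriptive features
(min, max, mean, median, SD) of the smoothed, location-conditioned sensor
series in the half-open window [t − buffer − L, t − buffer), standardized
within the majority room. Nested models are compared with chi-square
likelihood-ratio tests; window length and per-modality features are chosen
by an exploratory coefficient sweep; a forward build-up (models 0–9)
mirrors the staged analysis. A synthetic ward generator with known
generative parameters (`simulate_ward()`) makes every stage verifiable by
parameter recovery.

## Worked example

Simulate a small ward study, extract and quality-filter the pre-survey
windows at the 21-minute length, and fit the verbal-agitation model:

```r
library(wardtrig)

cfg <- sim_config(seed = 42, n_patients = 40, days = 4,
                  sample_period = 10, smoothing_span = 10)
ds <- simulate_ward(cfg)
ds
#> Synthetic ward study dataset
#>   40 patients x 4 days, 1440 surveys (28.3% agitated)
#>   829,440 sensor readings from 8 enclosures in 7 rooms
#>   location intervals: 8401 (off-map fraction 0.17)

fx <- extract_features(ds, lengths = 21)
sum(fx$features$pass)          # windows surviving the four quality filters
#> [1] 1035

d <- subset(as.data.frame(fx$features), pass & is.finite(z_sound_sd))
fit <- fit_glmm(verbal ~ z_sound_sd + time_group + maj_room_group +
                  (1 | patient_id), d)
summary(fit)
#>                            Estimate Std. Error z value Pr(>|z|)
#> (Intercept)                -3.59527    0.33687 -10.673  < 2e-16 ***
#> z_sound_sd                  0.59261    0.09728   6.092 1.12e-09 ***
#> time_group2                 0.87488    0.28624   3.056  0.00224 **
#> time_group3                 1.39660    0.28102   4.970 6.70e-07 ***
#> ...
#> Random intercept (per patient_id): SD = 0.8803
#> logLik = -344.8493, n = 1035, groups = 40
```

The planted generative coefficient for the standardized sound-SD was 0.68:
one within-room SD more sound variability in the 33-to-12-minute window
raises the odds of a verbal-agitation rating by

```r
odds_ratio(fit, "z_sound_sd")
#>    or lower upper
#> 1.809 1.495 2.189
```

and the ANOVA gate keeps the term:

```r
lrt(fit_glmm(verbal ~ time_group + maj_room_group + (1 | patient_id), d),
    fit)
#> LRT: delta deviance = 38.3595 on 1 df, p = 5.88e-10 -> keep (alpha = 0.05)
```

The full chain — sweep over window lengths, window and feature selection,
forward build-up per outcome, publication-style output tables and an
attrition log — runs as

```r
run_pipeline(sim = cfg, out_dir = "run1", lengths = seq(3, 30, 3), seed = 42)
```

A thin command-line wrapper lives at `inst/scripts/wardtrig.R`.

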