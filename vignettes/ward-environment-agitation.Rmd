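---
title: "Linking ward environment to agitation subtypes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking ward environment to agitation subtypes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

wardtrig implements a complete analysis chain for a question from
psychogeriatric care: do ambient light, sound and temperature in the minutes
*before* a momentary agitation rating predict whether a person with dementia
will be rated agitated — and do the motor and verbal subtypes respond to
different environmental factors? This vignette explains the statistical
model, every stage of the data processing, the synthetic ward that makes the
whole chain testable without patient data, and the design decisions that
were genuinely open.

## The model

The outcome is a binarized Pittsburgh Agitation Scale (PAS) rating collected
by nurses under an experience-sampling schedule (nine semirandom prompts per
day between 8 AM and 8 PM). Each of the four subtype scores (motor, verbal,
resistance to care, aggression; each 0–4) is present when it is at least 1;
overall agitation is present when any subtype is.

For survey $j$ of patient $i$ the package fits random-intercept binomial
GLMMs of the form

$$
\operatorname{logit}\,P(y_{ij} = 1)
 = \mathbf{x}_{ij}^\top\beta + b_i,
 \qquad b_i \sim \mathcal N(0, \sigma_b^2),
$$

where $\mathbf{x}_{ij}$ contains an intercept, the time-of-day group of the
survey (four clock bins $[8,12)$, $[12,16)$, $[16,20)$, $[20,8)$; reference
group 1 — a sundowning proxy), the majority-room group of the pre-survey
window (living room reference), and standardized environmental features.
The patient-level intercept $b_i$ absorbs stable between-patient differences
in agitation propensity. Because features are standardized within room, a
coefficient is the log-odds change per *one within-room SD* of the feature;
`odds_ratio()` exponentiates it.

`fit_glmm()` maximizes the marginal likelihood directly. The per-patient
integral over $b_i$ has no closed form and is evaluated by adaptive
Gauss–Hermite quadrature: the integrand is recentred at its conditional mode
(an inner Newton iteration, globally concave) and rescaled by the curvature
there, then integrated on 25 Hermite nodes by default (`nAGQ = 1` is the
Laplace approximation). Estimation is deterministic: fixed effects start at
the plain logistic fit, $\log\sigma_b$ at zero, and a quasi-Newton search
runs to a relative tolerance of $10^{-14}$ with one polish restart.
Inference on fixed effects is Wald-based (the convention of standard mixed
model summaries); the 95% CI is $\hat\beta \pm 1.96\,\mathrm{SE}$. Nested
models are compared by the chi-square likelihood-ratio test (`lrt()`,
`anova()`); no multiplicity correction is applied anywhere, deliberately —
the analysis is exploratory, not confirmatory.

Numerical safeguards worth knowing about: $\log\sigma_b$ is softly bounded
at $[-8, 4]$, and a fit whose variance estimate hits the lower bound is
reported with `boundary = TRUE` (this is how a zero-variance truth
manifests; the fixed effects then agree with plain `glm()`). Complete
separation is flagged as non-convergence rather than silently returning a
huge coefficient. If a "full" model ever attains a lower likelihood than
its nested comparator (a failed inner optimization), `lrt()` refits it from
the nested solution before testing, so the reported deviance difference is
never negative beyond tolerance.

## From sensor streams to features

Each survey's analysed interval is $[t - b - L,\; t - b)$ for buffer $b$
(default 12 minutes) and window length $L$: it *ends 12 minutes before* the
survey so that the features predict upcoming agitation rather than detect
ongoing agitation — audible verbal agitation would otherwise contaminate
the sound channel. All intervals are half-open: a reading at exactly the
window start belongs to the window, one at the end does not; likewise a
survey at exactly 20:00 falls outside the 8–20 frame.

Per window the stages are (`extract_window()` for one survey,
`extract_features()` vectorized over the study):

1. **Occupancy** (`locate_rooms()`): the patient's location trace is clipped
   to the window; trace gaps and explicit `off_map` intervals count as
   off-map. The *majority room* is the room with the most seconds (ties:
   earliest entered within the window).
2. **Fusion** (`fuse_sensor_series()`): readings of each occupied room are
   clipped to its segments; rooms with two sensor enclosures contribute the
   timestamp-aligned mean of both; sensorless rooms contribute nothing;
   segments are appended chronologically.
3. **Smoothing** (`smooth_series()`): a trailing moving average over the
   previous 5 seconds (including the current point), applied *after*
   concatenation — its purpose is exactly to soften room-transition jumps.
   Trailing (causal) rather than centred, because the pipeline feeds
   prediction and must not use future samples.
4. **Features** (`compute_features()`): min, max, mean, median and sample SD
   (denominator $n-1$) per modality, plus the point count.
5. **Quality filters** (`apply_quality_filters()`), all four evaluated
   independently: off-map fraction $< 50\%$ (time-based — robust to sampling
   gaps); at least $50\%$ of the expected points (window seconds divided by
   the nominal sampling period) in every modality; a sensored majority room;
   survey inside 8–20h. On realistic traces the off-map/sensorless path
   dominates the exclusions.
6. **Standardization** (`standardize_features()`): features are z-scored
   within (majority room, modality, feature) strata, so "+1" means one SD
   above that room's typical value — interpretable across rooms and wards.
   The standardizer is fitted per window length on quality-passing rows
   only; strata with fewer than two rows or zero spread yield undefined
   z-scores and those rows are excluded from modelling.

## Window and feature selection, model build-up

`sweep_windows()` fits the exploratory model
`outcome ~ z_feature + time_group + (1 | patient_id)` for every window
length (3–30 minutes in steps of 3, or any subset), every standardized
feature (5 per modality) and every outcome (overall, motor, verbal), and
records the feature coefficient with its Wald statistics — 450 fits at the
full sweep. `select_window()` then scores each length by the total
$|z|$-weight of the cells that are significant there *and* attain their
across-length maximum $|\hat\beta|$ there; the top-scoring length wins,
longer lengths winning ties. The weighting matters: features within a
modality are strongly mutually correlated, and unweighted vote counts let a
bloc of marginal cells herd onto the same spurious length.

`select_features()` picks, per outcome and modality, the feature with the
largest absolute coefficient at the chosen length (ties broken by the fixed
order min, max, mean, median, sd), and drops a whole modality when none of
its features is significant for any outcome — the rule is generic, though
in practice it is temperature that falls.

`forward_build()` runs the staged sequence per outcome: model 0 is the
patient-intercept null; models 1–2 add time group and majority-room group;
models 3–4 add the selected sound and light features separately on top of
the context; model 5 both; models 6–9 the interactions of each modality
with time and room. Every addition is gated by the LRT at $\alpha = .05$,
except that the contextual covariates are retained regardless (domain
knowledge: sundowning and location confounding), and all models in a
sequence are fitted on the identical listwise-complete row set so each
comparison is valid. `run_pipeline()` chains everything and writes an
auditable run directory (features, quality report, coefficient grid,
selection, fits, the ANOVA table, and a log with row counts after every
stage).

## The synthetic ward

`simulate_ward()` generates a complete study with known truth: a ward of
connected rooms (communal living and dining spaces large enough for two
sensor enclosures, a hallway, patient rooms — one without a sensor — and a
therapy room), continuous per-room environmental processes, semi-Markov
patient movement with configurable off-map (untracked) time, the stratified
survey schedule, and outcomes drawn from the logistic model above with the
environmental coefficients *planted* on the standardized features of the
causal window 33 to 12 minutes before each survey.

What the processes emulate, and the design constraints discovered while
building them:

* **Light** is lognormal with a diurnal profile (night ~4.5 lux, daytime
  tens of lux per room), calibrated so a simulated week pools to a median
  around 22 lux with an IQR spanning roughly 7–55 lux — the dim range
  reported for real dementia wards. **Sound** is a Gaussian dBA level with
  slow drift, a slowly varying noise scale and Poisson bursts (care
  activity); bursts and the volatility process are what make the window SD
  genuinely differ between windows. **Temperature** drifts slowly around
  22 °C and carries no planted effect.
* **Correlation times are window-scale** (7–10 minutes). Early versions
  used hour-scale drifts; then any two overlapping windows shared their
  slow state, a ward-week contained only ~20 effectively independent
  feature draws per room, and spurious cross-correlations of $\pm 0.2$
  between unrelated modalities were the norm. Worse, a 12-minute
  sub-window measured almost the same feature as the 21-minute causal
  window, making the causal length unidentifiable in principle. For the
  planted window to be *detectable*, the environment must fluctuate within
  it.
* **Each modality's window SD is driven by its own process.** Room
  transitions inflate the window SD of *every* modality simultaneously
  (the appended segments jump between room levels), which initially made
  temperature-SD a proxy for the causal sound-SD. The defaults therefore
  keep between-room temperature spread at a centrally-heated-ward level
  (±0.05 °C), give sound ample intrinsic volatility, and keep the burst
  rate near-flat across 8–20h so burst occurrence is not a clock-time
  proxy.
* **Truth standardization**: the generator standardizes its causal features
  within majority room using the *realized replicate's* moments
  (`truth_standardization = "empirical"`). A law-level alternative
  (`"law"`, moments of fresh single-room windows from the generative
  process) is retained, but single-room moments mis-scale the many windows
  that span several rooms, which biased recovered coefficients by up to
  ~40%. With empirical truth moments, recovery still crosses two
  independent standardizations, because the pipeline refits its own moments
  on quality-passing rows only.
* **Co-occurrence** of motor and verbal agitation comes from the shared
  patient intercept plus a mild direct term ($\kappa = 0.4$ times the motor
  indicator in the verbal predictor). $\kappa$ is kept mild deliberately:
  the verbal model of the analysis omits the motor indicator, and a strong
  direct coupling would attenuate the recovered sound coefficient through
  logistic non-collapsibility. Intercepts are calibrated so roughly 28% of
  surveys are agitated, with more motor-only than verbal-only surveys and a
  few agitated surveys that are neither (resistance/aggression riders).
* An optional `outcome_mode = "direct"` draws *overall agitation* from its
  own logistic predictor (subtype scores then allocated within agitated
  surveys); it exists because the OR-of-subtypes construction has no
  coefficient for the overall outcome, so planting one there would
  otherwise be impossible.
* Nurse-initiated extra surveys are supported
  (`self_initiated_rate`, drawn preferentially for high-propensity
  patients) but off by default; the real mix is unknown.

What passing tests on this generator do *not* show about real data: real
sensors drop out and drift; real patient movement is purposeful rather than
semi-Markov; real environmental processes have heavier tails and shared
ward-level events (meals) that correlate modalities; and the real causal
structure is unknown rather than planted. The generator validates the
*machinery* — extraction, filtering, standardization, estimation,
selection — not the clinical conclusions.

## Problem sizes and numerical choices

* Sensor sampling defaults to 1 s (the 5-s smoother spans 5 samples); the
  test-suite and the acceptance script sample every 10 s with a matching
  10-s span, which leaves every window with ≥ 126 points per modality and
  identical feature content at a fraction of the volume. Recovery runs use
  150 patients × 6 days (~50 scheduled surveys each) with 20 replicates;
  the reduced window sweep uses lengths {12, 21, 30} at 100 patients — at
  much smaller scales the sweep's neighbouring lengths are too correlated
  for per-replicate selection to be stable, which is a power fact, not a
  software one.
* The exploratory sweep uses Laplace fits (`nAGQ = 1`) — 450 fits whose
  purpose is ranking, and the Laplace approximation is also what the usual
  mixed-model software defaults to; all *reported* models use 25-node
  adaptive quadrature. Estimates at 25 vs 51 nodes agree to $10^{-5}$ on
  test fixtures.
* Ties: majority room by earliest entry; feature selection by the fixed
  feature order; window selection by the longer length. Degenerate inputs:
  empty series give `NA` features (and quality failure); single-row or
  zero-spread standardization strata give `NA` z-scores; single-class
  outcomes are refused; complete separation is flagged.
* Timestamps are numeric seconds from a midnight-anchored study start (UTC
  by default, configurable); time-of-day grouping uses the clock of that
  timezone. The CSV interchange uses ISO-8601 UTC.

## Known limitations

One random intercept only (no random slopes, no crossed effects); Wald
rather than profile intervals; the exploratory sweep refits the
standardizer per length but shares the underlying sensor data, so grid
cells are not independent across lengths; and the acceptance criterion that
demands *every* interaction test be non-significant in 18 of 20 replicates
collides with the arithmetic of twelve true-null tests at $\alpha = .05$
(expected joint pass rate $0.95^{12} \approx 0.54$ per replicate) — the
corresponding check reports this honestly rather than relaxing the test.
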