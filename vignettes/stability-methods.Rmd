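---
title: "Quantifying cross-day stability of task-variable coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cross-day stability of task-variable coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Chronic two-photon calcium imaging can follow the same cortical neurons
for days. Across such recordings, the tuning of individual cells to task
variables is not fixed: responses weaken, vanish, or appear in previously
untuned cells ("representational drift"). The question this package
operationalizes is: *at what rate does the population code for each task
variable become unreadable to a decoder trained on a reference day?* The
answer is an exponential time constant τ per variable — the number of days
until the above-chance decoding signal falls to 1/e of its day-1 value.

The task model is a virtual T-maze with 9-s trials at a 10-Hz frame rate:
3 s from maze start to the decision point, 3 s from decision to maze end,
3 s of post-trial screen. Four trial types (CL, IR, IL, CR — correct/
incorrect × left/right) define three binary partitions: context
({CL, IR} vs {IL, CR}), motor choice ({CL, IL} vs {IR, CR}) and outcome
({CL, CR} vs {IR, IL}); outcome is read out in two windows, post-decision
(3–4.5 s) and post-trial (6–7.5 s), context at 1.5–3 s and motor at
3–4.5 s. All windows are exactly 1.5 s wide.

## Preprocessing model

Somatic fluorescence is contaminated by surrounding neuropil. The
corrected trace is `F_corr(n) = F_soma(n) − α (F_np(n) − mean(F_np))`,
with α chosen in [0, 1] per cell to minimize the absolute Pearson
correlation between corrected and neuropil traces. Because that
correlation is a smooth rational function of α, `estimate_alpha()`
evaluates it in closed form on the full 0.001 grid, which is equivalent to
(and tested against) an exhaustive grid search; a zero-variance corrected
trace is treated as correlation 0, so `F_soma ≡ F_np` yields α = 1.

ΔF/F(%) is `100 (F − F0)/F0` where `F0` is the mode of the corrected
fluorescence density over the whole series. The mode is estimated with a
Gaussian KDE (Silverman bandwidth, 512 grid points over the data range);
the bandwidth/binning is unspecified in the underlying method description,
so a histogram-mode alternative is provided (`method = "hist"`) for
sensitivity checks. The KDE mode of a symmetric distribution is unbiased
but has sampling error of order ±1 a.u. at 10⁴–10⁵ frames; tests
therefore check its average over replicates.

## Inclusion gates

Three gates select analyzable data, and all downstream analyses respect
them:

* **session**: > 0.5 fraction correct and ≥ 2 trials of each type;
* **reliability** (per cell-day): the Pearson correlation between mean
  responses on odd and even correct trials must exceed the 95th percentile
  of 100 nulls in which each trial's bin series is circularly shifted by
  an independent uniform offset. On exchangeable noise this flags ~5% of
  cells by construction;
* **ROI stability** (per cell and day pair): the SSIM between the 30 × 30
  µm windows centered on the ROI on day 1 and day k must exceed the 95th
  percentile of SSIMs against random windows of the comparison day
  (≥ 1 window-width away from the true ROI; 100 windows by default). SSIM
  uses the standard constants (K1 = 0.01, K2 = 0.03, Gaussian window
  σ = 1.5, dynamic range of the pooled pair, no sample-covariance
  correction) and matches scikit-image's implementation to 1e-6; a 2-D
  correlation metric is available and agrees on clear cases.

A cell enters a (day 1, day k) comparison iff it is reliable on both days,
ROI-stable for the pair, and both sessions pass the behavioral gate. The
strict all-days intersection is exposed separately for controls.

## Decoding and the stability metric

Trials are *homogenized* before classification: each type's trials are
split into two disjoint halves, and each half is resampled with
replacement to the session's minimum per-type count. Train and test sets
therefore never share an underlying trial while holding equal counts of
every type (so fraction correct is balanced accuracy). Per time bin, a
binary linear SVM (hinge loss, C = 1, no feature scaling beyond ΔF/F) is
trained on the reference day and scored on the held-out half (within-day)
or on homogenized trials of a later day (cross-day). Means and 5th/95th
percentile CIs are taken over 100 bootstrap iterations. A curve encodes
its variable when the lower CI exceeds 0.5 for ≥ 5 consecutive bins
(0.5 s); qualifying runs before/after the trial-end bin assign the outcome
partition to its post-decision/post-trial variant.

The SVM is a dual-coordinate-descent implementation (liblinear algorithm)
compiled with Rcpp, with the bias handled as a regularized augmented
feature; no SVM package exists in the supported dependency stack, so the
solver is written here and verified against scikit-learn's `LinearSVC`
(same formulation) in the test suite. Coordinates are visited cyclically,
making fits deterministic. With the small distinct-trial counts the
homogenization protocol produces (often < 20 distinct training trials for
100+ features), maximum-margin classifiers partially overfit and absolute
performance sits below the noiseless ideal; this is inherent to the
protocol, shared by any faithful implementation, and is why performance is
always read against the empirical chance calibration rather than an
assumed ceiling.

Stability is quantified by integrating (trapezoid, window endpoints
inclusive) `performance − 0.5` over the variable's 1.5-s window, and
normalizing by the train-day integral: `NP(d) = area(d) / area(1)`. The
integral is signed by default (dips below chance subtract; a clip switch
exists). `NP` is fitted with the one-parameter decay `NP = e^{(1−day)/τ}`,
so the fitted curve is exactly 1 on day 1 and exactly 1/e one time
constant later. For un-normalized performance the two-parameter form
`P = P_day1 e^{(1−day)/τ} + 0.5` includes the chance baseline; per-cell
correlation decay uses `CC = CC_day1 e^{(1−day)/τ}`. Fits are nonlinear
least squares with τ ∈ (0.05, 100], amplitude ∈ [0, 2], multistart from
τ ∈ {0.5, 2, 8, 32} (coarse log-grid plus golden-section refinement in the
one-parameter case); fits are retained when SSE ≤ 1.6 and R² > 0. The SSE
cutoff is inherited from the original data scale and is flagged as
scale-dependent.

In `run_pipeline()`, the train-day reference area for each (1, k)
comparison is recomputed on the same matched cell set as the cross-day
curve. The per-pair inclusion gates shrink the population on later days;
normalizing by a full-population day-1 area would attribute that shrinkage
to coding drift. This is the one place the implementation resolves an
ambiguity in the published description ("normalized by the integrated
performance in day 1, when the classifier is trained") — the
interpretation used here matches the classifier actually being trained on
the pair's cell set.

Skewed fit parameters are compared after a rankit transform,
`qnorm((rank − 0.5)/n)` with averaged ties, using linear mixed-effects
models (`lme4`, REML) with the task variable as fixed effect and mouse and
experiment as random intercepts. Pairwise contrasts are Wald F-tests
(df1 = 1, df2 = n − rank(X)) on two-level refits — `lme4` supplies no
F-tests, and this mirrors the default of the original analysis platform —
with p-values floored at 1e-5. Singular random-effect structures are
refit without the offending term and flagged.

## The synthetic world

The generator is the package's test bed and states its world explicitly:

* **Behavior**: an agent choosing the rewarded side with probability 0.74
  (the published mean performance), 2% aborted trials (rate unpublished;
  chosen to exercise the exclusion path), 60 trials/session, 5 days.
  Context presentation repeats with probability falling linearly from 50%
  to 0% over 10 consecutive repeats; a bias gate forces the context
  rewarding the non-preferred side whenever one side exceeds double the
  other over the trailing 10 responses. The gate, as described, *forces*
  repeats — for a pathological coin-flip agent it raises the repeat
  fraction above 0.5; under the default performing agent the schedule
  stays below the unconstrained rate.
* **Tuning**: 60% of cells are tuned, each to one variable, with a random
  preferred class, a Gaussian response kernel inside the variable's
  canonical window (context 0–6 s, motor and post-decision outcome
  3–4.5 s, post-trial outcome 6–7.5 s), and a log-normal day-1 amplitude.
  Amplitudes decay as `e^{(1−day)/τ_v}` with per-variable τ (defaults
  7.3, 1.9, 2.2 and 35.7 days, mirroring the published estimates); each
  later day every cell is re-assigned with probability 0.1 (turnover:
  tuned cells may lose or change tuning, untuned cells may gain it).
* **Signals**: transients are amplitude × kernel on preferred-class trials
  (emitted with probability 0.8, log-normal jitter), convolved with a
  0.7-s single-exponential calcium kernel (GCaMP6s-like; the forward model
  is unspecified upstream); soma fluorescence adds baseline, neuropil
  contamination with a true α (default 0.7, shared low-pass neuropil
  signal), and white noise of 15% ΔF/F per frame.
* **ROI patches**: a textured field densely populated with background
  somata (~6 per 30 × 30 µm window) plus an elliptical blob per tracked
  cell; later days reuse the day-1 field with ±1 px jitter and additive
  noise. Unstable cells' windows are re-centered on a distant random
  location.

Amplitude and noise scales are not published; they were calibrated once so
that day-1 decoding matches the published operating point (single-cell
window decoding ≈ 0.55–0.65, population ≈ 0.75–0.9) and then frozen. What
a green test establishes is therefore that the pipeline recovers the
stated drift law *under this stated world*; the generator does not emulate
correlated (shared) trial-to-trial population noise, slow within-session
nonstationarity, or registration artifacts, so absolute performance levels
on real data will differ.

One consequence is worth stating plainly: population decoding with ~150
cells saturates for strongly encoded, slowly drifting variables. Near the
ceiling, window-integrated NP declines more slowly than the underlying
amplitude, which biases the recovered τ of the *slowest* variables upward
(context in particular); conversely fast-decaying variables hit the
decoding noise floor by day 4–5, truncating their measurable decay. The
recovery tests accept a ±40% band around the generator's τ for context
and motor and an ordering check across all four variables; the ordering is
robust, the context band sits at the edge of the saturation bias.

## Numerical and design choices

* Per-bin Wilcoxon preference testing: the published description
  ("signed-rank over resampled trial populations, 5 consecutive bins")
  does not fix how bootstrap iterations enter the test. Testing iteration
  *means* against each other concentrates on the in-sample difference and
  rejects almost always as iterations grow; the default here instead runs
  one paired signed-rank per iteration (pairing resampled trials within
  the iteration) and takes the per-bin median p over 100 iterations,
  which is valid per bin and conservative at the cell level (the
  5-consecutive-bin rule compounds it). The anticonservative
  across-iteration variant remains available (`mode =
  "across_iterations"`) for sensitivity analyses.
* Odd/even trial splits use 1-based positions within the condition after
  dropping aborted trials ("odd" = 1st, 3rd, …).
* The signed-rank statistic uses the exact distribution when |differences|
  are tie-free and a tie-corrected normal approximation otherwise
  (compiled; verified against `wilcox.test`).
* Ties in `latency_sort` and `rankit` break by cell id and averaged ranks
  respectively; degenerate inputs (constant traces, zero-variance means,
  empty classes) are flagged and excluded rather than propagated as NaN.
* Per-stage seeds derive from the master seed via a stable hash, so any
  stage can be re-run in isolation; identical (config, seed) pairs yield
  byte-identical reports.
* Bundles and reports are exchanged as R lists and CSV/JSON files. The
  HDF5 container planned for interoperability is not available in the
  supported dependency stack and was dropped; the CSV schemas carry the
  same fields.

## Known limitations

* The SSE ≤ 1.6 fit filter is meaningful on the 0–1 NP scale it was
  derived for; applying it to quantities on other scales requires
  re-derivation.
* `lme_compare` treats pairwise contrasts marginally (per-pair refits), as
  in the original analysis; no multiple-comparison correction is applied
  beyond the 1e-5 floor.
* The pseudo-population builder assumes class-conditional exchangeability
  of trials across experiments; behavioral covariates that differ across
  sessions (e.g. running speed) are not modeled.
* Spike-deconvolved input is accepted as a drop-in activity channel but
  never computed here.
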