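---
title: "Cue-conditioned placebo and nocebo analysis of multi-distance fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cue-conditioned placebo and nocebo analysis of multi-distance fNIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placebonirs)
```

## The experiment this package models

A differential conditioning session pairs two auditory cues with two
electrical shock intensities calibrated per participant: a low-frequency
(LF, 500 Hz) sound with a low-intensity shock (LS, 50% of the maximum
endurable current) and a high-frequency (HF, 2000 Hz) sound with a
high-intensity shock (HS, 90%). After a 20-trial training block (10 trials
per matched pair, in random order; sound 5 s, delay 5 s, shock 5 s, rest
10 s), a recording session delivers 32 trials: 13 LF–LS and 11 HF–HS matched
trials plus 4 LF–HS and 4 HF–LS mismatched trials (25%), pseudo-randomly
ordered, with rests drawn uniformly from 20–30 s so that cue onsets cannot be
anticipated. Mismatched trials elicit placebo (LF–HS: pain lower than the
shock warrants) and nocebo (HF–LS: pain higher) effects, quantified from
0–100 visual-analog-scale (VAS) ratings as

* pain-reduction index = VAS(HF–HS) − VAS(LF–HS),
* pain-enhancement index = VAS(HF–LS) − VAS(LF–LS).

Cortical hemodynamics are measured with a multi-distance fNIRS montage:
95 *composite* channels (3.0 cm source–detector separation, mixing cerebral
and extracerebral signal) and 5 *non-cerebral* short channels (1.5 cm,
dominated by scalp/skull physiology). The regions of interest are the left
and right dorsolateral prefrontal cortices (dl-PFC, Brodmann areas 9/46).
The analysis chain is: band-pass filter 0.01–0.1 Hz, remove the first two
principal components of the five short channels from every composite
channel, epoch the HbO series around each cue sound, average within cue,
and summarize each ROI as a cue-locked effect size

$$d \;=\; \frac{\overline{\mathrm{HbO}}_{[0,10)} - \overline{\mathrm{HbO}}_{[-5,0)}}{\mathrm{SD}\!\left(\mathrm{HbO}_{[-5,0)}\right)},$$

the baseline-corrected mean response in the 10 s after sound onset (the
window ends at shock onset, so shock identity cannot contaminate it) in
units of pre-cue baseline variability. The inferential battery on the
resulting tables comprises factorial ANOVAs (age x sex, with cue or
matched/mismatched condition as a repeated factor), Bonferroni post hoc
comparisons, per-group Pearson correlations between the pain-reduction index
and the right dl-PFC response to the safe (LF) cue with Holm correction,
forced-entry and stepwise multiple regressions with standardized
coefficients, Mann–Whitney U tests with the effect size $r = Z/\sqrt{N}$,
and distributional assumption checks.

## Pipeline design choices

**Trial ordering.** "Pseudo-random" is realized as a uniform permutation
re-drawn until no condition runs more than three trials in a row and no
mismatched trial occupies the first two positions (both constraints are
arguments of `build_recording_schedule()`, since the original design does
not pin them down). Rest durations are continuous-uniform on [20, 30] s,
the simplest model consistent with a reported mean rest near 25 s.

**Filtering.** The band-pass is a zero-phase (forward–backward) Butterworth
filter, order 3 per pass, applied in compiled code with odd-reflection
padding of four low-cut time constants so that edge transients never reach
the data. Zero-phase filtering preserves event-locked latency;
`filter_gain()` exposes the analytic squared-magnitude response that the
tests compare measured tone attenuations against. Series must be longer
than three low-cut periods or `bandpass()` refuses to run.

**Systemic removal.** Per chromophore, the five short-channel series are
mean-centered (not variance-standardized — the channels share units) and
decomposed over the full session; the first two left singular vectors are
the systemic component time courses, ordered by explained variance with the
sign fixed so each component's largest-magnitude loading is positive.
Each composite channel's least-squares projection onto that span is
subtracted, which makes every residual exactly orthogonal to the removed
components — a property the tests assert at the 1e-10 level. `n_components
= 0` is the identity; a rank-deficient short-channel set degrades gracefully
with a provenance warning.

**Windows.** All windows are half-open and onset-inclusive: baseline
[onset − 5, onset), response [onset, onset + 10), so sample counts are
exactly duration x sampling rate. Epoch averages for a cue include
mismatched trials that share the cue sound by default (`include_mismatched
= FALSE` restricts to matched trials), because the analysis window ends at
shock onset.

**The effect-size denominator.** The formula's "SD during the 5 s prior to
sound onset" admits two readings. Taken on the *trial-averaged* series, a
5-s window of 0.01–0.1 Hz band-limited noise is locally almost a straight
line: its sample SD has roughly one effective degree of freedom, so the
per-channel effect size inherits a coefficient of variation near 1 under any
stationary noise level — we verified this empirically across an order of
magnitude of noise amplitudes. Pooling the SD over the individual trials'
pre-cue windows (each centered on its own baseline mean) multiplies the
effective degrees of freedom by the trial count, stabilizes the denominator,
and yields effect sizes of a few units, the magnitude such studies report.
`effect_size()` therefore defaults to `sd_source = "trials"` and offers
`"average"` for the literal averaged-series reading. Channels with zero
baseline SD yield `NA` and are excluded from the ROI mean with a warning.

**ANOVA error models.** `factorial_anova()` offers two error models. The
`pooled` model treats the repeated factor as between-subjects in a single
error stratum; on 60 participants x 2 conditions it yields denominator df
112, the df convention of the SPSS-style output this analysis mirrors, and
is the fit's default. The `mixed` model nests the within factor in a
subject stratum (denominator df 56 for both strata on the same design) and
is the statistically recommended choice. On the 60-participant index tables
a two-way between ANOVA has denominator df 56; published tables sometimes
print 28 for this design, which is arithmetically inconsistent with n = 60
and is not emulated.

**Holm variants.** `holm_adjust()` implements the standard monotone
step-down rule (adjusted p = running max of $(m-j+1)\,p_{(j)}$, capped at
1); for the printed family {0.006, 0.023, 0.023, 0.329} it gives 0.024 and
0.069 for the two smallest. The `"raw-multiplier"` variant omits the
monotonicity step and reproduces the 0.046 sometimes printed for the tied
raw p of 0.023; it exists for arithmetic comparability and is not the
default.

**Mann–Whitney effect size.** The U test uses the normal approximation with
tie correction and no continuity correction, the convention under which the
reported effect size is $r = Z/\sqrt{n_1+n_2}$, signed by the first sample's
mean-rank direction. Degenerate all-tied samples return p = 1, r = 0 rather
than an error. The tests validate U against a brute-force pair-count oracle
and the p value against `wilcox.test(exact = FALSE, correct = FALSE)`.

**Stepwise regression.** Forward selection on the entry p value with
backward pruning at the same threshold (single alpha, matching the
two reported thresholds 0.01 and 0.05), terminating at a fixed point;
the final model is refit with z-scored response and predictors so the
coefficients are standardized betas, as in the forced-entry route.

## What the synthetic cohort emulates

`simulate_cohort()` generates four groups (elderly/young x male/female,
default n = 15 per group) with known ground truth:

* **Cerebral responses.** Each cue onset plants a canonical double-gamma
  hemodynamic response (peak 6 s, undershoot 16 s, ratio 1/6) convolved
  with the 5-s sound boxcar and normalized to unit peak, so a planted
  amplitude is a peak concentration change. dl-PFC channels carry the
  participant's hemisphere-and-cue-specific amplitude; other composite
  channels carry a smaller widespread auditory response (`background_amp`,
  default 0.6) so that every composite channel has a defined cue-locked
  signal-to-noise ratio. Short channels carry no cerebral term, by
  construction. HbR is modelled as −0.3 x the cerebral term plus
  independent noise (it is carried through I/O but not analysed), and
  HbT = HbO + HbR.
* **Systemic physiology.** A rank-2 (configurable) set of source time
  courses mixing Mayer-wave (0.1 Hz), respiratory (0.3 Hz) and cardiac
  (1.2 Hz) oscillations at random phase with a slow AR(1) process, mixed
  into *all* channels through a random positive loading matrix — so the
  short channels' leading principal components capture exactly the
  component contaminating the composite channels, which is what makes the
  removal step effective and testable. The Mayer-wave term dominates the in-band
  systemic signal (default amplitude 4 concentration units against unit-scale
  cerebral responses — scalp physiology outshines cortical signal, as in real
  multi-distance recordings), and the AR(1) drift has a ~100 s time constant
  so it does not mimic event-locked signal. Per-channel drift and white noise
  (default SD 1.2) complete the signal; single-trial responses remain
  noise-dominated.
* **Behavior and coupling.** Per-participant condition-mean VAS scores
  encode the placebo/nocebo structure; the pain-reduction index is coupled
  to the true right dl-PFC LF amplitude with per-group correlations
  defaulting to {0.669, 0.582, 0.580, 0.271} (elderly-male, elderly-female,
  young-male, young-female — the group pattern the analysis should
  recover). Per-trial ratings add noise (SD 2) and are clipped to
  [0, 100]. Demographics (age, MMSE, maximum endurable current) follow the
  published group means with SDs recovered from SEMs.

**Exact in-sample calibration.** By default the per-group latent scores
(amplitudes and indices) are drawn with `MASS::mvrnorm(empirical = TRUE)`,
so the configured group means, SDs and coupling correlations are realized
*exactly* in each simulated cohort. This is a deliberate design for
parameter-recovery testing: the sampling SD of a Pearson r at n = 200 is
≈ 0.066 for r = 0.271, larger than the recovery tolerances we want to
resolve, so with stochastic cohorts a recovery error would mostly measure
cohort sampling noise rather than pipeline distortion. `empirical = FALSE`
restores fully stochastic cohorts (and is what the generator falls back to
for groups smaller than 7).

**Free parameters.** No numeric dl-PFC amplitudes are published (the source
figures are not reproduced here), so the group amplitude means are
illustrative, chosen once to express the qualitative pattern (largest in
elderly females, smallest in young females); amplitude SDs are 0.65 x the
group's right-LF mean so every group has comparable relative spread. With
these defaults the pipeline-recovered ROI effect sizes correlate with the
true amplitudes at r > 0.9 in every group, and the recovered coupling
correlations sit within ±0.07 of the configured values at n = 200 per
group.

**What passing tests do and do not show.** The generator's noise is
stationary and Gaussian, its systemic component is exactly low-rank and
fully shared with the short channels, and there are no motion artifacts,
no optical-density-level effects, and no inter-channel differences in HRF
shape. Recovery results therefore demonstrate the pipeline's correctness
under its own assumptions, not performance on real recordings, where the
systemic component is only approximately low-rank and short channels are
imperfect references.

## Numerical conventions and problem sizes

Seeds: a single master seed; per-participant and per-replicate seeds are
derived with a stable integer hash (`derive_seed()`), all below 2^31.
Identical seeds give byte-identical schedules, recordings and fit tables.
Component sign and order ties in the PCA are resolved by explained variance
and the positive-largest-loading rule. Degenerate inputs (zero baseline SD,
empty ROI, rank-deficient short channels, one-level factors) raise errors
or produce flagged not-applicable rows rather than silent numbers.

The recovery studies run at the sizes the analysis is designed around:
n = 200 per group for correlation recovery and 100 master seeds at
n = 15 per group for the end-to-end pattern replication. Both run on the
packaged reduced montages (`"dlpfc"`: the ten ROI channels plus the five
short channels; `"right_dlpfc"`: right ROI only), which carry the identical
ROI and short channels as the full 95-channel montage — the recovered
quantities depend only on those channels, and the reduced montages keep the
studies fast. Channel-level claims (the SNR-improvement fraction) use the
full montage.

## A small worked cohort

```{r example}
cfg <- cohort_config(n_per_group = 8, seed = 3)
fit <- placebo_nirs(cfg, montage = "dlpfc")
fit
round(coef(fit), 3)
```

The printed per-group means and correlations show the configured pattern;
`summary(fit)` lists the full inferential table and `plot(fit)` draws the
per-group scatter of the reduction index against the right dl-PFC response
to the safe cue.

## Known limitations

* The pipeline starts at hemoglobin concentration changes; conversion from
  raw optical densities, probe digitization and registration to standard
  space are out of scope (ROI membership is taken from a channel table).
* HbR and HbT are simulated and carried through I/O but not analysed.
* Motion artifacts are not modelled and no motion correction is provided;
  the systemic-removal step implements the principal-component short-channel
  method only, not GLM short-channel regression or wavelet filtering.
* The `pooled` ANOVA default mirrors a reporting convention; for inference
  on new data the `mixed` model is the better-justified choice.
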