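---
title: "Dissecting sound-evoked activity in visual cortex: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting sound-evoked activity in visual cortex: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(soundmotion)
```

## The scientific question

Sounds evoke activity in the visual cortex of passively listening mice. Two
very different explanations are compatible with that observation: a direct
sensory route (auditory cortex projects to visual cortex), or a behavioral
route — sounds elicit small, stereotyped body movements (whisker twitches,
arousal changes), and movement-related signals are broadcast across the
brain. The analyses in this package are designed to separate the two. The
key signatures of the behavioral account are:

* sound-evoked population activity is **low-dimensional** (essentially one
  component), unlike the high-dimensional visual code;
* the same sound-evoked component can be **decoded from the face camera**
  about as well as from the neurons;
* an encoding model driven only by **observed movements predicts
  sound-evoked activity as well as a model given the sound identity**, and —
  unlike the stimulus model — also predicts its trial-to-trial fluctuations;
* the sound-related neural subspace **overlaps the movement-related
  subspace** estimated from stimulus-free epochs;
* movement **precedes** the neural activity by a few tens of milliseconds.

The package implements the full chain — synthetic session generation,
preprocessing, factorial marginalization, cross-validated PCA, template
decoding, ridge encoding models, and reduced-rank-regression subspace and
timing analyses — so each signature can be validated by parameter recovery
on data with known ground truth.

## The synthetic session generator

Real recordings of this kind cannot ship with a package, and parameter
recovery needs a known truth, so `generate_session()` is a first-class
module, not a test fixture. Its generative chain is deliberately the
behavioral account itself:

1. A latent state $s_j(t)$ per generative component ($j = 1..$ `sound_rank`)
   sums (a) each trial's sound kernel — per sound, 2–4 gamma-shaped bumps
   within ~1 s of onset, amplitude jittered per trial
   (`trial_gain_sd`, default 0.3) — (b) Gaussian fluctuations low-pass
   filtered at roughly 2 Hz, and (c) sparse brief movement bursts
   (`spont_burst_rate`, default 0.4 Hz, 50–150 ms wide). The bursts are a
   deliberate addition to the pure low-pass process: spontaneous facial
   motion in head-fixed mice is dominated by fast whisk and twitch events,
   and without that fast structure the movement-to-neural lag is not
   identifiable at the camera frame rate (adjacent lagged regressors become
   collinear).
2. Motion-energy PCs read out $s(t)$ linearly (PC1 with a strong positive
   loading, higher PCs with decaying random loadings) plus white noise.
   Linearity is an assumption; all downstream analyses are linear, so a
   nonlinear link would only lower every recovery score without changing
   what the tests demonstrate.
3. Each neuron fires as an inhomogeneous Poisson process with rate
   `baseline + loadings %*% s(t - lead_time) + visual_code(video)`,
   rectified at zero. The 30 ms `lead_time` means the behavioral latent
   drives movement first and neurons later — the timing signature the
   subspace module must recover.
4. The visual code is built from smooth shared temporal bases with
   power-law ($m^{-0.6}$) population weights and a dominant, positively
   loaded first component: a high-dimensional code with a realistic
   decaying eigenspectrum.
5. Pupil signals couple weakly to the latent; blinks are rare 100–300 ms
   dropouts that exercise the blink interpolation.

**Calibration.** The defaults are fixed to the regime the emulated
recordings report: with the default amplitudes (`kernel_amp = 4`,
`visual_amp = 5`, gamma baseline rates of mean 20 spikes/s) the reliable
video-related variance exceeds the sound-related variance by roughly an
order of magnitude (visual PC1 ≈ 6% of total variance, auditory PC1 ≈ 0.6%
at 30 neurons), and the spontaneous movement–neural correlation is ≈ 0.2.
The high-ish baseline with shape 8 keeps rate rectification rare, which is
what makes the sound drive *exactly* rank-`sound_rank` across neurons — the
invariant the dimensionality tests recover. Cortical neurons with strong
visual drives and low baselines are rectified much harder; in that regime
the spiking nonlinearity itself adds reliable sound-locked dimensions,
which is one reason real recordings show ~4 significant sound components
rather than 1.

What the generator does **not** emulate: spike-sorting artifacts, slow
non-stationarities (drift, satiety), shared noise beyond the single latent
(real cortical populations have rich noise correlations), nonlinear
motion-to-rate coupling, or raw video (motion PCs and their pixel masks are
generated directly, at the level facemap-style preprocessing would output).
Passing recovery tests on these sessions therefore shows the *estimators*
are correct and well-calibrated — not that real cortex is this simple.

## Preprocessing conventions

* Spikes are counted in half-open 30 ms bins over the whole session,
  smoothed with a causal half-Gaussian (SD 43 ms, truncated at non-negative
  lags, renormalized at the leading edge so DC gain is 1 everywhere), then
  z-scored per neuron over the full session trace — smoothing before
  standardization, in that order.
* The trial tensor `D[t, v, a, r, c]` uses a (−1, +3.8) s peri-onset window:
  160 bins at 30 ms. The repeat index preserves presentation order within
  each (video, sound) pair, and assembly is invariant to the ordering of
  the event table.
* Eye signals yield 9 channels: baseline-corrected pupil area and x/y
  position (each trial's mean over the second before onset subtracted),
  signed and unsigned between-bin eye motion, global (L2) motion, and the
  blink flag. Blink-flagged samples are linearly interpolated before any
  motion is computed; blinks at a window edge extend from the nearest valid
  sample. Unsigned channels are non-negative at this stage; standardization
  for decoding/encoding happens downstream.
* Camera-rate motion PCs are linearly interpolated onto the 30 ms bin grid
  (bin centers). Timing between camera frames and the neural bin grid is
  only good to ~25 ms, which is why all timing claims are stated in units
  of one camera frame.

## Marginalization

The balanced factorial design lets the tensor decompose exactly as in
factorial ANOVA: a grand mean `M[t,c]`, video component `V[t,v,c]` (average
over sounds and repeats minus `M`), sound component `A[t,a,c]`, interaction
`I[t,v,a,c]`, and trial noise `E`. Additivity is exact, each factor
component sums to zero over its own index, and under the balanced design
the squared norms partition the variance — all three properties are tested
to 1e−10. Unbalanced (incomplete) designs are rejected, not reweighted.
The blank screen and silence are ordinary factor levels, so "sound-evoked"
always means *relative to the grand average*, silence included.

## Cross-validated PCA and the dimensionality test

PCA weights `W` are fit on the trial-averaged component from the odd
repeats; both halves are projected through the same `W`, and the
per-component covariance between the halves' projections estimates the
reliable stimulus-locked variance. Independent noise cancels in
expectation, so noise components scatter around zero and can be negative —
they are never clipped. With `test = train` the estimator reduces exactly
to the ordinary PCA spectrum, and its sum is basis-invariant, which is what
makes the unbiasedness test clean. Since PC signs are arbitrary, each
weight column is flipped so its mean is non-negative, matching the
positive-bias convention used for population weights in vivo.

**The shuffle null.** Significance of each component is assessed by
relabeling: within every repeat, the (video, sound) pair labels are
randomly permuted — each trial gets both a new video and a new sound label
— and the component's test–retest covariance spectrum is recomputed, 1,000
times. Two details matter:

* *Pair permutation, not factorized permutation.* Permuting video and sound
  labels independently (a σ⊗τ product) would keep the design balanced and
  the true video signal would still cancel exactly from the shuffled sound
  marginal, giving an essentially exact null per component. The pair
  permutation breaks the balance, so the (large) stimulus-related signal
  bleeds into every shuffled component.
* *Pooled threshold.* A component is significant when its observed
  covariance strictly exceeds the 99th percentile of the shuffled
  covariance values pooled across components. Because of the leakage above,
  that pooled threshold sits far above the noise floor, making the test
  conservative. This is the only reading consistent with the zero
  interaction dimensionality reported on real recordings with hundreds of
  neurons: a per-component null is close to exact, so its ~1% per-component
  false-positive rate would produce spurious dimensions in roughly a
  quarter of sessions at 30 channels (and more with more channels). The
  per-component variant remains available via `null_type = "per_component"`.

Dimensionality is the count of significant components. On the generator's
sessions the pooled test recovers rank 1 and rank 3 exactly and reports
zero interaction dimensions.

## Template decoding

To decode the sound of a test trial, the training-half mean response to the
trial's video is subtracted (removing the video component), the residual is
projected on the top `n_components = 4` training-half sound PCs, and the
trial is assigned to the sound with the nearest training-half mean
projected time course (Euclidean distance on the whole flattened time
course; ties break to the lowest class index so decoding is deterministic).
Video decoding is symmetric with 30 components. Behavioral decoding feeds
the eye + motion-PC tensor through the identical procedure; when the tensor
has at most `n_components` channels the projection is a full rotation and
therefore a no-op for distances. Chance level is 1/12, verified by
relabeling within repeats.

## Encoding models

The target `Y` is the single-trial sound-plus-noise activity
`D − M − V`, projected on the top 4 sound PCs computed from the *full*
dataset (using full-data weights for the basis does not leak across the
train/test split of trials: the basis only fixes which axes are predicted).
Three designs predict it: stimulus indicators (one column per sound ×
peristimulus bin; 12 × 127 = 1,524 columns), lagged behavioral channels
(137 channels × 12 lags = 1,644), and their concatenation (3,168). Fitting
the stimulus design is equivalent to estimating the training-half mean
time course per sound — a test–retest benchmark, not an acoustic model.

* *Encoding window*: 127 bins (onset to +3.8 s). This is narrower than the
  160-bin marginalization window — the pre-onset second is excluded — and
  is forced by the stated 1,524-column stimulus design.
* *Lag grid*: 12 bin offsets, −3…+8 bins (−90 to +240 ms). Twelve lags
  cannot tile −100…+200 ms exactly at 30 ms; this asymmetric grid keeps 12
  lags, covers the stated negative range to bin resolution, and leaves room
  on the causal side where the movement-leads-neurons structure lives.
  Positive lag means earlier behavior predicting later activity.
* *Trial padding*: each trial contributes 12 all-NA rows at each edge, and
  lagged predictors are NA where the lag leaves the trial window; rows with
  NA are excluded from fitting and evaluation, so temporal filters can
  never straddle trials. In the concatenated design this leaves the
  stimulus indicators of the first/last few bins without support — those
  columns are retained (ridge keeps the solve well-posed) with a warning.
* *Ridge*: `B = argmin ||Y − XB||² + λ||B||²` solved by Cholesky on the
  penalized normal equations; λ from a 9-point log grid 1e−3…1e5 by 3-fold
  cross-validation over contiguous trial blocks within the training half
  (contiguous, not random, so slow co-fluctuations cannot leak across
  folds; ties go to the smaller λ). Predictors and targets are not
  re-standardized — channels are already z-scored and `Y` is mean-removed
  by construction, so no intercept is needed.

Trial-average quality: average target and prediction over all test-half
trials of each sound and take the Pearson correlation of the two flattened
(bins × sounds × components) matrices; a per-component variant is exposed
as an option since "elementwise" admits both readings. Trial-to-trial
("noise") quality: subtract each side's own per-sound test mean and
correlate the residuals. A stimulus-only model predicts identical responses
on every repeat, so its residual prediction is identically zero and the
noise correlation is reported as `NA` — that structural zero *is* the
scientific point, and it is asserted rather than patched over. Correlations
are combined across folds by Fisher's z (arctanh–mean–tanh), with |r| = 1
excluded with a warning.

## Movement subspace, overlap, and timing

During the spontaneous epoch, neurons (binned at the camera rate) are
predicted from 128 motion PCs × 21 lags (−10…+10 frames, symmetric since
the count is stated but not the placement) by reduced-rank regression:
ordinary least squares followed by SVD truncation of the fitted values to
rank 40 (chosen to match the sound-subspace comparison; configurable). The
channel-space factor `C` is orthonormal and ordered by explained variance.
The sound components from the two halves are projected on `C` and their
per-dimension test–retest covariance measured — cvPCA along
behavior-defined directions. The overlap is the ratio of the reliable
sound variance in the first 4 movement dimensions to that in the first 4
auditory PCs; it is reported as computed (noise can push it above 1). The
chance reference uses orthonormalized Gaussian random 4-dim subspaces (the
sampling law is a choice; any rotation-invariant law is equivalent), 95th
percentile.

Timing is measured twice, both at the camera frame rate on the spontaneous
epoch, with motion resampled at the spike-bin centers (point samples at bin
edges would bias the lag by half a frame against integrated spike counts):
the cross-correlogram peak of motion PC1 versus the auditory PC1
projection, and — robust to the autocorrelation of both series — the lag of
the peak absolute ridge weight of motion PC1 when predicting auditory PC1
from the lagged motion design. Positive values mean movement precedes. With
the generator's 30 ms lead and a 40 Hz camera both measures land on one to
two frames (25–50 ms), which is the attainable resolution.

## Problem sizes and reproducibility

All randomness is seeded: schedule, ground truth, session, shuffle,
random-subspace draws and the pipeline take explicit seeds, restore the
caller's RNG state, and reruns are bit-identical. The test suite and the
acceptance script run sessions at the full 12 × 12 × 4 stimulus design with
30 neurons and 16 motion PCs (128 for the design-structure checks), 600 s
of spontaneous data, 1,000 shuffles and 200 random subspaces; the
encoding-model comparison uses 4 × 6 × 4 sessions with 24 neurons. These
sizes were chosen as the smallest at which the recovery statistics are
stable across seeds; they are stated here so results can be scaled up
deliberately rather than rediscovered.

## Known limitations

* The generator's motion-to-neuron link is linear and single-latent per
  generative component; real movement codes are richer.
* The pooled shuffle threshold is conservative by construction; it trades
  sensitivity to weak extra components for a near-zero false-positive rate,
  exactly as the zero-interaction observation requires.
* `fit_rrr()` uses plain OLS + SVD; with fewer frames than lagged columns
  the solve is ridge-stabilized and `C` estimation degrades gracefully but
  is not regularized in any optimal sense.
* CSV is the only on-disk session format; tables are plain and documented,
  and at desk scale I/O is not a bottleneck.
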