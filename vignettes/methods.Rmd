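---
title: "Measuring sibilant place of articulation and validating it against listener ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sibilant place of articulation and validating it against listener ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`sibspect` implements one complete analysis: extract place-of-articulation
measures from recordings of children's /s/ and /ʃ/, screen the tokens,
prepare continuous listener ratings, and decide by mixed-model comparison
which acoustic measure best predicts those ratings. This vignette explains
the science behind each stage, the tunable parameters and their defaults,
the numerical machinery, and what the synthetic benchmark can and cannot
show.

## 1. The acoustic measures

Sibilant frication is turbulence noise filtered by the vocal tract in front
of the constriction. The resonance of that front cavity falls as the
constriction moves back: /s/ (alveolar, short cavity) resonates higher than
/ʃ/ (postalveolar, longer cavity). Two summary measures compete:

* **M1**, the spectral centroid: the weighted mean frequency of the
  spectrum, with weights equal to linear amplitude raised to an exponent
  (default 2, i.e. power weighting; amplitude weighting is available via
  `m1_power_exponent = 1` because the conventional definition is ambiguous
  on this point, and the choice is logged with every run configuration).
* **F_M**, the band-limited peak: the frequency of the maximum-power bin in
  a fixed mid-frequency band. Three bands are computed side by side —
  3–7, 3–8 and 3–9 kHz — because the optimal upper edge for young children,
  whose resonances sit higher than adults', is an open question the
  comparison itself is meant to answer. Band bounds are inclusive and ties
  break toward the lower frequency, so the measure is deterministic.

M1 responds to everything in the spectrum — tilt of the noise source,
low-frequency contamination, high-frequency emphasis — while F_M is a local
argmax and responds mostly to where the dominant mid-frequency resonance
sits. That difference is the scientific crux: if ratings follow articulation,
and F_M tracks articulation more faithfully, the F_M models should win the
AIC comparison.

### The measurement procedure

`measure_token()` runs, in order:

1. **High-band filtering** (`highband_filter()`): a zero-phase
   frequency-domain filter passing everything from 300 Hz to Nyquist, with a
   raised-cosine edge 100 Hz wide centred on the cutoff. It removes voicing
   remnants and low-frequency ambient noise. Implemented in the frequency
   domain so that it is exactly zero-phase and length-preserving.
2. **Window planning** (`plan_windows()`): the analysis region is the
   central 80% of the token, centred on its midpoint. Six 15 ms windows are
   placed with the first window starting at the region onset and the last
   ending at the region offset, equally spaced between. This placement makes
   the overlap fraction `max(0, (win - step)/win)` a pure function of token
   duration: a 90 ms token gives 24% overlap, a 60 ms token 56%. Overlap
   above 50% is *flagged* downstream, not removed, because heavily
   overlapping windows are not independent samples of the noise.
3. **Time-averaged spectrum** (`time_averaged_spectrum()`): each window is
   Hamming-tapered, zero-padded to 4096 points (≈10.8 Hz bins at 44.1 kHz)
   and transformed; the estimate is the arithmetic mean of the six power
   spectra on the linear scale. Averaging on the dB scale would change the
   estimator (it commutes with neither the centroid nor the mean), so it is
   not offered. No pre-emphasis is applied anywhere. The taper is
   configurable (`hann`, `blackman`, `boxcar`) because the analysis-window
   shape of common speech tools varies; the default follows general
   spectral-analysis practice.
4. **Measures**: M1 over 300 Hz–Nyquist, F_M in the three bands, the token
   duration and overlap fraction, and the *jump flag*: true when the peak is
   below 7 kHz in the 3–8 kHz band but above 8 kHz in the 3–9 kHz band. Such
   a jump means the widest band caught some higher-frequency energy
   concentration rather than the front-cavity resonance, and is reported per
   transcription category by `jump_report()`.

### Numerical behaviour of the peak estimator

A 15 ms Hamming window has an equivalent noise bandwidth near 90 Hz, and six
windows give roughly 12 degrees of freedom per resolution cell, so each
cell's power estimate has ≈40% relative standard deviation. Picking the
argmax of such an estimate over a resonance with a 300 Hz bandwidth is
itself a noisy operation: calibration on 2000 synthetic single-resonator
tokens puts the estimator's absolute error at a median near 45 Hz, about
89% of tokens within ±100 Hz and over 97% within ±250 Hz. This is a
property of the six-by-15 ms procedure, not of the implementation: longer
tokens do not help (the window count is fixed), and taper choice or
amplitude-versus-power averaging move the rate by under two points. The
package's recovery tests assert the calibrated bounds; users who need
tighter peak localization should average more windows (`n_windows` in
`spectral_config()`), at the cost of departing from the standard procedure.

## 2. Screening and scaling

`screen_tokens()` applies, in order:

1. **Duration**: tokens shorter than 60 ms are excluded (boundary retained).
   Less than 48 ms of analysable signal cannot support six 15 ms windows
   without extreme overlap.
2. **Outliers**: for each of the four measures and each target sound
   separately, mean and SD are computed *once* on the duration-passing set;
   a token is excluded if any of its four measures falls strictly outside
   ±2 SD for its own target group. The any-measure (union) rule produces a
   single common analysis set for all four models, which keeps the AIC
   comparison apples-to-apples; a per-measure alternative would give each
   model its own data and make AICs incomparable. Because the statistics
   are frozen (single pass), re-applying the rule to the screened set
   removes nothing — screening is idempotent, and the report's disposition
   counts always reconcile exactly.
3. **Overlap flag**: overlap above 50% is recorded but the token is kept.

Retained measures are min-max scaled onto [0, 1] (`scale_measures()`), with
the ranges stored so that new data can be projected consistently and scaling
can be inverted exactly. Scaling makes the fixed-effect coefficients of the
four measures directly comparable in magnitude.

Ratings of excluded stimuli are dropped token-wise: an excluded token takes
all of its ratings with it.

## 3. Ratings

VAS clicks are mapped linearly from pixel coordinates to [0, 1], 0 at the
/s/ end — a fixed convention that every downstream sign interpretation
depends on (a *negative* measure coefficient means "higher measure, more
/s/-like rating"). The beta likelihood is undefined at exactly 0 and 1, so
ratings are compressed with y' = (y(n−1) + 0.5)/n, applied uniformly rather
than only to boundary values so that the transformation is strictly monotone
and order-preserving; it converges to the identity as the analysis set
grows (|y' − y| ≤ 0.5/n).

## 4. The beta mixed-effects engine

The response model is mean–precision beta regression with a logit link and
constant precision φ. Fixed effects: intercept, target (/s/ = 1), optionally
one scaled measure and the target × measure interaction. Random effects are
crossed: a per-listener vector (intercept, target slope, measure slope) with
a fully correlated covariance, Cholesky-parameterized with log-scale
diagonal, and a per-stimulus intercept with SD σ_w. A diagonal listener
covariance is available by restricting `listener_re`.

Estimation is maximum likelihood with a **Laplace approximation**: the
random effects are spherically reparameterized (u = Λz, z ~ N(0, I)), the
joint mode over all random effects is found by a damped Newton iteration,
and the marginal log-likelihood is the joint log-density at the mode plus
half the log-determinant of the joint negative Hessian. The crossed
structure is exploited directly: the Hessian decomposes into block-diagonal
listener blocks, a diagonal stimulus block and a cross term, and is factored
by eliminating the stimulus coordinates first (a Schur complement), so the
dense work is only the listener part.

Numerical choices that matter:

* **Newton weights**: the observed second derivative of the beta
  log-likelihood with respect to the linear predictor can be positive far
  from the mode; where that happens the step uses the Fisher-style expected
  curvature (always positive) for that observation only, preserving
  Newton's local quadratic convergence.
* **Endgame**: near the mode the per-step decrease of the joint objective
  falls below floating-point resolution, where a line search only sees
  noise; full Newton steps are then taken and iteration stops on the
  gradient norm (1e-8) or at the numerical floor.
* **Outer optimization**: quasi-Newton (`nlminb`) over fixed effects,
  Cholesky entries, log σ_w and log φ, with an **analytic gradient** of the
  Laplace objective obtained by adjoint (implicit) differentiation of the
  log-determinant term — including the third-derivative contribution of the
  mode's dependence on the parameters. The gradient is validated against
  central finite differences in the test suite.
* **Starts and restarts**: the default fit pre-searches three seeded
  starting points (the first from an exact fixed-effects beta regression)
  and polishes the best, restarting the quasi-Newton up to twice; fits are
  deterministic given data and seed. Convergence is declared when the
  gradient max-norm is below 1e-2 (log-likelihood units per unit parameter);
  the attainable norm is limited by the inner solver's numerical floor,
  which scales with the log-likelihood's magnitude, and corresponds to
  log-likelihood errors far below anything that could move an AIC ranking
  or a likelihood-ratio test.
* **Degrees of freedom**: `n_params` counts fixed effects + free covariance
  parameters + φ, so AIC = 2k − 2ℓ and LRT df are self-consistent across
  nested specs. This convention matches `glmmTMB`'s for the same model
  family (asserted in a test).

Accuracy of the Laplace approximation itself is checked against adaptive
15-node Gauss–Hermite quadrature on one-random-effect models at the
per-listener rating load of the target design (hundreds of ratings per
listener, where the approximation error per listener integral is
~2 × 10⁻⁴), and against an importance-sampling estimate of the marginal
likelihood on a small crossed design. For a *single* observation the
Laplace error is O(1) and only vanishes in the small-variance limit; the
corresponding test therefore pins the random-effect SDs at 0.05, where the
2-D crossed integral collapses onto a 1-D quadrature to ~1e-5.

`lr_test()` clips the statistic at zero (boundary fits can produce tiny
negative differences) and `run_comparison()` keeps the interaction model
for a measure only when its LRT against the main-effects model is
significant at α = 0.05 — the inclusion decision is a procedure, not a
hard-coded structure. Models are ranked by AIC; exact ties break by the
fixed order m1, fm_3_7, fm_3_8, fm_3_9.

## 5. The synthetic benchmark

`synth_corpus()` emulates the study conditions the pipeline targets:

* **Source-filter tokens**: seeded Gaussian noise through a two-pole
  resonator (the front-cavity resonance; 3 dB bandwidth 300 Hz), an optional
  second resonator, a first-order spectral tilt (dB/octave around 1 kHz),
  and optional band-limited low-frequency rumble (flat below 200 Hz, gone by
  300 Hz) emulating ambient noise; unit RMS output.
* **Resonance distributions**: /s/ targets draw uniformly from 4.8–8.6 kHz,
  /ʃ/ targets from 3.4–6.8 kHz. The wide overlap (4.8–6.8 kHz) mirrors the
  large within-category spread and frequent intermediate productions of
  2–4-year-olds' sibilants, and is what gives the measure a job to do
  *within* each target category. Narrow transcription categories are
  assigned from the resonance relative to the overlap region — an emulation
  of perceptual categorization, not a perceptual model.
* **Tilt jitter** (SD 3 dB/octave per token): the mechanism by which the
  benchmark reproduces the qualitative headline result. Tilt variation
  moves M1 substantially (it integrates the whole spectrum) while leaving
  the band peak nearly untouched, so when ratings are driven by the *true*
  resonance, the F_M models should fit better than M1. This is a modeling
  choice, explicitly designed to emulate the hypothesized advantage of a
  local resonance measure over a global moment.
* **Ratings**: listener effect vectors from a configured multivariate
  normal (default SDs 0.3, identity correlation), stimulus intercepts
  (default SD 0.4), mean by inverse logit of the generative linear
  predictor, beta draws with φ = 10. The default fixed effects
  (1.0, −0.8, −1.5) encode the rating-scale orientation: a higher (more
  /s/-like) measure lowers the expected rating.

Every generator output is a pure function of its configuration and seed,
with per-component seed streams derived from the root seed.

**What passing the benchmark does and does not show.** The benchmark
demonstrates that the pipeline recovers known generative structure: that
the measurement chain localizes a known resonance to its sampling-noise
limit, that screening excludes exactly the planted violations, that the
model engine recovers known coefficients with calibrated standard errors
and test sizes, and that the AIC comparison identifies the measure that
actually drove the ratings. It does *not* show that real children's
fricatives have a single dominant front-cavity resonance, that real
listeners weight that resonance the way the generative model does, or that
the transcription emulation matches human categorization — those are
substantive claims only real corpora can test.

## 6. Problem sizes and runtime

The validation suite uses the full 40-listener × 300-stimulus crossed
design (12 000 ratings; 20 replicates) for parameter recovery, 200
reduced-size replicates for the null calibration of the likelihood-ratio
test, and 20 replicates of a 100-to-200-token × 12-listener corpus —
roughly a fifth of a typical perception-study corpus — for the AIC
comparisons.
The comparison replicates are sized so that the expected AIC gap between
the driving measure and its strongest competitor clearly exceeds the
gap's sampling noise; with fewer tokens the occasional corpus whose tilt
draws leave the centroid nearly collinear with the band peaks produces
honest near-ties. A full-design fit with standard errors takes on the
order of ten seconds, and the whole suite runs in well under half an hour
on one core.

## 7. Known limitations

* The fitter offers constant precision only — no dispersion submodel and no
  zero/one-inflation; boundary ratings must be compressed first.
* The Laplace approximation is not replaced by quadrature for small
  clusters; with very few ratings per listener the likelihood (and hence
  AIC) carries the approximation's bias.
* The TextGrid parser handles interval and point tiers in both text
  dialects (UTF-8/UTF-16) but not embedded newlines inside labels.
* The synthesizer does not model the vowel context that followed each
  fricative in the perceptual task; ratings are simulated from the
  fricative acoustics alone.
* WAV support covers canonical PCM 16/24-bit and float32 files;
  multichannel recordings are reduced to channel 1 with a warning.
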