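---
title: "Pupillary workload indicators: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pupillary workload indicators: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package computes

Cognitive workload leaves a trace in the pupil: under load, small abrupt
dilations become more frequent, independently of the slower light reflex.
The Index of Pupillary Activity (IPA) quantifies this as the rate of
wavelet-detected transient events per second of signal.  This package
implements the full analysis chain around that indicator for a
two-fixation-task / six-difficulty-level study design: per-eye IPA, the
between-eye mean and absolute-difference channels, within-participant
z-standardization, accuracy and fixation-precision checks, and a battery of
default-prior (JZS) Bayesian paired comparisons across task conditions.  A
synthetic binocular session generator with complete ground truth makes
every stage testable without access to raw recordings.

## The IPA chain

For one prepared pupil-diameter series $d_1,\dots,d_n$ (mm, regular grid at
$f_s$ Hz):

1. **Centering.** $x_i = d_i - \bar d$.  The indicator measures diameter
   *changes*; centering makes the result exactly invariant to constant
   offsets, and a constant series maps to the exact zero vector (hence a constant
   series yields IPA = 0 exactly, not merely to numerical tolerance).
2. **Wavelet detail.** Two cascaded periodized DWT steps with the Symlet-16
   filter bank; the level-2 detail band is kept and divided by
   $\sqrt{2^2} = 2$ (the per-level rescaling used by the open-source
   reference arithmetic).  At 300 Hz the level-2 band covers roughly
   37--75 Hz, where a ~10-sample transient dilation lives.
3. **Modulus maxima.** A coefficient is kept where its absolute value is a
   strict local maximum against the left neighbour and a non-strict one
   against the right (first index of a two-sample plateau wins; boundaries
   one-sided; zeros are never maxima).  All other positions are set to 0.
4. **Universal threshold.**
   $\lambda = f \cdot \hat\sigma \sqrt{2 \log n}$ with $n$ the number of
   coefficient positions, $\hat\sigma$ the population standard deviation of
   the sparse maxima sequence (zeros included — the reference
   implementation's estimator; a MAD-of-detail alternative is selectable),
   and natural log by default (base-2 selectable for strict reference-code
   compatibility).  The threshold factor $f$ defaults to **0.8**, the
   calibration that makes the IPA track the commercial ICA indicator most
   closely.
5. **Count.** Events are maxima with $|m| \ge \lambda$; IPA = events /
   duration, with duration $= n/f_s$ (the span the half-open segment window
   covers; dividing by $t_{last}-t_{first}$ would overstate the rate by one
   sample interval).

Two exact invariances follow from the construction and are enforced by
tests: adding a constant changes nothing, and scaling the series by $a > 0$
scales coefficients, maxima, $\hat\sigma$ and $\lambda$ alike, leaving the
event count unchanged.

### Numerical conventions worth knowing

* **Periodization.** The DWT treats the series as one period of a periodic
  signal: $a_k = \sum_j g_j\, x_{(2k - j) \bmod n}$ (0-based).  Odd-length
  inputs drop their final sample before decimation.  Series shorter than 4
  filter lengths (128 samples) are refused — periodic boundary artifacts
  dominate below that.
* **Decimation-phase sensitivity.** Shifting a segment window by a single
  sample changes which samples land on the even decimation grid, hence
  every detail coefficient, hence possibly the event count.  This is why
  segment boundaries and timestamps are serialized at the same 7-decimal
  precision — a boundary that rounds across a sample tick silently shifts
  the whole transform.
* **Duration bias.** $\lambda$ grows with $\sqrt{\log n}$, so longer
  segments apply a harder threshold and report slightly lower rates.
  Comparing a 54 s fixation task against ~5 s items therefore carries a
  positive "items > fixation" component from duration alone.  This is a
  property of the published algorithm, not of this implementation; the
  generator's null preset (below) equalizes durations so that true-null
  behaviour can be tested free of the confound.

## Indicator channels and standardization

Per segment, the left- and right-eye IPA values yield four channels:
`left`, `right`, `mean` $= (L+R)/2$, and `diff` $= |L-R|$.  The diff
channel operationalizes the reduction of autonomic variability under load:
the harder the task, the more the two pupils move in phase, the *smaller*
the absolute difference.  Directed hypotheses therefore point upward for
the mean channel and downward for the diff channel.

z-standardization is per participant and channel, across **all** of that
participant's segments (both fixation tasks and all 60 items), with the
$n-1$ denominator.  This puts all eight condition groups on one common
within-participant scale and removes inter-individual differences in
indicator range; affine transformations of a participant's values
($a x + b$, $a > 0$) standardize identically.  Two readings of
"standardized diff" exist; the default standardizes the raw absolute
difference, $z(|L-R|)$, and `standardize_indicators(mode = "diff_of_z")`
provides $|z(L) - z(R)|$ instead.  Missing segments stay missing — a
rejected segment never becomes a zero, because a zero would mimic "no
cognitive activity".

Condition aggregates are unweighted means over a label's usable segments.
Accuracy follows the test's scoring rule: possible items only, 1 for a
correct response, 0 for an incorrect or absent one (the conservative
reading for timeouts, which the scoring rule leaves open).  Fixation
precision is the $n-1$ standard deviation of gaze residuals around the
cross targets, per screen coordinate, pooled over a task's nine
presentations.

## The Bayesian comparison battery

Paired differences reduce to a one-sample design.  Under the null the
standardized effect $\delta$ is 0; under the alternative it has a
Cauchy$(0, r)$ prior with $r = 1$, with Jeffreys' prior on the variance —
the standard JZS construction.  With the data reduced to the $t$ statistic,
the marginal likelihood at fixed $\delta$ is the noncentral-$t$ density
with noncentrality $\sqrt{n}\,\delta$, so

$$\mathrm{BF}_{10} =
  \frac{\int t_\nu(t; \sqrt{n}\delta)\, \pi(\delta)\, d\delta}
       {t_\nu(t; 0)}.$$

The integral is evaluated by adaptive quadrature after the substitution
$\delta = r \tan\theta$, which maps the real line onto a bounded interval
(robust for any prior scale, including the $r \to 0$ limit where
BF $\to 1$).  Directed tests use the truncated half-Cauchy prior (twice
the mass on the selected half-line), which gives the exact identity
$\mathrm{BF}_{10}^{>} + \mathrm{BF}_{10}^{<} = 2\,\mathrm{BF}_{10}$.

The posterior of $\delta$ is proportional to likelihood × (possibly
truncated) prior.  It is normalized on a tangent-transformed grid with
composite Simpson weights, refined (grid doubling) until the posterior mean
is stable to $10^{-6}$; the reported interval is the central 95% credible
interval from the grid CDF.  Tests pin the quadrature against a
$10^6$-draw Monte-Carlo marginal-likelihood estimate (within 2%) and an
importance-sampling posterior oracle (mean within 0.5% of the posterior
sd).

Evidence bands follow the usual ladder — anecdotal (BF ≤ 3), moderate
(≤ 10), strong (≤ 30), very strong (≤ 100), extreme (> 100), mirrored at
the reciprocals for the null side — rendered as `*`/`'` through
`****`/`''''` in reports.  BF = 1 belongs to neither printed bracket and is
assigned to the null side by convention.  No multiple-testing adjustment is
applied; each pair is reported on its own, matching standard practice for
per-pair Bayes factors.

The default plan has eight ordered contrasts: fixation task 2 − fixation
task 1 (two-sided — the fatigue check), then Level a against both fixation
tasks and each level against its easier neighbour (directed).  Participants
missing either member of a pair are dropped from that pair only.  A
post-hoc pooled contrast (levels a+b vs c--f) can be appended with
`default_comparison_plan(pooled_extra = TRUE)`; it is provided as-is and
not validated further.

## The synthetic-data generator

Per eye and segment the generator sums: a baseline (default 4.2 mm, with
between-participant scatter, sd 0.4 mm); a linear drift (−0.05 mm/min, a
fatigue proxy); a hippus sinusoid (0.1 mm at 0.2 Hz, phase shared between
eyes); Poisson-timed Gaussian dilation bumps (amplitude 0.15 mm ± 20%,
width 33 ms ≈ 10 samples at 300 Hz so they land in the level-2 band — the
Gaussian $\sigma$ is width/8); and white noise (0.015 mm).  The coupling
parameter $\rho$ splits both the event rate and the noise variance into
shared and eye-specific parts: at $\rho = 1$ the eyes are sample-for-sample
identical and the diff channel is exactly 0.  Blinks are Poisson
(0.15 /s, 150 ms, 1 s refractory spacing) and invalidate both eyes;
`repair_gaps()` interpolates interior gaps up to 200 ms (a typical blink)
linearly and flags longer ones as degraded.

The **study** cohort preset encodes the emulated study conditions,
chosen once: fixation event rate 1.2 /s; all six levels 2.0 /s plus a
per-participant workload effect $e_p \sim N(0, 1)$ common to the levels, a
designed standardized level-vs-fixation effect of 0.8 with no designed
level-vs-level mean differences (the published pattern: the mean channel
separates fixation from test but not level from level); coupling 0.25
(fixation), 0.45 (one-transformation-step levels a, b), 0.75
(two-transformation-step levels c--f), which makes the diff channel fall
with difficulty and places its sharpest drop at the b→c boundary;
fixation rates equal before and after the test (no designed IPA fatigue
effect); per-level accuracy probabilities .95/.93/.86/.80/.73/.43 (the
published level means); item durations lognormal with level-wise medians
4--8 s (sdlog 0.4, floor 1.5 s, cap 60 s — response times are not published,
these are this package's realism choice); gaze scattered 15 px around the
fixation targets.  Event-rate and coupling profiles are *ordinal*
calibrations: the study reports no IPA values in physical units, so only
the ordering and rough effect sizes are designed, not absolute rates.

The **null** preset removes every designed difference: identical signal
parameters for all conditions, no participant workload effect, *and*
equalized segment durations (6 s items without jitter, single-window
fixation tasks) — the last because of the duration bias above.

Seed-splitting is stable and documented: `set.seed(master_seed)`, then one
`sample.int(2^31 - 1)` draw per participant in participant order; each
participant's session is generated entirely under their derived seed, with
a fixed draw order inside each segment.

What the generator does **not** emulate: pupil foreshortening with gaze
angle, luminance responses, saccade-induced artifacts, asymmetric or
partial blinks, tracker dropout bursts, and any mechanistic pupil dynamics.
Passing tests on synthetic cohorts therefore demonstrate that the pipeline
recovers what it is designed to measure under the assumed signal model —
not that the IPA is a valid workload indicator on real recordings, which is
the study question itself.

## Problem sizes used by the test suite

The bundled checks run, per decision made here: oracle equivalence on 100
ten-second segments and 1000 random maxima scans; rate monotonicity on
20 × 10 s segments at four rates; 20 replications of a 30-participant
designed cohort (full 62-segment sessions at 300 Hz, with the
indicator-to-Bayes chain restricted to the conditions the checked contrasts
use); five 30-participant null cohorts (full pipeline); a 55-participant
layout-only cohort for accuracy calibration.  The null-cohort H0 fraction
is pooled over the replicated cohorts because the per-pair probability of
H0-side evidence under a true null is ≈ 0.95, so a single 32-row table
scatters around the 0.90 line by chance.

## Known limitations

* Only the Symlet-16 / two-level / periodic configuration of the transform
  is implemented; the parameters exist in `ipa_params()` for
  forward-compatibility but other wavelets are not shipped.
* The exact semantics of the published threshold adaptation ("factor 0.8")
  follow the threshold-multiplier reading; the original calibration study
  defines it and is not public alongside the algorithm listing.
* The commercial ICA cannot be computed (unpublished algorithm); externally
  computed indicator values can enter the pipeline through the indicator
  table interface and flow through standardization, aggregation and the
  comparison battery unchanged.
* The low/high-frequency ratio variant of the indicator is out of scope.
* Item response times, absolute IPA levels per condition, and the
  magnitude of inter-eye coupling are not published; the corresponding
  generator settings are declared design choices, not estimates.
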