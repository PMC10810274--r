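---
title: "Identifying people from eNose body-odor measurements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying people from eNose body-odor measurements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enoseid)
```

## The problem

A metal-oxide electronic nose (eNose) exposes an array of cross-sensitive
gas sensors to the headspace above an odor source; each sensor reports a
conductivity ratio G0/G that evolves over the measurement phase and settles
toward a sensor-specific endpoint. A panel of such endpoints is an odor
fingerprint. `enoseid` asks the closed-set biometric question: given
endpoint fingerprints of body-odor samples (ear canal, armpit, lower back)
from a fixed roster of participants collected over several days on two
devices, can a new sample be assigned to the right person?

The package covers the full analysis chain: a canonical endpoint-table
data model with CSV readers/writers, drift correction by fresh-control
division, two deterministic classifiers (fine KNN and regularized LDA),
four validation designs, permutation and exact binomial significance
tests, and a synthetic cohort generator with known ground truth so every
stage can be exercised without access to any human dataset.

## Data model

A *measurement record* is one device's 10-sensor reading of one sample,
either as a 10-channel time series or condensed to 10 endpoints. The
*endpoint* of a channel is its final time sample (`extract_endpoints()`;
an optional trailing-window mean is exposed for robustness experiments,
default window 1, because no averaging is part of the canonical
definition). Records from all devices measuring the same sample are fused
into one feature vector — device 1 sensors 1–10, then device 2 — giving 20
features per sample for the default two-device design.

The exchange object is the `endpoint_table`: one row per fused sample with
`participant`, `day`, `kind` (`body`, `fresh_control`, …), `region`,
`replicate`, and strictly positive feature columns `d1_s1` … `d2_s10`.
Two CSV dialects round-trip losslessly: `wide` (canonical, one row per
fused sample) and `long` (one row per device-sensor reading; fused and
canonically sorted on read, so file row order is immaterial).

## Drift correction

Sensor response drifts between sessions, and body odor itself drifts.
The correction divides each body sample's feature vector element-wise by
the fused endpoints of the *matched fresh control*: a fixed reference
odorant prepared fresh and measured on the same day for the same
participant. Division is device-aligned — each device's body endpoints are
divided by that same device's control endpoints, the only physically
sensible alignment since the devices run at different flows. Any
per-sensor multiplicative factor a day imposes on both measurements
cancels exactly (`drift_correct()` is equivariant to shared positive
per-sensor gains; this is tested). Missing or duplicated controls are hard
errors in corrected runs; uncorrected runs pass body rows through.

A consequence worth knowing: the control measurement carries its own
noise, which division copies into *all* of that participant-day's
corrected samples. Corrected samples of one participant-day are therefore
correlated even when no participant signal exists. This is a property of
reference division itself, not of any implementation, and it is why the
package's null-behaviour checks run on uncorrected data.

## The synthetic cohort generator

`simulate_cohort()` emulates the sampling design the analyses assume:
12 participants × 5 consecutive days × 3 body regions × 3 replicates per
region-day, one fresh control per participant-day, everything measured by
2 devices × 10 sensors and fused to 20 features. Every multiplicative
term is log-normal, keeping endpoints strictly positive so division is
always well defined. For sensor *s* of device *v*, a body sample of
participant *p*, region *r*, day *d* has expected endpoint

\[
E = B_s \; g_{vs} \; D_{dvs}^{\kappa} \; S_{prs} \; J_{prds},
\]

with realized measurements additionally carrying a per-measurement
idiosyncratic drift term of log-scale \((1-\min(\kappa,1))\,
\sigma_{\text{drift}}\) and replicate noise. The matched fresh control
carries \(B_s g_{vs} D_{dvs}\) times its own noise. The parameters, with
defaults:

| parameter | default | meaning |
|---|---|---|
| `baseline_level` | 10 values in 0.6–2.4 | nominal per-sensor G0/G endpoint (unitless); one sensor sits below 1, mimicking a negative-signal sensor |
| `signature_scale` | 0.20 | log-sd of participant-region signatures \(S\) — the identity signal |
| `signature_day_jitter` | 0.10 | log-sd of day-to-day signature wobble \(J\) — source stability |
| `drift_scale` | 0.25 | log-sd of day × device drift \(D\) |
| `drift_coupling` (\(\kappa\)) | 0.7 | how faithfully body samples share the control's drift |
| `replicate_noise_scale` | 0.10 | log-sd of per-measurement noise |
| `device_gain_scale` | 0.05 | log-sd of fixed per-device sensor gains |

The structural defaults are the study design the package targets; the
stochastic scales are not measurable from published summary statistics,
so they were chosen once as plausible magnitudes for conductivity-ratio
data (tens of percent drift between sessions, ~10% replicate noise, a
signature on the same order as the drift) and are documented here rather
than revisited.

The coupling exponent \(\kappa\) is the single knob spanning the two
regimes the field observes: at \(\kappa = 1\) control division removes
drift exactly and correction can only help; at \(\kappa < 1\) body
samples drift partly on their own, so correction is imperfect across days
and can even hurt. The idiosyncratic term is drawn independently *per
measurement*. Drawing it per participant-day was considered and rejected:
a participant-day-level factor is itself an identity cue within a day,
which would make even signature-free cohorts classifiable and break the
null calibration below.

Every random draw comes from a deterministic stream keyed by seed and
entity (participant, day, device, …), so identical configurations are
bit-identical, and simulating fewer days reproduces exactly the records
shared with the full design. `simulate_time_series()` realizes each
measurement as saturating-exponential channels
\(G(t) = 1 + (E-1)(1-e^{-t/\tau})\) (default \(\tau\) = 8 s over a 50 s
phase), so endpoint extraction recovers \(E\) up to
\((E-1)e^{-50/\tau}\); extraction, fusion and the cohort generator agree
by construction and by test.

What the generator does *not* emulate: humidity and temperature
excursions, sensor poisoning or aging trends within a day, the chemistry
of the reference odorant, non-stationary signature changes (diet,
cosmetics), or heavy-tailed artifacts. Passing tests on synthetic data
therefore demonstrate that the pipeline's statistics behave as designed
under the assumed generative model — not that real body odor is this
clean.

## Classifiers

Both models are fully deterministic; all randomness in the package lives
in fold assignment and label shuffling.

**Fine KNN** (default `k = 2`): Euclidean distances on raw fused
features, no standardization by default (endpoints share a scale; a
`standardize` flag exists because toolbox defaults elsewhere differ).
Candidates are ordered by distance with training-row index breaking exact
ties; when the k votes split, the nearer neighbour among the tied classes
wins. With `k = 2` this rule always returns the nearest neighbour's
label, which is exactly the "fine" (fine-grained boundary) behaviour, and
it makes every prediction reproducible to the bit.

**LDA**: class means with a pooled within-class covariance (divisor
\(N - C\)), ridge \(\gamma\) added to the diagonal (default
\(10^{-6}\times\) mean diagonal — large enough to survive benign
collinearity, ~six orders below the signal), empirical priors, prediction
by the linear discriminant
\(\delta_c(x) = x^\top\Sigma^{-1}\mu_c - \tfrac12\mu_c^\top\Sigma^{-1}\mu_c
+ \log\pi_c\). A covariance still singular after the ridge is an error
suggesting a larger \(\gamma\), never a silent pseudo-inverse. Both
models are verified prediction-for-prediction against brute-force oracles
on more than a thousand random small instances, and LDA additionally
against an independent reference implementation.

## Validation designs

* `run_loo()` — leave-one-out over all samples (36-fold on one
  day-region). Deterministic.
* `run_one_per_participant()` — the stricter scheme: each participant's
  `m` samples are randomly assigned to `m` folds, every fold holding out
  exactly one sample per participant (train 2 / test 1 per person on a
  single day). Repeated `n_iterations` (default 500) times; the mean is
  reported as the design's accuracy, the median feeds the permutation
  test. Fold assignments are drawn independently per iteration per
  participant; the randomization scheme is not otherwise constrained, so
  this simplest choice is used. A "3-fold, test on 66.7%/train on 33.3%"
  description of this design circulates; it contradicts the worked
  definition (train 2 of 3, test 1 of 3 per person), which is what is
  implemented.
* `run_accumulated_days()` — the same scheme on growing day ranges; folds
  scale with the data (2 days: train 5 / test 1 per person; 4 days: train
  11 / test 1), keeping stringency constant.
* `run_day_holdout()` — train on a set of days, test on an unseen day
  (canonically days 1–4 vs day 5). The model is refit on the full
  training-day set; no model selection is involved.

Folds always partition the evaluation set; each sample is tested exactly
once per iteration; accuracy is micro-averaged (equal to macro here since
classes stay balanced).

## Significance

`permutation_test()` shuffles participant labels across all samples of
the evaluation table *before* fold construction and fitting — the
stricter of the two possible conventions — re-runs the design, and
repeats for `n_null` (default 500) iterations. The p-value is the add-one
estimator \((1 + \#\{\text{null} \ge \text{observed median}\})/(1 +
n_{\text{null}})\): it can never return 0, and with 500 nulls its floor
is \(1/501 \approx 0.002\). The `≥` is deliberate (conservative).

`binomial_point_p()` gives the exact chance probability of `r` correct
identifications out of `n` trials, \(P(r) = \binom{n}{r} p^r
(1-p)^{n-r}\) with \(p = 1/12 \approx 0.0833\) for a 12-person roster;
`accuracy_to_r()` converts an accuracy to `r` by half-up rounding.

One subtlety the package documents rather than hides: the chance level of
*leave-one-out* under permuted labels is not \(1/C\). Deleting the test
sample leaves its class with one fewer training representative, so the
exact null expectation of a nearest-neighbour LOO is \((m-1)/(N-1)\)
(2/35 ≈ 5.7% for 3 replicates of 12 participants), below 8.33%. The
class-balanced designs (one-per-participant, day holdout) have null
expectation exactly \(1/C\). The package's null-calibration tests check
each design against its exact chance level at the 99% binomial level.

## Numerical and degenerate-input choices

Endpoints must be strictly positive and finite; violations name the row
and column. Missing fresh controls name the participant-day. Equidistant
KNN neighbours resolve by training-row index; equal LDA discriminants by
first class level — both unreachable on continuous data but pinned down
for reproducibility. CSV serialization uses shortest-round-trip decimals
(lossless to at least 12 significant digits). Seeds are 32-bit; all
derived stream seeds stay below \(2^{31}\).

## Problem sizes used by the test suite

The suite exercises the full 12 × 5 × 3 × 3 design where arithmetic
matters (sample counts, fold sizes) and smaller cohorts (3–4 participants,
1–2 days, 1–2 regions) where only behaviour is at stake. Stochastic
checks use 10–100 fold iterations and 30–500 permutation nulls, and the
null-calibration and drift-monotonicity properties average over 20 seeds
with one region — sizes at which the binomial error bands used by the
assertions are already narrow.

## Limitations

Endpoint-only analysis discards time-course shape by design. The
generator's log-normal world has no heavy tails and no humidity
confounds. Reference division propagates control noise into all of a
participant-day's samples (see above). Real datasets must be adapted to
the canonical CSV schema by the user; no vendor export parser is
included. The permutation test treats iterations of the fold scheme as
exchangeable summaries and is not a substitute for new-subject
generalization claims.
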