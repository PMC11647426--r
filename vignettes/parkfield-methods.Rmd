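---
title: "parkfield: models, calibration, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{parkfield: models, calibration, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkfield)
```

## The problem this package addresses

Acute dopamine D1 (SCH23390) or D2 (haloperidol) receptor antagonism in mice
produces a transient, dose-dependent parkinsonian motor phenotype that can be
read out in a single open-field session: less distance travelled, fewer
movement initiations, lower peak speeds, more time immobile and frozen, with
effect onset within ~10 minutes of intraperitoneal injection and washout by
60-75 minutes.  `parkfield` implements the full analysis chain for such an
experiment — per-frame tracking trajectories in, dose-response statistics
out — together with a synthetic session generator that stands in for raw
tracking data, which the underlying study did not release.

Every tunable constant lives in one config file,
`inst/extdata/default_config.json`; the code reads defaults from there or
from the matching constructor defaults, never from scattered literals.

## Pharmacodynamic model

Suppression of locomotor drive is modelled as a separable product
$E(t, d) = E_{\max} \cdot \frac{d^h}{d^h + ED_{50}^h} \cdot B(t)$ with the
normalized Bateman function
$B(t) \propto e^{-k_e t} - e^{-k_a t}$, scaled so its maximum is exactly 1 at
$t^\* = \ln(k_a/k_e)/(k_a - k_e)$.  Consequences used by the tests: at
$d = ED_{50}$ and $t = t^\*$ the suppression is exactly $E_{\max}/2$; for
$k_a \gg k_e$, $B(t) \to e^{-k_e t}$; $E(\cdot, 0) \equiv 0$.

Parameter choices, with units and rationale:

| parameter | default | why |
|---|---|---|
| `ed50` (mg/kg) | 0.02 (SCH23390), 0.2 (haloperidol) | half-maximal dose placed at the low end of the dose range that produces clear hypokinesia for each compound, so the upper grid doses sit well above ED50 |
| `emax` | 0.97 | top doses must approach (not reach) complete suppression: ~90% effect at 5x ED50, matching near-total immobility early in high-dose sessions |
| `hill` | 1.5 | steep enough that the top dose nearly saturates while the lowest grid dose (0.25x ED50) retains a small but visible effect |
| `ka` (1/min) | 0.30 | onset: effect peak at $t^\* \approx 7.7$ min, i.e. established by the 10-min TOI start |
| `ke` (1/min) | 0.04 | washout: $B < 0.15$ beyond ~70 min, so significance is lost in the final bins |

These are generator constants, not physiological PK estimates; no plasma
compartments or IP absorption kinetics are modelled.

## Locomotion generator

Each session is a two-state semi-Markov process on [0, 90) min:

* **Immobile periods** end when a mobile bout initiates.  The initiation
  hazard is $h(t) = \text{bout\_rate}_0 \cdot \text{round\_factor}^{r-1}
  \cdot e^{-t/\tau} \cdot (1 - E(t, d))$ — within-session habituation
  (exponential, $\tau$ = `habituation_tau`), across-round habituation, and
  drug suppression all act multiplicatively on the same hazard.  Sampling
  uses thinning against the constant bound $\text{bout\_rate}_0 \cdot
  \text{round\_factor}^{r-1}$.  An immobile period is a **freeze** (head,
  center, tail all held) with probability `freeze_frac`; otherwise the center
  stays fixed while head and tail wobble with isotropic Gaussian noise
  (`posture_noise`), which is what makes the immobility/freezing distinction
  detectable downstream.
* **Mobile bouts** have exponential duration (`bout_mean_dur`) and move the
  center as a correlated random walk: per-frame log-normal speed (median
  `speed_scale * (1 - E)`, sdlog 0.45), heading increments
  $\mathcal{N}(0, dt/\text{heading\_persistence})$ plus a corner-directed
  pull of `thigmotaxis_strength * sin(target - heading) * dt`, and reflecting
  walls.  Head and tail sit at half a `body_length` along the heading axis,
  clamped into the arena.

All randomness flows through R's RNG under a per-session seed derived
deterministically from (master seed, animal index, round), so cohorts are
bit-reproducible and no global RNG state leaks.

### Calibration of the saline defaults

The stated calibration targets for a saline session are: mean measured
immobility ~70% of the 10-60 min TOI, above 80% in the final 30 minutes, and
a corner-zone occupancy plurality.  `bout_rate0 = 10.5`/min,
`bout_mean_dur = 4` s and `habituation_tau = 45` min were derived from the
alternating-renewal expectation (mobile fraction $h\bar d/(1 + h\bar d)$)
and then verified once by simulation: 20 default sessions give 71.4% TOI
immobility and 86.3% in the final 30 min (these are exactly the quantities
the acceptance script recomputes).  `thigmotaxis_strength = 2` rad/s yields
corner/wall/center fractions of roughly 0.47/0.40/0.14 — corner plurality
with substantial wall time.  The constants were fixed before the acceptance
assertions were frozen and are not revisited per-test.

### What the generator does and does not emulate

It reproduces: habituation within and across rounds, corner-biased
thigmotaxis, dose-dependent hypokinesia with onset/washout kinetics, the
freezing-as-subset-of-immobility structure, and the lattice dosing design
(one saline animal per 4-mouse batch, no repeated drug-dose combination,
at most four injections, >= 5 days apart).

It does **not** emulate: tracking dropouts or pixel noise beyond posture
wobble, postural changes (hunched back), the clockwise-rotation bias
reported anecdotally at 1 mg/kg haloperidol, sex differences, biphasic
low-dose D2 effects, or unbalanced group sizes (the design defaults to
balanced groups).  A green simulation-based test therefore establishes that
the *pipeline* behaves correctly on data with this statistical structure —
not that the generator is a validated model of mouse behaviour, and not that
the study's animal-level F statistics are reproduced (they depend on
unreleased raw data and are explicitly out of scope).

## Motor metrics: definitions and conventions

* **Immobility**: smoothed center speed (0.5 s boxcar, truncated at the
  session edges) below 1 cm/s sustained for >= 2 s.  Candidate runs separated
  by < 0.2 s of supra-threshold frames are merged first, suppressing
  single-frame tracking flicker.  The tracking engine's exact criteria are
  unpublished, so both thresholds are config-exposed; 2 s and the 0.8 m/s
  jitter cap are the assay's printed constants.
* **Freezing**: within immobile episodes, frames where smoothed head *and*
  tail speeds are also below threshold, in maximal runs >= 2 s.  No gap
  merging is applied to freezing runs (the merge is defined for the center
  criterion only).  Freezing time <= immobile time holds by construction.
* **Mobile episodes**: onsets of mobile intervals (the complement of the
  immobile episodes).  A session starting mobile contributes its first
  episode at t = 0.  Per-bin episode counts follow the *onset* bin; whether
  the original analysis counted onsets or per-bin overlap is not stated, so
  the onset convention was chosen and is documented here.
* **Rotations**: heading = angle of the tail-to-head body axis (not path
  direction, so rotations count even with a near-stationary center); wrapped
  per-frame increments feed a signed accumulator that ratchets at +/-360°.
  The comparison uses a 1e-9 rad tolerance so a mathematically exact full
  turn accumulated in floating point still counts.  Frames with body length
  < 1 cm are skipped and reported.
* **Maximum speed**: per 5-min bin, the max center frame speed after
  discarding frames above 0.8 m/s; empty bins are flagged missing.  Over a
  window, `absolute` = max of bin values; `averaged` = mean with missing
  bins as 0 — deliberately, because being dragged down by inactivity is what
  distinguishes the averaged readout.
* **Bins and windows**: half-open 5-min bins [k·5, (k+1)·5); the TOI is
  [10, 60) min with absolute max speed also reported on the [10, 35) and
  [35, 60) halves; time-based metrics contribute episode overlap to every
  bin spanned.
* **Zones**: 10-cm grid cells with half-open boundaries except the arena's
  far edges (every in-arena point gets exactly one cell); 4 corner, 12 wall,
  9 center cells; occupancy uses the body-center point only.

## Statistical layer

* **One-way ANOVA** is the classical fixed-effect between/within
  decomposition on TOI summaries, control included.
* **Dunnett's comparisons** use the max-|t| multivariate-t null with
  correlation $\sqrt{n_i n_j / ((n_i + n_0)(n_j + n_0))}$.  With one
  treatment group the procedure reduces exactly to the two-sided pooled
  t-test.  Otherwise the null is evaluated by Monte Carlo with a fixed
  internal seed and 1e6 draws (no deterministic multivariate-t quadrature is
  available among the allowed dependencies), reproducible to ~3 decimals;
  adjusted p-values are floored at the raw p.
* **Two-way time course**: ordinary fixed-effects treatment x bin ANOVA with
  interaction — no repeated-measures structure is imposed because none is
  stated for the original analysis; per-(dose, bin) contrasts use the pooled
  residual variance.  Sidak adjustment $1 - (1-p)^m$ is applied **per dose
  row** (m = number of non-missing bins) by default, matching a row-wise
  reading of the published tables; `per_table` and `per_column` families are
  config-selectable since the original family is unstated.  Missing cells
  are flagged NA, never imputed.  Rendered heatmaps clip to
  [0.0001, 0.9999], the printed range of the published tables; full
  precision is retained in the fit object.

## Parameter recovery

`fit_dose_response()` refits `emax` and `ed50` by least squares from
seed-averaged TOI distances on a dose grid, using the alternating-renewal
expectation `predict_toi_distance()` as the model plus a free multiplicative
scale.  The scale absorbs the constant bias of the renewal approximation
(segmentation edge effects, short-period censoring), so only the
dose-response *shape* identifies the parameters; on 20-seed grids both
recover within a few percent.

## Numerical and degenerate-input choices

* Timestamps must be strictly increasing with constant spacing (1e-6 s
  tolerance); the reader rejects, never resamples; `find_tracking_gaps()`
  reports irregular gaps for triage.  Zero-frame trajectories are invalid.
* A step between frames i and i+1 belongs to the window containing the later
  frame's timestamp; frame-level speed series copy the first defined value
  into frame 1.
* Episode boundaries are half-open `[start, end)`; the mobile/immobile
  partition is exact to one frame.
* Degenerate statistics fail loudly (all-identical ANOVA input, empty
  windows, misaligned bins), except inside the pipeline's stats stage, where
  degenerate *metrics* (e.g. an all-zero freezing count column in a short
  demo run) are skipped with a log line rather than aborting the run.
* The pipeline writes to a staging directory promoted only on success, so a
  failed run leaves no partial outputs.

## Known limitations

* The generator's realism ceiling (above) bounds what simulation-based tests
  can establish; analyses of real tracking exports should revisit the
  segmentation thresholds against their tracking engine.
* Dunnett p-values carry ~1e-3 Monte Carlo jitter (deterministic given the
  fixed internal seed).
* The two-way layer ignores within-animal correlation across bins; a
  mixed-effects alternative is deliberately out of scope.
* Arena coordinates treat each quadrant as an independent 50 x 50 cm arena;
  multi-animal interactions and occlusions are not modelled.
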