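---
title: "Sensory-memory signatures in event-segmented tracking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensory-memory signatures in event-segmented tracking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the generative models, the statistical battery, every tunable parameter
with its default and rationale, and the limits of what the synthetic data
can show.

## The question and the two architectures

A set of disks moves along *bilinear trajectories*: straight for the first
half of the motion, then all disks deviate synchronously by 30–180°
(clockwise or counter-clockwise at random) and move straight again. The
synchronized deviation splits the motion into two event segments. After the
motion stops, the observer is cued to report the direction of one
trajectory (single report, SR) or of all of them (full report, FR), for
either the pre- or the post-deviation segment.

Two memory architectures make different predictions. In the **shared**
architecture, sensory memory (SM) holds directions from both segments
(each item carrying a segment tag), so the classical SM signatures — decay
with delay, an SR-over-FR advantage, and SR ≈ FR1 — should appear for both
segments. In the **exclusive** architecture SM is an untagged buffer for
the current segment only, so the signatures should appear post-deviation
and vanish pre-deviation, where recall must rely on capacity-limited
short-term memory (STM).

The package simulates both architectures, plus two degenerate controls,
and asks whether the statistical battery can tell them apart.

## Stimulus generator

Displays default to a 22.5° × 17° screen (800 × 600 px, 39.5 × 29.5 cm at
1 m, 100 Hz); `pixel_subtense()` returns the exact arctangent pixel size
(1.697′ horizontal, 1.690′ vertical, mean 1.694′).

`sample_direction_set()` draws pre-deviation directions uniformly on the
circle and deviation magnitudes uniformly on [30°, 180°] with random sign,
then rejection-samples *whole* direction sets until all `2N` motion
directions are pairwise ≥ 20° apart (the separation that keeps reports
unambiguous). Resampling the whole set, rather than repairing offending
items, preserves exchangeability. Under the default convention the
acceptance event is independent of the deviation magnitudes (a disk's own
pre/post pair is always ≥ 30° apart, and all other pairings involve
directions that are uniform regardless of the deviation), so accepted
deviations remain exactly uniform — the property tests verify this with a
Kolmogorov–Smirnov check.

Two readings of "deviated by *x*°" are exposed, because the printed
arithmetic of the source experiments is consistent only under the second:

* `direction_change` (default for simulation): the post direction is the
  pre direction plus the signed deviation.
* `interior_angle` (used by the controls module): the angle at the vertex
  is *x*, so the direction *change* is 180° − *x*; a mean deviation of 105°
  then yields a mean direction difference of 75°.

Note an interaction with the separation rule: under `interior_angle`, a
deviation above 160° makes a disk's own two directions closer than 20°, so
the constraint truncates the deviation distribution. This is why the
constrained overwriting simulation falls below the unconstrained analytic
ceiling (see Controls).

Start points are drawn uniformly from the closed-form feasible rectangle
that keeps start, vertex and end (plus the 0.5° disk radius) inside the
display — the trajectory is piecewise linear, so vertex containment of all
three points implies containment of every frame. Sets whose start points
come within one disk diameter of each other are resampled (cap: 10,000
rounds, then an explicit infeasibility error; a path longer than the
display diagonal errors immediately). The 1 s static pre-motion period and
disk colors are design metadata only; nothing is rendered.

## Experiment designs

Four presets mirror the usual manipulations: `exp1a` (durations 200–1200 ms
at constant 5°/s), `exp1b` (same durations at constant 4° trajectory
length, so the pre-deviation cue delay spans 100–600 ms at constant signal
strength), `exp2` (post-deviation cue delays 0–1600 ms at 800 ms duration)
and `exp3` (set sizes 1–4). Each condition level is run in 10 blocks of 40
trials, the four reporting conditions equally frequent and randomly
interleaved within a block, and block order randomized — 1600 trials for
the four-level designs, 2400 for the six-level one. Pre-deviation cues
appear at motion offset, i.e. half the motion duration after the queried
segment ended; post-deviation cue delay is zero except in `exp2`.

## The observer model

The source models are qualitative, so the package commits to the minimal
standard psychophysics machinery that realizes them. Retrieval of a queried
direction proceeds through three stages:

1. **SM**: available with probability `exp(−t_eff / sm_tau_ms)`, where
   `t_eff = cue_delay + (report_order − 1) · inter_report_latency_ms`.
   Which segments SM may serve is the architectural difference: only the
   post-deviation segment under `exclusive`, both under `shared`.
2. **STM**: otherwise, the item is retrieved if it is among the
   `stm_capacity` items stored for that trial (sampled without
   replacement); STM does not decay within a trial.
3. **Guess**: otherwise, a uniform direction. A lapse also produces a
   uniform guess with probability `lapse_rate` regardless of memory state.

Retrieved directions are reported with wrapped-Gaussian noise
(`sm_sigma_deg` or `stm_sigma_deg`). The wrapped Gaussian is preferred to a
von Mises because its SD maps directly onto the RMS-error analyses; at
these concentrations the two are indistinguishable.

Defaults, with units and rationale:

| parameter | default | why |
|---|---|---|
| `sm_sigma_deg` | 15° | precise SM reports: TP ≈ 0.93 at zero delay, the upper range typical of trained observers |
| `sm_tau_ms` | 700 ms | few-hundred-ms iconic decay: availability falls from 0.87 at 100 ms to 0.10 at 1600 ms, spanning the cue-delay designs |
| `stm_capacity` | 2 items | severely limited STM; with 3 disks, one item per trial is unrecoverable pre-deviation |
| `stm_sigma_deg` | 35° | coarser durable traces: TP ≈ 0.85 for STM retrievals |
| `inter_report_latency_ms` | 1500 ms | time to aim and click one report; the sources do not state it, and it controls how fast FR2–FR4 degrade — it is deliberately a free parameter |
| `lapse_rate` | 0.02 | occasional attentional lapses, standard in psychometric modelling |

These defaults were chosen once to satisfy the qualitative signature
pattern (they are ordinary values for this class of model); nothing is
fitted to any published performance curve, which would be impossible
anyway since the human trial data are not deposited.

**Report order.** Observers choose their own full-report order. The default
policy is *strength ordering*: when the queried segment is not held in SM,
STM-stored items are reported first (ties at random); when SM holds the
segment, all items are equally strong and the order is uniform. This is
what makes the pre-deviation SR ≠ FR1 signature reproducible under the
exclusive architecture — an observer who reports remembered items first
makes FR1 *better* than SR when only STM is available (FR1 is almost
always a stored item, SR hits a stored item only K/N of the time). A
uniform-permutation policy is selectable, under which SR and FR1 are
identically distributed pre-deviation and the comparison carries no
information.

Cohorts (`make_cohort()`) apply multiplicative log-normal jitter (default
10%) to the noise SDs and the decay constant, giving the between-subject
variance that repeated-measures tests need.

## Scoring and the RMS ↔ TP equivalence

Errors are signed circular differences in (−180°, 180°] (the boundary maps
to +180°); `tp()` applies the linear map `1 − |δ|/180`.
`summarize_conditions()` averages TP per cell and per full-report order,
flags empty cells with a warning instead of dropping them, and is invariant
to record order.

`rms_tp_equivalence()` simulates, for 21 RMS levels spanning 1–90°, 1,000
zero-mean Gaussian errors and the mean TP, then the Pearson correlation
between level and mean TP. Two deliberate design choices:

* The TP transform is applied to the *raw* Gaussian errors. Circular
  wrapping at σ = 90° would compress 4.6% of the errors and bend the top
  of the curve (mean TP 0.612 instead of 0.601, correlation −0.9988
  instead of ≈ −1), destroying precisely the affine relation
  `E[TP] = 1 − RMS·√(2/π)/180` the analysis is meant to exhibit.
* One standard-Gaussian sample is rescaled to every level (common random
  numbers), so the level comparison is not diluted by independent
  sampling noise and the sample correlation is ≈ −1 to four decimals, as
  a near-noiseless comparison should give.

## Repeated-measures ANOVA

`rm_anova()` handles balanced fully-within designs with 1–3 factors:
replicates are averaged to per-subject cell means, each effect is tested
against its subject-by-effect interaction, and partial η² is
`SS_effect / (SS_effect + SS_error)`. The sums of squares are delegated to
`stats::lm`/`anova` on the saturated factorial (a vetted routine); an
independent hand-arithmetic oracle in the tests checks F, df and η² on a
fixed 4 × 2 × 3 fixture, and the two-level case is verified against the
squared paired-t identity. For effects with ≥ 2 numerator df, sphericity
is assessed with Mauchly's test on the covariance of orthonormal contrast
scores; when it rejects at p < .05, both df are multiplied by the
Greenhouse–Geisser ε = (tr S)² / (p · tr S²). With n subjects, Mauchly's
statistic needs n − 1 ≥ p contrasts; below that it is reported as `NA` and
no correction is applied — a real constraint at the 4–5 observer scale
this paradigm uses. Null simulations in the acceptance tests confirm a
≈ 5% type-I rate with 4 subjects and 4 levels.

## The signature battery and the verdict

For each segment, `signature_battery()` computes:

* **decay** — when the segment's cue delay varies across conditions (the
  post-deviation delays in `exp2`; durations in `exp1a`/`exp1b`
  pre-deviation, since there cue delay = duration/2), an RM-ANOVA main
  effect on single-report TP plus a negative trend. When the cue delay is
  fixed (post-deviation in `exp1a`/`exp1b`/`exp3`), decay is tested across
  full-report order at the largest set size, using the inter-report
  interval as the delay proxy. The order proxy has a known confound:
  strength-ordered reporting also produces an order decline when items are
  recalled from STM (best-remembered first), which is why decay alone
  never drives the verdict — it is conjoined with the SR advantage, which
  an STM-only segment does not show.
* **SR > FR** — report-type main effect (with stimulus condition as a
  second within factor where present; with two levels this is exactly the
  paired t) and a positive SR − FR mean difference.
* **SR = FR1** — *non-rejection* of the SR vs FR1 comparison at α. This is
  evidence of absence argued from a null result, so the battery always
  reports the raw mean difference and p value next to the boolean, and no
  multiple-testing correction is applied anywhere in the battery (each
  signature is interpreted on its own).

`classify_model()` declares SM present in a segment when **both**
positive-evidence signatures hold (decay ∧ SR > FR). The SR = FR1 entry is
tabulated against each architecture's predictions but does not gate the
verdict: under either generative architecture SR and FR1 are identically
distributed post-deviation, so the non-rejection signature is true-null
there and caps any verdict rule that requires it at 1 − α per segment —
an avoidable 5–10% misclassification floor. With the positive-evidence
rule, architecture recovery over replicate 4-observer cohorts on the
`exp1b` schedule exceeds 95% for both generative models (the acceptance
suite measures this over 100 cohorts per architecture, plus 100 guessing
cohorts for the false-positive envelope — problem sizes chosen to estimate
a ≥ 95% rate with useful precision at desk scale).

## Controls

`overwriting_bound()` gives the analytic TP ceiling for an observer who
answers pre-deviation queries with the post-deviation direction: under the
interior-angle convention a uniform 30–180° deviation has mean 105°, mean
direction difference 75°, ceiling `1 − 75/180 = 0.583`; under the
direction-change convention the ceiling is ≈ 0.417. `overwriting_simulation()`
verifies the ceiling by Monte Carlo and, when the 20° separation rule is
active, shows the constrained per-condition means sitting below it
(≈ 0.53, because the constraint truncates interior-angle deviations at
160°) — consistent with the 0.52–0.58 range such simulations produce.
`integration_correlation()` regresses |post-deviation SR error| on the
absolute inter-segment angle per observer: a midpoint-integrating reporter
shows slope ≈ 0.5, independent noise shows r ≈ 0, and `mean_r_squared()`
summarises observers by the mean squared correlation (for the printed
coefficients 0.23, 0.09, 0.36, 0.24 it returns 0.062, i.e. 0.06 at two
decimals).

## What the synthetic data are — and are not

The generator reproduces the *structure* of the paradigm: trial counts,
blocking, cue semantics, constrained geometry, and response distributions
rich enough to drive every statistic in the package. It does not emulate
eye movements, attention allocation across disks, perceptual learning,
masking dynamics at the deviation transient, heavy-tailed or swap errors
(reporting the wrong disk), or serial-position strategies beyond the
strength-ordering rule. Passing the recovery tests therefore shows that
the *pipeline* — scheduling, scoring, ANOVA, battery, classifier — draws
the right architectural conclusion from data whose generating process is
known; it does not certify the observer model as a quantitative account of
human performance, and no claim about the published human curves is made
or testable here, since those data are not deposited.

## Numerical conventions and degenerate inputs

Angles are degrees throughout (never serialized as radians); 0° points
rightward and counter-clockwise is positive; all signed differences wrap to
(−180°, 180°] with the boundary at +180°, so `tp(±180) = 0` is reached on
a set of measure zero. `tp()` refuses unwrapped inputs rather than
clamping. Rejection samplers cap at 10,000 rounds and raise explicit
infeasibility errors (a 4° path on a 3° × 3° display errors immediately via
the diagonal check). Empty summary cells are `NA` with a warning, never 0.
All randomness flows through R's global RNG, so a single `set.seed()`
before a pipeline run makes every artifact, including written CSV/JSON,
byte-reproducible.
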