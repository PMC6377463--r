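---
title: "Agent-based single-unit classification and pseudopopulation decoding: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Agent-based single-unit classification and pseudopopulation decoding: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mirrorpop analyses peri-event spike trains recorded while a macaque either
performs a Go/No-Go reach-and-grasp task (execution), watches an
experimenter perform it within the monkey's reach (observation), or watches
it out of reach (extrapersonal space). Three graspable objects (a ring, a
small cone and a big cone), each affording a different grip, appear one at a
time; after a tone-off Go/No-Go signal the cued agent either grasps and
pulls the target or withholds the action. The package implements the full
analysis chain — single-unit ANOVA classification, tuning metrics,
population dynamics and pseudopopulation decoding — together with a
synthetic spike-train generator so that every stage can be exercised and
verified against known ground truth. This vignette documents the models,
the defaults and the design choices that were genuinely open.

## The task model and the epochs of interest

Each trial carries five events in a fixed order: cue onset, object
presentation (light on), Go/No-Go signal (tone off), and, on Go trials
only, movement onset and pulling onset (performed by the monkey in the
execution task, by the experimenter elsewhere). All timestamps are
trial-relative seconds; absent events are missing values, never sentinels.
Five analysis epochs derive from these events: baseline (0.5 s before
object presentation), object presentation (0–0.5 s after light on),
premovement (0.5 s before movement onset), reaching–grasping (movement to
pulling onset, variable trial by trial) and holding (0.5 s after pulling
onset). All windows and bins are half-open, `[start, end)`: a spike on a
right edge belongs to the next bin, so non-overlapping partitions conserve
spikes exactly.

## The synthetic generator

The generator emulates the unit taxonomy the analyses are designed to
detect: action-related and object-related units crossed with self-type (ST,
responding only when the monkey acts or is the potential agent), other-type
(OT, only when the experimenter is) and self-and-other-type (SOT, both),
plus units responding in both domains and unresponsive units.

The rate model is deliberately simple: a per-unit baseline drawn uniformly
from `baseline_rate_range` (default 5–15 spikes/s), multiplied inside a
response window by a gain composed of the category gain
(`modulation_gain`, default 3), an object-tuning gain (default 1 for the
unit's preferred object, 0.4 otherwise) and, for object responses on Go
trials, a Go gain (default 1.5). Object-related categories respond in a
window from object presentation to 0.8 s after it; action-related
categories from 0.5 s before movement onset to 0.5 s after pulling onset
(hence only on Go trials). Object responses are confined to the monkey's
peripersonal space: every object category stays at baseline in the
extrapersonal task, whereas OT/SOT action categories follow the
experimenter's action there. The window edges carry 100-ms linear ramps —
no rate waveform is implied by the epoch analyses, and ramps avoid
artificial bin-boundary effects. SOT (and dual-domain) units scale their
modulation depth by `self_bias` in the execution task (default 1.3, a
moderate execution dominance; set it to 1 for strictly agent-invariant
units). Suppressed units (a configurable fraction, default 0.2) divide the
baseline by the same gain instead of multiplying, which floors rates at
zero by construction. Spikes are drawn from an inhomogeneous Poisson
process by thinning.

Event times are jittered per trial by sampling the inter-event intervals
from truncated normals (lower bound `min_gap`), which preserves the event
order by construction and keeps event means unbiased at the default jitter
scales (0.05–0.08 s). Only correct trials are generated, twelve per (task,
condition, object) cell by default — 216 trials over the full design.

What the generator does *not* emulate — and hence what passing tests do not
certify about recorded data: correlated variability across units (units are
independent, which matches the pseudopopulation assumption but not
simultaneous recordings), non-Poisson spiking statistics, latency
differences across objects, drifting baselines, and error trials.

## Single-unit classification

Two trial-level analyses are run per unit per task on Go trials: an action
design crossing Object (3 levels) with Epoch (baseline, premovement,
reaching–grasping, holding) and an object design crossing Object with
Epoch (baseline, object presentation). Each trial shows exactly one
object, so Object cannot repeat within a trial: the only coherent reading
of a two-factor repeated-measures design is the split-plot model with
trials as subjects nested in Object and Epoch varying within trial, and
that is what `unit_epoch_anova()` fits (via `aov()` with an
`Error(trial)` stratum). No sphericity correction is applied. A unit
responds in a design if the Epoch main effect or the Object × Epoch
interaction is significant at α = 0.05; a significant interaction triggers
Bonferroni post hoc paired contrasts — all epoch pairs within each object
level, corrected across the design's whole contrast family — at 0.01. The
contrast family is our choice (the test family is standard, its exact
composition was open). Response direction (enhanced vs suppressed) is the
sign of the strongest non-baseline epoch deviation from baseline; it was
likewise an open definition and it feeds the population-stage flipping.
Degenerate inputs (zero variance) yield p = 1 with a flag rather than an
error, so pathological synthetic units cannot crash the pipeline.

Units are task-related if any design/task responds; action-related,
object-related or both by which designs respond; and typed per domain as
ST (execution only), OT (observation only) or SOT (both). The
extrapersonal ANOVAs are computed as a far-space control and stored
alongside, but never enter the typing.

A known property of this rule deserves emphasis. "Main effect *or*
interaction" is a union of two 5% tests, so a fully unresponsive unit
passes a given design/task at ≈10%, and a unit tuned in one domain
acquires a spurious second domain with probability ≈1 − 0.9² ≈ 0.19, or a
spurious second task at ≈0.10. Joint recovery of the exact ground-truth
category *and* agent type therefore plateaus near 75–80% even for very
strong effects — the limit is the uncorrected multiplicity of the
classification rule itself, not estimation noise. The acceptance suite
measures this honestly; the Epoch main effect alone is calibrated at 5%.

## Tuning metrics

For action-related units metrics use a −0.5 to +0.8 s window around
movement onset; for object-related units 0 to +0.8 s after object
presentation; Go trials only, averaging the 36 trials in 20-ms bins. The
peak is the highest binned value (earliest bin on ties, for determinism);
burst duration spans the first bins below 66% of the peak on either side,
with window edges used (and the value flagged censored) when no such bin
exists; censored values are excluded from cross-task correlations. The
object preference index is PI = (n − Σᵢ rᵢ/r_pref)/(n − 1) with n = 3 and
r_pref the maximum — 0 for uniform responses, 1 for a response to a single
object. PI inputs are baseline-subtracted mean rates floored at zero:
whether netting was applied upstream was unstated, and flooring keeps the
index defined and in [0, 1] for suppressed units too. The PI null pools
the 36 trials, permutes object labels, re-splits into three sets of 12 and
recomputes, 1,000 times by default. Execution–observation comparisons of
SOT units use two-tailed Pearson correlation plus a paired t test per
parameter.

## Population dynamics

Heat-map matrices use 100-ms bins at 20-ms steps; population traces 60-ms
bins at 20-ms steps. Per unit, the mean baseline rate is subtracted
bin-by-bin, suppressed units (per the single-unit direction flag) are
flipped, and the result is scaled by the unit's absolute maximum bin
across conditions, bounding everything in [−1, 1]; all-zero units are
emitted as zeros with a flag. Rows are ordered by peak time within a
reference period, ties broken by unit id. The bin-wise object-selectivity
count applies an uncorrected one-way ANOVA (factor object, three 12-trial
groups) per unit per bin at α = 0.05. The population ANOVAs treat units
as subjects with all factors within-unit: Task × Epoch (2 × 4, with the
object-presentation and reaching–grasping epochs extended to 800 ms) and
Task × Condition × Epoch (3 × 2 × 2) per ST/OT/SOT subpopulation. The
standard error shading of population traces is across units — the
averaged entities — not trials; this was an open choice and is flagged
here.

## Pseudopopulation decoding

Decoding uses average firing rates in 150-ms bins at 50-ms intervals on a
dual-aligned axis: one segment aligned to object presentation and, after
an explicit gap, one aligned to the Go/No-Go signal, which exists on every
trial (so No-Go trials keep a full axis; movement-locked statistics simply
exclude them). No statistic is computed across the gap. Data points are
subsampled to 30 per class for Go/No-Go and agent decoding (60 points) and
10 per object (30 points), reconciling the 12 available trials per
condition with the printed data-point counts; each resample run draws a
fresh subsample. Points are grouped into as many splits as points per
condition, one point per unit per class per split, drawn independently
across units. Features are z-scored with statistics estimated from the
training splits only and applied to the held-out split; in cross-modal
runs (train one task, test another) the training task also supplies the
normalization statistics, so no test-task information enters training —
this train-only convention was an open question and is our choice. The
classifier assigns each test vector to the class whose training mean has
the highest Pearson correlation; exact ties take the smallest class index
(logged), and a zero-variance test vector draws a class at random under
the run's seed. Leave-one-split-out cross-validation is repeated over 50
resample runs by default.

Significance uses label shuffling: the decoding is rerun with permuted
labels (50 runs, same resampling structure; each permutation run is one
pass of the procedure by default, configurable). A bin is significant only
if the real accuracy strictly exceeds every null value there. Two
reporting rules coexist in the field — at least three consecutive
significant bins, and a minimum significant duration of 200 ms; the
run-length rule gates the reported intervals and each interval's duration
in seconds is reported alongside, so either threshold can be applied.
Single-epoch decoding (the 1,300-ms movement epoch or the 800-ms
object-presentation epoch as one bin) produces a train-task × test-task
accuracy matrix.

One intrinsic property of a correlation readout is worth knowing: it is
blind to any gain shared uniformly by the whole population, because after
z-scoring the class-mean vectors across units remain proportional and
correlations ignore scale. Agent information in this framework therefore
lives in pattern *heterogeneity* — mixtures of self-, other- and
invariant-tuned units, or unit-specific amplitude biases — not in a global
amplitude change; a perfectly homogeneous population with a uniform
execution bias decodes at (or, through cross-validation variance
asymmetries, slightly below) chance.

## Pipeline, seeds and problem sizes

`run_pipeline()` chains the stages; every stochastic stage derives its
seed deterministically from the global seed and the stage name, so a fixed
configuration reproduces byte-identical outputs. All analysis constants
live in the configuration with the standard defaults above. The default
population is 48 units (6 per single-domain category, 4 dual-domain, 8
unresponsive); a full default run — classification, metrics with 1,000 PI
shuffles, population report, and four decoding analyses with 50 resample
and 50 permutation runs — completes in a few minutes on one CPU. The test
suite uses smaller populations and run counts chosen to keep each check's
Monte-Carlo error well inside its assertion margin; the null-calibration
checks use 100 datasets of 100 unresponsive units, and the type-I checks
1,000 simulated null units per design.

## Known limitations

The classification multiplicity discussed above is the main one: exact
taxonomy recovery is bounded near 75–80% by the rule itself. Burst
durations from 20-ms binned averages of a few dozen trials are noisy —
single noise dips below the 66% threshold truncate them — so they are best
interpreted jointly with their censoring flags. The generator's
rate model is piecewise-linear and object tuning has a single contrast
parameter; analyses that depend on richer temporal structure (latency
gradients, ramping onsets) will see an idealized version of them. The
heat-map rendering is functional (matrices and orderings), not a pixel
reproduction of any particular figure style.
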