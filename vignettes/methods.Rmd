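---
title: "Methods: behaviour classification, closed-loop reinforcement and credit assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behaviour classification, closed-loop reinforcement and credit assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethocredit)
```

This vignette documents the models, parameter choices, numerical decisions
and known limitations behind `ethocredit`. The package covers a complete
analysis chain for closed-loop behavioural reinforcement experiments:
sensor calibration, featurization, unsupervised action discovery, online
matching, trigger simulation, and the downstream statistics that quantify
what reinforcement did to behaviour.

## From raw signals to actions

**Calibration.** A head-mounted sensor is never mounted perfectly level.
From a stationary window we estimate the rotation (pitch and roll only,
via the minimal Rodrigues rotation) that maps the mean gravity vector onto
the universal vertical $(0, 0, 1)$, and record the stationary gyroscope
baseline. Calibration subtracts the baseline first, then rotates both
accelerometer and gyroscope vectors. Windows whose acceleration-magnitude
standard deviation exceeds 0.02 g are rejected as non-stationary. The
rotation is orthonormal to $10^{-9}$ and re-calibrating an
already-calibrated stream is a no-op at the same tolerance.

**Gravity/body decomposition.** Each accelerometer axis is median-filtered
(kernel 11 samples = 55 ms at 200 Hz; removes impulsive spikes without
distorting postural dynamics) and high-pass filtered with a fourth-order
Butterworth at 0.5 Hz to isolate body acceleration (BA). The filter is
applied forward–backward (zero phase) so that the gravitational component
GA = (median-filtered signal) − BA stays time-aligned with BA; the kernel
length and the phase convention are package choices, exposed as arguments.
The first 2 s of every session are flagged as filter warm-up and excluded
from segment featurization.

**The four features.** Behaviour is summarized per non-overlapping 300 ms
segment by four discretized distributions:

| feature | meaning | bins |
|---|---|---|
| GAap | gravitational acceleration, anterior–posterior (posture) | 10 thresholds spanning [−1, 1] g → 9 interior + 2 unbounded = 11 |
| ACCdv | raw dorsal–ventral acceleration (movement momentum) | 10 thresholds spanning [−2, 2] g → 11 |
| GYRdv | dorsal–ventral gyroscope (turning) | thresholds 0, ±50, ±100 deg/s → 6 |
| TotBA | total body acceleration (resting vs moving) | 1 threshold → 2 |

The GAap/ACCdv threshold spans are configurable (`feature_bins()`); the
TotBA threshold is estimated once per dataset as the antilog of the
midpoint between the two component means of a two-component Gaussian
mixture fitted to log TotBA — the average value separating the bimodal
distribution — and is then held constant across sessions
(`rest_threshold()`, fallback 0.05 g with a warning when no bimodal
structure is found).

**Similarity.** Histograms are compared feature-wise by the 1-D
earth-mover's distance in its cumulative-sum form, with the ground
distance between adjacent bins set to $1/(n_{\text{bins}}-1)$ so each
feature contributes at most 1. With $dEM$ the sum over the four features,

$$S = -\left(\frac{dEM}{4}\right)^2 \in [-1, 0],$$

where 0 is identity and −1 maximal dissimilarity. These two endpoints are
exact by construction and are what the acceptance script recomputes.

**Clustering.** Affinity propagation on the pairwise similarity matrix,
with the preference set to the matrix minimum (a stable cluster-count
regime), damping 0.9, at most 1000 iterations and 50 consecutive
stable-exemplar iterations for convergence. No noise is injected: the
algorithm is deterministic, which matters because the exemplars seed the
online matcher. A fully degenerate input (all points mutually equidistant,
e.g. identical segments) carries no message-passing evidence and collapses
to a single cluster by an explicit guard. Non-convergence raises an error
carrying the iteration diagnostics rather than returning a partial result.

**Online matching and eligibility.** A segment is assigned to the action
with the highest exemplar similarity (equivalently lowest EMD; the argmax
is identical), ties to the lowest id. Target candidates for closed-loop
reinforcement must pass five filters: false-positive rate below 5.5% *and*
below the repertoire's 60th percentile; false-negative rate at or below
the 90th percentile; not serially repeated (neither median nor range of
the 3–18 s reappearance probabilities of the target and its five most
similar actions above the 90th percentile); shift-stable (percentage of
matching flips under ±one-bin GAap shifts at or below the 90th
percentile); and a fully moving exemplar (TotBA histogram value 1 in the
moving bin).

## The closed-loop trigger chain

Each arriving 300 ms segment is classified and fed to the trigger policy.
In single mode every target classification fires; in sequence mode a T1
classification arms the policy and the next T2 classification fires and
disarms it, however much time has passed. Firing emits a 600 ms train of
15 pulses of 10 ms at 25 Hz (25% duty cycle), with the train onset delayed
by a uniform 35–55 ms decision latency (latency never shifts
classification times). Design choices the description leaves open, made
here once: a fresh T1 is required after each trigger (consecutive T1s keep
the state armed without stacking), and classifications whose segment ends
before the current train finishes can neither fire nor arm. Extinction
phases disarm the policy entirely; contingency degradation replaces it
with a Poisson schedule at a matched mean rate.

## Dynamics, retrospective windows, and sequence analyses

**Action dynamics.** Frequencies are 2.5 min moving means on the 300 ms
grid, emitted only once the window has filled. Stage rates: f0 = 5 min
before the first reinforcement, f1 = 30 min after it, f2/f3 = the first
30 min of the session-2/3 series. Significance between stages uses the
literal run rule — 500 consecutive windows all above the reference stage's
99th-percentile bin (positive) or at or below its 5th-percentile bin
(negative), positive winning on conflict — rather than a parametric test,
because the run rule *is* the definition. The five ordered category rules
(increasing, sustained, transient, decreasing, other) are total: every
action receives exactly one label. The compressed notation "f1/2" in the
rules is read as "f1 or f2" (either comparison suffices).

**Retrospective windows.** 600 ms transitions (two adjacent segments,
lagged by the onset of their first segment relative to stimulation onset)
are counted on a ±2.4 s grid: 15 onset lags at 300 ms steps, a sliding
1.2 s window holding 3 of them, and a 3.6 s "outside" complement of 12.
Per-type probabilities across lags sum to 1. The differential probability
compares the within-window mass against the outside mass scaled to the
same window length (ratio 3/12), so a uniformly distributed type scores
exactly 0 and a type occurring only inside the window scores its full
within probability; types at or above 0.001 are enriched. The 2–6
baseline-count band (over 30 min) keeps rare-but-repeated types.
Tracking is animal-balanced: baseline-normalized frequencies are averaged
within animals before averaging across animals.

**Sequence learning.** The criterion is a baseline-subtracted trigger
frequency of 3.2/min. T1→T2 intervals run from the end of the latest T1 to
the end of the triggering T2 (0.3 s at immediate adjacency); T2→T1 from
the T2 end to the next T1 end. Refinement of a target is the median
target-normalized frequency of the actions uniquely similar to it
(top-12 by exemplar similarity after removing actions shared with the
other target; relaxed to top-9 when fewer than 3 unique actions remain),
scaled per animal so the minimum session maps to 0 and an index of 1 stays
1. The differential refinement D is the trapezoid area under the T1 curve
minus that under the T2 curve, summed until both curves have reached their
minima — positive D means T2 is the more refined target. This orientation
is the one consistent with "T1 at least as refined" corresponding to
per-session differences at or below zero, which anchors the starting-point
scan (latest such session before the first session whose median T1→T2
interval is ≤ 3 s; if none, the earliest session of closest refinement).
The turning point is the interior local maximum of the
starting-point-subtracted per-interval area progression; a monotone (or
end-tied) progression falls back to the last maximal session, flagged.
Rank profiles around triggers anchor their 300 ms bins at the performance
segment of the triggering action (trigger times are train onsets, one
segment later) and use mid-rank percentiles for ties. Sigmoid fits use a
four-parameter logistic; the half-maximum response divides fast from slow
learners.

**Predictors.** The multinomial logit of dynamics reporting group
(sustained increase = increasing ∪ sustained, transient, decreased as
reference) on z-scored target similarity and baseline time-to-target is
fitted by maximum likelihood (`nnet::multinom`); the deviance is twice the
gap to the saturated log-likelihood (zero for individual outcomes).
Cross-validation is 20 repeats × 10 stratified folds (stratification is a
package choice — it guarantees class presence; a fold that still loses a
class is refolded and logged), and the null distribution comes from
label-shuffled datasets run through the identical machinery. AUPRC is
computed one-vs-rest as step-wise average precision and macro-averaged;
model comparisons add the AIC penalty 2k to each model's deviance.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed once.

**Prototypes and raw signals.** An action prototype is a (posture pitch,
turn rate, mobility) triple with the implied four-feature histogram set.
`make_repertoire()` draws K prototypes by farthest-point (maximin)
selection *in EMD space* from a random candidate pool — real behavioural
clusters are mutually discriminable by construction, and selecting in
histogram space (rather than parameter space) respects the saturation of
the outer bins. Raw synthesis projects gravity through the pitch posture,
adds a 5 Hz three-axis body-acceleration carrier (120° phase offsets, so
the magnitude is a near-constant 0.3 g) gated by mobility, and a constant
GYRdv turn rate; session-level synthesis additionally low-passes the
gravity trajectory at 2 Hz, because postural change is continuous and a
step discontinuity would masquerade as body acceleration to the 0.5 Hz
high-pass. Mount misalignment and gyroscope bias are applied exactly as a
real sensor would and are removed by calibration to $10^{-9}$.
Magnetometer channels are not synthesized (the features never use them).

**What raw-mode validation shows.** With a data-estimated TotBA threshold,
online matching recovers ≥90% of ground-truth labels for slow-switching
agents over small repertoires (K = 8, mean bout ≈ 6 s, low noise). Under
crowded repertoires (K = 30) and fast switching, recovery degrades
gracefully (≈70–80%), dominated by bout-boundary segments whose postural
ramps genuinely span two actions — the same ambiguity that motivates the
false-positive/false-negative eligibility filters on real data. Passing
tests therefore validate the machinery, not a claim that real sensor data
are this clean: real signals add sensor drift, non-stationary noise, and
actions without a parametric generator.

**The behaving agent.** One action per 300 ms segment from a
row-stochastic Markov chain (default stickiness 0.6 → mean bout 0.75 s;
repertoire K = 30). Reinforcement applies a retrospectively time-decaying,
similarity-weighted eligibility update: every action performed at time
$t$ during or before a stimulation at time $s$ gains inbound transition
weight

$$\eta \cdot \exp\!\big(S(i, \text{target})/\sigma\big) \cdot
  \exp\!\big(-(s - t)/\tau\big),$$

added to its column before row renormalization; occurrences during the
600 ms train count as $\Delta t = 0$, and actions occurring only after the
train gain nothing. The exponential forms are the minimal monotone choice
and make the $\tau$ and $\sigma$ limits analytic (an indicator kernel as
$\sigma \to 0^+$; uniform credit as both diverge). They are a testing
assumption, not a claim about the animal's mechanism. A decay $\rho$
relaxes the matrix toward its base at each update. Defaults, chosen once
for realism at the package's session scale: $\eta = 0.002$ (a
several-session rise from ~1/min baselines to far above the 3.2/min
criterion, mirroring the scale of the observed learning curves),
$\sigma = 0.5$ similarity units, $\tau = 2$ s, $\rho = 0.002$.

**Structured agents.** Sequence agents route a behavioural corridor of
intermediate actions from T1 to T2; the corridor length sets the natural
median T1→T2 interval (about one mean bout per step), with follow-through
calibrated so a small majority of T1 performances complete the chain.
Credit-assignment agents instead surround a single target with ~10
low-rate feeder actions (each feeder→target transition landing in the
2–6-per-30-min band) and a post-target fan-out — the rare-but-persistent
sequential syntax that the retrospective-window analysis needs; on a
structureless uniform chain, "enriched" transitions are sampling noise and
no asymmetry can express, however long the simulation runs.

**What the generator reproduces.** Under these conditions the pipeline
recovers the qualitative structure of the reported findings:
pre-stimulation-enriched transitions outgain post-stimulation-enriched
ones after one reinforcement session when $\eta > 0$ and show no asymmetry
at $\eta = 0$; agents with shorter natural T1→T2 intervals reach the
criterion in no more sessions than long-interval agents in at least 80% of
seed pairs; and in slow-learning agents the proximal target's uniquely
similar set reaches low scaled refinement no later than the distal
target's.

## Problem sizes and reproducibility

Every stochastic operation takes an explicit seed and restores the
caller's RNG state; label streams are bit-for-bit reproducible per seed.
The validation suite runs at scaled-down sizes chosen as the package's
own defaults: 15 min reinforcement sessions with 30 min baselines, 20
seeds (or seed pairs) for the simulation-level properties,
5 × 10-fold cross-validation with 10 × 50 shuffled null models for the
predictor harness, and n = 5000 rows for coefficient recovery. The
complete suite runs in a few minutes on one CPU.

## Known limitations

- The synthetic kinematics are schematic: one postural degree of freedom,
  a single-band body-acceleration carrier, no magnetometer, no sensor
  drift within sessions.
- The eligibility-kernel agent is a generative stand-in; parameter values
  ($\eta, \sigma, \tau, \rho$) are not estimates of any biological
  quantity.
- Cohort-level quantities from real animals (sigmoid half-max sessions,
  interval–refinement regression slopes, reacher counts) depend on the
  animal data and are out of scope; the package computes them from data
  but does not claim to reproduce their published values from simulation.
- Affinity propagation at large segment counts is dense
  ($O(n^2)$ memory); repertoire discovery is intended for session-scale
  inputs (thousands of segments), as in the original workflow.
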