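---
title: "Methods: block-design fNIRS activation and connectivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: block-design fNIRS activation and connectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsconn)
```

## The analysis problem

`fnirsconn` implements a complete analysis chain for multi-channel fNIRS
recordings acquired under a block design in which subjects perform a
short-term number-memory task in two auditory environments (white noise
at ~65 dB versus silence). The montage covers 70 measurement channels
(22 frontal, 24 per temporal side) sampled at 10 Hz; each session
alternates 60 s rest blocks with three task blocks of ten
memorize (3 s) / retain (1 s) / answer (≤ 7 s) trials. Because answer
duration depends on the subject, session length and trial period vary
per subject and condition.

Three questions drive the chain:

1. **Activation** — does the accumulated cerebral-blood-flow (CBF)
   change in a channel differ between auditory environments?
2. **Connectivity** — does the channel-wise functional network,
   summarized by node strength, differ between environments?
3. **Behaviour** — do subjects split into phenotypes that benefit from
   noise, are unaffected, or benefit from silence, and do the neural
   measures differ accordingly?

Raw recordings of this kind are proprietary device exports and no
public reference dataset is bundled, so the package ships a synthetic
cohort generator with planted ground truth; every statistical property
of the pipeline is exercised against data whose correct answer is known
by construction.

## Preprocessing

The chain applied by `preprocess()` is:

1. **Dead-channel detection** (`detect_dead_channels`): a channel whose
   raw oxy-Hb trace satisfies `max |oxy| <= tol` (default `tol = 0`,
   i.e. consistently zero) is a non-detecting optode and is excluded
   from all statistics, while being retained in matrices as missing.
2. **Motion-artifact block rejection** (`reject_motion_blocks`): an
   oxy-Hb change between consecutive samples whose magnitude *strictly
   exceeds* 0.1 mM·mm marks a motion artifact; every task block
   containing one is dropped for that subject-condition, across all
   channels. The comparison is per sample at 10 Hz; a `per_second`
   option rescales the threshold for other conventions.
3. **Band-pass filtering** (`bandpass_filter`): zero-phase
   (forward–backward) application of an order-4 Butterworth band-pass
   with passband `1/(2T)` to 0.33 Hz, where `T` is the trial period in
   seconds. Zero-phase filtering avoids any lag between stimulus and
   filtered response; Butterworth was chosen for its monotone, flat
   passband, and the realized filter is recorded in the
   `preprocess_report` for reproducibility.
4. **Z-scoring** (`zscore_channels`): each retained channel is
   standardized to mean 0, SD 1 over the *entire* recording (rest and
   task), using the population (1/N) SD. fNIRS concentration changes
   are relative quantities whose scale depends on optical path length,
   so between-subject comparison requires this normalization.
5. **Baseline correction** (`baseline_correct`): within each task
   block, the value at the block's first sample is subtracted from all
   samples of the block, per channel, so every corrected block starts
   at exactly zero. The operation is idempotent.

Two points in this chain were genuinely open and are the package's own
design choices:

* **Where artifact detection runs.** The exclusion rules are stated in
  raw concentration units (mM·mm), and the analysis band-pass
  annihilates the very feature the motion rule looks for: an order-4
  band-pass at (0.045, 0.33) Hz reduces a 0.5 mM·mm single-sample
  spike to a maximum per-sample change of about 0.003 mM·mm. Running
  detection after filtering would therefore make the rule vacuous.
  `preprocess()` computes both exclusion masks from the raw trace and
  applies them downstream; the standalone operations accept whatever
  recording they are given.
* **What `T` is when trials vary.** The trial period is nominally
  3 + 1 + answer seconds, but realized answer durations vary, so `T`
  is taken as the mean realized trial duration of that
  subject-condition's design (`block_design$trial_period_s`). With the
  7 s answer ceiling this gives the familiar `T = 11 s`,
  `f_lo = 1/22 Hz`.
* **The Z-score window.** Whole-recording (rest + task) per channel:
  the least arbitrary choice, and the one that keeps the rest blocks as
  a reference level. Using task-only windows rescales all downstream
  measures monotonically and does not change test decisions under the
  null.

## Activation: accumulated CBF change

For each retained task block, the per-channel activation contribution
is the sum of the preprocessed samples over the block divided by the
number of samples in the block; contributions are averaged over
retained blocks (`accumulated_change`). Normalizing by block length
makes sessions of different duration comparable, and averaging over
*retained* blocks (rather than imputing rejected ones) follows directly
from the exclusion rule. The condition contrast
(`activation_contrast`) is white minus silent per channel.

## Connectivity: correlation, Fisher z, node strength

`task_timecourse` concatenates the retained task-block segments in
temporal order; `correlation_matrix` computes the 70 × 70 Pearson
matrix over that time course (one correlation per condition, over
concatenated blocks — the block-averaged alternative mixes estimates
with different effective lengths once blocks are rejected);
`fisher_transform` applies `atanh` off-diagonal, mapping correlations
to an approximately normal scale; and `node_strength` sums, for each
channel, the signed weights of its incident edges.

Numerical choices:

* The diagonal is excluded from strength — `atanh(1)` is infinite and a
  self-edge carries no information.
* Strength is *signed* by default (negative correlations subtract); an
  `absolute = TRUE` option exists but is off, since the weighted-graph
  definition sums weights as they are.
* Off-diagonal `|r| = 1` (duplicate channels) raises an error by
  default; `clip = TRUE` clips to ±(1 − 1e−12) for numerically
  degenerate duplicates only.
* Edge sums accumulate in ascending channel order in double precision,
  making results bit-reproducible against a reference edge-by-edge
  summation.

## Behavioural split and group statistics

`split_groups` computes each subject's performance difference
`d = score(white) − score(silent)` in percentage points and derives the
threshold as half the cohort standard deviation of `d` (sample, n−1
convention — the convention is pinned by tests). Labels follow a strict
reading of the rule: `d > threshold` is White, `|d| ≤ threshold`
(inclusive) is Average, `d < −threshold` is Silence, so a subject
exactly at the boundary is Average.

Condition comparisons use two-sided paired *t* tests with `df = n − 1`
(`paired_condition_test`, applied to VAS ratings and channel-wise to
activation and strength); between-group comparisons use Tukey's HSD on
a one-way ANOVA (`between_group_comparison`); multiplicity over the 70
channels is handled by Benjamini–Hochberg FDR (`fdr_correct` — BH
rather than BY, as no dependence structure argues for the heavier
correction). Zero-variance paired differences raise a degenerate-test
error rather than returning infinite statistics.

## The synthetic cohort generator

`cohort_spec()` holds every parameter of the data model; its defaults
*are* the emulated study conditions: 29 subjects in an 8/13/8 mix of
`white_benefit` / `unaffected` / `silence_benefit` phenotypes, 10 Hz,
60 s rest blocks, 3 × 10 trials with answers drawn uniformly from
4–7 s.

Signal model per channel (all amplitudes in mM·mm):

* **Hemodynamic response**: a canonical double-gamma HRF (peak ≈ 5–6 s,
  undershoot ≈ 15–16 s, ratio 1/6) convolved with the *trial encoding*
  boxcar (memorize + retain steps). Locking the response to trials
  rather than whole blocks matters: a whole-block boxcar is near-DC
  within a ~100 s block and would be removed by the 1/(2T) high-pass,
  whereas the trial-rate response (~0.11 Hz) lies inside the analysis
  band. Default amplitude 0.02 everywhere, with condition-specific
  increments of 0.025 planted frontally (white noise, unaffected
  phenotype) and over fusiform channels (silence, silence-benefit
  phenotype), mirroring the group-level activation patterns the
  analysis is designed to detect.
* **Connectivity factors**: unit-variance narrowband oscillations
  (~0.08–0.12 Hz, i.e. slow coherent vasomotion) scaled by
  `factor_scale` (0.01) and a per-channel loading. Narrowband factors
  survive the band-pass and are smooth enough never to trip the
  per-sample motion rule. Defaults: a weak montage-wide background
  factor (loading 0.2, both conditions); a white-condition factor over
  the middle temporal gyrus *and its co-correlated neighbours*
  (superior temporal, retrosubicular, subcentral, fusiform — 23
  channels) for the white-benefit phenotype; a silent-condition
  premotor/SMA factor for the other phenotypes. The broad coupling set
  is essential: after Z-scoring, adding private variance to a small set
  raises within-set correlations but *dilutes* every out-of-set edge,
  and with only the 8 MTG channels the dilution term dominates and the
  planted strength contrast reverses sign.
* **Physiological noise**: sinusoidal cardiac (1 Hz, amp 0.02) and
  respiratory (0.3 Hz, amp 0.002) components and slow drift (0.01 Hz,
  amp 0.02), each with per-channel random phase; an independent
  per-channel Mayer-band component (random frequency in 0.06–0.15 Hz,
  amp 0.015) supplying idiosyncratic in-band variance; white sensor
  noise (SD 0.01). Without the Mayer component the shared task response
  dominates the in-band variance and drives all pairwise correlations
  toward 1, which is neither realistic nor usable for connectivity
  testing.
* **Artifacts**: optional single-sample spikes (Poisson rate
  `artifact_rate`, amplitude 0.5 — well above the 0.1 mM·mm rejection
  threshold) and dead channels as exact-zero traces. Both default to
  off so that the default cohort is clean; tests plant them explicitly.
* **Deoxy-Hb** is generated as −0.4 × oxy plus independent noise and is
  carried through filtering but not analysed, matching the oxy-only
  analysis.
* **Behaviour**: scores (percent correct, truncated to [0, 100]) with
  phenotype × condition means of 85/75 (white-benefit), 80/80
  (unaffected) and 75/85 (silence-benefit), SD 2; VAS pleasantness
  (truncated to [0, 10]) with silent rated more pleasant except for the
  white-benefit phenotype. The ±10-point score separation equals five
  within-phenotype SDs of the paired difference, so the half-SD split
  recovers planted labels with accuracy above 0.9.

The literature quantifies neither noise amplitudes nor effect sizes in
concentration units; the values above were chosen once for realism and
testability (channel SDs of a few × 0.01 mM·mm, artifacts an order of
magnitude above the rejection threshold) and are documented rather than
tuned.

Determinism: `generate_cohort` derives one sub-seed per subject from
`spec$seed`; identical (spec, seed) give bitwise-identical cohorts.
Behavioural quantities are drawn before the recordings, so the
behavioural-only mode (`include_recordings = FALSE`) reproduces the
full mode's behaviour draw-for-draw.

## What the synthetic data do and do not show

Passing tests demonstrate that the pipeline recovers planted effects of
the assumed functional form — trial-locked double-gamma responses,
narrowband coherent factors, sinusoid-plus-white noise — and that its
statistics are calibrated under that model. Real fNIRS data add scalp
and systemic physiology with 1/f structure, motion artifacts that are
neither single-sample nor symmetric, optode-coupling drift, and
task-correlated systemic responses; none of these are modelled, so
passing here does not certify performance on real recordings. The
channel-to-region maps are shipped as static fixtures; the spatial
registration that produced them is out of scope, and the three
group-specific maps are provided as-is without any merging rule.

## Problem sizes used by the test suite

The suite runs entirely on synthetic data generated at test time.
Simulation-heavy checks use reduced designs whose statistical targets
do not depend on size: the type-I calibration uses 200 null cohorts of
10 subjects with 20 s rest blocks and 3 trials per block; the
group-split recovery uses 200 behavioural-only cohorts of 29 subjects;
the planted-coupling check uses six 16-subject cohorts with 20 s rest
blocks and 5 trials per block. Full-sized (29-subject, 60 s rest,
10-trial) cohorts are exercised in the pipeline integration test and by
`scripts/acceptance.R`.

## Worked example

```{r example, eval = FALSE}
spec <- cohort_spec(n_subjects = 29, seed = 1)
cohort <- generate_cohort(spec)
res <- analyze_cohort(cohort)
res
#> <group_assignment> threshold = 3.897; White 8, Average 11, Silence 10
#>   cohort VAS paired t(28) = -5.01, p = 2.71e-05
#>   cohort channels with condition-dependent strength at alpha=0.05: 34

# channel-wise activation tests within the White group
head(res$group_tests$White$activation)

# one subject's connectivity graph in the white-noise condition
res$graphs$s01$white
```
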