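# fnirsconn

Activation and functional-connectivity analysis for block-design fNIRS
(functional near-infrared spectroscopy) recordings, built around a
study design in which subjects perform a number-memory task in two
auditory environments — white noise and silence — while cerebral
blood-flow changes are measured over a 70-channel montage (22 frontal,
24 per temporal side) at 10 Hz.

The package is for researchers analysing multi-channel hemodynamic
time series under block designs: it implements the full chain from raw
oxy-Hb traces to group-level statistics, and ships a synthetic cohort
generator with planted ground truth so that every stage can be
validated without access to raw device exports.

## What it computes

**Preprocessing.** Per subject-condition: dead-channel exclusion
(consistently zero traces), motion-artifact rejection (any task block
containing a per-sample oxy-Hb change |Δ| > 0.1 mM·mm is dropped),
zero-phase order-4 Butterworth band-pass with passband

    f ∈ ( 1/(2T), 0.33 ) Hz,

where T is the subject's trial period in seconds, followed by
per-channel Z-scoring and task-block baseline correction.

**Activation.** The accumulated CBF change per channel:

    A_c = mean over retained blocks b of ( Σ_{t ∈ b} x_c(t) / N_b ),

the duration-normalized sum of the preprocessed signal over each task
block, averaged over blocks; condition contrasts are white − silent.

**Connectivity.** Pearson correlations of the 70 channels over the
concatenated task blocks give a symmetric correlation matrix R; Fisher
z-transformation z = atanh(r) yields the weighted adjacency of an
undirected graph; node strength is the signed sum of incident edge
weights, s_i = Σ_{j≠i} z_ij.

**Group statistics.** Subjects are split by the performance difference
d = score(white) − score(silent): d above half the cohort SD of d is
the White group, within ± the threshold Average, below −threshold
Silence. Conditions are compared with two-sided paired t tests
(df = n − 1, channel-wise with Benjamini–Hochberg FDR), groups with
Tukey's HSD.

## Worked example

```r
library(fnirsconn)

spec   <- cohort_spec(n_subjects = 29, seed = 1)  # emulated study conditions
cohort <- generate_cohort(spec)
res    <- analyze_cohort(cohort)
res
#> <group_assignment> threshold = 3.897; White 8, Average 11, Silence 10
#>   cohort VAS paired t(28) = -5.01, p = 2.71e-05
#>   cohort channels with condition-dependent strength at alpha=0.05: 34
```

The split threshold (3.9 percentage points, half the cohort SD of the
performance difference) assigns 8/11/10 subjects to the White /
Average / Silence groups for this seed. The cohort-level VAS test shows
silence rated more pleasant than white noise (negative t on the
white − silent difference, df = 28). Tukey comparisons of task score in
the white-noise condition separate the groups:

```r
res$tukey$score_white
#>        comparison      diff       lwr        upr        p.adj significant
#> 1 Silence-Average -3.040897 -5.102565 -0.9792281 3.087383e-03        TRUE
#> 2   White-Average  5.043194  2.850687  7.2357013 1.496651e-05        TRUE
#> 3   White-Silence  8.084091  5.845902 10.3222801 5.669652e-09        TRUE
```

Channel-wise tables (`res$cohort_tests$activation`,
`res$group_tests$White$strength`, …) carry the t statistic, df,
p-value, significance flag at α = 0.05 and FDR-adjusted q-value per
channel. Connectivity graphs per subject-condition are in
`res$graphs`, preprocessing decisions (passband, dead channels,
rejected blocks with offending samples) in `res$reports`.

A disk-based run with the same content plus a hashed manifest:

```r
run_pipeline(list(n_subjects = 29, seed = 1, output_dir = "run1"))
```

or from a shell via `inst/cli/pipeline.R`.

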