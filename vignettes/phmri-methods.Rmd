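---
title: "Methods: pharmacological fMRI activation mapping with phmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacological fMRI activation mapping with phmri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phmri)
```

## The problem

Pharmacological MRI (phMRI) maps the brain's response to a drug challenge
rather than to a task. In the awake-rodent design this package implements, a
subject is scanned continuously — 50 baseline volumes over 5 minutes at a
repetition time (TR) of 6 s, then drug delivery, then 450 more volumes over
45 minutes — and the question for every voxel is whether its blood oxygen
level dependent (BOLD) signal in a post-treatment window differs from its own
baseline. Voxel decisions are then aggregated to anatomical regions via a
segmented label atlas ("volume of activation", VOA), compared across
treatment groups, and summarised over named circuits (networks of regions)
as time courses.

The package provides that full chain, plus a synthetic 4D BOLD generator
with known ground truth, because the statistical pipeline — not any single
formula — is the thing that needs validating.

## The analysis model, stage by stage

### Global linear drift

Slow scanner drift over a 50-minute session mimics an off/on activation
paradigm and inflates false positives. Drift is modelled as *linear in
time* on the whole-brain mean series (the average over all voxels with a
nonzero atlas label at each acquisition). The ordinary least-squares slope is
expressed as a percentage of the fitted intercept per minute, and a session
is corrected only when |slope| exceeds a predefined limit, 0.015 % signal
per minute. Correction is *global*, not voxel-wise — a voxel-wise fit would
absorb genuine drug responses into the "drift" term and overcorrect.

Two conventions had to be pinned down because they are not forced by the
problem statement:

* **Time axis.** Acquisition *k* (1-based) sits at *(k−1)·TR/60* minutes.
  Any affine choice gives the same slope; the intercept convention matters
  only for expressing the slope in percent.
* **Removal is multiplicative.** The corrected series is
  *v′(x,t) = v(x,t) / (1 + slope·t/100)*. Division leaves the percent-change
  of a response that rides multiplicatively on the trend exactly intact,
  which is the unit every downstream statistic uses. (The synthetic
  generator superposes drift and response *additively* in percent units, so
  after division a superposed response is attenuated by the factor
  1/(1 + drift) ≤ ~0.25 % relative at the default drift over a session —
  far below the 2 % decision threshold; the distinction is documented here
  precisely because tests exercise both constructions.)

Correction order: drift correction precedes smoothing. The drift estimate is
defined on the raw global mean, and smoothing is a purely spatial operation
that cannot change a global temporal trend, so the order only matters for
bit-reproducibility; it is fixed and documented.

### Spatial smoothing

Gaussian smoothing with a full width at half maximum (FWHM) of 0.8 mm,
applied volume-wise to every acquisition as a separable 3D convolution with
σ = FWHM/(2√(2 ln 2)) converted to voxel units per axis. Boundaries are
symmetric (reflective): kernels are normalised and constants are preserved
exactly, so no rim darkening appears at the array edge. The convolution is
implemented in compiled code; a direct-summation R oracle pins its output in
the tests to 1e-10.

### Voxel statistics

For every brain voxel and each analysis window, three quantities:

1. **Percent BOLD change**: `100 · (mean(window) − mean(baseline)) /
   mean(baseline)`. Voxels with zero baseline mean are untestable and are
   excluded from the map and from the FDR family (they would otherwise
   inflate the family size with hypotheses that cannot be evaluated).
2. **Welch t-test** (two-tailed, unequal variances, Welch–Satterthwaite
   degrees of freedom) of the 50 baseline acquisitions against the 100
   window acquisitions. The statistic and df are computed vectorised across
   voxels, as row-wise test implementations in this field do; p-values come
   from the t distribution.
3. **Benjamini–Hochberg FDR** at q = 0.05, applied within subject across
   brain voxels, **separately per window**. The source procedure is cited
   only as "false-positive detection control", so the standard
   independence-based step-up is used; whether the family should instead
   pool the three windows is unstated upstream, and per-window was chosen
   because the windows are reported as separate analyses.

A voxel is **activated** when both gates pass: adjusted p ≤ q *and*
|percent change| ≥ 2 %. The 2 % amplitude floor reflects normal BOLD
fluctuation in the awake rodent; it is deliberately a separate rule from the
test — a noiseless 1.5 % response has p ≈ 0 everywhere yet activates
nothing. The activation sign is the sign of the percent change; reported
VOA tables count positive-BOLD voxels, but negative maps are retained.

### Windows

Baseline is acquisitions 1–50 (closed range). The three analysis windows are
*half-open*: [150, 250), [250, 350), [350, 450) — minutes 15–25, 25–35,
35–45. The conventional endpoint sharing ("150–250" and "250–350") would
otherwise double-count acquisition 250; half-open ranges keep the windows
pairwise disjoint at exactly 100 acquisitions (10 minutes) each, which the
independent per-window tests require.

### Region and group level

Per subject, the **volume of activation** of a region is its count of
activated voxels of the requested sign. Group comparisons per region and
window use the **Kruskal–Wallis** rank test (midranks, tie correction,
chi-square reference with groups−1 df) on the per-subject counts — counts
are heavily tied at zero, so the all-identical case is defined as H = 0,
p = 1. Treatment-versus-vehicle tables are pairwise two-group tests,
mirroring how such tables are printed; a four-group omnibus is also
available. Significance is p ≤ 0.05, and **no multiplicity correction is
applied across regions** by default — published VOA tables apply none and
flag the false-positive caveat instead; a flag enables BH across regions.

The printed per-group count in a comparison row is taken from the group
**composite map**: the voxel-wise mean of per-subject percent-change maps,
keeping voxels activated in at least half the subjects (`min_frequency =
0.5`). The p-value, by contrast, always comes from the per-subject counts —
a composite image cannot carry a between-subject test. Whether published
per-group counts are composite counts, medians, or means is not derivable
from the table layout; the composite reading is the default here and is
swappable (`rep_counts` argument; medians are used when no composites are
built).

### Circuit time courses

A network (circuit) is a named set of region ids; circuits may overlap,
since anatomical systems genuinely share members. The circuit time course of
a subject is, at each post-treatment acquisition, the mean over the
circuit's voxels of the voxel-wise percent change from that voxel's own
baseline — 450 values under the default scheme. Window means feed a
**mixed-design repeated-measures ANOVA** (group between subjects, window
within subjects; classical F for the group × window interaction, no
sphericity correction by default at three levels) and **Dunnett's
many-to-one test** of each treatment against vehicle per window, with
multivariate-t adjusted two-sided p-values. With a single treatment the
Dunnett p collapses to the pooled two-sample t-test p, which the tests
assert. The Dunnett integration is quasi-random; it runs under a fixed
internal seed (and restores the caller's RNG state) so that pipeline outputs
are byte-reproducible. Published error dfs for this design (e.g. 147) imply
more within-subject levels than the three windows described; dfs here are
computed from the implemented design and in vivo F values are not
reproduction targets.

### Registration

Registration *estimation* is interactive in practice and out of scope: the
package applies a user-supplied 9-parameter affine (translation mm, rotation
degrees in fixed x→y→z order about the volume centre, positive scales) and
propagates atlas labels one-to-one onto the session grid. Functional data
are resampled nearest-neighbour by default (intensity-preserving, hence
bit-stable tests; trilinear by flag). Synthetic data are generated directly
in atlas space, so identity is the tested default path.

## The synthetic cohort generator

Per brain voxel in region *r*:

    v(t) = baseline_level · (1 + drift(t)/100 + response_r(t)/100 + ε(t)/100)

with `drift(t) = drift_slope · minutes(t)`, a piecewise-linear
**ramp-to-plateau** response kernel (zero before onset, linear over
`ramp_duration` acquisitions, then constant at `plateau_amplitude` %), and
iid Gaussian noise ε with SD `noise_sd` %. Background voxels are exactly
zero. A haemodynamic basis function would add realism the analysis never
sees — all statistics are window means, which the ramp parameterises
transparently.

Defaults, chosen once as the study conditions the generator emulates:

| parameter | default | why |
|---|---|---|
| grid | 24 × 24 × 12 | desk-scale; `full_scale = TRUE` gives 96 × 96 × 22 |
| voxel size | 0.3125 × 0.3125 × 1.0 mm | 3 cm field of view over a 96 matrix; 1 mm slices |
| acquisitions | 500 at TR 6 s | 50-minute session, 50 baseline volumes |
| baseline_level | 1000 a.u. | arbitrary; all statistics are in percent |
| noise_sd | 1 % | plausible awake-rodent voxel noise at spin-echo contrast |
| drift_slope | 0.02 %/min | realistic scanner drift; above the 0.015 limit so the correction branch runs |
| response onset / ramp | acq 51, 60 acq | drug given after baseline; plateau (~11 min) reached before the first window |

Group sizes default to the emulated design: vehicle 9, idalopirdine 10,
donepezil 8, combination 9. Per-subject seeds are drawn once from the master
seed, so cohorts are bit-reproducible and any subject can be regenerated in
isolation.

The generated atlas packs regions as axis-aligned blocks with a 2-voxel
in-plane and 1-voxel through-plane background margin per cell. The margin is
a deliberate design choice: at 0.8 mm FWHM the in-plane σ is ≈ 1.1 voxels,
so a ≥ 4-voxel gap (≈ 3.7 σ) keeps one region's response from bleeding into
a neighbouring *null* region through the smoothing kernel, which would
otherwise confound specificity checks. Real atlas regions share boundaries;
this generator trades that realism for separable ground truth.

**What the simulator does not model:** motion, susceptibility distortion,
physiological (cardiac/respiratory) noise, temporal autocorrelation, and
partial-volume effects at region boundaries. Passing tests therefore show
that the *statistical chain* behaves as specified under its own
assumptions — Gaussian, temporally white noise — not that those assumptions
hold in vivo. Temporal autocorrelation in particular would make the
per-voxel Welch test anticonservative; prewhitened GLM modelling is an
explicit non-goal.

One interaction worth knowing: the global drift estimate includes the
response, because a responsive region raises the whole-brain mean after
onset. With one responsive region of ~1/6 of the brain at +4 %, the fitted
slope overshoots and correction tilts the response slightly (window means
shift by a few tenths of a percent). This mirrors how a global-mean method
behaves on real data and leaves the 2 %/4 % decision structure untouched.

## Numerical choices and degenerate inputs

* Welch test with both variances zero: equal means → t = 0, p = 1;
  different means → p = 0, flagged degenerate.
* Kruskal–Wallis with all observations identical → H = 0, p = 1. The
  chi-square reference is an approximation: at 3–4 subjects per group it
  sits within ~0.01 of the exact permutation p in the rejection tail but can
  differ by up to ~0.05 mid-range.
* Mixed ANOVA on exactly constant data → F = 0, p = 1 (the 0/0 ratio is
  defined away).
* Smoothing kernels truncate at ⌈3σ⌉ and renormalise; FWHM 0 is the
  identity.
* Drift correction when the fitted trend would cross zero raises an error
  rather than flipping signs.
* Ties in ranks use midranks with the standard correction (counts tie at 0
  constantly).

## Problem sizes used by the tests

The suite validates at deliberately reduced sizes, stated here as the
package's own choices: oracle equivalence on handfuls of observations; FDR
calibration on 200 simulated null subjects × 500 brain voxels; type-I
calibration of the mixed ANOVA and Dunnett tests on 1000 null simulations
each (4 groups × 9 subjects × 3 windows); ground-truth recovery on 20
cohorts of 9 + 9 subjects on the 24 × 24 × 12 grid with one +4 % region at
1 % noise, where the responsive region must be flagged (Kruskal–Wallis vs
vehicle, p ≤ 0.05) in ≥ 90 % of cohorts and each null region in ≤ 10 %.

## Worked example

```{r example}
set.seed(1)
at <- generate_atlas(c(24, 24, 12), n_regions = 6, seed = 99)
at
spec <- response_spec("drug", region_id = 3, onset_acquisition = 51,
                      ramp_duration = 60, plateau_amplitude = 4)
cfg <- session_config()          # 500 acq, TR 6 s, 1% noise, 0.02%/min drift
ses <- generate_session(at, spec, cfg, "drug", "demo", seed = 11)
res <- analyze_session(ses, at, pipeline_config())
res$drift
subset(res$voa, window == "25-35")
```

The drift slope exceeds the 0.015 %/min limit (the generator injects
0.02 %/min plus the response's contribution to the global mean), so the
session is corrected; all 320 voxels of region 3 are activated in every
window with a mean change near +4 %, and every other region stays at zero.

## Known limitations

* The FDR guarantee is per subject and window; no cluster-extent or
  spatially-aware inference is provided.
* Registration quality is the caller's responsibility; only transform
  *application* is implemented.
* The repeated-measures ANOVA requires complete windows per subject;
  unbalanced group sizes are fine, missing cells are not.
* No correction across the region family by default — by design, with the
  false-positive caveat inherited from the tables this mirrors.
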