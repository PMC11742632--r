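---
title: "Quantifying blood-brain barrier dysfunction from DCE-MRI: methods and design"
author: "bbbdmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying blood-brain barrier dysfunction from DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A subtly leaky blood-brain barrier (BBB) lets gadolinium-based contrast
agent accumulate slowly in brain tissue over the tens of minutes following
an intravenous injection. Dynamic contrast-enhanced MRI (DCE-MRI) samples a
T1-weighted volume every few seconds throughout that period; in tissue with
slow, trans-cellular leakage the late-phase contrast concentration grows
approximately linearly, and the linear rate per voxel is a direct measure of
local BBB permeability. `bbbdmap` implements this linear-slope quantification
chain end to end — from the raw spoiled-gradient-echo (SPGR) signal to
per-subject whole-brain and per-region BBB-dysfunction (BBBD) measures and
cohort-level statistics — together with a deterministic synthetic-cohort
generator used to validate every stage by parameter recovery.

## Signal model

The steady-state SPGR signal at flip angle $\alpha$ and repetition time
$TR$ is

$$ S = M_0 \sin\alpha \frac{1 - E_1}{1 - \cos\alpha \, E_1},
   \qquad E_1 = e^{-TR/T_1}. $$

$M_0$ absorbs proton density, coil gain and the static $T_2^*$ decay at the
echo time; contrast-induced $T_2^*$ changes are neglected, which is
appropriate in the low-concentration late-leakage regime this pipeline
targets.

**T1 mapping (variable flip angle / DESPOT1).** Pre-contrast volumes are
acquired at several flip angles and the SPGR equation is linearized as
$S/\sin\alpha = E_1\, S/\tan\alpha + M_0 (1-E_1)$; an ordinary
least-squares fit per voxel yields $E_1$ (hence $T_1$) and $M_0$
(`fitT1Vfa()`, `vfaT1Maps()`). Fits with slope outside $(0,1)$, a
degenerate design, or $T_1 > 10$ s are marked failed and propagate as
invalid voxels. The linearized estimator is validated against a nonlinear
least-squares fit of the forward model: exact agreement on noiseless data
and sub-0.1% agreement in expectation at SNR 100 (per realization the two
estimators differ by their noise weighting, an $O(\sigma^2)$ effect).

**Gain calibration.** The dynamic series is acquired with its own flip
angle and TR, so a per-voxel gain bridges the VFA-derived $M_0$ scale to
the dynamic signal scale: gain = mean pre-injection signal / predicted
baseline SPGR signal (`calibrateGain()`). Baseline frames are all frames
strictly before the injection time (minimum one).

**Concentration.** Per frame, the SPGR equation is inverted exactly:

$$ E_1(t) = \frac{g M_0 \sin\alpha - S(t)}{g M_0 \sin\alpha - S(t)\cos\alpha},
   \quad R_1(t) = -\frac{\ln E_1(t)}{TR}, \quad
   C(t) = \frac{R_1(t) - 1/T_1}{r_1}, $$

with $r_1$ the agent's longitudinal relaxivity in 1/(mM s)
(`signalToConcentration()`). Voxels where $E_1(t)$ leaves $(0,1)$ at any
frame are invalidated rather than clipped. Full inversion is the default
because the leakage slope is defined on concentration; the first-order
approximation $C \propto (S - S_0)/S_0$ is available as
`concMode = "linear_delta_s"` for sensitivity analysis (its slopes are in
arbitrary units but remain cross-subject comparable after sinus
normalization).

## Permeability maps

The leakage slope is the OLS slope of $C$ against time **in minutes** over
all frames from 6 minutes after injection to the end of the acquisition
(`fitLinearSlope()`; the window start is the `windowStartMin` parameter).
At least three frames are required; frames before the window never
influence the fit. Negative slopes (washout) are retained — only non-finite
fits are invalidated.

To cancel subject-level differences in contrast delivery and clearance,
each voxel's slope is divided by the slope measured in the superior
sagittal sinus — an intravascular reference (`sinusReference()`,
`normalizeSlopes()`). The sinus summary is the **median** over the ROI
(robust to partial-volume voxels; configurable to the mean). Normalization
is applied voxelwise; since regional summaries are ratios of counts this is
equivalent to region-level division for thresholding purposes. A
non-positive sinus slope signals an unusable scan and is an error, not a
silent pass-through. The resulting normalized slope map is dimensionless
and scale-invariant: multiplying all concentrations by any constant leaves
it unchanged (asserted exactly in the tests).

## Classification against healthy controls

* **Threshold.** The supra-threshold cutoff is the 95th percentile of the
  pooled multiset of all valid in-mask voxel values across all control
  subjects (`pooledPercentile()`), computed with linear interpolation
  between order statistics (type-7 quantile). Pooling across subjects (as
  opposed to averaging per-subject percentiles) follows from the reference
  cohort definition; the method is recorded in the `ControlReference`.
* **Whole-brain load.** A subject's BBBD load is the percentage of valid
  brain voxels strictly above the threshold (`brainBBBDPercent()`). By
  construction the pooled control fraction above threshold is 5%, so a
  homogeneous control cohort averages a load of ~5%.
* **Regional scores.** For each of the 124 atlas regions, the percentage
  of supra-threshold voxels is computed (`regionalPercent()`; regions with
  no valid voxels yield `NA`, never 0), then converted to a modified
  z-score against the control cohort:
  $z_r = 0.6745\,(x_r - \mathrm{median}_r)/\mathrm{MAD}_r$, with the MAD
  the unscaled median absolute deviation of the control values
  (`modifiedZ()`). Regions with $z_r > 2$ are flagged; flagging is
  one-sided because only elevated permeability is pathological here.
* **Degenerate spreads.** If a region's control MAD is zero the mean
  absolute deviation from the median is used instead; if that is also zero
  the reference is marked unstable and $z = +\infty$ when the value exceeds
  the control median, else 0 — degenerate, but never a crash and never a
  silent pass.
* **Alternative deviation.** `deviation = "mean_ad"` replaces
  median/MAD by mean/mean-absolute-deviation (no 0.6745 factor) for
  sensitivity analysis; the median/MAD form is the default and the one
  used throughout validation.

The reference (`buildControlReference()`) can be frozen to JSON and
restored bit-exactly (numbers are serialized with 17 significant digits),
so patient cohorts can be scored later against an identical reference
(`scoreSubject()`, `writeControlReference()`).

When controls themselves are scored, the default reference includes all
controls; `runCohort(looControls = TRUE)` instead scores each control's
regional z against the other $n-1$ controls (the pooled threshold is kept
fixed) — both conventions are defensible and the choice is recorded by the
caller.

## Group statistics

`compareGroups()` wraps Mann-Whitney (exact when $n_A n_B \le 400$ and no
ties, otherwise normal approximation with tie correction — the variant is
recorded in the result), Kruskal-Wallis and paired Wilcoxon, with Cohen's
d computed on pooled SD ($n_A + n_B - 2$ denominator; paired: mean
difference over its SD). `bhFdr()` applies the Benjamini-Hochberg step-up
rule across regions and reports cumulative-minimum adjusted p-values.
`hemisphericAsymmetry()` pairs homologous left/right regions by base name
and runs a paired comparison. `severityPca()` standardizes the clinical
features (seizure frequency, number of medications, years with epilepsy)
to zero mean and unit variance — a correlation-matrix PCA, chosen because
the features carry incommensurate units — and correlates PC scores with a
BBBD measure (Spearman by default, Pearson available).
`medianSplit()` groups subjects into high/low BBBD strictly above vs
at-or-below the median (ties to "low": deterministic, and with distinct
values and even $n$ it yields balanced halves) and tests binary covariates
with two-sided Fisher exact tests. All of these delegate the standard
machinery to base R's battle-tested implementations; the test suite pins
each one against an independent brute-force oracle (full rank enumeration,
explicit step-up rule, hypergeometric sums).

## The synthetic cohort generator

`cohortSpec()` fixes the study conditions; `makeAtlas()`, `makeSubject()`
and `makeCohort()` realize them. Defaults:

| parameter | default | meaning |
|---|---|---|
| `gridShape` | 32 x 32 x 8 | voxel lattice (2 x 2 x 6 mm spacing) |
| `nRegions` | 124 | parcellation size, 62 per hemisphere |
| `nControls`, `nPatients` | 58, 50 | cohort sizes |
| `protocol` | `"SUMC"` preset | TR 4 ms, TE 2 ms, FA 60 deg, VFA 5/15/20/25 deg at TR 10 ms, frame interval 18 s, 67 frames (20 min), Dotarem r1 = 3.89 |
| `controlSlopeMean`, `controlSlopeSd` | 0.05, 0.02 | true normalized slope of healthy tissue (dimensionless) |
| `effectNRegions`, `effectSize` | 20, +4 MAD | patient lesion model (below) |
| `sinusTrueSlope` | 0.4 mM/min | intravascular reference slope |
| `tissueT1Ms`, `bloodT1Ms` | 1300, 1700 ms | pre-contrast T1 at 3 T |
| `tissueM0` | 1000 a.u. | equilibrium signal |
| `bolusAmpTissue`, `bolusAmpSinus` | 0.05, 1 mM | first-pass bolus amplitudes |
| `noiseSd` | 0.05 a.u. | additive Gaussian signal noise, ~1% of the baseline tissue signal (SNR ~ 100) |

The phantom is an ellipsoidal brain split at the midline, each hemisphere
partitioned into 62 near-equal contiguous blocks with homologous
`roi_k_L`/`roi_k_R` names; the sinus ROI is a posterior midline strip
outside the brain. Per voxel, concentration is
$C(t) = A\,f(t) + k\,\max(0, t - t_\mathrm{inj})$ with $f$ a fixed
gamma-variate bolus template (unit peak 30 s post injection, shape 3).
The template is numerically zero (< 1e-11) by 6 minutes post injection,
so the late window contains a pure line and noiseless recovery is exact to
machine precision — the early phase must exist, but only the late linear
term carries ground truth. The signal is synthesized through the same SPGR
forward model the pipeline inverts, plus additive Gaussian noise (the
high-SNR regime; Rician corrections would matter only near the noise
floor). Everything is bit-deterministic under the master seed, with
per-subject seeds derived arithmetically from it.

**Patient effect.** Each patient receives `effectNRegions` randomly chosen
affected regions whose true normalized slopes are raised additively by
`effectSize` MADs of the control voxel-slope distribution
(MAD of $N(\mu,\sigma)$ = $0.6745\sigma$, so the default +4 MAD is a shift
of $2.70\sigma \approx 0.054$). This generator-side definition is analytic
and does not require calibrating against the pipeline's own output; a
multiplicative mode (`effectMode = "multiplier"`) is also available.

**What the generator does *not* emulate:** anatomy, spatial correlation of
physiological noise, between-subject biological variability of the healthy
slope distribution, motion or registration error, B1 inhomogeneity, and
arterial-input-function variability. Passing recovery tests therefore
demonstrates the correctness of the estimation chain under the stated
model, not robustness to those real-world effects.

## Numerical choices and problem sizes

* Percentile: type-7 linear interpolation; thresholding is strictly
  "greater than".
* Slope fit: closed-form OLS on centered times; time unit minutes.
* VFA fits, gain and inversion are fully vectorized over voxels; a
  32 x 32 x 8 x 67 subject runs in ~0.2 s, so the validation suite
  simulates full 58-subject control cohorts and repeated 20-vs-20
  detection cohorts directly (sizes chosen to mirror a realistic
  multi-center cohort at desk scale).
* Type-I-error calibration of the cohort comparison is evaluated at the
  per-subject summary level (two groups of 20 BBBD loads drawn from one
  skewed distribution, 200 replicates), which exercises exactly the
  statistic under test.

## Known limitations

* With a small control cohort (n = 20) and ~22-voxel regions, the regional
  supra-threshold percentage is a coarse discrete count (on average ~1
  voxel above threshold per region), and the modified z-score computed
  against a median/MAD estimated from so few controls has a slightly heavy
  right tail: the empirical false-flag rate at the z > 2 cutoff runs
  somewhat above the nominal ~5% (for continuous Gaussian regional values
  it would be ~4.6% at n = 20 and ~3.1% at n = 58 controls). This is a
  property of the modified-z procedure at coarse desk scale, not of the
  implementation; larger control cohorts, larger regions, or a calibrated
  cutoff restore the nominal rate.
* The linear ΔS/S0 mode is first-order and compresses high concentrations
  (relevant in the sinus); it is provided for sensitivity analysis, not as
  the default.
* No B1 correction is applied; flip-angle miscalibration biases T1 and
  hence absolute concentration, though sinus normalization removes the
  subject-level component of such scale errors.
* Registration/normalization to a standard space is assumed done upstream;
  all volumes of a study must already share grid and affine.
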