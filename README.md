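# bbbdmap

Quantification of slow blood-brain barrier dysfunction (BBBD) from dynamic
contrast-enhanced MRI (DCE-MRI), for neuroimaging researchers studying
subtle barrier leakage in epilepsy and other neurological conditions.

A compromised blood-brain barrier lets gadolinium contrast agent accumulate
slowly in brain tissue. `bbbdmap` turns a raw DCE acquisition into
per-subject and cohort-level BBBD measures:

1. **T1 mapping** — variable-flip-angle (DESPOT1) fit of the spoiled
   gradient-echo signal `S = M0 sin(a) (1 - E1) / (1 - cos(a) E1)`,
   `E1 = exp(-TR/T1)`, linearized per voxel.
2. **Concentration** — exact SPGR inversion per frame,
   `C(t) = (R1(t) - 1/T1) / r1`, using the agent's relaxivity `r1` from the
   site's acquisition protocol (four site presets ship with the package).
3. **Leakage slope** — ordinary least-squares slope of `C` against time
   (minutes) from 6 min after injection to the last frame, per voxel.
4. **Sinus normalization** — division by the median slope in a superior
   sagittal sinus ROI, cancelling subject-level contrast-delivery
   differences.
5. **Classification** — BBBD is defined as a normalized slope above the
   95th percentile of all pooled healthy-control voxels; subjects are
   summarized by % brain volume above threshold and by per-region modified
   z-scores `z = 0.6745 (x - median) / MAD` against the control cohort,
   flagging regions with `z > 2`.
6. **Group statistics** — Mann-Whitney / Kruskal-Wallis / paired Wilcoxon
   with Cohen's d, Benjamini-Hochberg FDR across the 124 atlas regions,
   left-right asymmetry, PCA-based disease-severity scores, and
   median-split high/low-BBBD contingency tests.

A deterministic synthetic-cohort generator (`cohortSpec()`, `makeCohort()`)
produces complete study inputs — atlas, masks, VFA volumes, dynamic 4D
series — with known ground-truth slopes, so the whole chain is validated by
parameter recovery without any clinical data.

## Worked example

```r
library(bbbdmap)

spec   <- cohortSpec(nControls = 12L, nPatients = 4L, seed = 2024L)
cohort <- makeCohortList(spec)
run    <- runCohort(cohort$subjects, cohort$geometry, spec@protocol)

run$reference
#> ControlReference | threshold 0.083059 (percentile 0.95, pooled voxels, linear interpolation (type 7)) from 12 controls
#>   modified z: median_mad, scale 0.6745, flag cutoff 2; 124 regions (0 unstable)

run$results[["ctrl001"]]
#> SubjectResult 'ctrl001' | 4.31% brain volume with BBBD; 5/124 regions flagged

run$results[["pat001"]]
#> SubjectResult 'pat001' | 17.99% brain volume with BBBD; 30/124 regions flagged

run$report$wholeBrain
#> GroupComparison [mann_whitney] n = 4/12 | statistic 48, p = 0.004346, d = 31.2 (normal approximation, tie-corrected)
```

The threshold (~0.083) is the 95th percentile of the pooled control
normalized slopes, so a healthy subject sits near 5% supra-threshold volume
(ctrl001: 4.31%). The synthetic patients carry 20 seeded high-permeability
regions each and show both an elevated whole-brain load (pat001: 17.99%)
and flagged regions; the cohort comparison separates the groups
(p = 0.004).

On-disk studies use the same layout the generator writes
(`makeCohort(spec, dir)` then `runCohortDir(dir)`), and a thin command-line
front end is available at `inst/scripts/bbbd-cli.R` with subcommands
`simulate`, `reference`, `score` and `report`. Control references freeze to
JSON (`writeControlReference()`) and restore bit-exactly for later patient
scoring.

## Package layout

- `R/` — S4 classes (`AcquisitionProtocol`, `DynamicSeries`, `T1Maps`,
  `NormalizedSlopeMap`, `BrainAtlas`, `ControlReference`, `SubjectResult`,
  ...) and the module functions.
- `inst/extdata/` — four site protocol YAMLs and the default 124-region
  label table (synthetic parcellation).
- `vignettes/bbbd-quantification.Rmd` — the methods vignette: model,
  assumptions, parameter choices, generator realism, limitations.
- `tests/testthat/` — unit, property and cohort-scale validation suites
  with independent brute-force oracles.
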