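# myelinmapr

Reliability analysis for surface-based cortical myelin mapping with
quantitative and weighted MR relaxometry parameters.

Cortical myelin density differs sharply between primary sensory/motor
areas and the rest of the cortex, and several MR parameters see it: the
longitudinal relaxation rate R1 = 1/T1 (s⁻¹) and its weighted counterpart
T1w, the effective transverse relaxation time T2\* (s) and its weighted
counterpart T2\*w, and the contrast-enhancing ratios T1w/T2\*w and
R1/T2\*. Which of the six should you trust to parcellate a cortex? This
package implements the statistical framework for answering that on a
triangulated surface, for neuroimaging methodologists comparing
acquisition strategies:

* **mono-exponential T2\* fitting** from multi-echo gradient-echo
  signals (log-linear, with a signal-weighted variant), the echo-ratio
  T2\*w map, reciprocal and ratio maps, and the T2\* < 0.024 s artifact
  exclusion mask;
* **FWHM-normalized coefficients of variation** per vertex,
  COV = (σ/μ)/FWHM, across subjects (inter) and scan-rescan sessions
  (intra), where the FWHM of the rescaled (3rd→0, 97th→1 percentile)
  average cortical distribution accounts for how much dynamic range a
  parameter actually uses;
* **parcellability variation** PV = σ_scan-rescan / FWHM_raw (lower =
  more reliable parcellation);
* **contrast-to-noise ratio per unit scan time**
  CNR = |S_roi − S_ref| / σ_pooled / √minutes against a lightly
  myelinated neighbor region;
* **depth-resolved vertex-wise Pearson correlations** between parameter
  pairs at 11 cortical depths;
* **two areal-border methods**: AUC-threshold contours (thresholds from
  the cumulative histogram mass between the 3rd and 97th percentiles,
  with coverage profiles and Jaccard overlap) and tangent-plane surface
  gradients (exact for linear fields);
* a **seeded synthetic cortical phantom** — icosphere or planar meshes,
  a 13-region myeloarchitectonic atlas, ground-truth R1/T2\* with depth
  profiles, vein artifacts, and simulated multi-subject scan-rescan
  acquisitions — emulating a 10-subject / 3-rescan study design.

Surfaces and per-vertex maps read and write GIFTI (`.surf.gii`,
`.func.gii`), flat CSV vertex tables and YAML configurations.

## Worked example

```r
library(myelinmapr)

bundle <- run_experiment(experiment_config(seed = 1), verbose = FALSE)
parameter_medians(bundle, "cov_inter")
```

```
median normalized inter-subject COV:
      R1      T1w      T2s     T2sw T1w/T2sw   R1/T2s
  0.0878   0.2280   0.2826   0.1993   0.3613   0.4055

median normalized intra-subject COV:
      R1      T1w      T2s     T2sw T1w/T2sw   R1/T2s
  0.0115   0.0192   0.0778   0.0577   0.0664   0.1134

median parcellability variation:
      R1      T1w      T2s     T2sw T1w/T2sw   R1/T2s
  0.0483   0.0393   0.2288   0.3221   0.1130   0.2568

depth-averaged correlations:
               pair          r    n
          R1 vs T2s -0.8284128 2531
        T1w vs T2sw -0.8579115 2531
 R1/T2s vs T1w/T2sw  0.9860274 2531
```

Reading these numbers: quantitative R1 has the lowest normalized COV both
between subjects (0.088) and scan-rescan (0.012) — it is the most stable
myelin-sensitive parameter — while the two ratio images have the highest
inter-subject COV (0.36/0.41), because noise from both parents propagates
into them. The longitudinal parameters (R1, T1w) score lower PV than the
transversal ones (T2\*, T2\*w): they locate a vertex more reliably within
the cortical histogram. R1 and T2\* are negatively correlated (more
myelin → higher R1, lower T2\*), most strongly at deep cortical
fractions. 31 of 2562 vertices fall below the 0.024 s T2\* exclusion
threshold (simulated vein artifacts) and enter no statistic.

`write_report(bundle, "out/")` writes the tidy CSV tables (per-ROI
mean ± inter-vertex SE for each metric), contour edge lists, the Jaccard
matrix, and GIFTI overlays. A thin command-line wrapper with
`simulate` / `metrics` / `parcellate` / `report` / `all` verbs lives at
`inst/scripts/run_pipeline.R`, taking `--config`, `--seed` and `--out`.

The methods vignette (`vignettes/reliability-methods.Rmd`) documents the
model, the phantom's variance decomposition, numerical choices and
limitations.

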