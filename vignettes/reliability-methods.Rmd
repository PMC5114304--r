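---
title: "Comparing quantitative and weighted relaxometry parameters for cortical myelin mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing quantitative and weighted relaxometry parameters for cortical myelin mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myelinmapr)
```

## The problem

Cortical myelin density varies systematically across the cortical sheet:
primary sensory and motor areas (somatosensory strip, V1/V2, the auditory
core, MT) are heavily myelinated, premotor and inferior frontal areas
moderately, and regions such as the retrosplenial cortex only lightly.
Several MR parameters are sensitive to this variation — the longitudinal
relaxation rate R1 = 1/T1 (s^-1) and its weighted counterpart T1w, the
effective transverse relaxation time T2\* (s) and its weighted counterpart
T2\*w = S(TE_last)/S(TE_first), and the two contrast-enhancing ratios
T1w/T2\*w and R1/T2\*. Any of them can in principle drive a surface-based
parcellation of the cortex, but they differ in how reliably they do so:
weighted intensities are in arbitrary units and inherit hardware and
sequence effects, T2\* estimation amplifies echo noise, and ratios inherit
noise from both parents.

This package implements the statistical machinery for that comparison on a
triangulated cortical surface, together with a seeded synthetic phantom
that emulates a 10-subject cohort in which 3 subjects are scanned twice.

## Reliability metrics

All metrics operate per vertex $v$ on depth-averaged surface maps of a
parameter $p$.

**Normalized coefficient of variation.** Across units (subjects for the
inter-subject variant, a subject's sessions for the intra-subject variant),

$$\mathrm{COV}_{pv} = \frac{\sigma_{pv}}{\mu_{pv}}\cdot
\frac{1}{\mathrm{FWHM}_p},$$

where the normalizing constant is the full width at half maximum of the
*rescaled* value distribution of the across-unit average map. Rescaling
maps the 3rd percentile to 0 and the 97th to 1; it makes the FWHM a
dimensionless measure of how much of its useful dynamic range a parameter
actually spreads the cortex over. Without this step a parameter that
compresses all cortical values into a narrow band would look spuriously
reproducible. The intra-subject variant computes each rescanned subject's
scan-rescan COV first and then averages the per-vertex COV across those
subjects.

**Parcellability variation.** How reliably a vertex can be located within
the cortical histogram:

$$\mathrm{PV}_{pv} = \frac{\bar\sigma_{pv}}{\mathrm{FWHM}_p^{\mathrm{raw}}},$$

with $\bar\sigma_{pv}$ the scan-rescan standard deviation averaged across
rescanned subjects and the FWHM now taken *before* rescaling, in the
parameter's own units. Lower PV means higher parcellability. PV is
invariant under positive affine transforms of the parameter, since the
scan-rescan sd and the raw FWHM scale together.

**Contrast-to-noise ratio per unit time.** For a region $y$ and its
designated lightly myelinated neighbor region $s$,

$$\mathrm{CNR}_{pyv} = \frac{|S_{pyv} - S_{psv}|}{\sigma_{s+y}}
\cdot\frac{1}{\sqrt{t}},$$

where the reference $S_{psv}$ is a seeded random draw from the neighbor
region (a deterministic `region_median` mode is provided for pipelines
that must not consume randomness), $\sigma_{s+y}$ is the pooled
inter-vertex sd of both regions (the noise estimate) and $t$ the scan
duration in minutes attributed to the parameter. Single-source parameters
are charged their own sequence's duration (8:02 min for the longitudinal
pair, 8:33 min for the transversal pair); ratios are charged the sum,
since producing them costs both acquisitions.

**Sampling conventions.** Sample (n−1) standard deviations are used
throughout: with 2–3 units per vertex, the unbiased estimator matters.
The FWHM is estimated from the value distribution of the across-unit
average map (not as an average of per-unit FWHMs; the phrase "average
cortical distribution" admits both readings and this one is fixed here
and documented). Rescaled values are *not* clamped to [0, 1]; clamping
would pile mass onto the endpoints and distort the half-maximum
crossings.

## From echoes to maps

T2\* is fitted per vertex from 4-echo gradient-echo magnitudes by
ordinary least squares on the log-signal (slope $=-1/T_2^*$, intercept
$=\log S_0$), which is exact in the noiseless limit; a signal-weighted
variant (`weighted = TRUE`) applies first-order variance stabilization
for lower-SNR use. Vertices with any non-positive echo are marked
unfittable and carried as `NA` through every downstream operation; a
non-negative slope (no measurable decay) yields the `+Inf` marker rather
than a negative time. Vertices whose across-subject average T2\* falls
below 0.024 s are excluded from all statistics — at 7 T such values flag
static-field artifacts (air–tissue interfaces, large veins) rather than
tissue.

Maps are sampled at 11 relative cortical depths (0 = white-matter
boundary to 1 = pial surface in steps of 0.1) and averaged over the
inclusive 20–80 % window (7 samples), which avoids partial-volume
contamination at the ribbon's extremes; both endpoints are included by
choice, and depth samples are equally weighted (thickness weighting would
require per-vertex thickness, which the surface representation does not
carry here). Curvature residualization — OLS of the map on mesh
curvature, returning mean-preserving residuals — is applied to T1w and R1
only, the parameters with a documented gyral/sulcal bias; which
parameters are residualized is a configuration choice.

## Areal borders

Two border methods are implemented. The *threshold* method computes the
AUC threshold: the value at which the cumulative histogram mass between
the 3rd and 97th percentiles reaches a target percentage — operationally
the percentage-quantile of the distribution truncated to that range, with
the percentile anchors included as endpoints so 0 % maps to p3 and 100 %
to p97 exactly. Coverage profiles (fraction of an ROI at or above the
threshold, comparison by ≥) over 60–90 % quantify threshold dependence;
contours are the mesh edges straddling the thresholded mask, which on a
closed mesh close into loops (each straddling edge lies in exactly two
mixed-label triangles). Before thresholding, all parameters are oriented
to increase with myelination (T2\*(w) is mapped to R2\*(w) by
reciprocal); overlap between parameter parcellations is summarized by the
Jaccard coefficient, with the empty/empty case defined as 1. The
*gradient* method projects each vertex's one-ring onto its tangent plane
(normal from area-weighted triangle normals; angle-weighted available
behind a flag) and fits a least-squares plane; the fitted slope magnitude
is exact for linear fields on planar meshes. Thresholding the gradient
map yields border candidates deliberately without ridge-linking or gap
filling: the borders this method produces are discontinuous, and
completing them is an observer decision, not something the package should
silently fake.

## The synthetic phantom

The phantom generates, per subject, ground-truth R1 and T2\* on an
ROI-structured mesh (13 named regions in three myelination classes plus
lightly myelinated background), then simulates sessions by pushing the
truth through the same forward models the analysis inverts: 4-echo decay
plus Gaussian noise for the transversal family, additive noise in the R1
domain, and a strictly monotone sigmoidal intensity transform for T1w
that spreads the central part of the R1 range over a broader relative
intensity range while compressing the tails — the mechanism by which a
weighted reconstruction trades absolute interpretability for local
contrast.

The variance decomposition is the scientifically load-bearing part:

* the fine-grained myelin topography (smooth multiplicative field,
  2 mm smoothness) is *shared* across subjects, as real myeloarchitecture
  largely is; subjects add region-level log-normal factors (sd 2.5 %), a
  smaller private field (sd 1.5 %), and family-specific global factors —
  small for calibration-stable quantitative R1 (sd 1 %), sizeable for
  T2\* (sd 9 %, emulating B0 shim and head-orientation sensitivity) — and
  an intensity gain on the weighted T1w reconstruction (sd 7 %,
  emulating the arbitrary-units instability of weighted images);
* session noise: echo noise sd 2.5 a.u. against S0 ≈ 100 (per-echo SNR
  ≈ 40, which makes the log-linear fit's noise amplification visible in
  T2\*, as it is in vivo) and R1 noise sd 0.008 s^-1 (≈ 1.5 %);
* depth profiles are linear in depth fraction (R1 falls by 15 % from the
  white-matter boundary to the pial surface, T2\* rises by 12 %), and the
  T2\* field mixes a myelin-shared anticorrelated component dominating at
  depth with an independent component growing toward the pial surface, so
  the R1–T2\* anticorrelation is strongest deep and weakens pially;
* about 1 % of vertices, at population-fixed locations, are vein
  artifacts with T2\* in 0.012–0.022 s — below the exclusion threshold,
  so the exclusion mechanism has real work to do.

Class centers (R1 0.62/0.57/0.52 s^-1, T2\* 0.029/0.032/0.035 s for
heavy/moderate/light) and the field amplitude (4 %) were chosen once so
that the depth-averaged cortical R1 distribution has an FWHM of the order
of 0.05 s^-1 and relative class separations are comparable between
families, and so that the rescaled FWHM of T1w exceeds R1's (the
weighted transform's range-broadening) — magnitudes on the scale reported
for in-vivo 7 T cortical distributions.

What the phantom deliberately does **not** contain: volumetric imaging
and reconstruction, B1+ transmit fields and their correction, Rician
noise (Gaussian is an adequate approximation at the simulated SNR and
keeps the noiseless round trip exact), B0-orientation dependence of T2\*,
inter-subject surface registration (all subjects share one mesh by
construction), and hemispheric asymmetries. Passing tests on the phantom
therefore validate the *statistical machinery and its orderings*, not
the acquisition physics of any particular scanner.

## Numerical choices

* **FWHM estimation**: Gaussian KDE with Silverman's bandwidth (default)
  or a Freedman–Diaconis histogram; the width is taken between the
  outermost half-maximum crossings of the density, by linear
  interpolation. A density that never falls below half maximum on one
  side raises an estimation error with a diagnostic rather than
  returning a guess.
* **Geodesic smoothing** is iterated conservative edge diffusion with
  symmetric area-weighted edge weights: the global area-weighted mean is
  conserved exactly, every update is a convex combination (discrete
  maximum principle), and the iteration count is derived from the target
  kernel variance and the measured per-step variance of the diffusion
  stencil. On a 0.25 mm planar grid the realized kernel width is within a
  few percent of the requested 1 mm. Exact geodesic-distance kernels
  (heat method, Dijkstra) were not needed at these kernel sizes.
* **Percentiles/quantiles** use R's default linear interpolation
  (type 7) everywhere, so p3/p97 anchors, rescaling and AUC thresholds
  are mutually consistent.
* **Unfittable values** travel as `NA`, R's native explicit missing
  marker, and every statistic excludes them from its `n`; no sentinel
  numbers are ever mixed into valid ranges. `+Inf` marks the zero-decay
  fit limit specifically.
* **Seeding**: every generator is a pure function of (inputs, seed); a
  master seed derives subject, session and CNR-reference streams, and
  generators restore the caller's RNG state.

## Problem sizes and runtime

The default experiment runs on an icosphere at subdivision resolution 4
(2562 vertices, mean edge ≈ 0.75 mm at radius 10 mm) with 10 subjects
and 3 rescans; it completes in a few seconds on one CPU. The test suite
uses resolution 3 (642 vertices) for cohort-level properties and small
planar patches for geometric exactness checks. These sizes were chosen
as the smallest at which the surface machinery (sub-millimeter edges
against 1 mm smoothing kernels, 13-region atlases) behaves like its
full-scale counterpart.

## A worked run

```{r run, eval = FALSE}
bundle <- run_experiment(experiment_config(seed = 1))
parameter_medians(bundle, "cov_inter")
parameter_medians(bundle, "pv")
```

On the default phantom the medians reproduce the qualitative structure
the metrics were designed to expose: quantitative R1 attains the lowest
inter- and intra-subject normalized COV, the two ratio images the
highest inter-subject COV, and the longitudinal parameters (R1, T1w)
lower PV than the transversal ones (T2\*, T2\*w). The test suite asserts
exactly these orderings (`tests/testthat/test-acceptance.R`), and
`scripts/acceptance.R` recomputes the numbers from scratch for any seed.

## Known limitations

* The weighted transform is a documented monotone sigmoid, not a Bloch
  simulation of an MP2RAGE lookup; it reproduces the range-broadening
  behavior, not the sequence physics.
* The iterated-diffusion kernel is only approximately Gaussian and its
  width calibration assumes a quasi-uniform mesh; strongly anisotropic
  meshes would need exact geodesic kernels.
* Graph-distance (hop) metrics drive atlas construction; on meshes with
  very heterogeneous edge lengths hop distance and geodesic distance
  diverge.
* The intra-subject COV pools the rescanned subjects after the
  per-subject σ/μ step (the alternative order — pooling sessions before
  dividing — is a one-line change in `cov_vertexwise` but is not the
  default, and the default is asserted by tests).
* With 2 sessions per subject the scan-rescan sd has 1 degree of
  freedom per vertex; PV maps are accordingly noisy per vertex and only
  their region medians are interpreted.
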