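---
title: "Quantifying hepatic lesion burden in sinusoidal obstruction syndrome: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hepatic lesion burden in sinusoidal obstruction syndrome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sosct)
```

## The measurement problem

Sinusoidal obstruction syndrome caused by pyrrolizidine alkaloids (PA-SOS)
congests the hepatic sinusoids and delays contrast inflow, so affected
parenchyma appears as patchy hypoattenuating tissue on hepatic-venous-phase
contrast CT. `sosct` turns that appearance into numbers: the liver volume,
the hypoattenuating lesion volume, and their ratio

$$\mathrm{Ratio} = \frac{V(\mathrm{ROI_{lesion}})}{V(\mathrm{ROI_{liver}})} \in [0, 1],$$

which is then related to clinical severity and outcome by a conventional
ANOVA/LSD/Pearson layer. This vignette explains each stage, the tunable
parameters and their defaults, the choices that were genuinely open, and
what the synthetic test data do and do not establish.

## Denoising: Perona–Malik anisotropic diffusion

Threshold-based extraction is fragile on raw CT because noise widens every
tissue's HU distribution. The package therefore runs the explicit
Perona–Malik scheme before any threshold is estimated:

$$u \leftarrow u + \Delta t \sum_{d} g(\nabla_d u)\, \nabla_d u,$$

where $\nabla_d u$ are nearest-neighbour differences and the conduction
$g$ shrinks with gradient magnitude, so smoothing stalls at tissue
boundaries.

Parameters (`diffusionParams()`):

* `iterations = 4`, `timeStep = 0.125` — the protocol values for this
  application; both well inside the explicit-stability bounds.
* `kappa = 30` HU — the contrast scale separating "noise" gradients
  (smoothed) from "edge" gradients (preserved). The liver/lesion contrast
  is ~50 HU and noise is below ~10 HU, so 30 HU sits between them. The
  original protocol does not state a value; `kappa` is therefore exposed
  as a parameter rather than presented as a reconstruction.
* `conduction = "exponential"` ($g(s) = e^{-(s/\kappa)^2}$) by default:
  it favours preserving high-contrast edges, which is what liver/lesion
  and liver/background boundaries are. The rational variant
  $g(s) = 1/(1+(s/\kappa)^2)$ is selectable.
* `mode = "slice_2d"` by default: with 5-mm slices and ~0.7–2 mm in-plane
  spacing, index-space 3-D gradients mix very different physical scales,
  and thick-slice CT filtering is conventionally applied per axial slice.
  `volume_3d` (6-neighbourhood, $\Delta t \le 1/6$) is available.
* Differences are taken in index space, not divided by physical spacing —
  the standard formulation; spacing-aware gradients would silently change
  the meaning of `kappa`.

Numerically, the scheme with replicated-edge (zero-flux) boundaries
conserves the global intensity sum exactly (pairwise antisymmetric fluxes)
and is a convex update at the default step sizes, so the output range never
exceeds the input range. Both properties are asserted in the test suite, as
is voxel-level agreement with an independently coded straight-loop
implementation of the update rule.

## Threshold estimation and the lesion interval

The original workflow derived HU thresholds from a manual approximate
delineation using a commercial package whose mechanism is undocumented.
This package's explicit stand-in (`estimateThreshold()`) is a percentile
bracket: the interval is the $[p_{lo}, p_{hi}]$ percentile range (default
1–99) of the denoised HU values under an operator scribble. Percentiles
are robust to stray voxels, reproducible, and reduce to min/max at
$(0, 100)$. This is a design choice, not a reconstruction.

Three scribbles drive the segmentation:

* a **liver** scribble spanning the whole organ — including its lesions,
  since $\mathrm{ROI_{lesion}} \subseteq \mathrm{ROI_{liver}}$ and the
  Ratio denominator is whole-liver volume;
* a **low-density** scribble on hypoattenuating tissue, giving $[a, b]$;
* an **enhancement** scribble on enhancing parenchyma, giving $[c, d]$.

The lesion interval is $[a, (b+c)/2]$ (`lesionInterval()`): the upper
bound is moved to the midpoint of the HU gap between the two tissues.
Both interval ends are treated as closed. The source notation prints a
mismatched bracket for the upper end; closing it makes the touching case
$b = c$ well-defined and costs at most a set of voxels with HU exactly
equal to the bound. This dialect is fixed, not configurable — a single
convention avoids silent divergence between analyses. If $(b+c)/2 < a$ the
interval is empty and an error is raised; overlapping tissue intervals
($b \ge c$) warn but proceed, since the midpoint rule still yields a valid
interval.

## Region growing

`regionGrow()` returns every voxel connected to a seed through voxels whose
HU lies inside the closed interval, computed by a vectorised breadth-first
wavefront. Properties guaranteed (and tested): the result is independent of
seed order and traversal order; contains every seed; contains only
in-interval voxels; and never shrinks when the interval widens.

Choices:

* **Connectivity 6** by default. Face-only adjacency resists leakage
  through diagonal noise bridges; 26 is available for sensitivity
  analysis.
* **Bounding masks.** Liver growth is bounded by the manual approximate
  delineation of the organ. Lesion growth is bounded by the liver mask:
  lesions are hepatic by definition, and in real PA-SOS ascites (near
  10 HU, present in virtually all patients) would otherwise connect to the
  lesion interval outside the organ. Whether the original lesion growing
  was so constrained is unstated; the constraint is this package's choice
  and also guarantees the invariant
  $\mathrm{ROI_{lesion}} \subseteq \mathrm{ROI_{liver}}$.
* The threshold-source scribble and the bounding delineation are separate
  arguments (`segmentLiver(..., bounding = )`). A generous outline
  necessarily includes non-liver voxels, which must not contaminate the
  percentile bracket; conversely the scribble need not cover the organ's
  full extent. By default the scribble bounds its own growth.
* No hole-filling or morphological post-processing: only components
  touching seeds are returned, matching plain region growing; anything
  more would be unanchored invention.
* The enhancement region's threshold feeds the lesion interval, but its
  mask is not a volumetry output — only liver and lesion volumes are
  reported.

## Volumetry

A voxel is a filled cell: $V = \mathrm{count} \times s_x s_y s_z$ mm³,
converted to litres by $10^{-6}$, with no partial-volume modelling.
Spacing always comes from the image header. Tabular output rounds volumes
to 3 decimals (L) and ratios to 4; internal computation keeps full
precision. A lesion volume exceeding the liver volume raises an error
rather than clamping — it can only arise from a segmentation defect, and
clamping would hide it.

## Cohort statistics

* `describeValues()`: mean and **sample** SD ($n-1$ divisor). The divisor
  is pinned empirically by the transcribed cohort: the printed age SD
  (12.70) reproduces only with $n-1$ (the $n$ divisor gives 12.44), and
  the test suite asserts exactly that.
* `anovaFromSummary()`: one-way ANOVA reconstructed from per-group
  $(n_i, m_i, s_i)$ alone — $SS_b = \sum n_i(m_i - \bar x)^2$,
  $SS_w = \sum (n_i - 1)s_i^2$, $F = (SS_b/df_b)/(SS_w/df_w)$. This is
  algebraically the raw-data F, so published summary tables can be
  re-analysed. `anovaRaw()` (backed by `stats::aov`) must agree with it on
  every input; the identity is property-tested on random data.
* `lsdPosthoc()`: Fisher LSD — unadjusted pairwise $t$ tests on the
  pooled within-group mean square, by definition without multiplicity
  correction; equivalent to pooled-variance two-sample $t$ tests in the
  two-group case (tested).
* `pearsonCorrelation()`: product-moment correlation with the $t$
  transform on $n-2$ df (via `stats::cor.test`).
* $\alpha = 0.05$ throughout; group order follows the configuration
  (mild/moderate/severe; recovery/cirrhosis/death), never silent sorting.
  A `"<0.05"`/`">0.05"` rendering (`formatP()`) mirrors clinical tables.

Degenerate inputs are explicit: when $SS_w = 0$, F is $+\infty$ (distinct
means) or undefined (all values equal), returned with a `degenerate` flag
rather than an error or a fabricated number.

### Reproducing the published tables

`reproduceTables()` re-derives, from the transcribed fixtures alone, every
per-patient ratio, the cohort averages, and every per-group F. Two
published cells are not reproducible from their own printed summaries and
are flagged as expected mismatches: the lesion-volume-by-severity F
(whose severe-group cell duplicates the whole-cohort lesion mean — a
likely typographical slip) and the Ratio-by-outcome F. For the remaining
rows, the published F values stem from unrounded raw data while the
recomputation starts from summaries printed to ~4 significant figures;
propagating that half-ulp rounding through the F formula gives a
discrepancy bound of order $0.005\,F$ (with a 0.01 floor), which is the
agreement band the report applies. The transcribed per-patient table uses
2.081 L for one liver volume where the published row prints digits
transposed (2.018): only 2.081 is consistent with both that row's printed
ratio and the printed cohort average. The published per-patient lab values
were never released, so the published Pearson coefficients cannot be
recomputed; the procedure is implemented and verified against its defining
formula instead.

## Synthetic data: what it emulates and what it does not

The phantom (`makePhantom()`) emulates exactly the image structure the
pipeline's assumptions rest on: an enhanced liver (ellipsoid, parenchyma
$110 \pm 8$ HU), hypoattenuating lesions inside it (union of random
spheroidal blobs, $60 \pm 8$ HU), air background ($-1000$ HU), optional
ascites shell (10 HU), and global additive noise (SD 5 HU). Geometry
defaults — an 80×80×24 grid at 2×2×5 mm, ellipsoid semi-axes 62/50/45 mm,
12 blobs with 12–26 mm semi-axes — were chosen once for a plausible
moderate-disease lesion fraction and tractable runtimes, and are not
tuned thereafter. The manifest records exact truth volumes, so end-to-end
runs can be scored against ground truth; at these defaults the pipeline
recovers the Ratio to within a few thousandths across seeds (asserted at
±0.05 absolute).

Not emulated: partial-volume averaging at boundaries, beam hardening,
reconstruction kernels, anatomical liver shape, vessels, and
heterogeneous (textured) lesion interiors. Passing phantom tests therefore
demonstrates the *algorithmic* correctness and noise robustness of the
chain — thresholds, growing, volumetry, statistics — not clinical
segmentation accuracy on real scans, which cannot be assessed without the
original (undeposited) images.

`phantomAnnotations()` stands in for the operator: interior scribbles
(eroded truth), a generous bounding outline (dilated truth), and one seed
per lesion blob placed at the voxel closest to the blob's median HU — a
deterministic proxy for "click representative tissue".

The cohort simulator (`makeCohort()`) draws group-structured Ratios from
normals truncated to $[0,1]$ (rejection sampling; truncation bias is
negligible at the default SDs) and lab values from normals floored at 0,
with group sizes and moments defaulting to the transcribed severity
summaries (n = 6/10/9). It underpins two Monte-Carlo checks: type-I
calibration (two identical groups; rejection rate ≈ 0.05) and power at
the published severity parameters (rejection rate > 0.99). All generator
randomness flows from one explicit seed per call and never disturbs the
caller's RNG stream.

## Numerical and engineering choices

* Volumes are reoriented to canonical RAS axes on load, so voxel indices
  are unambiguous; any declared rescale slope/intercept is applied, and HU
  stay floating point thereafter (diffusion output is non-integer).
  DICOM ingestion is out of scope — NIfTI only.
* Internal voxel indices are 1-based (idiomatic R); plain-text seed files
  use the 0-based convention of the surrounding imaging ecosystem and are
  converted on read.
* Seeds are validated eagerly with named errors (outside grid, outside
  bounding mask, HU outside interval) — segmentation failures should point
  at the offending input, not surface as empty masks.
* Problem sizes in the routine test run: 20×20×10 grids (×100 random
  instances) for the region-growing equivalence oracle, 80×80×24 phantoms
  (×10 seeds) end-to-end, and 1000 Monte-Carlo replicates per calibration
  arm — sizes at which the whole suite completes in well under a minute
  while each check retains its discriminating power.

## Known limitations

* Threshold estimation is a stated stand-in for an undocumented commercial
  procedure; absolute agreement with the original tool on the same scans
  cannot be verified.
* No vessel exclusion, multi-phase fusion, or automatic liver
  localisation: seeds and scribbles are required input.
* Voxel-counting volumetry is biased at boundaries by up to half a voxel
  shell; at 2×2×5 mm this is well under the ±0.05 Ratio tolerance used
  throughout, but thick-slice data make lesion surfaces, not volumes, the
  dominant error term.
* The statistics layer implements exactly the published analysis plan
  (one-way ANOVA, LSD, Pearson, α = 0.05, no multiplicity correction
  beyond LSD's definition); it is not a general modelling toolkit.
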