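---
title: "Quantifying diffuse low-grade glioma growth from segmentation masks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying diffuse low-grade glioma growth from segmentation masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lggrowth)
```

## The measurement problem

Diffuse low-grade gliomas (WHO grade 2, LGG) are slow-growing, infiltrative
brain tumors followed for years with FLAIR MRI. Their growth rate carries
direct clinical weight: a mean tumor diameter expanding around 3–4 mm/year
is the usual post-surgical regime, while a velocity of diameter expansion
(VDE) reaching 8 mm/year signals impending anaplastic transformation.
Manual volume segmentation is the reference for quantifying that growth but
takes minutes per scan, so clinical practice leans on linear caliper
measurements. After surgery the lesion is no longer a compact blob: it is
one or several residues draped around a resection cavity, and naive caliper
placement either crosses the cavity or straddles disconnected residues.
This package implements a complete, rule-based measurement pipeline for
that post-surgical situation, plus the statistical layer needed to judge a
linear method against the segmented-volume ground truth.

## Measures and models

**The five diameters.** On the axial slices of a label mask (0 background,
1 tumor, 2 cavity) the tumor width `W` is the longest in-plane chord between
two tumor boundary voxels, in any direction; the perpendicular width `PW`
is the longest chord in the *same* axial slice within ±5° of perpendicular
to `W`. `D1`, `D2`, `D3` are the whole-residue extents along the
transversal, antero–posterior and inferior–superior axes. Two LGG-specific
rules apply: (1) chords must remain within tumor tissue as much as
possible — operationalized as a cavity/background crossing fraction of at
most 10% of the chord length, with a flagged fallback to the
minimal-crossing chord when no compliant chord exists (a hard zero would
leave `W` undefined on annular residues); (2) with multiple residues, the
linear measures are taken on the largest 26-connected component only, while
the segmented volume counts every residue.

**Size estimates.** `1D = W` (mm), `2D = W × PW` (mm²),
`3D = (D1 × D2 × D3) / 2` (the ellipsoid half-product, reported in mL), and
the segmented volume `V` = per-slice tumor area × slice pitch (thickness
plus any declared gap). Tumors below 10 mm (1D), 100 mm² (2D) or 0.5 mL
(3D) at baseline are non-measurable for that method.

**MTD and VDE.** `MTD.3D = (D1·D2·D3)^(1/3)` and `MTD.V = (2V)^(1/3)`; the
two coincide exactly when `V` is itself the half-product estimate, an
identity the test suite asserts. The VDE is the ordinary least-squares
slope of MTD against time (years of 365.25 days) over windows at least 6
months (182 days) long containing no treatment event. On a mathematically
perfect sphere of diameter `d`, `MTD.V = (π/3)^(1/3)·d ≈ 1.0156·d` — the
halving convention carries a small, documented upward bias on true spheres.

**Response assessment.** The baseline is the first MRI between 72 hours and
2 years post-surgery (or the last scan before chemotherapy onset, in
chemotherapy-response mode). Progression is a percent change from baseline
at or above 20% (1D), 25% (2D) or 40% (3D and segmented volume) under the
RANO-derived rules (inclusive `≥`), or strictly above 16% / 33% / 52% (and
15% for the MTD.3D change) under the LGG-optimized set. The
segmented-volume label, always under the 40% rule, is the ground truth the
linear methods are judged against — a deliberate, configurable asymmetry.
Note the geometry these thresholds ignore: scaling every diameter of a
sphere by 1.20 raises its surface product by 44% and its half-product
volume by 72.8%, so a single progression "percentage" means very different
things per method.

**Agreement layer.** Pearson correlation, Lin's concordance correlation
(classical population-moment form; Fisher-z confidence interval with Lin's
asymptotic variance), Bland–Altman limits of agreement
(mean ± 1.96 SD of the paired differences), cross-tabulation diagnostics
computed exactly from the 2×2 integer counts (Clopper–Pearson exact CIs),
and an empirical ROC over all observed change cutoffs whose trapezoidal
AUC equals the normalized Mann–Whitney U statistic. The "optimal"
threshold maximizes the Youden index, ties broken toward higher
specificity; a closest-to-(0,1) criterion is available. These are the
standard readings of the respective outputs of clinical statistics
packages; where a choice existed it is a documented argument, not a
constant.

## The synthetic cohort

No imaging data ships with the package; a generator produces cohorts with
the geometric and temporal structure the pipeline assumes:

* a main residue modelled as a rotated ellipsoid whose radius is modulated
  by a smooth band-limited angular field (8 low-frequency cosine waves,
  amplitude a fraction ≤ 0.5 of the local radius) — lobulated rather than
  noisy, the shape regime in which the half-product estimate drifts;
* an optional spherical resection cavity (every simulated patient has one
  by default, as in a surgically treated population), carved *after* the
  union with satellites and labelled 2 so measurement rules can distinguish
  cavity from background;
* 0–3 satellite residues placed in a shell around the cavity — the spatial
  distribution of real residues around cavities is not characterized in the
  literature, so uniform placement in a shell is an explicit, arbitrary
  choice;
* growth at a patient-specific true VDE. In isotropic mode all semi-axes
  scale equally; in anisotropic mode each growth step allocates the whole
  MTD increment to one axis (LGGs grow preferentially along white matter
  fibers), with the axis cycling x→y→z across successive steps — a fixed
  axis would scale one semi-axis cubically over a multi-year follow-up and
  outgrow the 128 mm image;
* calendar dates (surgery, scans every 90–180 days, optional chemotherapy
  and radiotherapy onsets between scans), because baseline selection
  depends on 72-hour and 2-year offsets from surgery, and VDE windows on
  event dates.

Ground truth lives on the linear-measure scale: `true_mtd = (2a·2b·2c)^(1/3)`
of the unperturbed main ellipsoid (so a sphere of diameter d has true MTD
exactly d and growth is linear in time by construction) and
`true_volume = true_mtd³/2`, its halving-convention volume. The geometric
volume `(4/3)πabc` is smaller by the factor `3/π ≈ 0.955` and is used
directly wherever voxel-count volumes are compared to analytic ones.

What the generator does **not** emulate: FLAIR intensities (masks only),
rater disagreement on the delineation itself, registration error between
timepoints, infiltrative fuzzy borders, or real residue topology. Passing
tests therefore demonstrate correctness of the measurement and statistics
machinery under controlled geometry — not clinical performance on patient
images, which depends on segmentation quality and anatomy the simulation
does not model. Cohort-level published diagnostics (AUCs near 0.83,
sensitivity/specificity trade-offs per method, LGG-optimized thresholds)
derive from clinical cohorts and are deliberately not reproduction targets.

## Numerical conventions

* **Caliper convention.** Chord length = euclidean distance between
  endpoint voxel centers plus one in-plane voxel projected onto the chord
  direction; axis extents = (max − min voxel index + 1) × spacing. Applied
  consistently, these make sphere identities (`W ≈ D1 ≈ D2 ≈ D3`) hold. A
  lesion centered exactly on a voxel center is the worst case (+1 voxel on
  an extent); generic sub-voxel positions are unbiased.
* **Crossing fraction.** Each candidate chord is sampled at
  `2·ceil(slice diagonal in voxels) + 1` evenly spaced points (at least
  half-voxel resolution); the fraction of samples on non-tumor labels is
  the crossing fraction. The sample count depends only on the slice, so
  the quantity is well defined independently of search order, and an
  exhaustive test oracle reproduces it exactly.
* **Connectivity** is 26-connected in 3D; stricter connectivity would
  fragment thin infiltrative bridges between diffuse residues. Exact
  volume ties between residues break toward the smaller lexicographic
  centroid, with a warning.
* **Search budget.** Slices with more than 2000 boundary voxels are
  uniformly strided before the pair search; `exact = TRUE` disables this
  (the validation suite always runs exact). Slices are processed in
  decreasing order of an in-plane bounding-box bound so the search stops
  early.
* **Degenerate inputs.** A single-voxel lesion reports the in-plane voxel
  diagonal for both `W` and `PW`, flagged `"degenerate"`; empty tumors are
  an explicit error for measurement operations and an exclusion record
  (never an exception) for baseline selection.
* **Windows.** A scan dated exactly on a treatment event belongs to both
  adjacent treatment-free segments. Windows are maximal treatment-free
  segments by default (avoiding double-counted correlated pairs in
  concordance analyses); a pairwise per-assessment mode is available.
  Repeated surgeries split windows rather than resetting the baseline
  date.
* **Measurability is a baseline property**: a follow-up that shrinks below
  the measurability floor still classifies (as non-progression); dropping
  it would bias sensitivity.

## Problem sizes in the test suite

The validation suite runs on desk-scale geometry chosen to keep the whole
suite near a minute while leaving the assertions sharp: 64³–96³ voxel
grids at 1 mm isotropic spacing for single-lesion checks, an exhaustive
chord oracle on 25 randomized ≤64³ masks (including cavity and open-C
cases), and an end-to-end cohort of 32 patients × 3 scans with planted
slow (1 mm/year) and fast (8 mm/year) growers. The latter recovers the
planted mean VDE within ±0.5 mm/year — the scale of voxelization noise on
6-month windows at 1 mm spacing — and the ROC-optimal 3D threshold within
one grid step of the 40% volume-truth rule (with fully separated classes,
any cutoff in the separation gap is Youden-optimal; the package reports
the highest-specificity one, i.e. the largest non-progressor change).

## Known limitations

* `W`/`PW` are defined on axial slices; a lesion whose true longest axis is
  strongly oblique to the axial plane will have `W < D3`-type geometry that
  only the 3D extents capture — one reason the diameter triple is the
  preferred linear method.
* The crossing rule treats background and cavity alike when penalizing
  chords; whether a chord may bridge a concave background gap *within* one
  connected residue is genuinely ambiguous in the measurement tradition,
  and the 10% tolerance is an explicit operational choice (flagged in the
  output whenever the fallback path fires).
* The half-product estimate converges to `3/π ≈ 0.955` of the geometric
  ellipsoid volume, not to 1; agreement between `size_3d` and the
  segmented volume on near-ellipsoidal lesions reflects that constant, and
  irregular shapes move it further.
* Lin's CCC confidence intervals use the asymptotic variance; at the small
  window counts of subgroup analyses they are indicative only, and
  subgroups with fewer than 3 windows report `NA` with a note.
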