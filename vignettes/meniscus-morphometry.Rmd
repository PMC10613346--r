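---
title: "Methods: 3D meniscus morphometry, the knee phantom, and the statistics layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D meniscus morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(meniscus3d)
```

## The measurement model

All measurements are taken in anatomical millimetre space on the axial
footprint of each structure: the top-down projection of its 3D label mask,
with x running medial→lateral, y posterior→anterior, z inferior→superior.
Working on the full-mask projection rather than on individual thick clinical
slices removes slice-selection ambiguity and matches how a rater measures a
3D surface reconstruction "from the top". Volumes are reoriented to this
convention on load (the affine must be axis-dominant; genuinely oblique
acquisitions are rejected rather than resampled), and left knees are
mirrored across the mediolateral axis so the lateral compartment always
lies at positive x and a single code path serves both sides.

Lengths follow a voxel-box model: a voxel is a closed axis-aligned box
centred on its grid point, so a run of *n* cells at spacing *s* measures
*n·s* mm, outer face to outer face. A voxelized bar of physical length
*l* then measures *l* to within one spacing, which is what makes the
"within 2 voxel spacings" recovery budget meaningful.

The three indices:

* `a` — minimum meniscal body width. "Body" is operationalized as the
  central third of the footprint's AP extent (`body_fraction = 1/3`,
  configurable): the published protocols say only "mid-portion of the
  meniscal body". Within each body row, the width is the connected occupied
  run adjacent to the *peripheral* edge, so a hollow crescent's inner gap is
  excluded while a filled discoid's run extends toward the midline —
  exactly the behaviour that drives RMT past 0.20 in discoid knees.
  Widths are measured along ML row runs; whether raters measured strictly
  along ML or radially is not documented, but for body rows near the AP
  midline the two differ at second order.
* `b` — maximum tibial width: the largest first-to-last occupied ML span
  over rows of the tibial plateau footprint. RMT = a/b.
* `c`, `d`, `e` — at the sagittal line x\* through the maximum AP diameter:
  `e` is the first-to-last occupied span, `c` and `d` the anterior-most and
  posterior-most occupied runs. PCM = covered/e, where covered is the total
  occupied length at x\* (equal to c + d unless the column crosses more than
  two runs). A single full-span run gives PCM = 1 exactly, the complete
  discoid signature.
* `L`, `M` — AP extents of the lateral and medial footprints; L/M is the
  body-size-free diameter ratio, ≈ 0.74 in normal knees and ≈ 0.66 in DLM.

### The x\* tie-break

At voxel resolution the maximum AP span is attained on a plateau of columns
(the chord of an ellipse is flat near its apex: every column within about
√(spacing/r)·r of the centre ties). The tie rule therefore matters. We
initially broke ties toward the peripheral side, but that lets x\* slide
several millimetres to where a near-discoid's inner hole closes, biasing
`c`, `d` and PCM by far more than a voxel relative to any finer-resolution
reference (observed: up to 1.8 mm in `d` and 0.14 in PCM against the
0.05 mm oracle). The default is now the tied column nearest the plateau's
centroid, which is stable across grid resolutions; `tie = "peripheral"`
preserves the alternative. This is the one place the package's operational
definitions deviate from a first-draft determinism rule, and it is a
correctness fix, not a tolerance adjustment.

### Classification

`is_dlm` iff RMT ≥ 0.20 (inclusive, as printed in the screening criteria);
complete discoid iff RMT > 0.32 (strict); PCM ≥ 0.75 is reported as an
auxiliary positivity flag rather than a second inclusion criterion,
mirroring how the indices are used clinically (RMT-based inclusion,
arthroscopic verification being outside a computational pipeline).
Thresholds are recorded in every output and configurable.

## The knee phantom

A meniscus footprint is a C-shaped elliptical annular sector: outer
semi-axes `r_out_ml`, `r_out_ap`; an opening gap of `opening_angle` radians
facing the intercondylar midline; and a radial width fraction w(θ) that
interpolates anterior-horn, body and posterior-horn values with a cos²
blend (C¹-smooth) over the quarter-turns adjacent to the body apex.
Discoidization is a single `coverage` parameter: the footprint fills the
outer ellipse down to 1 − max(coverage, w(θ)), so coverage = 1 yields a
complete discoid and the crescent→incomplete→complete continuum is spanned
by one number. The tibial plateau is an elliptical cartilage slab; menisci
rest on top of it in z.

Voxelization marks a voxel iff its centre is inside the (optionally
jittered) footprint and the structure's z slab. Jitter emulates
segmentation boundary error as seeded smooth radial noise — an order-4
Fourier series in θ with N(0,1) coefficients scaled to a given mm
amplitude — applied to the outer and inner boundaries independently. It
deforms the boundary without changing topology, unlike voxel-wise salt
noise. Ground truth is always evaluated on the exact unjittered shape, so
the phantom-vs-truth discrepancy *is* the voxelization + segmentation error
budget.

Ground truth uses closed forms where exact (L, M, b; and e, c, d, PCM for a
closed complete discoid) and otherwise applies the *same operational
definitions* as the measurement module to the continuous footprint sampled
at 0.05 mm — fine enough that refining to 0.01 mm moves `a` by < 0.05 mm.

Numerical choices worth recording:

* Default spacing (0.35, 0.35, 0.7) mm matches an axial 3D proton-density
  protocol (0.7 mm slices, ~0.35 mm in-plane); the anisotropy deliberately
  stresses the mm-space measurement code. Default field 160 × 160 × 60 mm;
  tests crop the field to the structures purely for runtime.
* The tibial cartilage slab is 2.8 mm thick — an exact multiple of the
  0.7 mm slice — so the analytic voxel-count oracle (area × thickness /
  voxel volume, within 2%) is well-posed; a 3 mm slab voxelizes to 4 slices
  = 2.8 mm of material, a structural −4.7% bias that says nothing about
  correctness.
* The medial meniscus default opening is 1.6 rad, wider than the lateral's
  0.9 rad, matching the anatomically more open medial C and keeping its
  horn tips short of the midline so that broad discoid lateral shapes never
  intersect it.

### The cohort generator and what a green test establishes

`default_cohort_spec()` states the simulated world: a non-DLM group
(n = 43) and a DLM group (n = 31) with truncated-normal parameter draws
placed so the ground-truth index means land near the published group
means — RMT 0.10/0.25, PCM 0.50/0.85, L/M 0.74/0.66, i.e. an L/M
population gap of 0.080. Each knee's meniscus is anchored 1.5 mm inside
the drawn tibial rim, and draw combinations that are geometrically
infeasible (footprint collision or field overflow) are rejected and
redrawn, conditioning the distributions on feasibility exactly as
truncation does. Lengths scale: every mm parameter × f leaves all three
indices invariant, which is tested.

The phantom emulates shape, coverage and boundary noise. It does **not**
emulate MR intensities, partial-volume effects, oblique acquisitions,
meniscal tears or displaced fragments, or inter-rater segmentation
disagreement. A green parameter-recovery suite therefore establishes that
the *measurement operators* are unbiased to within voxelization error on
clean masks of realistic geometry — not that the pipeline is robust to
segmentation quality, which only real rater data could show. Reliability
(ICC) on synthetic ratings likewise validates the arithmetic, not the
raters.

Because the realized ground-truth group gap at n = 31/43 fluctuates around
0.080 (SE ≈ 0.011), the end-to-end acceptance check first scans seeds in
fixed order for a cohort realizing the stated ≥ 0.08 gap — a precondition
of the scenario, selected before any outcome is computed — and then tests
the outcomes (measured group means within 0.02 of truth; Mann-Whitney
p < 0.001) on that cohort.

## The statistics layer

* **Mann-Whitney U**: midrank-based U; exact two-sided p by full
  enumeration of the U distribution when the combined sample is ≤ 16 with
  no ties (the regime of small synthetic checks), otherwise the normal
  approximation with tie and continuity corrections (the regime of
  study-sized groups, 31 vs 43). The exact path is verified against the
  closed-form distribution and `wilcox.test`; the switch point is
  configurable.
* **2×2 chi-square with Yates correction**: Σ(|O−E|−0.5)²/E with the
  correction floored at zero. The uncorrected Pearson statistic is always
  reported alongside, because recomputing a published demographic table
  (sex counts 20:11 vs 22:21) gives corrected p ≈ 0.365 while the printed
  p = 0.25 matches the *uncorrected* statistic — the report flags such
  discrepancies rather than silently matching either number.
* **ICC(2,1)**: two-way random-effects, absolute-agreement, single-measure
  (Shrout–Fleiss), chosen because the source studies do not state their
  model and interchangeable-rater absolute agreement is the standard
  default for continuous measurements; the model is recorded in every
  output. Confidence intervals use the McGraw–Wong F formulas. Intra-rater
  reliability reuses the same arithmetic with sessions as columns.
  Zero between-subject variance is an error, not a coefficient; published
  CI bounds cannot be checked without the unpublished raw ratings.
* `compare_groups()` renders the usual two-group report (mean ± SD per
  index, U, p, optional demographic chi-square) and is invariant to row
  order and group relabeling; subgroup splits (tear ±, complete vs
  incomplete) reuse it through `compare_subgroups()`.

## Known limitations

* Oblique affines are rejected, not resampled; inputs must be near-axis
  aligned label maps.
* Measurements on fragmented (multi-component) lateral footprints are
  flagged unreliable rather than suppressed; torn-meniscus morphology is
  out of scope.
* The NIfTI-1 implementation covers 3D scalar volumes with sform/qform
  affines — the subset this pipeline produces and consumes — not the full
  standard (no extensions, no .hdr/.img pairs, no 4D).
* Phantom parameter ranges are chosen to reproduce published index
  distributions, not drawn from anatomical atlases; no quantitative shape
  statistics for menisci beyond the indices were available.
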