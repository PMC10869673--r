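---
title: "Curating multi-station whole-body MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating multi-station whole-body MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbcure)
```

## The problem

Whole-body MRI for marrow disease is acquired as a series of couch-position
"stations", each covering part of the body, which vendor software then
"composes" (stitches) into a single volume per contrast.  A complete
radiological read needs seven series — Dixon in-phase, out-of-phase, fat
and water, diffusion-weighted b50 and b900, and the ADC map — and machine
learning pipelines need those series to be geometrically consistent.  In
clinically sourced data the composition step is a systematic source of
defects:

* **slice overlap** — adjacent stations contribute slices at duplicate or
  too-close positions (redundant but repairable information);
* **slice underlap** — slices are missing at a station boundary
  (unrecoverable: the tissue was never stored at those positions);
* **per-station in-plane offsets** — the fat and water reconstructions,
  nominally co-registered, are shifted against each other by a translation
  that varies from station to station;
* **misordered stations** — blocks appear in the wrong anatomical order;
* **fat–water swaps** — the Dixon reconstruction's inherent labelling
  ambiguity exchanges fat and water content globally, per station, or in a
  local region.

`wbcure` detects and, where information permits, repairs these defects;
harmonises all series of a session onto a single grid with NIfTI export;
allocates subjects to study phases stratified by disease category; and
writes every action into an auditable, self-documenting run record.
Because no clinical data can ship with the package, a synthetic phantom
generator with ground-truth defect injection is a first-class module: every
detector and repair is verified against sessions whose defects are known
exactly.

## The phantom's stated world

The phantom is a piecewise-constant body: a cylinder of water-dominated
soft tissue (water signal 100, fat 10, arbitrary units) wrapped in a
subcutaneous fat rim (fat 100, water 10), with low-signal bone ellipsoids
(both ≈ 5) and water-bright lesions (water 120) carrying their own ADC.
Compartment ADCs are 1.0×10⁻³ mm²/s (soft tissue), 0.4×10⁻³ (fat),
0.2×10⁻³ (bone), per-lesion configurable (defaults 0.6–0.7×10⁻³) — ordinary
magnitudes for abdominal tissue and marrow lesions.  Acquired channels
(fat, water, b50) carry independent Gaussian noise with σ = 2 % of the rim
intensity; derived channels obey the signal model exactly:

* `in_phase = fat + water`, `out_of_phase = |water − fat|` (two-point Dixon
  identities);
* `b900 = b50 · exp(−(900 − 50) · ADC)` voxelwise — the mono-exponential
  diffusion decay with the protocol's two b-values, so
  `ADC = ln(b50/b900)/850` inverts it in closed form.

Noise is Gaussian rather than Rician, and there is no coil profile, bias
field, susceptibility or motion modelling: the phantom emulates the
*geometry* and *labelling* failure modes of composition, not MR physics.
A green test therefore establishes that the algorithms recover injected
composition defects — it says nothing about detector performance against
artefacts this model omits (metal, motion, low SNR), which the package
deliberately only flags for human review.

Defaults (4 stations, 800 mm coverage, 5 mm slices, 4 mm in-plane) describe
a compact but realistically proportioned whole-body acquisition.  The test
suite uses a smaller 3-station fixture (240 mm, 6 mm / 8 mm) so that the
50-seed × 6-class recovery sweep stays inside its time budget; phantom
dimensions affect runtime only, not any tested statistic's definition.

## Geometry audit

Slice positions are the projections of each slice's patient-space position
onto the slice normal (LPS convention, normal = row × column direction
cosines).  Each inter-slice gap `g` is compared with the nominal spacing
`s`: contiguous when `|g − s| ≤ tol·s`, underlap when `g > s(1 + tol)`,
overlap when `g < s(1 − tol)`; duplicate positions are a full overlap.  The
defect size in whole slices is `round(|g − s|/s)` — deleting `n` slices
yields a gap of `(n+1)s` and hence size `n`.  The tolerance default is 5 %:
stored positions are float-precise, but composition rounding was the reason
a tolerance is needed at all; it is a config knob and is logged.  When no
nominal spacing is available it is inferred as the mode of the gaps rounded
to 0.1 mm, which is robust as long as most of a stack is clean.  Severity
follows the audit contract: any underlap → red (data are missing), overlaps
only → amber (repairable without loss), otherwise ok.  Runs of defective
boundaries separated by at most one contiguous boundary are grouped into a
single finding, because one composition event leaves interleaved
duplicate-position patterns.

## Repairs

**Regridding.**  The output grid spans first-to-last position at the
nominal spacing.  Duplicate-position slices are averaged, then every output
slice is linearly interpolated along the normal.  Slices falling inside an
underlap (no measured slice within half a spacing, bracketing interval
wider than `s(1+tol)`) are interpolated *and* marked in a boolean
`missing_mask`, shipped as a NIfTI sidecar: downstream consumers stay
rectilinear but can exclude fabricated voxels.  Interpolation is linear
because the repair claim is "no loss of information" only for overlaps;
masked fabrication is the honest treatment of underlaps.

**Offsets.**  The per-station translation between fat (moving) and water
(reference) is estimated by phase correlation of gradient-magnitude images
averaged over the station's slices, at integer-pixel resolution, bounded
±16 px by default.  Water is the reference because disease reading is
water/DWI-centric.  Integer resolution is deliberate: sub-pixel composition
shifts were not observed, and sub-pixel resampling would blur training
data.  Correction translates each block by the negated estimate with zero
padding; estimation on the corrected stack returns (0, 0) (fixed point).
Offsets are corrected *before* swap detection: a misaligned fat rim mimics
a station swap in the rim statistic, while phase correlation keys on shared
anatomy edges and is label-robust.

**Station order.**  Blocks are misordered iff their mean slice positions
are not monotonic in block order; sorting blocks by mean position restores
the order and slice positions are reassigned monotonically.

## Fat–water swap detection

The subcutaneous rim of the body is adipose, so
`(mean(fat) − mean(water)) / mean(fat + water)` over the rim is positive on
correctly labelled anatomy and exactly negated under a label exchange.  The
body mask is an Otsu threshold on fat + water with a one-pixel
morphological opening and slice-wise hole filling (interior low-signal
bone must not punch holes that masquerade as rim), the rim its two-pixel
erosion complement.  A whole-volume statistic below −θ (θ = 0.2 by
default) is a global swap; otherwise each station is tested.  Local swaps
are searched as 6-connected components (≥ 40 voxels by default) of
confidently misclassified solid voxels — water-dominant rim or
fat-dominant deep interior, where "deep" means eroded past the whole
subcutaneous layer (6 px default).  Global and station findings are fixed
by exchanging content; **local findings are never auto-corrected**, only
flagged, because local swaps co-occur with artefacts (implanted metal) and
relabelling sub-regions risks corrupting genuine signal.  The detector is
explicitly a heuristic stand-in for the study's manual review; θ,
the minimum component volume and the erosion radii are config values
recorded in the run record.

The opening substitutes for a largest-connected-component step: both
remove noise-scale speckle from the mask, and the opening is vectorisable
in R where a per-slice BFS is not.

## Harmonisation and NIfTI

The common grid takes its voxel size from the DWI (b900, else b50) — the
transverse Dixon protocol was designed to match the DWI resolution — and
its field of view from the union of all series extents, overridable by an
explicit grid.  Resampling is trilinear (nearest for masks) in world
coordinates and requires a uniform slice grid, i.e. audit + regrid come
first; voxels outside the source get 0 plus an out-of-field mask rather
than NaN, keeping integer dtypes valid.  Trilinear interpolation reproduces
degree-1 polynomials exactly, which the tests exploit as an oracle.

NIfTI-1 output converts the internal LPS geometry to the RAS+ affine by
negating the first two rows; voxel (0,0,0) is the first-slice first-voxel
centre, the sform carries the affine (qform 0), data are float32 (uint8
for masks).  No NIfTI (or DICOM) library exists in the supported R stack,
so the package carries minimal codecs for exactly the subset it emits;
the NIfTI writer was cross-validated against nibabel and the decoded
affine frozen into the test suite, and the DICOM codec (Explicit VR Little
Endian, single-frame MR, uint16 with per-series rescale) is covered by
round-trip and binary-layout tests.

## Disease coding and phase allocation

Per-session disease patterns are subsets of {D, EM, PM, F, MN, I, N, H}
(diffuse, extramedullary, paramedullary, focal, micronodular, inactive,
new-diagnosis, healthy); H excludes all others.  For stratified allocation,
patterns coalesce to four categories.  The precedence **F > D > I** is this
package's default, not an inherited rule: focal disease is the eventual
segmentation target, so a session showing focal plus diffuse disease
counts as focal.  MN maps to F by default (micronodular disease is focal
in character).  EM, PM and N alone determine no category and such patterns
raise an "uncategorisable" error rather than guess.  All three choices are
config knobs and are logged.  Where a subject's sessions carry mixed
patterns, the subject-level category defaults to coalescing the union of
all session patterns — a flagged, overridable reduction, since no published
rule exists.

Allocation is per *subject*, never per session, so a subject cannot leak
between training (Phase 1) and validation (Phases 2–3).  The prospective
trial cohort goes to Phase 3 unconditionally.  Within each remaining
category, subject IDs are sorted, shuffled by a seeded RNG (in fixed
category order, so the plan is independent of input file order), and the
first `round(fraction·n)` (half-up) go to Phase 1.  Fractions are settable
per category — published per-category splits are visibly unequal, so a
single global fraction could not reproduce a study-like plan.  The plan
serialises with its seed and config, making it exactly re-runnable.

## Run records and QA

Every pipeline operation appends exactly one step (name, parameters,
findings, timestamp) to a session's run record, which exports as JSON and
as a crystallised non-interactive HTML page stored under the session's
REPORTS resource in a local `project/subject/session/{DICOM,NIFTI,REPORTS,
SEGMENTATIONS,ECRF}` tree mirroring an XNAT hierarchy.  Project metrics
(sessions curated, exclusions by reason, swap prevalence, protocol mix)
are recomputed from the run records alone — nothing is counted that an
auditor could not recount.  Pseudonyms are HMAC-SHA256 of the patient ID
under a secret salt (deterministic per salt, infeasible to invert without
it); a conservative tag list (dates, institution, physicians, birth date,
sex, age, address) is stripped, pixel data and geometry untouched, and a
private marker tag makes the operation idempotent.  The id map can be
written encrypted at rest with a key that would come from the environment,
never from the repository.

## Numerical choices and degenerate inputs

* Gap classification needs ≥ 2 slices; all-duplicate stacks are degenerate
  for regridding and rejected.
* Slice-position matching uses 0.01 mm everywhere (grid comparison,
  duplicate detection, uniformity checks) — well below any real spacing,
  well above float noise.
* Phase correlation peaks are searched inside the ±16 px bound; a stronger
  peak outside it either errors or flags, per config ("the shift is bigger
  than the search window" must never silently truncate).
* Orientation vectors must be unit and orthogonal to 1e-6; mixed
  orientations within a DICOM series are an error, not a warning.
* Zero-variance blocks make offset estimation meaningless and error as
  "uninformative"; an empty body rim does the same for the swap statistic.
* Ties in the allocation shuffle cannot occur (IDs are unique); ties in
  station mean positions leave the order verdict "ordered" only if
  non-strictly monotonic.

## Known limitations

* Detector thresholds (θ = 0.2, 40-voxel minimum component) were chosen on
  the phantom's contrast levels; clinical data would need tuning against
  expert review, for which no public ground truth exists.
* No intensity harmonisation across scanners (histogram matching, ComBat)
  — geometric reformatting only.
* No re-composition from original uncomposed station data, no automated
  local-swap correction, no XNAT REST integration: a local directory
  layout and flag-for-review stand in.
* The DICOM codec reads only what the package writes (Explicit VR Little
  Endian); it is a fixture transport, not a general PACS client.
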