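---
title: "Report-guided ruling-out of false-positive tumor contours"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Report-guided ruling-out of false-positive tumor contours}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionmatch)
```

## The problem

Deep-learning auto-segmentation of head-and-neck gross tumor volumes — the
primary tumor (GTVp) and involved lymph nodes (GTVn) — fails at the
*instance* level far more often than at the voxel level: on local clinical
data the dominant error mode is whole spurious components (false-positive
contours around inflammation, physiological uptake, benign lesions), plus a
smaller number of missed PET-negative nodes (false negatives).  Voxel
metrics like DSC dilute these errors; clinically they matter most, because
a false-positive contour irradiates healthy tissue and a missed node risks
recurrence.

The radiologist's PET/CT diagnosis report already enumerates every genuine
lesion, with some combination of laterality, axial (PET) slice number,
size, SUVbw, lymph-node level and anatomic region.  `lesionmatch`
operationalises that knowledge: it extracts structured lesion records from
the report, matches them geometrically to the connected components of the
auto-segmentation masks, deletes the unmatched components as false
positives, and flags unmatched records as false negatives for physician
review.  The package never edits matched contours and never draws missing
ones — false negatives are reported, not repaired, because contouring a
node the model missed is a clinical decision.

## Lesion records and report extraction

A `lesion_record` is one reported lesion: class (`primary`/`node`),
laterality (`left`/`right`/`bilateral`/`midline`/`unknown`), optional PET
slice number, anatomic region (primaries), LN level (nodes), size, SUVbw,
and a `grouped` flag for "clusters" / "several nodes" descriptions.  A
grouped record may match several contour components but counts as one
reported lesion.

Records can come from three routes:

* **LLM extraction** (`llm_extract()`): a backend is any object with one
  `complete(text) -> text` method.  Two instruction templates are shipped;
  the second additionally directs the model to use the report's Impression
  paragraph to decide whether a finding is a genuine primary tumor or
  node, which suppresses benign high-uptake findings.  The package pins
  the reply format to a fixed-header markdown table (the model reply is
  parsed by `parse_markdown_table()`; unknown columns are ignored).
  Offline runs and tests use `mock_backend()` and recorded transcripts
  only — replaying a stored transcript reproduces the records exactly, so
  extraction results are auditable and deterministic.
* **The fixture dialect** (`parse_structured_report()`): one lesion per
  line, `class;laterality;slice;region_or_level;size;suv[;grouped]`.  This
  is this package's own deterministic stand-in for model output (it is not
  a clinical format); rendering and parsing round-trip losslessly.
* **JSON/CSV tables** (`read_records()`).

`validate_records()` flags the known extraction failure modes: one primary
split into several records (duplicate class/slice pairs), nodes outside
the head-and-neck level vocabulary (e.g. axillary nodes leaking in), and
records too underspecified to match.

## Coordinate conventions

All in-memory millimetre coordinates are DICOM LPS (+x patient-left, +y
posterior, +z superior).  NIfTI headers describe a RAS+ world, so affines
are negated in x and y on read and write.  Voxel indices are 0-based;
report slice numbers are 1-based, with the numbering direction
(superior-to-inferior by default) a per-case setting, since scanners
differ and reports do not say.  The exported PET–CT rigid registration
matrix is read from a 4-row text file; a `invert_on_load` flag covers
exports in the opposite (passive) convention rather than guessing.  The
rotation block must be orthonormal within `1e-6`; anything else is
rejected as a corrupt export rather than re-orthogonalised.

The midline plane defaults to the x coordinate of the body-contour
centroid (grid centre if no body mask is available) with a ±5 mm band
classified as `midline`.  A `midline` centroid is compatible with either
reported side, and `bilateral` records accept any side.

## The matching algorithm

Contour instances are the maximal 3D connected components of each
prediction mask (26-connectivity by default; components under 2 voxels are
dropped as speckle).  GTVp and GTVn are matched independently against the
records of their class.  Records with a slice number are handled first:

**Scenario 1 (slice location).**  Instance centroids are mapped from the
CT frame into the PET frame with the inverted registration matrix and
converted to slice numbers.  For each record, in ascending reported slice:
candidates are the unmatched instances whose laterality agrees; the
candidate with the nearest centroid slice is selected (ties to the larger
volume); the pair is confirmed only if the instance's axial span covers
the reported slice within `slice_tolerance` (default 0, the strict rule;
1 absorbs registration rounding).  Confirmed instances leave the pool.
The axial span is taken from the instance's extreme-z voxel centres mapped
into the PET frame.

**Scenario 2 (anatomic location).**  Instances left over after scenario 1
meet the records without slice numbers.  A node record matches an instance
whose centroid lies inside the reported LN level's mask (overlapping level
masks resolve to the smallest, i.e. most specific, level) with agreeing
laterality.  A primary record matches an instance whose centroid lies in
the record's anatomic-region bounding box: each box face is placed on the
corresponding extent face of a named organ-at-risk, and for a one-sided
record the contralateral face is replaced by the midline plane.  A
configurable `margin_mm` (default 0) expands boxes to soften failures for
lesions near a face.

Instances unmatched after both passes are the false positives;
`rule_out()` erases exactly their voxels (and is idempotent).  Unmatched
records are the false negatives.  Where two records compete for one
instance, the nearer-slice record wins and the other becomes a false
negative — the simplest rule consistent with nearest-centroid matching;
a "bilateral" primary is kept as a single record rather than split into
two candidates.

Determinism: instances are processed in a canonical order (descending
volume, then lexicographic first voxel), so the set of removed voxels is
invariant to input order.

## Metrics

* `dsc()`: \(2|A\cap B|/(|A|+|B|)\); both masks empty scores 1 (perfect
  agreement on absence), empty-vs-nonempty scores 0.
* `hd95()`: surfaces are foreground voxels with a 6-connected background
  neighbour; the two directed nearest-surface distance sets (between voxel
  centres, in mm) are pooled and the 95th percentile taken with linear
  interpolation (`quantile()` type 7).  Undefined when either mask is
  empty, and reported as `NA` in that case.
* `precision_from_ledger()`: with \(TP = N - FP - FN\) over instance
  counts, precision is \(TP/(TP+FP)\).  The source material never states
  its precision formula; this accounting is adopted because it alone
  reproduces every published ledger cell (e.g. 111 instances with 17 FP
  and 8 FN give \(86/103 = 0.835 \to 0.83\); 40/5/0 give
  \(35/40 = 0.875 \to 0.88\), rounded half-up to two decimals).
* `paired_t_test()`: before/after comparisons are on the same cases, so a
  paired test is the default (the unpaired form is available via
  `paired = FALSE`); pairs with undefined metrics are dropped, and an
  all-zero difference vector returns the degenerate \(p = 1\) with a
  warning.

## The synthetic phantom generator

There is no public dataset pairing auto-segmentation masks with radiology
reports, so the package carries a first-class generator
(`generate_case()`, `generate_cohort()`) whose cases exercise every stage
of the pipeline and whose error structure is known *by construction*:

* A 64×64×80 CT grid at 2 mm and a 52×52×64 PET grid at 3 mm, rigidly
  related by a small transform (defaults: 6° about z, ≤ 10 mm translation;
  bounds of 10° / 20 mm keep all lesions on both grids).
* Six cuboid OARs (body, brainstem, spinal cord, mandible, hyoid, cricoid)
  and eight cuboid LN-level compartments (1b–5b) tiling a neck-like
  volume; the packaged region-definition table references exactly these
  structures.  The published face-to-OAR table for the five primary-tumor
  regions is not available, so the shipped JSON is a documented,
  geometrically consistent placeholder that sites should edit — every
  pipeline run logs the table used.
* Lesions are ellipsoids placed inside (side, level) "slots"; taking a
  slot retires every same-side slot with an overlapping z band, which
  keeps same-side lesions separated by more than any contour span and
  makes the matching guarantees analytic rather than statistical.
* Genuine predictions are the ground-truth ellipsoids shifted one voxel
  posteriorly (a realistic imperfect DSC of roughly 0.7–0.8); injected
  false positives are extra ellipsoids that violate their scenario's
  matching criterion by construction (wrong side for primaries; unused
  level and distant slice for nodes) and never touch ground truth.
* False negatives mimic the clinical mechanism: the record exists, the
  prediction does not, and the record's SUVbw is drawn from the
  PET-negative range 0.97–2.09 observed for such nodes, while detected
  lesions draw from 2.2–12.0.
* `scenario_mix` (default 0.6) controls the fraction of records given
  slice numbers; the remainder carry only level/region.

`cohort_allocation(44)` reproduces the reference cohort's error structure
exactly: 40 primaries and 111 nodes (151 instances), 17 nodal FPs spread
over 12 cases, 5 primary FPs (four on cases with no genuine primary), and
8 FN nodes on 8 cases.  FP-affected and FN-affected cases are disjoint in
this allocation; that mirrors the reported improvement pattern and makes
the per-case monotone-improvement property (DSC never falls, HD95 never
rises after ruling out) hold exactly — when a removed false positive sits
nearer to an orphaned ground-truth lesion than any genuine prediction,
HD95 can legitimately rise, and the generator can produce such stress
cases when FPs and FNs are requested together.

What the phantom does **not** emulate: real CT/PET intensities, irregular
lesion shapes, deformable anatomy, report language variability, or
extraction errors by a live LLM.  Passing tests therefore demonstrate the
correctness of the matching logic and metrics under the stated geometric
assumptions, not clinical performance.

## Problem sizes and numerical choices

The validation cohort is 44 cases at the grid sizes above (a few seconds
per case to generate and classify); metric oracles are verified
exhaustively on masks up to 16³.  Rigid matrices invert to the identity
within 1e-9; frame round-trips are asserted at 1e-6 mm.  Slice conversion
rounds to the nearest axial plane.  LN-level overlap resolves to the
smallest level; equal-extent ties resolve alphabetically.  HD95 uses
blocked nearest-neighbour search, bounding memory at a few tens of MB.

## Known limitations

* Anatomic regions are axis-aligned boxes; tumors near a face can fall
  outside (mitigated by `margin_mm`, properly fixed only by probabilistic
  anatomical maps — out of scope here).
* DICOM-RTSTRUCT input is not parsed; masks must arrive as NIfTI (an
  adapter is a natural extension).
* The registration matrix is consumed, never computed; PET is never
  resampled onto CT.
* Live LLM backends are deliberately out of the test surface; any
  clinical use of the extraction route requires human oversight of the
  extracted table.
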