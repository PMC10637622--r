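---
title: "A hermetic DICOM pipeline for CT segmentation volumetry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hermetic DICOM pipeline for CT segmentation volumetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qvbridge)
```

## The problem this package addresses

Research-grade CT segmentation models consume and produce single-file NIfTI
volumes, while clinical image traffic is DICOM: one part-10 file per slice,
identified by a study/series/instance UID tree, moved between nodes by store
operations, and viewed from an archive. Bridging the two worlds — so that a
segmentation algorithm can be shadow-tested on newly acquired studies and its
results viewed at a workstation as overlays with a volume measurement —
requires a chain of unglamorous but correctness-critical steps:

1. receive and filter the series of interest, anonymize it;
2. decide when a series is *complete* (slices arrive as individual files
   with no end-of-series marker);
3. assemble the slice stack into a geometric volume with a correct
   voxel-to-world mapping;
4. run the segmentation algorithm;
5. encode the mask as a DICOM SEG object linked per frame to the source
   slices;
6. extract the segmented volume in milliliters from the SEG pixel data and
   publish it as a DICOM structured report (SR).

`qvbridge` implements this chain as a single testable R package. Every stage
is exercised hermetically on synthetic CT phantoms whose lesion volumes are
known analytically, so the whole pipeline can be verified without any
clinical data, network, or trained model.

## Series completion by timeout

A DICOM sender gives no signal that a series is finished. The router
therefore keeps one receive buffer per series with a deadline
`last_receipt_time + timeout_s`, and declares the series complete when the
clock reaches the deadline. Properties worth stating precisely:

* **Default** `timeout_s = 30` seconds. This is the conventional value for
  a quiet period after which an abdominal CT series pushed across a hospital
  network can be assumed complete; it is configurable per site.
* **Boundary**: completion fires at `now >= deadline` (inclusive). Some
  convention is required; the inclusive one makes "completes exactly
  `timeout_s` after the final instance" literally true.
* **Retransmission**: a re-received SOP instance replaces its buffered copy
  without growing the buffer — duplicate delivery is normal DICOM behavior —
  but it *does* reset the deadline, since it is evidence the sender is
  still active.
* **Clock injection**: every time-dependent operation takes `now` as an
  argument. The tests drive a simulated clock through randomized arrival
  schedules and assert two invariants: no series completes while any
  inter-arrival gap shorter than the timeout is still open, and every
  series completes exactly at `last arrival + timeout_s`, never earlier.
* **Serialization**: completed series are handed downstream one at a time
  in deadline order, so a slow segmentation never interleaves two studies.

## Anonymization

The de-identification list is a deliberate, documented subset of the DICOM
Basic Profile: patient name/ID are replaced with placeholders, birth date,
sex, accession number, referring physician and study ID are emptied, and
address, phone, age, institution, operator, performing physician and device
serial are removed, along with *all* private (odd-group) tags. Dates of
acquisition are retained: the phantom workflow has no real dates to protect,
and the archive viewer needs them for ordering. Geometry tags, rescale tags,
pixel data and the series description pass through untouched — they are what
the downstream stages consume.

UID remapping is memoized per session: the first query for a UID mints a
fresh replacement under the configured organizational root, later queries
return the same replacement, and replacements map to themselves. This makes
the map injective by construction (a keyed hash could collide), keeps a
study's UID tree consistent across its series, SEG and SR, and makes
anonymization idempotent — anonymizing an already anonymized instance is a
no-op, which the tests assert tag-for-tag.

## Geometry: DICOM stacks and the voxel-to-world affine

Slices are sorted by the projection of `ImagePositionPatient` onto the slice
normal (the cross product of the row and column direction cosines) — never
by `InstanceNumber`, whose semantics vary by vendor. The slice step is the
mean adjacent projection difference; any step deviating from the mean by
more than 1% relative is a hard geometry error. That tolerance is tight
enough to catch a single missing 3 mm slice (a 100% step deviation) yet
loose enough for floating-point jitter in decimal-string tags. Degenerate
but legal input — a single slice — falls back to the `SliceThickness` tag.

The assembled array is indexed `[column, row, slice]`, and the affine maps
zero-based indices to world millimeters in RAS orientation (the NIfTI
convention). DICOM positions are LPS; conversion negates x and y. Hounsfield
rescale (slope/intercept) is applied at assembly, so every downstream stage
works in physical units. The correctness oracle is brute force: for random
voxel indices the affine-mapped coordinate is compared against a position
computed independently, slice by slice, from the raw DICOM tags; agreement
is required to 1e-6 mm.

A practical note on precision: decimal-string (DS) tags are written with 10
significant digits, which keeps positions below 1000 mm accurate to better
than 1e-6 mm through a write/read cycle. NIfTI stores its affine as 32-bit
floats, so volume round trips promise voxel-exact data but only 1e-5
affine agreement; where a NIfTI file re-enters the pipeline (the
external-command segmenter), grid congruence is checked at the file
format's tolerance and the full-precision input grid is then re-attached.

## The phantom: what it emulates and what it does not

The generator emits multi-slice axial CT series with the acquisition
parameters of a portal-venous abdominal study: 3 mm section thickness by
default, contiguous slices, with series lengths in the 91–203 range at
full scale (the package default is 120 slices; most tests use far fewer).
The default series description contains "Portal Venous" so phantoms pass
the shipped series filter, and the demo adds a "Scout" series to exercise
filter rejection. Instances deliberately carry identifying tags (names,
accession number, institution, device serial, a private tag) so the
anonymizer and its audit have real work to do.

Lesions are ellipsoids with exact analytic volume
$V = \tfrac{4}{3}\pi r_1 r_2 r_3$. Rasterization is by **voxel-center
inclusion**: a voxel is labeled when its center satisfies
$\sum_i ((x_i - c_i)/r_i)^2 \le 1$, surface included. This rule was chosen
over partial-volume weighting because it admits an exact independent
oracle — a brute-force loop over all voxel centers — so the voxelized
ground-truth count is *provably* right, and every downstream volume can be
compared against it exactly. The voxelized volume converges to the analytic
volume as spacing is refined (verified at 2, 1 and 0.5 mm); at 1 mm
isotropic spacing a 10 mm sphere is off by about 0.02 mL, i.e. ~0.5%.

Pixel content is analytic and noise-free. The phantom does **not** model CT
noise texture, partial-volume blur at lesion boundaries, contrast phases,
metal or motion artifacts, or non-axial acquisitions beyond what the
orientation vector expresses. Consequently, a passing end-to-end run
demonstrates that the *plumbing* — routing, completion, conversion,
encoding, volumetry, linkage — is exact, and says nothing about how any
particular segmentation model performs on real tissue. That separation is
intentional: model quality is the user's concern, pipeline fidelity is
this package's.

HU encoding uses signed 16-bit stored values with rescale intercept −1024
and slope 1, the common CT convention, precisely so that rescale handling
is exercised rather than bypassed.

## The segmenter contract

The inference stage is a plugin: volume in, label volume out, same shape,
same affine (to 1e-6), non-negative integer labels. Outputs are validated
before anything flows downstream; violations and plugin crashes surface as
typed errors attached to the series' summary row, and the pipeline
continues with the next series.

The shipped reference segmenter thresholds an HU band and then filters
26-connected components (drop those below a minimum size; optionally keep
only the largest, ties broken by earliest component in column-major scan
order — a documented, deterministic choice). On a noise-free phantom whose
lesion HU lies inside the band and background outside, it provably recovers
the ground-truth mask exactly, which is what makes exact end-to-end volume
assertions possible. It stands in for a trained network; real models plug
in either as R functions or through the external-command adapter, which
materializes the volume as `input.nii.gz`, runs a user command, and reads
back `labels.nii.gz` — the standard file convention for research
segmentation tools.

## SEG encoding choices

* **Binary, not fractional**: masks are hard labels, one bit per voxel,
  packed little-endian within the byte stream (the decoder is checked
  against an independent bit-by-bit unpacking loop).
* **Compact frames**: only slices containing at least one labeled voxel
  get a frame; decoding re-inflates the full grid with zeros elsewhere.
  Every frame carries a derivation reference to its source SOP instance
  and the slice's plane position, and the SEG inherits the source study
  UID, which is what makes the archive's UID tree auditable.
* **Single segment per object**: multi-label masks would be encoded as one
  SEG per label sharing a series. This keeps frame bookkeeping trivial and
  matches single-pathology outputs.
* **Empty masks are an error**, not an empty SEG: a segmentation object
  with no frames is ill-formed. The orchestrator catches the condition and
  ships a zero-volume SR without a SEG, marking the series "empty-result".
* **Display color** is stored the standard way, as 16-bit CIELab. The
  package converts sRGB→CIELab on encode and back on decode; because the
  16-bit Lab grid is much finer than 8-bit RGB, every 8-bit color
  round-trips exactly (asserted over the corner colors and random samples).

## Volumetry and the structured report

Volume is computed along two genuinely independent paths:

* **SEG path**: set-bit count across all frames × row spacing × column
  spacing × measured slice step ÷ 1000.
* **Label path**: nonzero-voxel count × |det(affine 3×3)| ÷ 1000.

For orthonormal direction cosines the two voxel volumes are identical, so
the paths must agree exactly — the test suite requires agreement within
0.1 mL across ≥25 randomized phantoms and observes agreement at
floating-point precision. The slice *step* measured from sorted positions
is used, never the `SliceThickness` tag, because thickness and spacing
differ on gapped or overlapping acquisitions.

The SR is a Comprehensive SR document holding a numeric content item
(concept "Volume", UCUM milliliters, value at full precision) and a text
statement. The statement template is `"<label> volume: <v> mL"` with `v`
rounded to one decimal and rendered without a trailing ".0" when integral
("Splenic volume: 40 mL", "splenic volume: 44.4 mL"). Alternative display
phrasings such as "splenic vol: 44.4 mL" are treated as viewer-side
variants of the same canonical template. The numeric item always carries
the unrounded value; only the human-readable text rounds.

Before building the SR, the orchestrator re-validates the SEG against the
routed series (every frame reference must resolve, the study UID must
match) and cross-checks the two volume paths, failing fast on
disagreement — a deliberate choice where the behavior was otherwise open.

## Orchestration and transport

The pipeline runs single-process with pluggable transports: an inbox
directory stands in for the inbound store service and an archive directory
for the query/retrieve archive, so the hermetic mode used by the tests and
the demo is the deployment mode with directories in place of network
endpoints. The module boundary mirrors the two-host split (router side vs.
processing side), which keeps a networked deployment a configuration
change. A DICOM network transport (DIMSE association handling) is out of
scope for this package; the sink interface is the seam where a store
client plugs in.

Each series gets a unique working directory holding `image.nii.gz`,
`labels.nii.gz` and `seg.dcm` — useful both for debugging and as the file
interface for external models. Per-stage wall-clock timings (archive,
convert, inference, encode, report) are recorded in the run summary, so a
site can produce its own end-to-end timing breakdown on its own hardware;
no timing number is asserted by tests, since clock times are
hardware-bound.

## Problem sizes used in verification

The package's own verification runs on deliberately small grids so the
whole suite stays fast and deterministic: randomized phantoms of 16–32
pixels in-plane and 6–14 slices for codec and volumetry properties (25
specs), 10 phantoms × 20 random indices for the geometry oracle, 100
randomized schedules for the timeout state machine, a 40-slice 64×64
phantom for the end-to-end demo, and 2/1/0.5 mm isotropic grids (up to
53³ voxels) for the convergence check. These sizes are choices about test
economy, not limits of the implementation: the generator and codec handle
full 512×512×200 series; they are simply not needed to establish the
properties above, all of which are resolution-independent or explicitly
tested under refinement.

## Known limitations

* Only the Explicit VR Little Endian transfer syntax is read and written;
  compressed or implicit-VR input must be transcoded upstream.
* Single-frame CT input only; multi-frame enhanced CT, gantry-tilt
  correction and resampling are out of scope.
* Series with non-uniform spacing, duplicate positions, or mixed
  orientation are rejected fail-fast rather than repaired — silently
  mis-assembled geometry is worse than a refused series.
* No DICOM network services (store SCP/SCU, query/retrieve) and no viewer;
  directory transport and the sink interface mark the integration points.
* The anonymizer implements a documented subset of the Basic Profile
  suitable for phantom and research traffic, not a certified full-profile
  de-identification.
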