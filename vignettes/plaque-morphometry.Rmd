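---
title: "Gap-junction plaque morphometry from nanogold SBF-SEM stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap-junction plaque morphometry from nanogold SBF-SEM stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquemorph)
```

## The measurement problem

Gap junctions couple cardiomyocytes electrically at the intercalated disc
(ID). In serial block-face scanning electron microscopy (SBF-SEM) of tissue
in which connexin-43 (Cx43) has been immunolabelled with silver-enhanced
nanogold, a gap-junction plaque appears in each 50 nm section as **two
parallel, closely packed strings of dark beads**, one string per apposed
membrane. Three structural readouts carry the biology:

* **Area per length** — the intercellular area enclosed between the two
  bead strings in a section, divided by the plaque length in that section.
  Units reduce to nm: it is the mean inter-membrane gap. Widening of this
  space reflects loss of mechanical/adhesive integrity at the disc.
* **Maximal width** — the widest point between the two membranes anywhere
  in the plaque (over all sections): localized bulging of the
  intercellular space.
* **Hemiplaques** — stretches where one membrane carries a run of Cx43
  label with no opposing label in register: orphan (undocked) hemichannels
  rather than complete intercellular channels.

These quantities were originally measured by hand on volume EM
reconstructions. `plaquemorph` implements the same definitions as an
automated, testable pipeline, and — because raw EM volumes of this kind
are rarely deposited — pairs it with a synthetic stack generator that
produces the same imagery with complete ground truth, so every stage can
be validated by parameter recovery.

## The generative model

A plaque is a smooth planar ribbon: a natural cubic spline through
control points, arc-parameterized at ~1 nm. The local inter-membrane gap is

$$ g(s, z) \;=\; g_0 \;+\; \sum_j A_j \, m_j(z) \,
   \exp\!\left(-\frac{(s - c_j)^2}{2 w_j^2}\right), $$

a baseline $g_0$ plus Gaussian bulges of amplitude $A_j$, arc center
$c_j$ and width $w_j$; $m_j(z)$ interpolates the amplitude linearly across
the spanned sections, because biological bulges persist across several
50 nm cuts. The two bead strings lie at perpendicular offsets
$\pm g(s,z)/2$ from the midline.

Bead placement is **paired by default**: one renewal stream of arc
positions per section (mean spacing 50 nm, jitter s.d. 8 nm truncated at
±2 s.d. so ordering is preserved), and both sides receive a bead at each
position up to a small registration jitter (s.d. 5 nm, truncated). This
mirrors the biology — opposing beads label the two connexons of docked
channels, so label sits in register across the gap. An `independent` mode
(each side its own stream) is available; with independent streams the
sides drift out of arc register and mutual-nearest pairing fails in
patches, which produces hemiplaque-like artifacts no real plaque shows.
**Orphan runs** delete the named side's beads over an arc interval; the
surviving single strand is the ground-truth hemiplaque.

Rendering: beads are inverted Gaussian spots with full width equal to the
sampled diameter (uniform 10–20 nm, the silver-enhancement size band) and
amplitude `bead_contrast` (0.55 of the dynamic range); membranes are faint
dark curves at 30% of bead contrast; the background sits at 0.75 with a
smooth mottle (s.d. 0.05, 200 nm correlation length) and additive Gaussian
noise (s.d. 0.04). Overlapping stamps combine by maximum, so the darkness
of touching beads stays bounded. Default voxels are 3.5 nm laterally and
50 nm axially; since bead diameters never exceed the section thickness,
each bead exists in exactly one slice. All randomness flows from one seed;
identical inputs and seed reproduce the stack bit for bit.

These rendering and cohort parameters were fixed once, as a plausible
emulation of silver-enhanced backscatter imagery, before any recovery
experiments; they are conditions, not tuning knobs.

### What the generator does not emulate

No organelles (mitochondria, desmosomes, myofibrils), no section
compression or alignment jitter, no charging or detector artifacts, no
electron-optical point-spread model. Passing recovery tests therefore
demonstrates the pipeline's correctness on geometry and photometry like
this, not robustness to every pathology of real acquisitions; on real
data the detector threshold and the clustering radius are the parameters
to revisit first.

## Detection

Beads are dark, round, and of known size, so the detector is a per-slice
scale-normalized Laplacian-of-Gaussian filter bank with scales matched to
the 10–20 nm diameter band ($\sigma = d / 2\sqrt{2\ln 2}$, four scales),
maxima over position and scale, a response threshold, greedy non-maximum
suppression at 12 nm, then two-stage subpixel refinement: quadratic
interpolation of the response peak followed by an iterative
Gaussian-weighted centroid of inverted intensity. On synthetic fixtures
the refinement chain localizes beads to ~0.4 nm (about a tenth of a
pixel); both precision and recall exceed 0.9 at a 15 nm match radius.

The response threshold (0.12 on intensities in [0, 1]) was calibrated on
synthetic fixtures only: a matched bead yields a response of roughly half
its contrast (~0.27), a membrane ridge roughly half of its own (~0.08),
so the default sits between the two. It is exposed in
`detection_params()`.

## Reconstruction

Detections are grouped into plaques by single-linkage connected
components in physical 3D coordinates (z scaled by the section thickness;
link distance 150 nm, three bead spacings), with components below 6 beads
discarded. Per slice:

1. **Ordering.** Beads are ordered by projection onto their principal
   axis. If that ordering folds the arc (ordered path longer than 1.6×
   the diameter path of the Euclidean minimum-spanning tree), the MST
   path ordering is used instead. The 1.6 factor separates the two
   failure modes: a genuine fold roughly doubles the ordered path, while
   the MST diameter path of a wide double string may travel up one side
   and back down the other, which must *not* win on gently curved
   plaques.
2. **Midline.** A moving-average curve through the ordered cloud,
   extended 200 nm past both ends along the end tangents (so terminal
   beads project perpendicularly instead of radially onto an endpoint),
   then refined twice toward the true bisector: beads split by offset
   sign, each side's offset profile interpolated along the arc, midline
   moved to their mean. Accuracy on parallel-string fixtures is better
   than 2 nm.
3. **Sides.** The sign of the perpendicular offset assigns side A/B;
   beads within 2 nm of the midline are assigned by neighbour vote and
   flagged. Slice midlines are oriented consistently through the stack
   (chord dot product with the previous slice), which propagates the
   labelling.
4. **Inner space.** Side polylines join bead centroids in arc order (no
   smoothing). Both sides are trimmed to their common arc overlap, capped
   with straight end segments, and the enclosed area computed by the
   shoelace formula. Ends where only one side extends are excluded from
   area but remain eligible as hemiplaque evidence. A self-intersecting
   contour is repaired by shrinking the interval (5% steps) and flagged.

The area is deliberately measured between the *bead strings*, not
image-intensity membrane traces: that is the structure the labelling
defines, and it is what was drawn by hand in the original workflow.

## Morphometrics

Per plane: length = midline arc length over the trimmed overlap; area;
area/length. Per plaque: the unweighted mean of plane ratios (plane counts
are reported so a weighted reanalysis is possible), and the maximal width
as the supremum of the inter-polyline perpendicular distance sampled at
≤5 nm arc steps over all planes — a supremum over the structure, not over
bead vertices.

Pairing is mutual-nearest on arc position, accepted when the arc offset is
within 0.6× the slice's median within-side bead spacing (scale-free) and
the Euclidean separation is at most 120 nm (generously above the widest
bulge, so widened-but-docked regions do not masquerade as orphans).
Hemiplaque segments are maximal runs of ≥3 consecutive unpaired beads on
one side spanning ≥100 nm (~2 bead spacings — robust to a single missed
detection), extended by half a spacing at each end; both thresholds are
configurable. Per-slice segment lengths are summed across sections, and
the hemiplaque fraction is 100 × summed hemiplaque length / summed plaque
length. The ground-truth oracle reports the arc-length union of the
generating orphan runs and its fraction of the arc length; numerator and
denominator conventions differ from the recovered ones by the slice
count, which cancels in the fraction — the fraction is therefore the
quantity compared in recovery tests.

## Statistics

The original protocol is reproduced exactly: each group is tested with
Shapiro-Wilk and Kolmogorov-Smirnov, and counts as normal when it passes
*either* at p > 0.05. Because the normal parameters are estimated from
the sample, the KS p-value uses the Lilliefors correction (a naive-KS
flag exists for auditing). Two normal groups are compared with the
two-sided pooled-variance Student's t (Welch behind a flag); otherwise
Mann-Whitney, exact by full enumeration of rank assignments when both
n ≤ 8 (valid under ties; `stats::wilcox.test` declines exact p-values
with ties) and a tie- and continuity-corrected normal approximation
otherwise. Significance is p < 0.05; no multiple-testing correction is
applied, and the number of comparisons is recorded in the report.
Box-whisker summaries are five-number min–max summaries with type-7
(linear interpolation) quartiles.

## Validation design and problem sizes

* **Oracle equivalences** (dual routes): shoelace vs grid-counting areas;
  single-linkage clustering vs brute-force connected components; exact
  Mann-Whitney vs the exact Wilcoxon distribution and brute-force
  enumeration; pooled t vs its closed form.
* **Detection quality**: precision/recall ≥ 0.9 on two-genotype fixtures
  over five seeds.
* **Parameter recovery**: cohorts of 20 control-like plaques (gap
  ~N(20, 2.5) nm, no orphans) and 20 KO-like plaques (baseline
  ~N(25, 4) nm, bulges rescaled to a widest point of 70–100 nm, orphan
  runs in ~60% of plaques covering ~20% of the arc when present), each
  plaque 1.2–2 µm long over 5–8 sections in its own stack, full image
  pipeline. Group-mean recovery errors, averaged over seeds 1–5: area
  per length and maximal width within 15% relative, hemiplaque fraction
  within 5 percentage points, hemiplaque prevalence within 10 points.
* **Directional replication**: 100 simulated cohorts (n = 20/group) of
  ground-truth metrics pushed through the gate + test protocol; the
  KO-like group must be significantly larger on area per length, maximal
  width and hemiplaque fraction (direction assessed on group means — the
  KO *median* fraction is legitimately 0 whenever fewer than half its
  plaques carry orphan runs). Ground-truth metrics are used here because
  the replicate count is about the statistical protocol, not the image
  chain, which the recovery experiment already exercises end to end.

These problem sizes (one plaque per stack, 5–8 sections, ~40–60 beads per
section) were chosen as the smallest instances that still contain every
structural feature the measurements depend on.

## Numerical choices and degenerate inputs

Quantization to 8 or 16 bits happens once at generation; detection runs on
the stored values, so TIFF round-trips are lossless. Zero-variance samples
fail the normality gate explicitly (flagged degenerate). Slices with fewer
than 4 beads are skipped with a warning; a side with a single bead
contributes no polyline but still counts as hemiplaque evidence. Arc ties
in offset interpolation are broken by a 1e-9 nm perturbation. The
clustering grid uses cell binning, so it is exact (not approximate) with
respect to the link distance.

## Known limitations

* The inner-space area between orphaned stretches uses a straight chord
  across the gap in the bead-less side's polyline, slightly underestimating
  the area of bulged orphan regions relative to the generative truth.
* The maximal width, as a supremum over noisy offsets, carries a small
  positive bias (~1 nm at the achieved localization accuracy) on
  constant-gap plaques.
* Hemiplaque runs shorter than ~2 bead spacings are below the calling
  thresholds by design and are missed; the group-level fraction absorbs
  this within its tolerance.
* Plaques curved beyond a semicircle within one slice rely on the MST
  ordering path; a full principal-curve iteration is not implemented.
* No hierarchical modelling of heart/ROI nesting: plaques are pooled as
  in the original protocol, but heart and ROI identifiers are retained in
  the tables so users can reanalyze with mixed models.
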