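---
title: "Methods: colony detection, screening and coordinate mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colony detection, screening and coordinate mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its own methods: the assumptions
behind each stage, the tunable parameters and why their defaults are what
they are, what the synthetic plates do and do not emulate, and the design
choices that were genuinely open.

## The detection model and its assumptions

The pipeline assumes a single circular Petri dish photographed from above:
a bright plastic wall ring on a dark deck, agar of roughly uniform
brightness, and colonies that are *locally brighter than the agar around
them* with a single intensity maximum each. Everything downstream leans on
those two properties.

**Dish detection.** Sobel gradients are computed over the full image and
the ~6,000 strongest edge pixels vote for circle centres along their
gradient direction, at every admissible radius (derived from the configured
85–89 mm outer-diameter range and the mm/px scale). The accumulator peak is
only used as a seed: the final centre and radius come from an algebraic
(Kasa) least-squares circle fit to the edge points near the outermost
radius-histogram peak, iterated once on refreshed inliers. The fit is
what delivers sub-pixel accuracy; the Hough vote only needs to be right to
a few pixels. Detection fails with an explicit error when edge support is
too thin (blank image) or the fitted diameter falls outside the configured
range.

**Inner-plate segmentation.** The crop is blurred (Gaussian, σ = 0.15 mm)
and compared against its local Gaussian-weighted mean: a pixel is
foreground when it exceeds that mean by 3 gray levels (offset C = −3 in
the usual adaptive-threshold convention, threshold = mean − C). Two
parameters matter here:

* *block size*, default 2.5 mm — the averaging window must be wider than
  the structure to detect. Colonies in this domain reach ~2.5 mm radius,
  and their apex is nearly flat; with a window much smaller than the
  colony, the apex of a large low-contrast (blue) colony rises only 2–4
  gray levels above its neighbourhood mean and drops out. At 2.5 mm the
  apex excess is roughly twice that, while the smallest colonies (0.6 mm
  radius) are unaffected because they fit inside the window entirely.
* *offset*, default −3 gray — the post-blur noise floor is ≈ 0.6 gray
  (σ = 3 sensor noise attenuated by the 1.5 px blur), so 3 gray is a ≈ 5σ
  criterion: flat agar essentially never fires, and stray single pixels
  that do are removed by the minimum-area filter (area of a 0.3 mm-radius
  disc).

Each surviving component is replaced by its filled convex hull (Sklansky
via `grDevices::chull`, scanline-rasterized). This is what makes the
block-size choice forgiving: a large colony detected as an apex cap plus an
edge ring still hulls to its full footprint. Thresholding is restricted to
the inner disc — dish radius minus the 2 mm wall minus a 0.5 mm *edge
guard*. The guard exists because the agar-to-wall brightness ramp, smeared
inwards by the blur and shifted by residual dish-fit error, otherwise
leaks thin bright arcs into the mask whose convex hulls balloon into large
false segments.

**Border annulus.** The annulus between the guarded inner disc and the
crop bounds is treated separately: multiplicative uniform speckle noise
(±20%) is injected in the annulus, edges are found with a Canny-style
operator (Gaussian smoothing at 0.2 mm, Sobel gradients, hysteresis at
0.1/0.3 of the annulus intensity range), the plastic border is removed by
discarding edge pixels that sit on the fitted wall circles *and* point
radially (|cos∠(gradient, radius)| > 0.94 within ±4 px of either wall
circle — a colony outline crossing the wall is locally tangential there,
so it survives), then erosion, hole filling, and subtraction of a top-hat
debris residue (structuring element 0.5 mm). Edges are computed over the
whole crop so the outline of a colony straddling the wall stays closed and
can be hole-filled; only the output is masked to the annulus, which abuts
the guarded inner disc exactly — a gap between the two masks would cut a
straddling colony in two. A blue colony lying *on* the bright wall is
nearly contrast-free and may be missed; such colonies are unpickable
anyway, which is why the wall margin exists.

**Group splitting.** Regional maxima of the smoothed grayscale
(σ = 0.3 mm) inside each colony segment are accepted brightest-first under
a minimum separation d_min = 0.8 mm; k ≥ 2 accepted maxima split the
segment by seeded region growing (`EBImage::propagate`) on the smoothed
intensity — a marker-controlled watershed — and the segment's sublabel
becomes "k colonies". The two constants bracket the geometry: 0.8 mm is
below the 1.2 mm minimum colony diameter, so genuinely touching colonies
(centre distance ≳ 0.75 of summed radii) always present two maxima farther
apart than d_min, while the smoothing scale is far above the residual
noise, so a single colony's flat apex yields maxima only within 1–2 px of
each other, which the separation rule merges. Spurious splits of single
colonies remain possible at low frequency on irregular real colonies;
aspect-ratio or circle-search filters were deliberately left out of scope.

## Measurement, screening, mapping

Area is the raw mask pixel count times scale²; the equivalent diameter is
that of the equal-area disc. Hue is averaged on the unit circle (a white
population straddling the 0°/360° wrap must not average to cyan), and the
colour mark uses Euclidean distance in the HSV cone embedding
(S·V·cos H, S·V·sin H, V), which both handles the wrap and collapses hue
for desaturated or dark pixels where hue is meaningless. All three marks
are normalized per candidate set (min–max for size, /255 for fluorescence,
/d_max for colour), so a score is a *ranking* within one run, not an
absolute calibration; degenerate normalizations (single candidate,
all-equal values) give the mark 1. Ties in the total score break by
ascending colony id, making selections deterministic and
input-order-invariant.

Coordinate mapping is exact bookkeeping: crop-local centroid → offset from
the crop-local dish centre → plus the dish-to-labware offset → ×scale →
image-to-right-handed conversion (y negated) → 90° anticlockwise rotation
(u, v) → (−v, u) → per-axis sign flags. The handedness of a deployment's
camera mount is not knowable from software, hence the sign flags; the
inverse map is provided and round-trips to < 10⁻⁶ px, which the tests
assert.

## What the synthetic plates emulate — and what they don't

The generator renders: an 85–89 mm dish (bright wall, agar fill) on a dark
background; 12–453 colonies as truncated Gaussian domes (σ = r/2,
alpha-blended so overlaps don't double brightness), radii 0.6–2.5 mm; a
configurable fraction in touching pairs/triples (centre distance 0.78–0.95
of summed radii) and a fraction inside the 2 mm wall margin; two colour
phenotypes (white / X-gal blue, 50/50); an optional flat-disc fluorescence
channel; a linear illumination ramp (±10%); Gaussian sensor noise (σ = 3
gray); and a few sub-0.5 mm dust specks. Placement is rejection sampling
with a 10,000-retry budget per colony, radius resampled per attempt (dense
plates fill with smaller colonies, as crowded real plates do); exceeding
the budget is an explicit error, not a silent shortfall. Everything is
quantized to 8 bits, and all randomness derives from the plate seed with
the caller's RNG state restored, so a seed fixes the image bit-for-bit.

Not emulated: lens distortion, specular highlights, agar texture and
condensation, irregular or nested colony morphologies, colony-colour
gradients, and artifact types beyond small bright specks. Passing the
synthetic benchmark therefore demonstrates the pipeline's *logic* —
counting, splitting, screening, mapping — under controlled difficulty; it
does not certify performance on real photographs, where threshold and
blur parameters would be re-fitted the same way they were fitted here, on
plates with known counts.

The dome profile is not incidental: single-maximum, radially decaying
colonies are exactly the assumption the splitter exploits, so the
generator and detector meet at the same model of what a colony is.

## The canonical benchmark and problem sizes

`benchmark-v1` is fixed in code: 20 plates, master seed 42, per-plate
colony counts uniform on 12–453 (≈ 4,000 colonies in total), group
fraction 0.10, border fraction 0.05, 3 artifacts, ±10% illumination,
σ = 3 noise, 0.1 mm/px, 940 px images. Per-plate parameters are drawn once
from the master seed, so plate *i* is reproducible in isolation and the
benchmark can be streamed plate-by-plate in constant memory. Twenty plates
keep a full run (generation + detection + matching) in the
few-minutes range on one CPU while still spanning the sparse-to-crowded
load range; the unit tests use smaller 30 mm dishes at 340 px for the same
reason. Matching uses greedy nearest-neighbour pairing at 1 mm tolerance —
the scale of both the picking tolerance and the minimum colony size — and
detection-style metrics without true negatives: sensitivity TP/(TP+FN),
precision TP/(TP+FP), accuracy TP/(TP+FP+FN) (a Jaccard-type score, hence
never above either), raw performance TP/truths. Detections matched to
colonies inside the wall margin are bookkept separately (`not_pickable`)
rather than counted as noise, mirroring how a manual audit distinguishes
"real but unreachable" from "false".

## Open choices and their resolutions

* **Adaptive-threshold block and offset** (2.5 mm, −3 gray): fitted on
  synthetic fixtures against known counts, as described above.
* **Speckle amplitude and Canny thresholds**: ±20% multiplicative noise
  with hysteresis at 0.1/0.3 of the annulus range; smoothing inside the
  Canny operator is what keeps the speckle field itself below threshold.
* **Wall suppression**: geometric (fitted circles + radial-gradient test)
  rather than purely morphological — a 2 mm-wide bright band and 1.2–5 mm
  colonies overlap in every single-scale morphological criterion we
  examined, while the fitted circle is known to sub-pixel accuracy anyway.
* **Augmentation bookkeeping**: the 16 rotation×mirror combinations minus
  the identity give 15 derivatives per source; only 8 are geometrically
  distinct (dihedral group), and the coincident ones are retained as
  separate dataset entries to match the established ×15 accounting.
* **Split grouping**: train/validation splitting is grouped by source
  image so augmented copies of one plate cannot leak across the split;
  sizes are matched to round(0.75·n) at the nearest source boundary.
* **Destination order**: column-wise (A1, B1, …) — the order a multi-well
  plate is filled during a picking run.
* **Unpickable margin** 2 mm and **minimum diameter** 1 mm: the margin
  keeps the tip clear of the plastic wall; below ~1 mm equivalent
  diameter, positioning error makes transfers unreliable.

## Known limitations

Blue colonies on the wall band are near-invisible (above); heavily
overlapping same-colour pairs closer than ~0.75 of summed radii merge into
one maximum and are counted as one; dust specks larger than the minimum
colony size are indistinguishable from colonies by design; and the scores
are per-run rankings, so thresholds on them do not transfer between
plates. The classical detector is deliberately replaceable: any callable
producing a segment map can take its place behind the same interface.
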