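---
title: "Methods: from binary worm masks to posture, tracks and calcium traces"
author: "nemaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from binary worm masks to posture, tracks and calcium traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemaquant)
```

# Scope and assumptions

`nemaquant` starts where a segmenter stops: it consumes per-frame binary
masks of *C. elegans* (from a foundation vision model, a threshold, or any
other source) and produces morphometry, swimming posture metrics, crawling
tracks and calcium-imaging fluorescence traces. The package deliberately
contains no segmentation model; everything downstream is deterministic,
inspectable image geometry and signal processing.

Assumptions on the inputs:

* one worm per mask (multi-worm scenes are reduced to per-worm masks by the
  candidate filtering stage);
* image coordinates `(row, col)` with row 1 at the top; masks are logical
  matrices the size of the frame;
* video frames are contiguous and equally spaced in time (`fps` known).

# Mask post-processing

Candidate masks from a segmenter are cleaned in four steps. Masks touching
the frame border are excluded outright, since partially-imaged worms bias
every morphometric feature. Overlapping candidates (a segmenter often emits
several masks covering sub-parts of one body) are grouped into connected
components of the pairwise-overlap graph and only the largest-area mask per
component survives, so each worm is counted once. Small speckle components
are removed by connected-component analysis with a configurable minimum
area (default 50 px) and connectivity (default 8; the field's tools vary
here, so both 4 and 8 are supported). Finally, video streams undergo
per-frame quality control (empty, oversized — default threshold 5x the
median stream area — and sibling-overlapping masks are flagged, never
silently dropped), and isolated missing frames are filled by temporal
interpolation: the pixelwise union of the nearest non-empty neighbours
reduced to its largest component. Gaps longer than 3 frames are refused
with an error; a dropout that long is a segmentation problem, not an
interpolation problem.

Classification of candidates into worm / not-worm is a pluggable predicate.
The default is a transparent shape heuristic — elongation (centerline
length over mean width) at least 4 and bounding-box solidity inside
[0.02, 0.7] — which makes the pipeline fully testable without trained
weights; a learned classifier can be dropped in without touching anything
else.

# Centerline extraction

The skeleton chain is the technical core of the package:

1. **Thinning.** Iterative two-subpass morphological thinning reduces the
   mask to an 8-connected, one-pixel-wide skeleton.
2. **Graph analysis.** Skeleton pixels become graph nodes; 8-neighbour
   edges carry Euclidean weights (1 or sqrt(2)). Diagonal edges whose two
   pixels share an orthogonal skeleton neighbour are dropped — they are
   redundant and would create spurious 3-cycles. The centerline is the
   maximum-total-length simple path between two degree-1 endpoints; side
   branches disappear by construction, and ties break towards the
   lexicographically smallest endpoint pair so results are reproducible.
3. **Self-touch correction.** Deeply bent postures (O- and 6-shapes) make
   the worm touch itself, so the raw skeleton contains loops. While the
   skeleton graph has cycles, the cycle edge whose deletion least reduces
   the maximum endpoint-to-endpoint path length is removed. For a closed
   ring this opens the loop at the cheapest point; for a 6-shape it opens
   the loop right at the stem junction, so the path traverses stem and
   loop perimeter once. The algorithm itself is this package's design (the
   goal — one continuous skeleton per frame — is what is fixed); it is
   isolated behind `correctSelfTouching` and swappable.
4. **Tip extension.** Thinning erodes the skeleton short of the body tips
   by roughly half the local width. Each end is extended along its
   outward tangent to the mask boundary, capped by the distance-transform
   value at the endpoint so blunt ends do not run into a corner. Without
   this step body length is systematically underestimated by up to ~10%
   on short worms.
5. **Spline resampling and ridge refinement.** The path is smoothed by a
   cubic smoothing spline per coordinate against cumulative arc length and
   sampled at 100 equally spaced parameters. Because the thinned path
   carries coherent sub-pixel wiggle that corrupts curvature, each point
   is then moved along its local normal to the parabolic maximum of the
   mask's distance transform (the medial ridge) and the spline is refit
   with 12 effective degrees of freedom. The refinement is worth an order
   of magnitude in curvature accuracy; the final df value trades residual
   ridge noise against the ability to follow deep bends (a full O-loop
   needs roughly 8 df; 12 leaves headroom without readmitting noise).
6. **Widths.** Width at a point is the extent of the mask along the local
   normal, i.e. a diameter, not a half-width (the convention is stated
   because published descriptions leave it open). It is computed as
   `2 d - 1` from the distance transform (pixel-as-unit-square boundary
   convention) and cross-checked by direct normal ray-casting; when the
   two disagree by more than 20% — near strong bends, where the distance
   transform sees the opposite wall — the ray-cast wins.

Morphometry then reports mask area (true-pixel count), boundary-polygon
perimeter, centerline length (sum of consecutive-point distances) and the
width profile. Skeletons remain orientation-agnostic until a tracking or
device-geometry stage assigns the head.

# Posture metrics

**Curvature** is the arc-length derivative of the tangent angle, smoothed
with a normalized Gaussian kernel of window 50 points and sigma 10 points
along the 100-point skeleton (these defaults are the field-standard
configuration for this representation and are exposed as
`posture$curvature_window` / `curvature_sigma`). Signs are consistent along
the body: positive bends toward the left of travel along increasing point
order. Reversing the point order flips the sign and preserves magnitude.

**Amplitude** is the per-point perpendicular distance to the straight
head–tail chord. When the endpoints (nearly) coincide — closed O postures;
the threshold is 2% of body length — the chord is replaced by the line
through the two most distant skeleton points and the result is flagged.

**Shape classes** are assigned by a decision cascade on two dimensionless
features: total bend `mean |curvature| * length` (radians) and normalized
amplitude `max amplitude / length`. A frame whose body length falls more
than one standard deviation below the video mean is classified `turned`
(out-of-plane roll shortens the projected body) before anything else, which
is why classification requires two-pass processing. Then: at least two
curvature sign changes with low amplitude mark the S-family (`s_shape`
above 2.2 rad of total bend, otherwise `mild_s`); very high bend with
moderate amplitude is `six_shape` (>= 5.0 rad), high bend with high
amplitude `o_shape` (>= 4.2 rad), moderate bend (>= 1.1 rad) splits into
`u_shape` / `c_shape` at normalized amplitude 0.34, and everything else is
`straight`. The numeric boundaries were calibrated once on the synthetic
exemplar of each class (the generator shapes were designed to sit at the
class archetypes) and are shipped as an editable table
(`shapeThresholds()`); published sources describe the classes verbally
without printing thresholds, so these values are this package's own and
will not reproduce any particular laboratory's frame-by-frame labels.

**Wavelength** follows the class: for S-shapes, twice the mean arc-length
spacing between successive curvature extrema of alternating sign
(peak floor: 25% of the profile maximum); for C-shapes, fixed at twice the
body length; none for straight or turned frames. U/O/6 shapes are a single
deep bend and follow the C rule, flagged as such. Wave number is body
length over wavelength.

**Spatial frequency** is the argmax of the DFT magnitude spectrum of the
mean-subtracted curvature profile, in cycles per body length (zero bin
excluded; a constant profile returns none).

**Temporal frequency** analyses the z-scored per-frame mean absolute
curvature series in sliding windows of 30 frames with 25 frames overlap
(step 5; the sliding step is stated explicitly because "overlap" alone
leaves it ambiguous). Each window yields a Hann-windowed, mean-removed
power spectral density; the highest-power spectral peak — or, when no peak
exists, the highest-power frequency — is assigned to the window center,
and window values are linearly interpolated (constant extension at the
ends) so every frame has a dominant frequency. The frequency resolution is
fps/30; recovery tests therefore assert agreement within one bin.

# Crawling tracks

Wide-field recordings are too coarse to find the head by brightness, so
head identity is temporal: endpoint pairs are first chained frame-to-frame
by the optimal 2x2 assignment (the general formulation is the assignment
problem; with two endpoints the optimum is a comparison of the two
pairings), then, within every 5-frame sliding window, the endpoint group
with the larger cumulative displacement is voted head — worms lead with
the head and it oscillates. Votes from overlapping windows are aggregated
per frame by majority; on displacement ties (a perfectly still worm) the
previous call persists, so assignments never flip without evidence. A
second pass repairs single-frame swaps: a head jumping more than 3x the
median recent head displacement *onto the previous tail position* (so that
swapping reduces the discontinuity) is flipped back. Genuine fast
manoeuvres move the head somewhere new and are untouched.

The head-bend angle is the signed angle between the principal axis of the
posterior 85% of the skeleton (total least squares, oriented anteriorly)
and the vector from the head-region base to the head tip; `head_fraction`
defaults to 0.15 because the anatomical "head" has no fixed pixel extent
at this resolution.

Centroid paths are smoothed per coordinate with a Savitzky–Golay filter
(window 11 frames, polynomial order 3) — polynomial smoothing preserves
genuine accelerations that a moving average would blunt, and reproduces
straight-line motion exactly. Motion classification compares each frame's
centroid velocity with 0.5 px/frame: below is `stationary`; otherwise the
sign of the projection onto the centroid-to-head axis separates `forward`
from `backward`, with an exactly perpendicular velocity deterministically
`stationary`. (One published account of this procedure states the
stationary cut-off as 0.6 px/s in a figure caption and 0.5 px/frame in the
methods; the methods value is the default here and the threshold plus its
unit are configuration.) Isolated label runs shorter than 3 frames flanked
by one common, jointly credible state are relabelled iteratively to a
fixpoint; rapid alternations with no credible flank stay untouched.
Maximal constant-label runs become bouts with duration and travelled
distance; path summaries report total path length, maximum displacement
from origin, state fractions (which sum to one exactly) and mean bout
durations.

All tracking outputs are invariant to global rotation and translation of
the scene.

# Calcium imaging

The recording geometry is a microfluidic device imaged at 512x512 px and
10 fps, with the worm's head facing the stimulus stream; head orientation
therefore comes from device geometry (the skeleton end nearer the tracked
neuron region), not from temporal tracking.

A fixed 110x110 px crop window is centred on the rounded mean of the
per-frame region centers of mass and clamped inside the frame, so
compartment coordinates are comparable across the video. Background is
estimated by distance-transform analysis: 100 single-pixel samples drawn
uniformly without replacement (fixed, configurable seed) from pixels at
least 40 px from any segmented structure; if too few pixels qualify all
eligible ones are used, and the distance requirement halves (flagged)
rather than failing. Background can be applied per frame (default) or as
the recording mean (`background_mode = "recording"`), which is preferable
under stationary illumination since it removes the sampling variance from
every frame; which of the two a published trace used is generally not
recoverable, so both are first-class.

Per-compartment brightness is the mean image intensity over the mask, and
`corrected = raw - background` elementwise. Traces are normalized min–max
to [0, 1] by default; dF/F with a 10th-percentile baseline is available
(`normalization = "dff"`) because the normalization behind published
figures is typically unstated — comparisons in this package's tests
therefore use normalization-invariant statistics, chiefly the mean
absolute difference from the trace mean, which strictly decreases when
transients are artificially flattened (the failure mode of rigid-ROI
extraction this statistic was designed to expose).

Whole-body head angles use the signed angle between the anterior 30% and
posterior 70% endpoint-to-endpoint vectors, smoothed by a centred 3-frame
moving average. The dorsoventral sign is resolved from the spatial
relationship between the loop and nrD compartments: the sign of the cross
product of the loop-to-nrD centroid offset with the anterior body axis,
by majority over frames, determines the mounting side; angle signs are
flipped if needed so positive means dorsal (the convention is stated in
all outputs). Fiji-style relative ellipse estimates in [-1, 1] can be
mapped onto [-90, 90] degrees for comparison.

# The synthetic generator, and what passing tests mean

`renderWorm` builds masks as unions of disks of the local half-width
centred along an analytic centerline (straight, arc, Cartesian sine,
C/U/O-with-gap/6 shapes), so centerline, curvature and width truth are
exact by construction rather than re-measured. Disk-union rendering was
chosen over polygon rasterization precisely for this analytic width truth.
`renderSequence` translates a worm along its head tangent under a
piecewise-constant motion program while the anterior quarter oscillates
sinusoidally (default 20 degrees at 1 Hz — large enough that the head is
identifiable by mobility, small enough that a stationary worm's centroid
stays under the stationary threshold); truth includes per-frame head
identity, centroid and motion state. `renderFluorescence` paints three
elliptical compartments with programmed intensities over a uniform
background with Gaussian noise.

Default desk-scale conditions: body length 300 px for still worms;
sequences use a 140 px worm in a 512x612 frame, preserving the roughly
0.25% worm-to-frame area ratio of wide-field recordings (the generator's
native 2448x2048 geometry scaled down); fluorescence stacks are 256x256
with background 100 and noise sigma 5 camera units. Tests run tens of
frames per sequence — enough for every window-based estimator to operate —
and the frequency suites use 600-frame scalar series, all chosen so the
full suite exercises every stage at realistic geometry.

What the generator does *not* emulate: texture and illumination gradients,
optics (defocus, diffraction), segmentation errors other than speckle
noise and missing frames, worm self-occlusion in depth, and body-shape
deformation during locomotion (sequences translate a rigid posture with an
oscillating head). Passing tests therefore certify the geometry and
signal-processing chain on clean masks — they do not certify any
particular segmenter, and real recordings will add mask noise that enters
every metric upstream of this package.

# Numerical choices and degenerate inputs

* Thinning of a blob so small it vanishes keeps the central pixel; a
  skeleton reduced to a single point raises a degenerate-posture error.
* Paths shorter than 4 points cannot be splined and error out.
* `smooth.spline` failures (near-duplicate parameters) fall back to linear
  interpolation; post-smoothing duplicate points trigger the same
  fallback.
* The curvature kernel reflects the angle series at both boundaries, which
  is exact for constant curvature; the first and last interior values are
  replicated to the endpoints.
* Natural-spline end bias rolls curvature off over roughly the outer
  quarter of the body; curvature guarantees therefore apply to interior
  points (the central half), and tests assert exactly that.
* Tie-breaks are deterministic everywhere: lexicographic endpoint order in
  path extraction, first-candidate edge deletion in self-touch correction,
  persistence on head-vote ties, `stationary` on zero velocity projection.
* Empty inputs: empty candidate lists produce empty tables with warnings,
  not errors; all-false masks are returned unchanged with a warning.

# Known limitations

* A perfectly closed O (endpoint separation below the amplitude fallback
  threshold) has no meaningful head–tail chord; the fallback line through
  the two most distant points yields a lower amplitude than a nearly
  closed O, so fully closed rings can classify as `six_shape`. The
  generator's O family always leaves a gap.
* Head identity requires head mobility. A sequence with zero head
  oscillation and rigid translation is genuinely ambiguous (both ends are
  equally mobile), and the assignment falls back to a persistent but
  arbitrary choice.
* Perimeter is the boundary-pixel-center polygon length; digital
  perimeters carry shape-dependent bias of a few percent (underestimates
  rectangles, overestimates disks) that no single estimator removes.
* Motion classification near bout transitions inherits the Savitzky–Golay
  window's smearing; guarantees hold beyond 2 frames of a transition.
* Multi-worm tracking across collisions and omega-turn event detection are
  out of scope.
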