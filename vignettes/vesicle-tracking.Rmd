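---
title: "Tracking vesicles in noisy fluorescence movies: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking vesicles in noisy fluorescence movies: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`vestrack` tracks small, fast, sub-resolution particles — typically
post-Golgi transport vesicles — in 2D time-lapse fluorescence movies where
the particles of interest share the channel with much brighter nuisance
structure (Golgi ministacks, diffuse ER signal, out-of-focus blobs). This
vignette explains the models behind each stage, the parameters that matter,
and the choices made where the design was genuinely open. It states no
empirical result that the package's tests and `scripts/acceptance.R` do not
themselves compute.

## Coordinates and units

`x` is the column and `y` the row, both 0-based with pixel centers on
integer coordinates; frame indices are 0-based. Track files store pixels
and frames only, so they are valid without calibration; micrometres and
seconds are derived on demand from `pixel_size_nm` and `frame_interval_s`,
and any function that needs physical units stops with an error when the
metadata is absent rather than assuming a default.

## Detection

### Preprocessing

The background is estimated per pixel as the mean (optionally median) over
a window of `m` consecutive frames centered on the current frame and
truncated at the sequence ends, then subtracted with clipping at zero. A
centered window treats both temporal directions symmetrically; `m = 20` by
default — long enough that a moving vesicle does not dominate its own
background estimate, short enough to follow slow illumination drift.
Contrast-limited adaptive histogram equalization (CLAHE, via `EBImage`)
then boosts dim spots; frames are min-max normalized first, which makes the
result exactly invariant to global affine intensity changes. Defaults: clip
0.01, 32 px tiles.

Optional drift correction estimates one translation per frame by maximizing
the mutual information of a 32-bin joint histogram against the previous
registered frame (integer grid search ±5 px, parabolic refinement), and
applies cumulative shifts by bilinear interpolation. Only translation is
modeled: specimen drift in these preparations is rigid at the frame scale.

### Multiscale spot enhancement

Each frame is filtered iteratively over a ladder of spot scales
$\sigma^1 < \dots < \sigma^K$. Iteration $k$ convolves the masked image
with a Laplacian-of-Gaussian kernel,

$$f(x, y, \sigma^k) = LoG(\sigma^k) * \bigl(b(x, y, \sigma^{k-1})\, g(x, y)\bigr),
\qquad b(\sigma^0) \equiv 1,$$

and updates the binary mask to $f > T^k$ with the adaptive threshold

$$T^k = \mu^k + c\,\varsigma^k,$$

where $\mu^k$ and $\varsigma^k$ are the mean and standard deviation of the
whole response image. The kernels are scale-normalized (multiplied by
$\sigma^2$) and negated so bright blobs of matching size give positive
peaks of comparable height across scales, and shifted to zero mean so a
constant image maps to a null response (a numerically constant response
yields an empty mask rather than thresholding noise). Defaults:
$\sigma \in \{1.0, 1.5, 2.5, 4.0\}$ px and $c = 0.8$. A low $c$ is
deliberate: the candidate pool is allowed to be noisy because the
classifier that follows is the stage that rejects background, and raising
$c$ enough to suppress noise also starts losing genuine dim spots.
$\mu^k/\varsigma^k$ are computed over the full response image, not only
masked pixels, matching the "mean intensity of the image" reading of the
threshold rule.

Candidates are 3×3 local maxima of the final response inside the final
mask; peaks closer than `min_peak_sep_px` (3 px) merge, keeping the higher
response.

### The patch classifier

A small CNN decides, per 16×16 candidate ROI, spot versus background:
3×3×16 conv → ReLU → 3×3×32 conv → ReLU → 2×2 max-pool → 64-unit dense →
ReLU → 2-way softmax. It is trained with binary cross-entropy and RMSprop
(lr 10⁻³, decay 0.9), and the training set is augmented with the three
right-angle rotations and horizontal/vertical flips (×6). Patches are
min-max normalized individually, so classification depends on shape rather
than absolute brightness. The network is deliberately tiny: a few hundred
annotated ROIs suffice, and the same weights transfer across movies when
the particle appearance is similar. Training is exactly reproducible:
seeded initialization, shuffling and augmentation, and single-threaded
deterministic linear algebra. The forward/backward passes are implemented
directly on im2col-style matrices; gradients were verified against central
differences during development.

Candidates are accepted when the spot-class probability reaches `p_min`,
0.99 by default. That threshold looks severe for a probability but is the
right operating point for this classifier: on genuine spots the softmax
saturates (matched truth positions almost all score above 0.9999), while
background candidates that slip past the filter spread broadly below, so
a high bar keeps essentially all true spots and removes an order of
magnitude more background than a 0.5 bar does. Lower it when particles
are so dim or so unlike the training patches that their probabilities no
longer saturate.

Two practical notes. First, the classifier should be trained on patches
rendered under the *same imaging conditions* it will prune (the
`render_training_patches()` generator draws negatives from diffuse
background, distractor cores and distractor rims of the same scenario);
a mismatched training scenario can multiply the false-detection rate by an
order of magnitude. Second, candidates within `roi_px/2` of the frame
border are rejected rather than padded — both the classifier and the
centroid refinement need complete windows.

### Subpixel localization

Accepted candidates are refined by iterative center of mass: take the
window of radius `refine_radius_px` (3 px) around the current estimate on
the background-subtracted frame, subtract the window minimum, move to the
intensity centroid; stop below a 0.01 px step or after 20 iterations, with
single-step moves capped at the window radius. An all-constant window
(zero mass) stops refinement and flags the detection. A 3 px radius suits
PSF widths near 1–2 px; enlarge it together with `roi_px` for bigger
particles.

## Linking

### Tracklets

Frames are processed sequentially. Open tracklets are matched to the
current frame's detections with a gated Hungarian assignment on Euclidean
distance (`max_link_dist_px`, default 5 px — set it above the largest
plausible per-frame displacement); unmatched detections open new
tracklets, tracklets missing for more than `max_missed_frames` (2) close,
and tracklets reaching `max_tracklet_len` (10) close with a successor
continuing from the same position, to keep each fragment short and
reliable. The assignment solver is an O(n³) shortest-augmenting-path
Hungarian implementation that maximizes cardinality among gated pairs
before minimizing cost; it is property-tested against brute-force
enumeration.

### Tracklet connectivity

Whether an ordered tracklet pair belongs to one trajectory is inferred
from a discrete Bayesian network over seven evidence variables: intensity
similarity `I` (ratio of terminal ROI means), orientation `Or` and speed
`Sp` similarity of the terminal segments, end-to-start distance `D`, frame
gap `G`, and a `sequence` node with parents order `Od` and overlap `Ov`.
Pairs farther than `pair_gate_px` (15 px) or more than `pair_gate_frames`
(5) apart are never scored. Evidence is discretized into three ordinal
states (plus `unknown` for what a single-detection tracklet cannot
supply); the thresholds ship in the configuration (intensity ratio
1.3/2, angle 45°/120°, speed ratio 1.5/3, distance thirds of the gate,
gap 0–1/2–3/>3 frames).

The published description of this network does not include its
conditional probability tables, so the package generates the CS table
from an editable odds table: each favorable evidence state multiplies the
odds of `CS = TRUE` (e.g. aligned headings ×2.5, reversed ×0.15, temporal
overlap ×0.2 versus clean succession ×3), starting from even prior odds.
This keeps the network fully user-tunable while reproducing the intended
qualitative ordering — aligned, equal-speed, equal-intensity continuations
outscore reversed or overlapping ones. Inference is exact enumeration;
the network is far too small to need sampling.

Assembly solves one predecessor/successor Hungarian pass with cost
$1 - P_c$ gated at $1 -$ `score_min` (0.5), then concatenates chains.
Temporally overlapping pairs are scored (the overlap evidence exists for
exactly this case) but never *executed* as joins: a join requires a
non-negative frame gap so that detections are conserved and frames stay
strictly increasing within a track. Multi-pass linking re-runs
scoring/assembly with per-pass overrides — typically a small distance gate
first (slow particles), then a larger one (fast particles) — and records
the pass index on every join.

## Trajectory analytics

Per track (positions $p_i$, $N$ detections, frame interval $t$):
total distance $\sum_i \lVert p_{i+1} - p_i \rVert$, net distance
$\lVert p_N - p_1 \rVert$, maximum distance $\max_i \lVert p_i - p_1
\rVert$ (the distance-from-start formulation; a largest-pairwise variant
is trivially derivable but the start-anchored form is what the measure
table defines), trajectory time, net orientation (degrees, 0 = +x, 90 =
up in the displayed image), normalized mean brightness (mean ROI
intensity over the sequence's brightest pixel, averaged over detections),
mean curvilinear and straight-line speeds, sliding-window maximum speed,
and moving-segment count and mean duration. Frames missed inside a track
count toward its time — speeds would otherwise be overestimated across
gaps.

Moving/paused segmentation uses a rolling MSD exponent: within a centered
5-point window, the mean squared displacement at lags 1–3 is fitted in
log-log; points at slope ≥ 1.4 (between diffusive 1 and ballistic 2) are
moving, and runs of ≥ 2 moving points form segments. Tracks under 5
points are flagged unsegmentable (the windowed MSD is meaningless there),
and the sliding maximum speed then falls back to treating the whole track
as one segment. The maximum curvilinear speed slides a window of
`round(window_s / frame_interval_s)` intervals (1 s default) over windows
fully inside a moving segment.

Directional statistics: tracks are classed apical/lateral/basal (or
leading/perpendicular/trailing) by whether the net heading is within 45°
of the axis, within 45° of its opposite, or neither, with ties at exactly
45° going to the axial class; polar histograms bin headings into 36
sectors of 10°, excluding tracks with net displacement under 1 µm, and
normalize counts to tracks per minute; axis displacement projects the net
vector onto the axis unit vector. Per-frame Pearson correlation between
two channels supports colocalization time courses, reported raw, as a
delta anchored at a reference time point, and normalized by the maximum
delta $K$ ($Y = Y/K$).

## Evaluation

Estimated tracks are compared with ground truth through an optimal
one-to-one pairing minimizing the gated track distance: over the union of
two tracks' frames, each frame contributes the point distance capped at
$\varepsilon$, with $\varepsilon$ charged where either track has no
point. Leaving a truth track unpaired costs $\varepsilon$ per point, so
pairing is only ever chosen when it helps; pairs without a single point
match inside the gate are dissolved. From the pairing: $\alpha$ (1 minus
the normalized matching distance; ignores spurious tracks), $\beta$ (same
numerator over a denominator inflated by spurious-track mass, so $0 \le
\beta \le \alpha$), point- and track-level Jaccard coefficients, RMSE
over matched points, and $\gamma$ — the fraction of truth tracks paired
with at least `gamma_min_cover` (default 0.5) of their points matched
within $\varepsilon$ (default 5 px). The exact aggregation conventions of
the historical benchmark tool are not fully published; these operational
definitions are the package's contract, with $\varepsilon$ and the cover
fraction always reported alongside results.

## The synthetic scenario

`simulate_movie()` emulates the standard evaluation setting for vesicle
trackers: sub-resolution spots rendered as isotropic Gaussians (σ 1.3 px)
over a flat background (50 counts) with per-pixel Poisson noise, at
density presets low/middle/high = 10/50/100 particles per 512×512 frame
and peak SNRs of 1, 2, 4 or 7 under the shot-noise definition
$\mathrm{SNR} = A/\sqrt{A+b}$, solved for the peak amplitude $A$ above
background $b$. Immobile "Golgi-like" distractors (Gaussians with σ 3–6
px at 3–10× the spot amplitude) and the diffuse background reproduce the
nuisance structure of real release-assay movies. Motion models: directed
(constant speed/heading), Brownian, and switching — directed runs with
geometric dwell times (mean 10 frames moving, 5 paused, with jitter),
which produces the moving-segment structure the analytics measure.
Particles spawn away from the border and reflect at a 12 px soft margin
so they remain inside the usable field of view for the whole movie;
default metadata is 100 nm pixels at 4 frames/s, typical of fast Airyscan
imaging. Identical parameters and seed give byte-identical movies and
ground truth.

What the generator does *not* emulate: photobleaching, camera gain/EM
noise, 3D defocus, merging/splitting compartments, and motion of the
distractors. Passing the built-in end-to-end checks therefore shows the
pipeline is correct and well-behaved under controlled conditions, not
that any particular biological movie will reach the same scores.

## Problem sizes and determinism

The shipped tests validate detection and end-to-end tracking on one
512×512, 100-frame, low-density movie per SNR in {7, 4, 2}, with a
classifier trained on 250 + 250 patches for 15 epochs; classifier
property tests use 100 + 100 patches, 15 epochs, three seeds; metric and
geometry properties run on 1 000 randomly generated tracks, and the
assignment solver is compared against brute force on 100 random matrices
up to 6×6. These sizes are the package's chosen validation scale; all of
them are parameters, not limits. Every stochastic step (generation,
initialization, shuffling) is seeded, no stage is parallelized, and
writers embed no timestamps, so a fixed seed reproduces every output file
byte for byte regardless of thread settings.

## Known limitations

* The classifier must be retrained when particle appearance changes
  substantially (different PSF width, very different SNR regime); weights
  trained at SNR 7 degrade gracefully at SNR 4 and fail at SNR 2, as the
  acceptance run shows.
* The Bayesian-network tables are calibrated defaults, not learned from
  annotated joins; they are exposed in the configuration precisely so
  users can tune them.
* Linking handles neither merging nor splitting particles, and overlap
  joins are never executed (see above).
* Registration is translation-only; rotating or deforming specimens need
  external correction first.
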