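---
title: "Methods: how mitodyn segments, scores and classifies mitochondrial dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how mitodyn segments, scores and classifies mitochondrial dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the models and
procedures, the assumptions they rest on, the parameters that matter, and
the numerical decisions taken where the underlying method left room.

## The analysis problem

Mitochondria in a live cell continuously divide and fuse. Given a
time-lapse movie of a fluorescently labelled mitochondrial population
(single channel, fixed frame interval, fixed pixel size), the pipeline
answers three questions per organelle: did it just undergo fission, fusion
or neither; what did it look like just before; and which aspects of its
morphology and neighbourhood predict the outcome.

Coordinates are 1-based (row, column) pixel indices — the native R matrix
convention — with a pixel treated as a unit square; multiplying by
`pixel_size_um` converts to µm. All tabular results are tibbles so the
stages chain naturally with the pipe.

## Segmentation

**Background flattening.** Each frame passes through a white top-hat:
`frame - opening(frame)`, where the opening is `tophat_counts` (default 5)
iterated erosions followed by the same number of dilations with a square
element of `tophat_size_px` (default 3) pixels. The iterated element spans
11 px, so any structure thinner than ~1.1 µm at 0.1 µm/px survives at full
amplitude while smooth background vanishes. Numerical conventions: frames
are rescaled into [0, 1] for the grayscale morphology and rescaled back;
borders are replicate-padded once by the iterated element radius, so a
constant frame maps exactly to zero. A user-supplied `prefilter` function
can be inserted before the top-hat; the pipeline does not attempt to
reproduce any vendor deconvolution, whose algorithm is not public — the
top-hat alone provides the background correction the later stages rely on.

**Threshold estimation.** The square-root transform of the ROI intensity
profile is treated as two empirical populations: a normal background body
and a brighter object shoulder strictly to its right. The background mean
is the histogram mode (Freedman–Diaconis bin width); because fine FD bins
make the raw argmax jittery under count noise, the counts are smoothed with
a 5-bin moving average before the maximal bin is taken — a stabilization of
the same estimator, not a different one. The background SD is the RMS
deviation of the values at or below the mode, mirrored about it: the left
flank is pure background under the two-population assumption, so the
shoulder cannot inflate σ. The lower threshold limit is
`mode + threshold_sigma_mult × σ` (default multiplier 3) in square-root
space, squared for raw intensities. Degenerate inputs (constant profile,
fewer than 1000 values) are errors.

By default the threshold is estimated once per movie on the first frame
(within the ROI when present) and reused — organelle movement then cannot
masquerade as intensity drift — with `threshold_per_frame = TRUE` available
when illumination is non-stationary. Both modes are deliberate: the choice
between them is a property of the acquisition, not of the method.

**Binarization.** Pixels strictly above the raw limit are foreground.
"Clean" is `clean_iterations` (default 2) rounds of binary opening with a
3×3 cross followed by removal of components under 4 px; "separate" is
`separate_iterations` (default 3) rounds of watershed splitting on the
distance transform, smoothed with a Gaussian of σ =
`separate_smooth_sigma` (default 1 px), seeds merged when closer than 2 px
or shallower than `separate_tolerance` (default 1 px of distance). The
final labels are 8-connected; holes use 4-connectivity — the complementary
pairing that keeps the Euler characteristic consistent. Thresholding is
invariant under any strictly monotone intensity rescaling applied to both
frame and limit.

## Event detection

**Relations.** Regions of consecutive frames are related when they overlap
in at least one pixel *and* at least one of the two is the other's maximal
overlap partner. All argmax ties are included: the maximum rule does not
specify a tie-break, and including every tied region keeps the weight
accounting exact. Later-frame regions with no ancestor and earlier-frame
regions with no descendant are logged as appearances/disappearances rather
than silently dropped — they are the signature of segmentation failures.

**Scores.** Every later-frame region carries a unit weight regardless of
size, split equally among its ancestors; an earlier region's score is the
sum of what it receives. The score is the vote of the next frame on the
region's fate: above 1 fission, below 1 fusion, exactly 1 (within 1e-9)
stable. Equal splitting is the reading consistent with a uniform unit
weight; an overlap-proportional variant is available
(`overlap_weighted_scores = TRUE`) without changing the default. Weight
conservation — the sum of defined scores equals the number of later regions
with at least one ancestor — holds exactly for every frame pair and is
enforced by property tests.

**Persistence.** A preliminary call at frame *t* is confirmed only when the
skip-frame score (*t* → *t*+2) lies strictly on the same side of 1. At 5 s
intervals this is the 10 s persistence requirement that rejects transient
contacts. One consequence is worth stating plainly: a one-frame contact is
correctly rejected as a fusion, but its dissolution — the joined region
splitting one frame later into fragments that then persist — satisfies the
fission rule literally. The synthetic-truth comparison
(`score_detection()`) therefore excludes fission records at
passing-dissolution frames from the precision denominator instead of
counting them as false positives.

## Morphometry

Eleven features per confirmed event, measured on the region in the frame
directly preceding the event; stable regions are not measured.

* **area_um2** — pixel count × pixel area.
* **perimeter_um** — length of the traced outer boundary polygon (1 per
  axial step, √2 per diagonal). An edge-pixel-count variant
  (`perimeter_edge_count`) is provided because both definitions circulate;
  the boundary-walk form is the default as the better-behaved metric. The
  outer contour is used throughout (holes do not add perimeter) so that the
  same closed curve parameterizes the neck detector.
* **extent**, **solidity** — pixel count over bounding-box and convex-hull
  pixel counts. The hull is the convex hull of pixel centres; containment
  is decided by half-plane tests with ties counted inside.
* **eccentricity** — from second central moments with the standard 1/12
  unit-pixel correction.
* **euler_number** — 1 minus the number of 4-connected holes; reported as
  the standard characteristic (an affine transform of a raw hole count, so
  any ranking built on it is unaffected).
* **n_necks, min_neck_width_um** — the boundary is ordered by
  Moore-neighbour contour tracing; D[p,q] is the Euclidean distance between
  boundary pixels p and q; D is smoothed with a separable Gaussian
  (`neck_kernel_px` = 5 taps, σ = 1.25 px) applied cyclically over both
  boundary indices, because the boundary is a closed curve and non-cyclic
  smoothing would manufacture artifacts at the arbitrary trace start. Necks
  are *isolated* minima of the smoothed matrix. Two artifact decisions make
  "isolated" precise. First, pairs whose shorter boundary-arc separation is
  below 3 × `neck_kernel_px` are excluded — adjacent contour pixels are
  trivially close and would otherwise all be minima. Second, minima are
  detected as weak-minimum plateaus (connected components of entries no
  larger than any of their 8 cyclic index-neighbours) accepted only when
  every outside neighbour is strictly larger: a strict single-entry rule
  either misses symmetric constrictions entirely (exact ties) or fires on
  the edges of the flat valley floor that a straight tube produces, which
  drains into its end caps and is not a constriction. Mirrored components
  across the matrix diagonal are the same unordered pair and count once.
  The reported width is the raw (unsmoothed) distance at the minimum, in
  µm. Regions with fewer than 12 boundary pixels report zero necks and an
  undefined width.
* **nn_distance_um** — cytosol gap to the nearest other region: minimal
  boundary-to-boundary pixel-centre distance minus one pixel (two regions
  in side-by-side contact are at distance 0), floored at zero.
* **neighbor_surface_um** — summed boundary length of other regions'
  boundary pixels lying within `neighbor_radius_um` (default 10 µm) of this
  region, each contour pixel contributing half of its two incident step
  lengths.
* **orientation_deg** — acute angle (0–90°) between the region's
  second-moment major axis and the radial line from the nucleus centroid to
  the region centroid, a proxy for alignment with the microtubule network.
  Missing when no nucleus centroid is supplied; nn/neighbour features are
  missing for a frame's only region. Missing values are imputed by the
  class-agnostic column median at training time (with a message), never at
  measurement time.

## Classification

`train_forest()` fits `n_trees` = 2000 bagged classification trees with
`rf_split_candidates` = 3 candidate features per split (the conventional
reading of that tuning constant in random-forest implementations),
seeded from the run configuration. Class priors are left as observed — no
reweighting — so the majority class is typically predicted better; on
70/30 fusion-biased data the fusion class error is the smaller one, and
the out-of-bag error is the weighted mean of the class errors.

Importance is out-of-bag permutation importance: the mean per-tree increase
in OOB misclassification when one feature's values are permuted, with the
per-tree spread as its uncertainty, computed overall and restricted to each
true class. This is the standard operationalization of "error increase when
a feature is removed from consideration" in the random-forest framework and
is what yields per-feature SDs; a literal refit-without-the-feature variant
is available (`importance_refit = TRUE`) but is documented as blind to
signal carried redundantly by correlated features (dropping perimeter costs
little when area can substitute), and it defines no per-tree SD. Worth
knowing when reading importance tables: an exactly duplicated feature does
not halve its importance — permuting one copy leaves the other intact
inside any given tree — the copies share the rank region below the
original's value.

`class_error_curve()` exposes the OOB errors of the nested sub-ensembles
formed by the first *n* trees, the curve that flattens once the forest
exceeds a hundred-odd trees. `stump_boundary()` is the single-bifurcation
decision boundary: the threshold minimizing Gini impurity over all
midpoints between consecutive sorted unique values, ties broken toward the
smaller threshold, each side labelled by its majority class.

## Pre-event dynamics

For simple events only — 1→2 fissions and 2→1 fusions — the reference
region is tracked backward up to `pre_event_frames` = 8 frames by following
the unique stable ancestor in the reversed frame pair; the trace terminates
early as soon as the backward identity is not a strict 1→1 relation
(truncation, not imputation: the per-offset n is reported and shrinks
monotonically going back). Perimeter and solidity are normalized to the
frame just before the event, so P/P₀ = S/S₀ = 1 at offset 0 exactly;
group means and standard errors (SD/√n) are reported per offset and call.

## The synthetic scene generator

The generator is the package's stand-in for raw movies and defines the
conditions under which the pipeline is validated: a 220 × 220 px field at
0.1 µm/px (a 22 µm × 22 µm peripheral snapshot), 60 frames at 5 s,
12 objects of which ~40% are tubular, background N(100, 10) with objects at
N(220, 10) (a 12σ contrast; the generator requires at least 6σ), objects
placed with ≥ 4 px mutual gaps. Those defaults are chosen once to make
scenes structurally comparable to peripheral mitochondrial fields —
organelle widths of 0.5–0.9 µm, below the top-hat's 1.1 µm ceiling — and
the density low enough that identity is unambiguous, which is what the
event-scoring rule itself assumes.

Scripted events morph the ground truth minimally, the way real frame pairs
do: fission deletes a 2-px band across the principal axis (children persist
to the end of the movie; sub-8-px crumbs are dropped); fusion replaces the
pair with a capsule of near-uniform width along their centroid axis — a
relaxed fused organelle rather than a dumbbell, so the watershed separation
step sees a single ridge, as it would once a real fusion product relaxes;
passing bridges a pair for exactly one frame. An optional
`fission_growth_per_frame` swells a fissioning object isotropically over
the frames before its split, giving the backward traces a recoverable
scripted morphology change. Intensities are redrawn independently every
frame; all randomness flows from one seed.

What the scenes do *not* emulate: photobleaching, focus drift, stage
drift, object motility, point-spread blur, 3D structure, and densities at
which identities genuinely entangle. Passing tests on these scenes
therefore demonstrate the correctness of the operators and the
recoverability of planted signal — not robustness to every confound of
live-cell imaging.

For classifier-scale questions the package generates feature tables
directly (`generate_event_features()`): 800 events by default with a 70/30
fusion/fission imbalance, plausible marginal distributions and
correlations (area, neck count rising with perimeter; solidity falling),
and labels drawn from P(fission) = logistic(2·z(perimeter) − 2·z(solidity)
+ c) with c solved so the expected fission fraction is met. The planted
association — fission probability rising with perimeter, falling with
solidity — is the structure the forest, the importance ranking and the
stump directions are tested against.

## Problem sizes and determinism

The shipped tests run the pipeline at sizes chosen to exercise every code
path while keeping the suite brisk: oracle equivalence on 200+ random
fixtures (≤ 30 × 30 px, ≤ 6 regions), weight conservation on 50 generated
scenes, forests of 300–1000 trees for unit properties and the full
2000-tree configuration for the recovery checks, and one full-scale
60-frame, 220 × 220 px end-to-end run. Every stochastic step is seeded;
rerunning any stage with the same inputs, configuration and seed
reproduces its output tables byte for byte.

## Known limitations

* Tracking is overlap-based with no motion model and no gap closing:
  organelles that move more than their own footprint per frame, or vanish
  for a frame, break identity (logged as disappearance/appearance).
* The neck operator counts constriction/branch signatures in the boundary
  distance matrix; it is not a skeleton-based branch count, and on deeply
  lobed shapes the two notions can differ.
* Perimeter, solidity and neck widths inherit pixel quantization; sub-pixel
  morphology changes (a few percent on a small object) are below its
  resolution.
* The threshold model assumes the background is the dominant mode and the
  objects sit strictly brighter; movies violating either assumption (dense
  fields, strong vignetting) need the per-frame threshold mode or a
  prefilter.
* With class priors left as observed, strongly imbalanced event sets trade
  minority-class sensitivity for calibration with observed frequencies —
  intentional, but worth remembering when comparing class errors.
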