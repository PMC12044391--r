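---
title: "Quantifying cell-cell interactions during electrotaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-cell interactions during electrotaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(cellcontacts)
library(dplyr)
```

## The measurement problem

Epithelial cells migrating at low density collide with one another, and
what a cell does after a collision — repolarize away (contact inhibition of
locomotion, CIL), align its velocity with its neighbour, or ignore the
encounter — shapes collective behaviour. When a direct-current electric
field is applied, cells additionally acquire a directed migratory command
(electrotaxis), and the question becomes how the field reshapes the
collision responses. This package quantifies both ingredients from
time-lapse segmentation masks: per-frame integer label images in which
each cell keeps one positive label, plus the physical calibration
(micrometres per pixel, minutes per frame) and a schedule saying when the
field was on and in which direction.

All coordinates use the image convention throughout: x = column x
pixel size, y = row x pixel size, y increasing downward, pixels 0-based.
Angles are measured in this frame consistently, so no result depends on
mixing conventions.

## From masks to kinematics

`cell_states()` reduces each (cell, frame) mask to a centroid, an area,
and a moment-equivalent ellipse: the unique ellipse whose uniform disk has
the same second central moments as the pixel set (each pixel contributes
the covariance of a unit square, the classic 1/12 correction, so small
rasterized shapes recover their generating parameters closely). Fewer than
three pixels, or an exactly collinear pixel set, cannot support an
ellipse; such fits fall back to a half-pixel disk and carry a `degenerate`
flag rather than failing.

`compute_velocities()` uses the forward difference
v(t) = (x(t + dt) - x(t)) / dt in um/h. The forward difference is not an
arbitrary choice: the interaction metrics below are defined on the
velocity change between successive frames, so the velocity attached at
frame t must look forward. Velocities are undefined (NA, never zero) at a
track's last frame and across gaps; `allow_gaps = TRUE` optionally spans
gaps using the true elapsed time.

Directionality with respect to the field is
Phi = mean over cells of cos(theta_i), with theta_i the angle between the
cell's velocity and the field direction: 1 when everything moves with the
field, 0 for isotropic motion. Cells with zero speed are excluded (their
cosine is undefined), and Phi is reported only while the field is on.

## Contacts, events, clusters

Two cells are in contact wherever their masks are directly adjacent.
Adjacency for contact *existence* defaults to 8-connectivity — a diagonal
touch is a touch — while the interface *length* counts only 4-adjacent
pixel pairs times the pixel size, so a straight shared edge of k pixels
has length k x pixel size and a pure diagonal touch has length zero. Both
choices are configurable; the defaults favour robustness to rasterization
while keeping the length well defined.

A contact event is a maximal run of consecutive frames a pair stays in
contact; its duration is (number of frames) x dt. By default a pair that
separates for even one frame starts a new event (`gap_tolerance = 0`),
because no merging rule is obviously right; the tolerance is exposed for
users who prefer to bridge flicker. Clusters are connected components of
the per-frame contact graph (singletons included), with the cluster speed
the mean of member speeds.

## Localizing a contact on the cell surface

These cells are strongly polarized and move along their *short* axis. The
front is therefore the short-axis direction of the fitted ellipse, signed
to agree with the velocity. Each contact is reduced to one representative
site — the centroid of the focal-side boundary pixels — projected to the
closest point on the focal cell's ellipse (solved in the ellipse-aligned
frame by reduction to the first quadrant and a bracketed root find on the
boundary parameter; the bracket is guaranteed, and points on the axes or
at the centre are handled analytically). The contact angle
phi = arccos(front . unit(site - centre)) lies in [0, pi]: 0 at the front
pole, pi/2 at either side, pi at the rear. Taking the arccosine makes the
measure left-right symmetric by construction, which doubles the effective
sample count per bin at the cost of not distinguishing left from right.

If a cell moves exactly along its long axis the front is ambiguous; the
tie is broken toward positive x (then positive y) and the sample flagged,
rather than silently dropped, since this violates the polarized-motion
assumption the front definition rests on. Samples with zero velocity are
skipped outright — there is no defensible way to orient them.

## The interaction metrics

For an oriented pair (focal i, neighbour j) in contact at frame t:

- **CIL**: `cil()` = unit(v_i(t+dt) - v_i(t)) . unit(x_i(t) - x_j(t)),
  in [-1, 1]; +1 means the focal cell accelerated directly away from its
  neighbour. Note the metric scores *velocity change away from the
  neighbour*; a fast neighbour ramming a slow cell from behind also scores
  positive ("pushing"), which is repulsion in the metric's sense without
  classical repolarization.
- **Alignment**: `alignment()` = (cos angle(v_i(t+dt), v_j(t+dt)) -
  cos angle(v_i(t), v_j(t))) / 2, in [-1, 1]; +1 is a pair that went from
  perfectly anti-aligned to perfectly aligned across the contact frame.

Both formulas normalize by magnitudes, so zero velocity change, coincident
centroids, or any zero velocity make the respective metric undefined. Such
samples are kept with validity flags and excluded from means — imputing 0
would bias every aggregate toward neutrality — and the dropped-sample
counts are conserved and reported, so kept + dropped always equals the
number of oriented contacts.

Metrics are evaluated at every frame of a contact, since the definitions
are per-frame. The first frame of each run is flagged `is_onset`:
event-level summaries use those rows, because a collision response is
expressed across the onset frame (v(t) is the last pre-response stride,
v(t+dt) the first post-response one). By default samples are restricted to
pairwise contacts — frames where each partner touches exactly one cell —
since the two-cell metrics are not meaningful inside larger clusters,
which contribute to cluster statistics instead.

`response_map()` aggregates samples on a grid of phi (8 equal bins on
[0, pi]; the resolution is a reporting choice, not a model parameter) by
neighbour-speed class: slow below 50 um/h, fast above 100 um/h,
intermediate speeds discarded so the two classes are cleanly separated.
Cells of the grid with at least `n_min = 5` valid samples get a behaviour
label from `classify_behavior()`: positive mean CIL beyond a dead zone
tau = 0.1 reads "repel" versus "stick", positive mean alignment "align"
versus "scatter", and both metrics inside the dead zone is "neutral".
When the alignment mean falls inside the dead zone but the CIL mean does
not, the alignment word follows the sign. The wording is deliberately
configuration, not code: the four-way taxonomy has been described with
conflicting conventions, so the mapping can be overridden wholesale.

## Statistics

All two-sample comparisons use the unpaired two-sided Mann-Whitney U test
(`two_sample_test()`): exact when the combined sample size is at most 20
with no ties, normal approximation with tie correction otherwise. Time
series are compared pointwise in time and p values are reported
uncorrected, with an explicit note in the summary report; a correction
would change the error model, and the pointwise convention is stated
rather than hidden. Condition statistics default to the analysis window
60-180 min — the first field-on period — so control and stimulated movies
are compared over the same interval.

## The synthetic generator

The simulator is a test harness, not a biological claim: it produces
movies with the statistical structure the analysis assumes, so every
stage is exercisable with known ground truth. Cells are persistent random
walkers: each frame, the polarity angle is redrawn from a von Mises
density proportional to exp(kappa_p cos(th - th_old) +
kappa_e cos(th - th_field)) — the product of a persistence term and a
field-bias term, itself von Mises, sampled with the Best-Fisher rejection
scheme. kappa_e = 0 recovers an unbiased walk; large kappa_e slaves the
polarity to the field. Step speeds are log-normal.

Defaults mirror the experimental scales: dt = 5 min, 60 frames (5 h),
median speed 60 um/h with sdlog 0.5 so both the slow (<50) and fast
(>100 um/h) neighbour-speed classes are populated, field schedule off for
1 h, +x for 1-3 h, -x for 3-5 h, and sparse seeding (12 cells in a
400 um arena) matching the low-density regime of the assay. Sparseness
matters beyond realism: with strong alignment responses a dense
population orders into a flock, after which collisions occur between
already-aligned cells and the per-collision alignment signal is
structurally diluted.

Cells are drawn as ellipses (18 x 10 um semi-axes) with the major axis
perpendicular to the polarity, rasterized with contested pixels resolved
to the nearer centre (deterministic and label-order independent). Two
cells interact when their bodies come within one pixel — a
boundary-sampling ellipse test — so simulator contacts and mask-adjacency
contacts coincide frame-accurately; this coupling is what lets the
onset-frame metric capture the programmed response. On contact onset, with
probability `p_cil` a cell repolarizes directly away from its neighbour
(the geometry the CIL metric scores exactly), and with probability
`p_align` it relaxes its polarity toward the neighbour's at rate 0.5 per
frame while the contact lasts (both partners relaxing mutually at rate
0.5 meet at the circular midpoint in one step). A response committed at
onset frame s is expressed in the stride from s+1 to s+2, so the
measurement at the onset frame — which differences v(s) and v(s+1) —
sees the full response; a committed response is expressed even if the
touch flickers off for a frame. A hard core (20 um) is enforced by
pairwise separation sweeps, and the boundary either reflects (default;
required for rasterization) or wraps periodically (preferred for
trajectory-level statistics, since reflective walls turn biased cells
around and depress directionality near the boundary).

What the generator does *not* emulate: cell deformation on contact (shapes
are rigid ellipses), proliferation and death, segmentation errors, uneven
illumination, or mechanistic electrotaxis. Passing tests therefore show
the *measurement chain* is correct and sensitive, not that real cells
behave like the model.

## Numerical choices

- Closest-point projection: bracketed root find (Brent) on the distance
  derivative in the first quadrant, tolerance near machine precision;
  points within 1e-10 relative of an axis are handled by the analytic
  branch, which also absorbs rotation round-off for ellipses at
  theta = pi/2. A point exactly at the centre returns the minor-axis
  endpoint (the true nearest boundary point) with an `ambiguous` flag.
- Frame-to-frame linking (`link_tracks()`, for movies without persistent
  labels): optimal gated assignment per frame transition via a
  shortest-augmenting-path LAP solver on the standard padded matrix with
  alternative cost 1.05 x gate, then gap closing between track ends and
  starts (defaults: 100 um link gate, up to 3 frames and 150 um). Ties are
  resolved deterministically. This is a convenience linker for sparse
  scenes; it does not implement merging or splitting.
- Determinism: a fixed simulator seed yields bit-identical movies and
  tables (the caller's RNG state is saved and restored), and rerunning the
  pipeline with the same inputs and configuration writes byte-identical
  artifacts, each stamped with an FNV-1a hash of the configuration.

## Problem sizes used by the test suite

The packaged tests and the acceptance script run the generator at the
default study scale (12 cells, 400 um, 60 frames, three seeds per
condition), which yields 50-150 analysable collisions per condition —
enough to separate programmed responses from the null at p < 0.01 while
keeping a full run in minutes on one core. Oracle-equivalence checks use
100 random 64 x 64 label images, 1000 random point-ellipse pairs against
a 100,000-point boundary sampling, exhaustive enumeration of the
Mann-Whitney null at combined n <= 10, and factorial assignment
enumeration at up to 5 cells per frame.

## Known limitations

- The contact representative site is a single centroid per (pair, frame);
  extended or multi-patch interfaces are summarized by one angle.
- The linker is gated nearest-assignment with gap closing; cells that
  cross or collide can swap identities, as in any centroid-based linker.
- Pairwise restriction discards contact frames inside clusters of three
  or more; cluster-internal responses are out of scope.
- The behaviour taxonomy is a reporting layer on two means; it inherits
  their sampling noise, which is why labels require `n_min` samples.

## A short worked example

```{r example, eval = FALSE}
fx <- make_fixture("electrotaxis_basic", seed = 1)
res <- analyze_movie(fx$movie, field_schedule())
glance(res$map)
res$direction |> filter(!is.na(phi)) |> summarise(mean_phi = mean(phi))
autoplot(res$map)
```
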