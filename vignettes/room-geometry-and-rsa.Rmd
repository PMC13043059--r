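---
title: "Single-view room geometry and representational similarity analysis with scenelayout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-view room geometry and representational similarity analysis with scenelayout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenelayout)
```

## The problem

An observer standing in a room can, from a single view, judge how the
surrounding walls are oriented and which of them are near. `scenelayout`
implements the computational side of studying that ability: it reconstructs
the camera's internal and external parameters and the room's wall layout
from sparse human line annotations of a single photograph, converts the
layout into two egocentric *boundary feature models* (wall orientation and
wall relative distance), and provides the partial-correlation
representational similarity analysis (RSA) machinery used to ask whether
neural dissimilarity structure carries unique information about those
layout features over and above generic image statistics.

Everything is testable without any external dataset: a synthetic
Manhattan-room simulator forward-projects exact ground truth (segmentation
maps, corner locations, vanishing points, annotations) so that every stage
of the reconstruction can be validated as a parameter-recovery experiment.

## Camera model and self-pose from vanishing points

The camera model is the standard pinhole projection `m = K [R | t] X` with
skew, yaw and translation fixed at zero and the principal point `O` at the
exact image center. All internal arithmetic uses *centered* pixel
coordinates (0-based pixel centers minus `((W-1)/2, (H-1)/2)`, x rightward,
y downward) and homogeneous 2-D points, so that vanishing points at
infinity are ordinary values rather than failures.

An annotation supplies two pairs of image segments; each pair marks 3-D
lines that are parallel to the ground and to each other, and the two pairs
are orthogonal in 3-D. Each pair's intersection is a vanishing point (V1,
V2); the line through them is the horizon `H`. With `Oh` the foot of the
perpendicular from `O` to `H`, orthogonality of the two annotated
directions forces V1 and V2 onto opposite sides of `Oh` and gives the focal
length:

    h^2 = |OhV1| * |OhV2|,   f^2 = h^2 - |OOh|^2 = -(V1 - O).(V2 - O)

Both forms are computed and must agree to 1e-9 relative; an annotation
with both vanishing points on the same side of `Oh` has no real focal
length and is rejected as inconsistent.

The forward axis vanishing point `Vs` is the intersection of the vertical
line through `O` with `H`; its partner `Vc` (left-right axis) sits at
`|OhVc| = h^2 / |OhVs|` on the opposite side of `Oh`. At zero roll `Vs`
coincides with `Oh` and `Vc` is at infinity along the horizon. The rotation
columns are `r1 = K^-1 Vc / ||.||`, `r3 = K^-1 Vs / ||.||`,
`r2 = r1 x r3`, from which

    pitch = atan2(r3_y, r3_z),   roll = atan2(r2_x, r1_x)

Sign conventions (a genuinely open choice, fixed here once): positive pitch
means the optical axis is raised, so the horizon falls *below* the image
center; positive roll means the horizon appears rotated clockwise in the
displayed image. The rotation order is roll about the optical axis followed
by pitch about the image-horizontal axis — the order under which "Vs lies
on the vertical through O" is exact for rolled cameras. Under these
conventions the recovered `roll` is the intrinsic rotation angle about the
optical axis (not the image inclination of the horizon, which differs by a
factor `1/cos(pitch)` in its tangent when the camera is pitched); the
noise-free synthetic round trip then reproduces the generator's signed
pitch and roll to better than 1e-6 degrees.

The vertical vanishing point `V3` exploits the orthocenter property: `O` is
the orthocenter of the triangle V1 V2 V3, so `V3` lies on the perpendicular
from `O` to `H` at `V3 = -(f^2 / delta) n`, with `n` the unit horizon
normal and `delta` the signed distance of `H` from `O`. When the horizon
passes through `O`, `V3` is at infinity — returned homogeneously, not as an
error.

### Degenerate inputs

* Two parallel segments (angle below `tol_parallel_deg`, default 0.01
  degrees) intersect at infinity; the tolerance exists because sub-pixel
  noise on short near-parallel segments otherwise produces absurd finite
  vanishing points.
* If *one* annotated direction is parallel to the image plane its
  vanishing point is at infinity and the focal length is genuinely
  undetermined (the orthogonality constraint no longer involves `f`); this
  is reported as "insufficient perspective". An exactly frontal, zero-roll
  view annotated along the room axes is the canonical example. Such poses
  form a measure-zero set under the simulator's continuous sampling.

## Outlining walls and rasterizing the layout

One wall annotation (edge line `L1` with endpoints at the wall-wall
corners, height line `L2` between the ceiling and floor junctions) plus the
calibrated geometry determines the full Manhattan layout:

1. `Va` = intersection of `L1` with the horizon. Lines from `Va` through
   `L2`'s endpoints are the annotated wall's ceiling and floor junctions.
2. Lines from `V3` through `L1`'s endpoints are its junctions with the
   neighbouring walls; pairwise intersections give corners p2, p3
   (ceiling) and p6, p7 (floor).
3. `Vo`, the orthogonal walls' vanishing point, sits at
   `|OhVo| = h^2 / |OhVa|` opposite `Va`; rays from the corners away from
   `Vo`, clipped to the frame's outer pixel boundary, give the outer
   corners p1, p5, p4, p8. A frontal annotated wall has `Va` at infinity
   and `Vo = Oh`, handled homogeneously.

Rasterization is a pixel-center test against the exact boundary lines, not
a polygon fill: each pixel is first assigned to the left/middle/right band
by the two vertical junction lines, then to ceiling/wall/floor by that
band's junction lines. Pixels whose center lies exactly on a boundary go to
the wall band, and on wall-wall boundaries to the leftmost label, making
re-rasterization bit-exact. Labels are fixed and positional: 0 unknown, 1
ceiling, 2 floor, 3 left wall, 4 middle wall, 5 right wall (ordered left to
right; a missing side wall leaves its label unused rather than re-numbering
the rest — this keeps the reconstruction and the ground-truth renderer
label-compatible even when a one-pixel sliver of wall sits at the frame
edge).

Wall orientation angles follow `theta_a = atan(|OhVa| / h)`,
`theta_o = atan(|OhVo| / h)`; the two are exact complements
(`tan theta_a * tan theta_o = 1`). These are angles of the walls' *edge
directions*; the aerial view stores instead the wall-*plane* angle relative
to frontal (0 = facing the observer), i.e. `90 - theta`, which is what the
orientation feature model needs per viewing direction.

Aerial-view angular spans map each wall's vertical junction lines to their
horizon crossings and convert those to world azimuths *through the
recovered rotation* (`phi = atan2(d_x, d_y)` of the back-projected
direction). At zero roll this is identical to the horizon-distance formula
`phi = atan(u / h)`; for rolled cameras the rotation-based form remains
exact while the shortcut is biased by up to about a degree at the sampled
roll range, so the exact form is used throughout.

## Boundary feature models

**Orientation model.** The horizontal field of view is divided into 5 bins
with triangular kernels `Fi(phi) = max(0, (sigma - |phi - phi_ic|)/sigma)`
(`sigma` = FOV/5). The piecewise-constant orientation field `O(phi)` — the
wall-plane angle at viewing direction `phi`, in degrees, and 0 where no
side wall is visible (the least-informative choice for open directions; an
empty scene maps to the zero vector) — is integrated against each kernel:
`Ri = integral O(phi) Fi(phi) dphi`. Integration is a midpoint rule on a
fixed grid of 2000 steps (0.03 degrees at a 60-degree FOV), far below any
tolerance used in testing and fully deterministic. The kernels form an
exact partition of unity at least `sigma/2` inside the FOV, so a constant
field integrates to `constant * sigma` in interior bins (edge bins lose
`sigma/8` of kernel mass outside the FOV).

**Relative distance model.** The image is cut into 5 vertical strips with
integer boundaries `round(k W / 5)`; each strip's value is the proportion
of its own pixels labeled as any side wall (per-strip denominators keep
bins comparable when `W` is not divisible by 5). Nearer walls occupy more
pixels under perspective, so the profile is a coarse egocentric distance
code. A variant that subtracts the ceiling-plus-floor proportion per strip
is available (`method = "area_difference"`); the proportion form is
primary because it is the operational definition used to build the model
RDMs.

Feature RDMs use city-block distance; neural RDMs are one minus the
Pearson correlation between condition patterns; externally computed
feature matrices can enter via Euclidean (image statistics) or cosine
(semantic embedding) distances. Orientation enters the features in
degrees; city-block RDM ranks are invariant to that global unit choice.

## Partial-correlation RSA and group inference

`partial_spearman()` rank-transforms the lower-triangle vectors of the
neural and target RDMs (average ranks for ties), regresses both on the
control rank vectors plus an intercept by least squares, and returns the
Pearson correlation of the residuals — the standard symmetric residual
definition of a partial Spearman correlation. With no controls it equals
the full Spearman correlation to machine precision, and it is invariant to
any strictly monotone transform of any input RDM. Constant rank vectors,
collinear controls, and a control identical to the target (zero-variance
residual) are errors, named after the offending RDM.

Group-level inference is a one-sample t-test of the per-subject
coefficients against zero — upper-tailed for model-coding tests, as a
coefficient below chance is not interpretable as coding — followed by
Benjamini-Hochberg step-up FDR across all (model x region) families of one
analysis. Coefficients are tested directly, without a Fisher z-transform.
Task contrasts are paired t-tests on subject-wise coefficient differences,
two-tailed, FDR-corrected across contrasts. In the full pipeline
(`rsa_group_pipeline()`) each target model's partial correlation controls
for *all* other models, including the competing layout model; this is what
lets a region coding relative distance reject the orientation model and
vice versa.

## The synthetic-room simulator and what it does (not) emulate

`sample_room()` draws rooms 3-8 m across and deep with 2.4-3.3 m ceilings,
an eye-height camera (1.4-1.8 m) in the back half of the room, focal
lengths 300-1200 px on a 650 x 520 frame, pitch in [-30, 30] degrees, roll
in [-10, 10] degrees, and room yaw in [-30, 30] degrees. The frame size is
a typical stimulus-presentation resolution for scene images; the other
ranges are chosen once as realistic hand-held indoor photography
conditions. Rendering casts one ray per pixel center; since the room is
convex, the visible surface is simply the boundary plane with the smallest
positive ray parameter — a construction simple enough to double as its own
oracle (tests compare it to an independent per-pixel loop).

Annotator emulation picks, deterministically, the far wall's ceiling and
floor junction edges (across direction) and the ceiling and floor junctions
of the most visible side wall (depth direction); the wall annotation marks
the far wall with `L1` on its floor edge between the true corners.
Annotation noise is isotropic Gaussian per endpoint coordinate — the
simplest calibratable model, since no empirical annotator noise model is
available. A single master seed drives scene sampling and jitter; failures
(e.g. no side wall in view) are resampled from an incremented stream.

What passing synthetic tests shows: the geometry, rasterization, feature
and statistics code paths are exact and consistent end to end, and degrade
gracefully and monotonically with annotation noise (at 1-2 px jitter the
mean pitch/roll/pixel errors are of the same order as the published
real-image validation errors of this family of methods). What it does not
show: robustness to lens distortion (not simulated; real wide-angle images
violate the straight-line assumption), to annotators choosing short or
unfavourable edges, to non-Manhattan rooms, or to occluding furniture —
the pixel-error metric here compares pure layout labels.

## Planted-dissociation experiment

`planted_dissociation_experiment()` is a desk-scale analogue of the
region-dissociation logic: 60 synthetic scenes yield the two layout model
RDMs; three nuisance RDMs (Gaussian feature matrices under Euclidean
distance, an exponential one under cosine distance) stand in for low-,
mid- and high-level image models; each of 8 simulated subjects' neural
RDMs in the "distance region" is the rank transform of the relative
distance RDM plus Gaussian noise, and likewise for orientation in the
"orientation region". The noise SD is set from the closed-form Pearson
attenuation `rho = 1 / sqrt(1 + sd^2 / var(ranks))` so the planted full
Spearman correlation is about 0.3 — fixed analytically up front, not tuned.
The group pipeline must return q < 0.05 for the planted model and
q > 0.05 for the other model in each region.

## Numerical choices, in one place

* Parallel-segment tolerance 0.01 degrees; below it, intersections go to
  infinity.
* Orientation-field integration: midpoint rule, 2000 fixed steps.
* Rasterization ties: boundary pixels to the wall band, wall-wall ties to
  the lower label; bit-exact reruns.
* Ray-frame clipping uses the outer pixel boundary (-0.5 ... W-0.5).
* Floats serialize with 17 significant digits; segmentation PNGs are 8-bit
  grayscale with pixel value = label (exact round trip); logs carry no
  timestamps so identical runs are byte-identical.
* Problem sizes in the shipped validation: 200 noise-free scenes for
  exact recovery, 100 scenes per jitter level over {0, 0.5, 1, 2, 4} px,
  100 random RDM triples for the partial-correlation oracle, 8 x 60 for
  the planted dissociation — sizes at which every check is stable across
  seeds while the whole suite stays quick to run.

## Known limitations

* Focal length is unrecoverable from annotations whose vanishing points
  include one at infinity (see above); real annotators avoid this by
  choosing oblique line pairs, the simulator by continuous pose sampling.
* The layout model assumes at most three mutually orthogonal side walls;
  curved or oblique walls are out of scope.
* When the annotated wall is the leftmost (or rightmost) wall, the region
  beyond its outer edge has no reconstructable label and is left
  "unknown" rather than guessed.
* The paper-form `theta = atan(|OhV|/h)` orientation is exact only at zero
  roll; the package therefore reports rotation-based orientations in the
  aerial view while keeping the formula available for the geometric
  identities it satisfies.
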