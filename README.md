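# scenelayout

Single-view reconstruction of camera self-pose and Manhattan-world indoor
layout from sparse human line annotations, the boundary feature models
built on that layout, and the partial-correlation representational
similarity analysis (RSA) used to compare those models against neural
dissimilarity structure.

The package is aimed at vision and spatial-cognition researchers who want
to (a) turn a handful of annotated line segments on an indoor photograph
into calibrated scene geometry, (b) express that geometry as egocentric
boundary features, and (c) test, with proper group statistics, whether a
neural (or any other) dissimilarity structure carries unique information
about those features.

## What it computes

**Calibration.** Two annotated pairs of mutually orthogonal,
ground-parallel image lines give two vanishing points V1, V2 and the
horizon H. With O the principal point (image center) and Oh its foot on H,

```
h² = |OhV1|·|OhV2|        f² = h² − |OOh|² = −(V1−O)·(V2−O)
```

yields the focal length; the axis vanishing points Vs (forward; vertical
line through O ∩ H) and Vc (left–right; |OhVc| = h²/|OhVs|, opposite side)
give the rotation columns r1 = K⁻¹Vc/‖·‖, r3 = K⁻¹Vs/‖·‖, r2 = r1 × r3 and
the self-pose: pitch = atan2(r3_y, r3_z), roll = atan2(r2_x, r1_x). The
vertical vanishing point V3 follows from O being the orthocenter of
triangle V1V2V3.

**Layout.** One wall annotation (corner-to-corner edge line L1, ceiling-to-
floor height line L2) is propagated through Va = L1 ∩ H, V3, and
Vo (|OhVo| = h²/|OhVa|) into the full corner set p1…p8, a per-pixel
segmentation map (ceiling / floor / left / middle / right wall), wall
orientation angles θa = atan(|OhVa|/h), θo = 90° − θa, and an aerial view
of oriented wall spans across the horizontal field of view.

**Features and RSA.** A 5-bin triangular-kernel soft histogram integrates
the wall-plane orientation field over the FOV
(Fᵢ(φ) = max(0, (σ−|φ−φᵢᶜ|)/σ), Rᵢ = ∫O(φ)Fᵢ(φ)dφ); a 5-strip profile of
side-wall pixel proportions encodes relative wall distance. City-block /
Euclidean / cosine model RDMs and 1−Pearson neural RDMs feed a partial
Spearman correlation (Pearson on rank residuals after regressing out
control RDMs), one-tailed group t-tests with Benjamini–Hochberg FDR, and
paired task contrasts.

**Synthetic oracle.** A Manhattan-room simulator renders exact ground
truth (segmentation, corners, vanishing points) by forward projection and
fabricates optionally jittered annotations, so the whole pipeline is
validated as a parameter-recovery experiment with no external data.

## Worked example

Simulate a room, annotate it with 1 px of noise, and reconstruct:

```r
library(scenelayout)

scene_spec <- sample_room(42)
scene <- render_ground_truth(scene_spec$room, scene_spec$camera)
scene
#> <synthetic_scene  7.6x7.7x2.7 m room, yaw 19.8 deg, f 421 px, pitch 9.4,
#>  roll 4.1, 2 side wall(s) visible>

ann <- synth_annotations(scene, jitter_px = 1, rng_seed = 7)
cal <- calibrate_camera(ann$calibration)
cal$camera
#> <camera_model  f = 413.28 px  pitch = 9.851 deg  roll = 4.082 deg  hFOV = 76.36 deg>

corners <- outline_walls(ann$wall, cal$geometry)
seg <- rasterize_segmentation(corners)
pixel_error(seg, scene$seg)
#> 0.31

build_aerial_view(corners, cal$camera)
#> <aerial_view  FOV 76.4 deg, 2 wall(s)>
#>   wall 4: orientation 19.32 deg, span [-38.11, 10.66] deg
#>   wall 5: orientation 70.68 deg, span [10.66, 37.57] deg

round(as.numeric(reldist_feature(seg)), 3)
#> 0.431 0.393 0.356 0.414 0.538
```

With one pixel of annotation jitter the true camera (f = 421 px,
pitch 9.4°, roll 4.1°) comes back as f = 413 px, pitch 9.85°, roll 4.08°,
and only 0.31 % of pixels are mislabeled; the middle wall's recovered
plane angle (19.3°) matches the room's 19.8° heading. At zero jitter the
recovery is exact to machine precision.

The RSA stage works on any RDMs:

```r
res <- planted_dissociation_experiment(n_subjects = 8, n_conditions = 60, seed = 31)
res$group[, c("region", "model", "mean", "q")]
```

simulates two "brain regions", one coding relative distance and one coding
orientation, and shows the group pipeline attributing each region to its
planted model (q < 0.05) and rejecting the other (q > 0.05) while
controlling for three nuisance feature RDMs and the competing layout
model.

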