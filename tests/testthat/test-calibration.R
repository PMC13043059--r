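test_that("intersect_lines solves finite, parallel and coincident cases", {
  # hand solution of y = 2x and y = -x + 4
  s1 <- segment2d(c(0, 0), c(1, 2))
  s2 <- segment2d(c(4, 0), c(3, 1))
  expect_equal(hpoint_xy(intersect_lines(s1, s2)), c(4 / 3, 8 / 3),
               tolerance = 1e-12)
  # both lines through the origin
  s3 <- segment2d(c(0, 0), c(2, 0))
  s4 <- segment2d(c(0, 0), c(2, 2))
  expect_equal(hpoint_xy(intersect_lines(s3, s4)), c(0, 0), tolerance = 1e-12)
  # two horizontal lines: point at infinity along (1, 0)
  p <- intersect_lines(segment2d(c(0, 0), c(10, 0)),
                       segment2d(c(0, 5), c(10, 5)))
  expect_true(is_infinite_point(p))
  expect_equal(abs(p[1] / sqrt(p[1]^2 + p[2]^2)), 1)
  # coincident lines
  expect_error(intersect_lines(segment2d(c(0, 0), c(10, 0)),
                               segment2d(c(20, 0), c(30, 0))),
               "degenerate")
})

test_that("worked micro-scene: geometry, focal length, axis VPs, V3, pose", {
  g <- micro_scene_geometry()
  expect_equal(hpoint_xy(g$v1), c(-500, -100), tolerance = 1e-9)
  expect_equal(hpoint_xy(g$v2), c(700, -100), tolerance = 1e-9)
  expect_equal(g$oh, c(0, -100), tolerance = 1e-9)
  expect_equal(g$h, sqrt(350000), tolerance = 1e-12)

  f <- estimate_focal(g)
  expect_equal(f^2, 340000, tolerance = 1e-12)

  g <- locate_axis_vps(g)
  expect_equal(hpoint_xy(g$vs), c(0, -100), tolerance = 1e-9)  # Vs = Oh
  expect_true(is_infinite_point(g$vc))

  g <- locate_v3(g)
  expect_equal(hpoint_xy(g$v3), c(0, 3400), tolerance = 1e-6)
  # altitude-from-V1 orthogonality: (O - V1) . (V3 - V2) = 0
  expect_equal(sum(c(500, 100) * (c(0, 3400) - c(700, -100))), 0)
  # f^2 from the (V1, V3) orthogonal pair agrees with (V1, V2)
  f2_13 <- -sum(hpoint_xy(g$v1) * hpoint_xy(g$v3))
  expect_equal(f2_13, f^2, tolerance = 1e-9)

  cam <- recover_pose(g, f)
  expect_equal(cam$roll_deg, 0, tolerance = 1e-9)
  expect_equal(abs(cam$pitch_deg), atan(100 / f) * 180 / pi, tolerance = 1e-9)
  expect_equal(abs(cam$pitch_deg), 9.7315, tolerance = 1e-4)
  # rotation is orthonormal with det +1
  expect_equal(unname(t(cam$rotation) %*% cam$rotation), diag(3),
               tolerance = 1e-12)
  expect_equal(det(cam$rotation), 1, tolerance = 1e-12)
})

test_that("symmetric horizon through the center gives Oh = O and h = |OV1|", {
  frame <- image_frame(650, 520)
  v1 <- c(-600 + frame$cx, frame$cy)
  v2 <- c(600 + frame$cx, frame$cy)
  seg_through <- function(p, ang) {
    segment2d(p + 150 * c(cos(ang), sin(ang)), p + 350 * c(cos(ang), sin(ang)))
  }
  ann <- calibration_annotation(
    pair_u = list(seg_through(v1, 0.4), seg_through(v1, 0.9)),
    pair_v = list(seg_through(v2, 2.4), seg_through(v2, 2.8)), frame = frame)
  g <- build_vanishing_geometry(ann)
  expect_equal(g$oh, c(0, 0), tolerance = 1e-9)
  expect_equal(g$h, 600, tolerance = 1e-9)
  expect_equal(estimate_focal(g), 600, tolerance = 1e-9)
  # horizon through O: V3 at infinity, pose is the identity
  g <- locate_v3(locate_axis_vps(g))
  expect_true(is_infinite_point(g$v3))
  cam <- recover_pose(g, 600)
  expect_equal(cam$pitch_deg, 0, tolerance = 1e-9)
  expect_equal(cam$roll_deg, 0, tolerance = 1e-9)
})

test_that("same-side vanishing points are rejected as inconsistent", {
  frame <- image_frame(650, 520)
  v1 <- c(100 + frame$cx, -100 + frame$cy)
  v2 <- c(700 + frame$cx, -100 + frame$cy)
  seg_through <- function(p, ang) {
    segment2d(p + 150 * c(cos(ang), sin(ang)), p + 350 * c(cos(ang), sin(ang)))
  }
  ann <- calibration_annotation(
    pair_u = list(seg_through(v1, 0.4), seg_through(v1, 0.9)),
    pair_v = list(seg_through(v2, 2.4), seg_through(v2, 2.8)), frame = frame)
  expect_error(build_vanishing_geometry(ann), "inconsistent annotation")
})

test_that("|OhVs| * |OhVc| = h^2 on rolled synthetic scenes", {
  for (seed in 1:12) {
    scene <- scenelayout:::sample_scene(seed)
    ann <- synth_annotations(scene, 0, 1)
    g <- locate_axis_vps(build_vanishing_geometry(ann$calibration))
    if (is_infinite_point(g$vs) || is_infinite_point(g$vc)) next
    d_vs <- sqrt(sum((hpoint_xy(g$vs) - g$oh)^2))
    d_vc <- sqrt(sum((hpoint_xy(g$vc) - g$oh)^2))
    expect_equal(d_vs * d_vc, g$h^2, tolerance = 1e-9)
    # Vs and Vc on opposite sides of Oh
    u <- scenelayout:::hline_dir(g$h_line)
    expect_lt(sum((hpoint_xy(g$vs) - g$oh) * u) *
                sum((hpoint_xy(g$vc) - g$oh) * u), 0)
  }
})

test_that("noise-free round trip recovers f, pitch, roll on random scenes", {
  for (seed in 101:125) {
    r <- pipeline_errors(seed)
    expect_lt(r$d_pitch, 1e-6)
    expect_lt(r$d_roll, 1e-6)
    expect_lt(r$rel_df, 1e-6)
  }
})

test_that("V3 matches the projected vertical vanishing point", {
  for (seed in c(3, 17, 31)) {
    scene <- scenelayout:::sample_scene(seed)
    ann <- synth_annotations(scene, 0, 1)
    g <- locate_v3(build_vanishing_geometry(ann$calibration))
    expect_equal(hpoint_xy(g$v3), hpoint_xy(scene$vps$v3), tolerance = 1e-6)
    # f^2 agrees between the (V1, V2) and (V1, V3) pairs
    f2 <- estimate_focal(g)^2
    expect_equal(-sum(hpoint_xy(g$v1) * hpoint_xy(g$v3)), f2,
                 tolerance = 1e-9 * f2)
  }
})

test_that("calibration depends only on centered coordinates", {
  # Same centered geometry expressed in two frames of different size:
  # coordinates shifted by the center offset give identical results.
  ann_small <- micro_scene_annotation(image_frame(650, 520))
  big <- image_frame(850, 620)  # center moves by (100, 50)
  shift <- function(s) segment2d(s[1, ] + c(100, 50), s[2, ] + c(100, 50))
  ann_big <- calibration_annotation(
    pair_u = lapply(ann_small$pair_u, shift),
    pair_v = lapply(ann_small$pair_v, shift), frame = big)
  cal_s <- calibrate_camera(ann_small)
  cal_b <- calibrate_camera(ann_big)
  expect_equal(cal_b$camera$focal_length_px, cal_s$camera$focal_length_px,
               tolerance = 1e-12)
  expect_equal(cal_b$camera$pitch_deg, cal_s$camera$pitch_deg,
               tolerance = 1e-12)
  expect_equal(cal_b$camera$roll_deg, cal_s$camera$roll_deg,
               tolerance = 1e-12)
})

test_that("degenerate annotations raise informative errors", {
  frame <- image_frame(100, 100)
  horiz <- list(segment2d(c(0, 10), c(50, 10)), segment2d(c(0, 40), c(50, 40)))
  vert <- list(segment2d(c(10, 0), c(10, 50)), segment2d(c(40, 0), c(40, 50)))
  ann <- calibration_annotation(horiz, vert, frame)
  expect_error(build_vanishing_geometry(ann), "no perspective")
  expect_error(segment2d(c(1, 1), c(1.5, 1.5)), "separated")
})
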