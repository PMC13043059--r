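# Shared fixtures, all built in code.

# Annotation whose vanishing points are exactly V1 = (-500, -100),
# V2 = (700, -100) in centered coordinates of a 650 x 520 frame: the
# worked micro-scene used throughout the calibration tests
# (h = sqrt(500 * 700), f = sqrt(340000), V3 = (0, 3400)).
micro_scene_annotation <- function(frame = image_frame(650, 520)) {
  v1 <- c(-500 + frame$cx, -100 + frame$cy)
  v2 <- c(700 + frame$cx, -100 + frame$cy)
  seg_through <- function(p, ang, r1 = 200, r2 = 400) {
    segment2d(p + r1 * c(cos(ang), sin(ang)), p + r2 * c(cos(ang), sin(ang)))
  }
  calibration_annotation(
    pair_u = list(seg_through(v1, 0.3), seg_through(v1, 0.7)),
    pair_v = list(seg_through(v2, 2.5), seg_through(v2, 2.9)),
    frame = frame)
}

micro_scene_geometry <- function() {
  build_vanishing_geometry(micro_scene_annotation())
}

# Random valid RDM on n conditions.
random_rdm <- function(n, ids = NULL) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- stats::runif(n * (n - 1) / 2)
  rdm(m + t(m), ids)
}

# Independent partial-Spearman oracle: explicit normal-equations solve on
# rank-transformed lower-triangle vectors, then Pearson correlation of the
# residuals. Shares no code with the package implementation.
oracle_partial_spearman <- function(neural, target, controls) {
  lv <- function(x) {
    m <- unclass(as.matrix(x))
    rank(m[lower.tri(m)], ties.method = "average")
  }
  y1 <- lv(neural); y2 <- lv(target)
  X <- cbind(1, vapply(controls, lv, numeric(length(y1))))
  beta1 <- solve(t(X) %*% X, t(X) %*% y1)
  beta2 <- solve(t(X) %*% X, t(X) %*% y2)
  r1 <- y1 - as.numeric(X %*% beta1)
  r2 <- y2 - as.numeric(X %*% beta2)
  sum(r1 * r2) / sqrt(sum(r1^2) * sum(r2^2))
}

# Brute-force renderer oracle: per-pixel scalar loop, nearest positive
# ray-plane intersection, written independently of the vectorized renderer.
oracle_render <- function(room, camera) {
  frame <- camera$frame
  rot <- scenelayout:::make_rotation(camera$pitch_deg, camera$roll_deg)
  g <- room$room_yaw_deg * pi / 180
  rzr <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
  cpos <- camera$position_m
  planes <- list(list(n = c(0, 0, 1), off = room$height_m - cpos[3], lab = 1L),
                 list(n = c(0, 0, 1), off = -cpos[3], lab = 2L),
                 list(n = rzr[, 1], off = -cpos[1], lab = 3L),
                 list(n = rzr[, 2], off = room$depth_m - cpos[2], lab = 4L),
                 list(n = rzr[, 1], off = room$width_m - cpos[1], lab = 5L),
                 list(n = rzr[, 2], off = -cpos[2], lab = 0L))
  out <- matrix(0L, frame$height_px, frame$width_px)
  for (col in seq_len(frame$width_px)) {
    for (row in seq_len(frame$height_px)) {
      d_cam <- c(((col - 1) - frame$cx) / camera$f_px,
                 ((row - 1) - frame$cy) / camera$f_px, 1)
      d <- as.numeric(t(rot) %*% d_cam)
      tb <- Inf; lb <- 0L
      for (pl in planes) {
        den <- sum(pl$n * d)
        if (den == 0) next
        tt <- pl$off / den
        if (tt > 0 && tt < tb) { tb <- tt; lb <- pl$lab }
      }
      out[row, col] <- lb
    }
  }
  out
}

# Full noise-free pipeline on one sampled scene; returns recovery errors.
pipeline_errors <- function(seed, jitter = 0) {
  scene <- scenelayout:::sample_scene(seed)
  ann <- synth_annotations(scene, jitter, rng_seed = seed + 7L)
  cal <- calibrate_camera(ann$calibration)
  corners <- outline_walls(ann$wall, cal$geometry)
  seg <- rasterize_segmentation(corners)
  av <- build_aerial_view(corners, cal$camera)
  mid <- Filter(function(w) w$label == 4L, av)[[1]]
  list(scene = scene, cal = cal, corners = corners, seg = seg, aerial = av,
       d_pitch = abs(cal$camera$pitch_deg - scene$camera$pitch_deg),
       d_roll = abs(cal$camera$roll_deg - scene$camera$roll_deg),
       rel_df = abs(cal$camera$focal_length_px - scene$camera$f_px) /
         scene$camera$f_px,
       d_orient = abs(mid$orientation_deg - abs(scene$room$room_yaw_deg)),
       pix = pixel_error(seg, scene$seg))
}
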