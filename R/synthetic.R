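#' Synthetic Manhattan rooms: forward projection ground truth
#'
#' The simulator samples rectangular rooms and cameras, renders exact
#' per-pixel layout segmentation maps by ray-plane intersection, projects
#' room corners and axis vanishing points, and fabricates (optionally
#' jittered) human-style line annotations. It is the package's ground-truth
#' oracle: every reconstruction quantity (focal length, pitch, roll, wall
#' outlines, orientations, segmentation) can be checked against the exact
#' forward model.
#'
#' Conventions: world frame x rightward, y forward, z upward, camera at the
#' origin; camera frame x rightward, y downward, z along the optical axis.
#' The world-to-camera rotation is `R = P(pitch) Rz(roll) M` where `M` maps
#' world axes to camera axes at identity pose, roll is about the optical
#' axis (positive = horizon clockwise in the displayed image) and pitch
#' about the image-horizontal axis (positive = optical axis raised). Yaw is
#' fixed at zero; the room's heading relative to the camera is carried by
#' `room_yaw_deg`.
#'
#' @name synthetic-scenes
NULL

# World->camera rotation for the stated convention.
make_rotation <- function(pitch_deg, roll_deg) {
  th <- pitch_deg * pi / 180
  rh <- roll_deg * pi / 180
  M <- rbind(c(1, 0, 0),
             c(0, 0, -1),
             c(0, 1, 0))
  Rz <- rbind(c(cos(rh), -sin(rh), 0),
              c(sin(rh), cos(rh), 0),
              c(0, 0, 1))
  P <- rbind(c(1, 0, 0),
             c(0, cos(th), sin(th)),
             c(0, -sin(th), cos(th)))
  P %*% Rz %*% M
}

# Project world points (n x 3, camera at origin) to centered pixel coords.
project_points <- function(pts, rot, f) {
  cam <- pts %*% t(rot)
  if (any(cam[, 3] <= 1e-12)) {
    stop("point at or behind the camera plane cannot be projected")
  }
  cbind(f * cam[, 1] / cam[, 3], f * cam[, 2] / cam[, 3])
}

# Vanishing point of a world direction, as a centered-coordinate hpoint.
project_direction <- function(d, rot, f) {
  cam <- as.numeric(rot %*% d)
  if (abs(cam[3]) < 1e-14 * sqrt(sum(cam^2))) {
    return(hpoint_inf(cam[1], cam[2]))
  }
  hpoint(f * cam[1] / cam[3], f * cam[2] / cam[3])
}

#' Room and camera specifications
#'
#' @param width_m,depth_m,height_m Interior dimensions in metres.
#' @param room_yaw_deg Heading of the room's forward axis relative to the
#'   camera's forward axis (degrees; the camera's own yaw is zero by
#'   convention).
#' @return `room_spec` / `camera_spec` objects.
#' @export
room_spec <- function(width_m, depth_m, height_m, room_yaw_deg = 0) {
  stopifnot(width_m > 0, depth_m > 0, height_m > 0)
  structure(list(width_m = width_m, depth_m = depth_m, height_m = height_m,
                 room_yaw_deg = room_yaw_deg, n_side_walls = NA_integer_),
            class = "room_spec")
}

#' @rdname room_spec
#' @param position_m Camera position in room coordinates (x across, y into
#'   the room, z above the floor); must be strictly inside the room.
#' @param pitch_deg,roll_deg Camera self-pose angles (degrees).
#' @param f_px Focal length in pixels.
#' @param frame An [image_frame()].
#' @export
camera_spec <- function(position_m, pitch_deg, roll_deg, f_px, frame) {
  stopifnot(length(position_m) == 3, f_px > 0, inherits(frame, "image_frame"),
            abs(pitch_deg) < 45, abs(roll_deg) < 30)
  structure(list(position_m = as.numeric(position_m), pitch_deg = pitch_deg,
                 roll_deg = roll_deg, f_px = f_px, frame = frame),
            class = "camera_spec")
}

#' Default sampling ranges for the synthetic experiments
#'
#' Focal length 300-1200 px, pitch -30..30 deg, roll -10..10 deg, room yaw
#' -30..30 deg on a 650 x 520 frame; room dimensions 3-8 m across and deep
#' with 2.4-3.3 m ceilings and an eye-height camera placed in the back
#' half of the room.
#'
#' @return Named list of c(min, max) ranges plus frame dimensions.
#' @export
default_scene_ranges <- function() {
  list(f_px = c(300, 1200), pitch_deg = c(-30, 30), roll_deg = c(-10, 10),
       room_yaw_deg = c(-30, 30), width_m = c(3, 8), depth_m = c(3, 8),
       height_m = c(2.4, 3.3), cam_x_rel = c(0.35, 0.65),
       cam_y_rel = c(0.10, 0.35), cam_z_m = c(1.4, 1.8),
       frame_w = 650, frame_h = 520)
}

# Draw uniformly from a c(min, max) range.
runif_range <- function(r) if (r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's global RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Sample a random room and camera
#'
#' Deterministic given `rng_seed`; all parameters drawn uniformly from
#' `ranges`.
#'
#' @param rng_seed Integer seed.
#' @param ranges As returned by [default_scene_ranges()].
#' @return List with `room` ([room_spec()]) and `camera` ([camera_spec()]).
#' @export
sample_room <- function(rng_seed, ranges = default_scene_ranges()) {
  with_seed(rng_seed, {
    room <- room_spec(width_m = runif_range(ranges$width_m),
                      depth_m = runif_range(ranges$depth_m),
                      height_m = runif_range(ranges$height_m),
                      room_yaw_deg = runif_range(ranges$room_yaw_deg))
    frame <- image_frame(ranges$frame_w, ranges$frame_h)
    pos <- c(runif_range(ranges$cam_x_rel) * room$width_m,
             runif_range(ranges$cam_y_rel) * room$depth_m,
             min(runif_range(ranges$cam_z_m), 0.9 * room$height_m))
    camera <- camera_spec(position_m = pos,
                          pitch_deg = runif_range(ranges$pitch_deg),
                          roll_deg = runif_range(ranges$roll_deg),
                          f_px = runif_range(ranges$f_px),
                          frame = frame)
    list(room = room, camera = camera)
  })
}

# Room->world rotation about the vertical axis.
room_rotation <- function(room) {
  g <- room$room_yaw_deg * pi / 180
  rbind(c(cos(g), -sin(g), 0),
        c(sin(g), cos(g), 0),
        c(0, 0, 1))
}

#' Render exact ground truth for a synthetic scene
#'
#' Casts one ray per pixel center; since the room is convex, the visible
#' surface is the boundary plane with the smallest positive ray parameter.
#' Labels: 1 ceiling, 2 floor, 3 left wall, 4 middle (far) wall, 5 right
#' wall (positional labels, ordered left to right).
#'
#' @param room A [room_spec()].
#' @param camera A [camera_spec()].
#' @return Object of class `synthetic_scene`: `room`, `camera`, `seg`
#'   (layout_segmentation), `corners` (projected far-wall corner and edge
#'   points, 0-based pixel coords), `vps` (exact vanishing points of the
#'   room axes, centered coords), `rotation`.
#' @export
render_ground_truth <- function(room, camera) {
  frame <- camera$frame
  f <- camera$f_px
  rot <- make_rotation(camera$pitch_deg, camera$roll_deg)
  rzr <- room_rotation(room)
  cpos <- camera$position_m
  stopifnot(cpos[1] > 0, cpos[1] < room$width_m,
            cpos[2] > 0, cpos[2] < room$depth_m,
            cpos[3] > 0, cpos[3] < room$height_m)

  # Bounding planes n . X = off in world coordinates (camera at origin).
  nx <- rzr[, 1]; ny <- rzr[, 2]; nz <- c(0, 0, 1)
  planes <- list(
    ceiling = list(n = nz, off = room$height_m - cpos[3], label = 1L),
    floor   = list(n = nz, off = -cpos[3], label = 2L),
    left    = list(n = nx, off = -cpos[1], label = 3L),
    far     = list(n = ny, off = room$depth_m - cpos[2], label = 4L),
    right   = list(n = nx, off = room$width_m - cpos[1], label = 5L),
    near    = list(n = ny, off = -cpos[2], label = 0L))

  w <- frame$width_px; hh <- frame$height_px
  xs <- (0:(w - 1)) - frame$cx
  ys <- (0:(hh - 1)) - frame$cy
  # Ray directions in world coordinates, one column block per pixel.
  dx_cam <- rep(xs, each = hh) / f
  dy_cam <- rep(ys, times = w) / f
  rt <- t(rot)  # camera->world
  dwx <- rt[1, 1] * dx_cam + rt[1, 2] * dy_cam + rt[1, 3]
  dwy <- rt[2, 1] * dx_cam + rt[2, 2] * dy_cam + rt[2, 3]
  dwz <- rt[3, 1] * dx_cam + rt[3, 2] * dy_cam + rt[3, 3]

  tbest <- rep(Inf, w * hh)
  lab <- integer(w * hh)
  for (pl in planes) {
    den <- pl$n[1] * dwx + pl$n[2] * dwy + pl$n[3] * dwz
    t <- pl$off / den
    hit <- is.finite(t) & t > 0 & t < tbest
    tbest[hit] <- t[hit]
    lab[hit] <- pl$label
  }
  seg <- matrix(lab, nrow = hh, ncol = w)
  seg <- new_layout_segmentation(seg, frame)

  # Far-wall key points (room coordinates) and their projections.
  key_room <- rbind(
    c(0, room$depth_m, 0),                        # bottom-left corner
    c(room$width_m, room$depth_m, 0),             # bottom-right corner
    c(room$width_m, room$depth_m, room$height_m), # top-right corner
    c(0, room$depth_m, room$height_m),            # top-left corner
    c(room$width_m / 2, room$depth_m, 0),         # bottom mid edge
    c(room$width_m / 2, room$depth_m, room$height_m)) # top mid edge
  key_world <- sweep(key_room, 2, cpos) %*% t(rzr)
  key_px <- project_points(key_world, rot, f)
  key_px <- uncenter_xy(frame, key_px)
  rownames(key_px) <- c("p6", "p7", "p3", "p2", "l2_floor", "l2_ceiling")

  vps <- list(v1 = project_direction(rzr[, 1], rot, f),
              v2 = project_direction(rzr[, 2], rot, f),
              v3 = project_direction(c(0, 0, 1), rot, f))

  room$n_side_walls <- sum(c(3L, 4L, 5L) %in% seg)
  structure(list(room = room, camera = camera, seg = seg,
                 corners = key_px, vps = vps, rotation = rot),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene  %.1fx%.1fx%.1f m room, yaw %.1f deg, f %.0f px, pitch %.1f, roll %.1f, %d side wall(s) visible>\n",
              x$room$width_m, x$room$depth_m, x$room$height_m,
              x$room$room_yaw_deg, x$camera$f_px, x$camera$pitch_deg,
              x$camera$roll_deg, x$room$n_side_walls))
  invisible(x)
}

# Project a room-coordinate point of a rendered scene to 0-based pixels.
scene_project <- function(scene, q_room) {
  w <- sweep(rbind(q_room), 2, scene$camera$position_m) %*% t(room_rotation(scene$room))
  px <- project_points(w, scene$rotation, scene$camera$f_px)
  uncenter_xy(scene$camera$frame, px)[1, ]
}

#' Simulate human line annotations for a rendered scene
#'
#' The calibration pair along the room's across direction uses the far
#' wall's ceiling and floor junction edges; the orthogonal pair uses the
#' ceiling and floor junctions of the most visible side wall. The wall
#' annotation marks the far wall: L1 along its floor edge with endpoints at
#' the true wall-wall corners, L2 spanning ceiling to floor at the wall's
#' horizontal middle. Isotropic Gaussian jitter of scale `jitter_px` is
#' added independently to every endpoint coordinate.
#'
#' @param scene A [render_ground_truth()] result.
#' @param jitter_px Annotation noise scale in pixels (0 = exact).
#' @param rng_seed Integer seed for the jitter stream.
#' @return List with `calibration` (a [calibration_annotation()]) and
#'   `wall` (a [wall_annotation()], position "middle").
#' @export
synth_annotations <- function(scene, jitter_px = 0, rng_seed = 1) {
  room <- scene$room
  cpos <- scene$camera$position_m
  side_px <- c(left = sum(scene$seg == 3L), right = sum(scene$seg == 5L))
  if (all(side_px == 0) || !(4L %in% scene$seg)) {
    stop("degenerate scene: middle wall or both side walls out of view")
  }
  wside <- if (side_px["right"] >= side_px["left"]) "right" else "left"
  xw <- if (wside == "right") room$width_m else 0
  # Near endpoint of the side-wall edge segments: as close to the camera as
  # possible while keeping both the floor and ceiling points safely in
  # front of the camera plane (a steeply pitched camera can put nearby
  # floor or ceiling points behind it).
  rzr <- room_rotation(room)
  depth_of <- function(q_room) {
    (scene$rotation %*% (rzr %*% (q_room - cpos)))[3]
  }
  y_near <- NA_real_
  for (frac in c(0.25, 0.4, 0.55, 0.7, 0.85)) {
    y_try <- cpos[2] + frac * (room$depth_m - cpos[2])
    if (depth_of(c(xw, y_try, 0)) > 0.1 &&
        depth_of(c(xw, y_try, room$height_m)) > 0.1) {
      y_near <- y_try
      break
    }
  }
  if (is.na(y_near)) stop("degenerate scene: no visible stretch of side-wall edge")

  pr <- function(q) scene_project(scene, q)
  seg_from <- function(qa, qb) segment2d(pr(qa), pr(qb))

  pair_u <- list(
    seg_from(c(0, room$depth_m, room$height_m), c(room$width_m, room$depth_m, room$height_m)),
    seg_from(c(0, room$depth_m, 0), c(room$width_m, room$depth_m, 0)))
  pair_v <- list(
    seg_from(c(xw, y_near, room$height_m), c(xw, room$depth_m, room$height_m)),
    seg_from(c(xw, y_near, 0), c(xw, room$depth_m, 0)))
  l1 <- seg_from(c(0, room$depth_m, 0), c(room$width_m, room$depth_m, 0))
  l2 <- seg_from(c(room$width_m / 2, room$depth_m, room$height_m),
                 c(room$width_m / 2, room$depth_m, 0))

  if (jitter_px > 0) {
    jit <- function(s) segment2d(s[1, ] + stats::rnorm(2, 0, jitter_px),
                                 s[2, ] + stats::rnorm(2, 0, jitter_px))
    jittered <- with_seed(rng_seed, {
      list(pair_u = lapply(pair_u, jit), pair_v = lapply(pair_v, jit),
           l1 = jit(l1), l2 = jit(l2))
    })
    pair_u <- jittered$pair_u; pair_v <- jittered$pair_v
    l1 <- jittered$l1; l2 <- jittered$l2
  }
  list(calibration = calibration_annotation(pair_u, pair_v, scene$camera$frame),
       wall = wall_annotation(l1, l2, "middle"))
}

# Sample + render, resampling degenerate draws from an incremented stream.
sample_scene <- function(rng_seed, ranges = default_scene_ranges(),
                         max_tries = 64) {
  for (k in seq_len(max_tries) - 1L) {
    spec <- sample_room(rng_seed + k, ranges)
    scene <- try(render_ground_truth(spec$room, spec$camera), silent = TRUE)
    if (inherits(scene, "try-error")) next
    if ((4L %in% scene$seg) && any(c(3L, 5L) %in% scene$seg)) {
      attr(scene, "resamples") <- k
      return(scene)
    }
  }
  stop("could not sample a non-degenerate scene after ", max_tries, " tries")
}

#' Full parameter-recovery experiment over synthetic scenes
#'
#' For each scene: sample and render ground truth, simulate annotations at
#' the requested jitter, run the full pipeline (calibration, pose recovery,
#' wall outlining, rasterization), and record absolute pitch/roll errors,
#' relative focal error, wall-orientation error, and segmentation pixel
#' error. Pipeline failures are recorded as failure rows, never dropped.
#'
#' @param n_scenes Number of scenes.
#' @param jitter_px Annotation jitter (pixels).
#' @param seed Master seed; every scene's sampling and jitter stream
#'   derives from it.
#' @param ranges Scene parameter ranges, see [default_scene_ranges()].
#' @return List of class `recovery_experiment`: `scenes` (one row per
#'   scene) and `summary` (means and SDs over successful scenes).
#' @export
recovery_experiment <- function(n_scenes, jitter_px = 0, seed = 1,
                                ranges = default_scene_ranges()) {
  stopifnot(n_scenes >= 1)
  scene_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 100L, n_scenes))
  rows <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    scene <- sample_scene(scene_seeds[i], ranges)
    res <- tryCatch({
      ann <- synth_annotations(scene, jitter_px, rng_seed = scene_seeds[i] + 7L)
      cal <- calibrate_camera(ann$calibration)
      corners <- outline_walls(ann$wall, cal$geometry)
      seg <- rasterize_segmentation(corners)
      av <- build_aerial_view(corners, cal$camera)
      ori_rec <- Filter(function(w) w$label == 4L, av)[[1]]$orientation_deg
      data.frame(
        scene = i,
        f_true = scene$camera$f_px, f_rec = cal$camera$focal_length_px,
        pitch_true = scene$camera$pitch_deg, pitch_rec = cal$camera$pitch_deg,
        roll_true = scene$camera$roll_deg, roll_rec = cal$camera$roll_deg,
        abs_pitch_err_deg = abs(cal$camera$pitch_deg - scene$camera$pitch_deg),
        abs_roll_err_deg = abs(cal$camera$roll_deg - scene$camera$roll_deg),
        rel_f_err = abs(cal$camera$focal_length_px - scene$camera$f_px) /
          scene$camera$f_px,
        orient_err_deg = abs(ori_rec - abs(scene$room$room_yaw_deg)),
        pixel_err_pct = pixel_error(seg, scene$seg),
        ok = TRUE)
    }, error = function(e) {
      data.frame(scene = i, f_true = scene$camera$f_px, f_rec = NA_real_,
                 pitch_true = scene$camera$pitch_deg, pitch_rec = NA_real_,
                 roll_true = scene$camera$roll_deg, roll_rec = NA_real_,
                 abs_pitch_err_deg = NA_real_, abs_roll_err_deg = NA_real_,
                 rel_f_err = NA_real_, orient_err_deg = NA_real_,
                 pixel_err_pct = NA_real_, ok = FALSE)
    })
    rows[[i]] <- res
  }
  tab <- do.call(rbind, rows)
  met <- c("abs_pitch_err_deg", "abs_roll_err_deg", "rel_f_err",
           "orient_err_deg", "pixel_err_pct")
  summ <- data.frame(
    metric = met,
    mean = vapply(met, function(m) mean(tab[[m]], na.rm = TRUE), 0),
    sd = vapply(met, function(m) stats::sd(tab[[m]], na.rm = TRUE), 0),
    max = vapply(met, function(m) max(tab[[m]], na.rm = TRUE), 0),
    row.names = NULL)
  structure(list(scenes = tab, summary = summ,
                 n_failed = sum(!tab$ok), jitter_px = jitter_px, seed = seed),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat(sprintf("<recovery_experiment  n = %d scenes, jitter = %g px, %d failure(s)>\n",
              nrow(x$scenes), x$jitter_px, x$n_failed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# camera_model carrying the generator's exact parameters (for running the
# layout stages against ground truth, bypassing annotation calibration).
truth_camera_model <- function(scene) {
  cam <- scene$camera
  structure(list(frame = cam$frame, focal_length_px = cam$f_px,
                 pitch_deg = cam$pitch_deg, roll_deg = cam$roll_deg,
                 rotation = scene$rotation,
                 h_px = cam$f_px / cos(cam$pitch_deg * pi / 180),
                 fov_h_deg = 2 * atan(cam$frame$width_px / (2 * cam$f_px)) *
                   180 / pi),
            class = "camera_model")
}

# vanishing_geometry built from the generator's exact camera rather than
# from annotations; valid even where annotation pairs would be degenerate
# (e.g. an axis-parallel direction vanishing at infinity).
truth_geometry <- function(scene) {
  f <- scene$camera$f_px
  v1 <- scene$vps$v1; v2 <- scene$vps$v2
  h_line <- cross3(as.numeric(v1), as.numeric(v2))
  oh <- hline_foot_origin(h_line)
  g <- structure(list(v1 = v1, v2 = v2, h_line = h_line, oh = oh,
                      h = sqrt(f^2 + sum(oh^2)), frame = scene$camera$frame),
                 class = "vanishing_geometry")
  g$v3 <- scene$vps$v3
  locate_axis_vps(g)
}

# Exact aerial-view wall description from the true room geometry: azimuths
# of the far-wall corners and the wall-plane angles relative to frontal.
truth_aerial <- function(scene) {
  room <- scene$room; cpos <- scene$camera$position_m
  rzr <- room_rotation(room)
  az <- function(q_room) {
    w <- as.numeric(rzr %*% (q_room - cpos))
    atan2(w[1], w[2]) * 180 / pi
  }
  a_left <- az(c(0, room$depth_m, 0))
  a_right <- az(c(room$width_m, room$depth_m, 0))
  fov2 <- atan(scene$camera$frame$width_px / (2 * scene$camera$f_px)) * 180 / pi
  ori_mid <- abs(room$room_yaw_deg)
  list(mid = c(a_left, a_right), fov_half = fov2,
       orientation_mid = ori_mid, orientation_side = 90 - ori_mid)
}
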