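#' Image frame with centered principal point
#'
#' The principal point is assumed to sit at the exact image center,
#' `((width - 1) / 2, (height - 1) / 2)` in 0-based pixel-center
#' coordinates. All projective computation inside the package runs in
#' *centered* coordinates (pixel coordinates minus the principal point,
#' x rightward, y downward), which makes the principal point the origin.
#'
#' @param width_px,height_px Image dimensions in pixels (integers >= 2).
#' @return An object of class `image_frame`.
#' @export
image_frame <- function(width_px, height_px) {
  width_px <- as.integer(width_px)
  height_px <- as.integer(height_px)
  stopifnot(width_px >= 2, height_px >= 2)
  structure(list(width_px = width_px, height_px = height_px,
                 cx = (width_px - 1) / 2, cy = (height_px - 1) / 2),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame %d x %d px, principal point (%.1f, %.1f)>\n",
              x$width_px, x$height_px, x$cx, x$cy))
  invisible(x)
}

# Pixel -> centered coordinates and back. `xy` is a length-2 vector or a
# 2-column matrix.
center_xy <- function(frame, xy) {
  if (is.matrix(xy)) return(cbind(xy[, 1] - frame$cx, xy[, 2] - frame$cy))
  c(xy[1] - frame$cx, xy[2] - frame$cy)
}

uncenter_xy <- function(frame, xy) {
  if (is.matrix(xy)) return(cbind(xy[, 1] + frame$cx, xy[, 2] + frame$cy))
  c(xy[1] + frame$cx, xy[2] + frame$cy)
}

#' 2D line segment
#'
#' @param a,b Endpoints, length-2 numeric vectors in 0-based pixel
#'   coordinates (x rightward, y downward). Endpoints closer than 1 px are
#'   rejected: such an annotation carries no usable direction.
#' @return A 2x2 matrix (rows = endpoints) of class `segment2d`.
#' @export
segment2d <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == 2, length(b) == 2, all(is.finite(c(a, b))))
  if (sqrt(sum((a - b)^2)) <= 1) {
    stop("degenerate annotation: segment endpoints are not separated by more than 1 px")
  }
  structure(rbind(a = a, b = b), class = c("segment2d", "matrix"))
}

seg_dir <- function(seg) {
  d <- seg[2, ] - seg[1, ]
  d / sqrt(sum(d^2))
}

seg_line <- function(seg) hline_through_xy(seg[1, ], seg[2, ])

# Apply a coordinate shift to a segment (used to move into centered coords).
seg_shift <- function(seg, dx, dy) {
  structure(rbind(a = seg[1, ] - c(dx, dy), b = seg[2, ] - c(dx, dy)),
            class = c("segment2d", "matrix"))
}

#' Calibration annotation: two orthogonal pairs of ground-parallel lines
#'
#' Each pair marks two image edges that are parallel to each other and to
#' the ground in 3D; the two pairs are mutually orthogonal in 3D. The
#' intersection of each pair is a vanishing point, and the line joining the
#' two vanishing points is the horizon.
#'
#' @param pair_u,pair_v Lists of two [segment2d()] each.
#' @param frame An [image_frame()].
#' @return Object of class `calibration_annotation`.
#' @export
calibration_annotation <- function(pair_u, pair_v, frame) {
  stopifnot(inherits(frame, "image_frame"),
            length(pair_u) == 2, length(pair_v) == 2)
  pair_u <- lapply(pair_u, function(s) if (inherits(s, "segment2d")) s else segment2d(s[1, ], s[2, ]))
  pair_v <- lapply(pair_v, function(s) if (inherits(s, "segment2d")) s else segment2d(s[1, ], s[2, ]))
  structure(list(pair_u = pair_u, pair_v = pair_v, frame = frame),
            class = "calibration_annotation")
}

#' Intersect the infinite lines through two segments
#'
#' Returns the homogeneous intersection point of the two infinite lines
#' supporting the segments. If the lines are parallel within
#' `tol_parallel_deg` the intersection is reported at infinity along the
#' shared direction: sub-pixel annotation noise on short, nearly parallel
#' segments would otherwise place an absurd finite vanishing point at an
#' enormous but meaningless coordinate.
#'
#' @param seg_a,seg_b [segment2d()] objects (any consistent 2D coordinate
#'   system).
#' @param tol_parallel_deg Angular tolerance (degrees) below which the two
#'   lines are treated as parallel.
#' @return An [hpoint()]; at infinity when the lines are parallel.
#' @export
intersect_lines <- function(seg_a, seg_b, tol_parallel_deg = 0.01) {
  d1 <- seg_dir(seg_a)
  d2 <- seg_dir(seg_b)
  cross <- d1[1] * d2[2] - d1[2] * d2[1]
  sin_tol <- sin(tol_parallel_deg * pi / 180)
  if (abs(cross) < sin_tol) {
    # Parallel within tolerance. Coincident lines carry no vanishing point.
    l1 <- seg_line(seg_a)
    dist_b <- abs(hline_eval(l1, seg_b[1, 1], seg_b[1, 2])) /
      sqrt(l1[1]^2 + l1[2]^2)
    if (dist_b < 1e-9) stop("degenerate annotation: the two segments lie on the same line")
    return(hpoint_inf(d1[1], d1[2]))
  }
  hline_intersect(seg_line(seg_a), seg_line(seg_b))
}

#' Build the projective skeleton of an image from a calibration annotation
#'
#' Computes the two vanishing points V1, V2 of the annotated orthogonal
#' ground-parallel directions, the horizon line H through them, the foot
#' point Oh of the principal point on H, and the scalar
#' `h = sqrt(|OhV1| * |OhV2|)`. The orthogonality of the two annotated 3D
#' directions forces V1 and V2 to lie on opposite sides of Oh along the
#' horizon; annotations violating this admit no real focal length and are
#' rejected.
#'
#' All stored coordinates are *centered* (principal point at the origin).
#'
#' @param annot A [calibration_annotation()].
#' @param tol_parallel_deg Passed to [intersect_lines()].
#' @return Object of class `vanishing_geometry` with fields `v1`, `v2`
#'   ([hpoint()]s), `h_line` (homogeneous line), `oh` (length-2), `h`
#'   (scalar, px), and `frame`.
#' @export
build_vanishing_geometry <- function(annot, tol_parallel_deg = 0.01) {
  stopifnot(inherits(annot, "calibration_annotation"))
  frame <- annot$frame
  cseg <- function(s) seg_shift(s, frame$cx, frame$cy)
  v1 <- intersect_lines(cseg(annot$pair_u[[1]]), cseg(annot$pair_u[[2]]),
                        tol_parallel_deg)
  v2 <- intersect_lines(cseg(annot$pair_v[[1]]), cseg(annot$pair_v[[2]]),
                        tol_parallel_deg)
  if (is_infinite_point(v1) && is_infinite_point(v2)) {
    stop("no perspective information: both vanishing points are at infinity")
  }
  if (is_infinite_point(v1) || is_infinite_point(v2)) {
    stop("insufficient perspective: a vanishing point at infinity leaves the focal length undetermined")
  }
  p1 <- hpoint_xy(v1); p2 <- hpoint_xy(v2)
  if (sqrt(sum((p1 - p2)^2)) < 1e-9) {
    stop("degenerate annotation: the two vanishing points coincide")
  }
  h_line <- hline_through(v1, v2)
  oh <- hline_foot_origin(h_line)
  u <- hline_dir(h_line)
  s1 <- sum((p1 - oh) * u)
  s2 <- sum((p2 - oh) * u)
  if (s1 * s2 >= 0) {
    stop("inconsistent annotation: vanishing points on the same side of Oh (orthogonality impossible)")
  }
  structure(list(v1 = v1, v2 = v2, h_line = h_line, oh = oh,
                 h = sqrt(abs(s1) * abs(s2)), frame = frame),
            class = "vanishing_geometry")
}

#' @export
print.vanishing_geometry <- function(x, ...) {
  cat(sprintf("<vanishing_geometry  V1 (%.2f, %.2f)  V2 (%.2f, %.2f)  h = %.2f px>\n",
              hpoint_xy(x$v1)[1], hpoint_xy(x$v1)[2],
              hpoint_xy(x$v2)[1], hpoint_xy(x$v2)[2], x$h))
  invisible(x)
}

#' Estimate the focal length from the vanishing geometry
#'
#' `f^2 = h^2 - |OOh|^2`, equivalently `f^2 = -(V1 - O) . (V2 - O)` in
#' centered coordinates; the two forms are algebraically identical for an
#' orthogonal pair and both are computed as a numerical cross-check.
#'
#' @param geom A `vanishing_geometry` object.
#' @return Focal length in pixels (positive scalar).
#' @export
estimate_focal <- function(geom) {
  stopifnot(inherits(geom, "vanishing_geometry"))
  p1 <- hpoint_xy(geom$v1); p2 <- hpoint_xy(geom$v2)
  f2_dot <- -sum(p1 * p2)
  f2_h <- geom$h^2 - sum(geom$oh^2)
  if (f2_dot <= 0) {
    stop("inconsistent annotation: h^2 <= |OOh|^2, no real focal length")
  }
  if (abs(f2_dot - f2_h) > 1e-9 * abs(f2_dot)) {
    stop("internal inconsistency between the two focal-length forms")
  }
  sqrt(f2_dot)
}

#' Locate the forward and left-right axis vanishing points Vs and Vc
#'
#' Vs is the intersection of the vertical line through the principal point
#' with the horizon; Vc sits on the horizon at distance `h^2 / |OhVs|` from
#' Oh on the opposite side. At zero roll Vs coincides with Oh and Vc is the
#' point at infinity along the horizon.
#'
#' @param geom A `vanishing_geometry` object.
#' @return The geometry with fields `vs` and `vc` ([hpoint()]s) added.
#' @export
locate_axis_vps <- function(geom) {
  stopifnot(inherits(geom, "vanishing_geometry"))
  l <- geom$h_line
  u <- hline_dir(l)
  # Vertical line through the (centered) principal point: x = 0. The two
  # lines are parallel only when the horizon itself is vertical (l[2] = 0).
  if (abs(l[2]) < .Machine$double.eps * max(abs(l))) {
    # Horizon parallel to the vertical axis (|roll| = 90 deg): Vs at infinity.
    vs <- hpoint_inf(0, 1)
    s_vs <- Inf
  } else {
    vs <- hline_intersect(l, c(1, 0, 0))
    s_vs <- sum((hpoint_xy(vs) - geom$oh) * u)
  }
  if (is.finite(s_vs) && abs(s_vs) < 1e-12 * max(1, geom$h)) {
    vc <- hpoint_inf(u[1], u[2])
    vs <- hpoint(geom$oh[1], geom$oh[2])
  } else if (!is.finite(s_vs)) {
    vc <- hpoint(geom$oh[1], geom$oh[2])
  } else {
    d <- geom$h^2 / abs(s_vs)
    xy <- geom$oh - sign(s_vs) * d * u
    vc <- hpoint(xy[1], xy[2])
  }
  geom$vs <- vs
  geom$vc <- vc
  geom
}

# K^-1 applied to a homogeneous point in centered pixel coordinates,
# returned as a unit 3-vector (camera-frame direction). Finite points are
# canonicalized to the forward (positive camera-z) direction; points at
# infinity map to image-plane-parallel unit directions with an arbitrary
# but fixed sign.
kinv_dir <- function(p, f) {
  p <- as.numeric(p)
  v <- c(p[1] / f, p[2] / f, p[3])
  if (v[3] < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Recover camera pitch and roll from the axis vanishing points
#'
#' The rotation columns are built from the axis vanishing points:
#' `r1 = K^-1 Vc / ||.||` (left-right axis), `r3 = K^-1 Vs / ||.||`
#' (forward axis), `r2 = r1 x r3` (vertical axis). Signs are fixed so that
#' the forward axis points in front of the camera (`r3_z > 0`) and the
#' rightward axis has a positive image-x component, which restricts pitch
#' and roll to (-90, 90) degrees. Then
#' `pitch = atan2(r3_y, r3_z)` (positive = optical axis raised, horizon
#' below the image center) and `roll = atan2(r2_x, r1_x)` (positive =
#' horizon rotated clockwise in the displayed image).
#'
#' @param geom A `vanishing_geometry` object carrying `vs`/`vc` (see
#'   [locate_axis_vps()]; they are computed on the fly if absent).
#' @param f Focal length in pixels.
#' @return Object of class `camera_model`: fields `frame`,
#'   `focal_length_px`, `pitch_deg`, `roll_deg`, `rotation` (orthonormal
#'   3x3, det +1, columns = camera-frame directions of the world right,
#'   forward and up axes), `fov_h_deg`.
#' @export
recover_pose <- function(geom, f) {
  stopifnot(inherits(geom, "vanishing_geometry"), f > 0)
  if (is.null(geom$vs)) geom <- locate_axis_vps(geom)
  r3 <- kinv_dir(geom$vs, f)
  if (r3[3] < 0) r3 <- -r3
  r1 <- kinv_dir(geom$vc, f)
  if (r1[1] < 0) r1 <- -r1
  if (sqrt(sum(cross3(r1, r3)^2)) < 1e-12) {
    stop("degenerate rotation: r1 parallel to r3")
  }
  r2 <- cross3(r1, r3)
  pitch <- atan2(r3[2], r3[3]) * 180 / pi
  roll <- atan2(r2[1], r1[1]) * 180 / pi
  # Orthonormal world->camera rotation, columns = right, forward, up.
  up <- r2 / sqrt(sum(r2^2))
  fwd <- r3
  right <- cross3(fwd, up)
  right <- right / sqrt(sum(right^2))
  rot <- cbind(right, fwd, up)
  structure(list(frame = geom$frame, focal_length_px = f,
                 pitch_deg = pitch, roll_deg = roll, rotation = rot,
                 h_px = geom$h,
                 fov_h_deg = 2 * atan(geom$frame$width_px / (2 * f)) * 180 / pi),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model  f = %.2f px  pitch = %.3f deg  roll = %.3f deg  hFOV = %.2f deg>\n",
              x$focal_length_px, x$pitch_deg, x$roll_deg, x$fov_h_deg))
  invisible(x)
}

#' Locate the vertical vanishing point V3
#'
#' The principal point is the orthocenter of the triangle V1 V2 V3, so V3
#' lies on the perpendicular from O to the horizon and satisfies
#' `(O - V1) . (V3 - V2) = 0`. When the horizon passes through O the
#' altitude never re-crosses it and V3 is at infinity along the
#' perpendicular direction.
#'
#' @param geom A `vanishing_geometry` object with finite V1, V2.
#' @return The geometry with field `v3` ([hpoint()]) added.
#' @export
locate_v3 <- function(geom) {
  stopifnot(inherits(geom, "vanishing_geometry"))
  l <- geom$h_line
  n <- c(l[1], l[2]) / sqrt(l[1]^2 + l[2]^2)
  p1 <- hpoint_xy(geom$v1); p2 <- hpoint_xy(geom$v2)
  f2 <- -sum(p1 * p2)
  delta <- sum(n * p1)  # signed distance of H from the origin
  if (abs(delta) < 1e-12 * max(1, sqrt(abs(f2)))) {
    geom$v3 <- hpoint_inf(n[1], n[2])
  } else {
    t <- -f2 / delta
    geom$v3 <- hpoint(t * n[1], t * n[2])
  }
  geom
}

#' Full single-image calibration pipeline
#'
#' Runs [build_vanishing_geometry()], [estimate_focal()],
#' [locate_axis_vps()], [locate_v3()] and [recover_pose()] in sequence.
#'
#' @inheritParams build_vanishing_geometry
#' @return List with `geometry` (a completed `vanishing_geometry` object) and
#'   `camera` (a `camera_model`).
#' @examples
#' fr <- image_frame(650, 520)
#' ann <- calibration_annotation(
#'   pair_u = list(segment2d(c(100, 400), c(300, 380)),
#'                 segment2d(c(120, 470), c(320, 430))),
#'   pair_v = list(segment2d(c(350, 380), c(550, 400)),
#'                 segment2d(c(330, 430), c(530, 470))),
#'   frame = fr)
#' cal <- calibrate_camera(ann)
#' cal$camera
#' @export
calibrate_camera <- function(annot, tol_parallel_deg = 0.01) {
  geom <- build_vanishing_geometry(annot, tol_parallel_deg)
  f <- estimate_focal(geom)
  geom <- locate_axis_vps(geom)
  geom <- locate_v3(geom)
  camera <- recover_pose(geom, f)
  list(geometry = geom, camera = camera)
}
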