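#' Wall annotation: one edge line and one height line
#'
#' `L1` marks a ground-parallel edge of the annotated wall with endpoints at
#' the wall-wall corners; `L2` marks the wall's vertical extent between its
#' ceiling and floor junctions. `position` names the annotated wall's role
#' when fewer than three side walls are present.
#'
#' @param L1,L2 [segment2d()] objects in 0-based pixel coordinates.
#' @param position One of "left", "middle", "right".
#' @return Object of class `wall_annotation`.
#' @export
wall_annotation <- function(L1, L2, position = c("middle", "left", "right")) {
  position <- match.arg(position)
  stopifnot(inherits(L1, "segment2d") || is.matrix(L1),
            inherits(L2, "segment2d") || is.matrix(L2))
  if (!inherits(L1, "segment2d")) L1 <- segment2d(L1[1, ], L1[2, ])
  if (!inherits(L2, "segment2d")) L2 <- segment2d(L2[1, ], L2[2, ])
  structure(list(L1 = L1, L2 = L2, position = position),
            class = "wall_annotation")
}

# Constructor for segmentation rasters: integer matrix (rows = image rows).
new_layout_segmentation <- function(mat, frame) {
  stopifnot(nrow(mat) == frame$height_px, ncol(mat) == frame$width_px)
  storage.mode(mat) <- "integer"
  structure(mat, class = c("layout_segmentation", "matrix"),
            frame = frame,
            legend = c(`0` = "unknown", `1` = "ceiling", `2` = "floor",
                       `3` = "left wall", `4` = "middle wall",
                       `5` = "right wall"))
}

#' @export
print.layout_segmentation <- function(x, ...) {
  cnt <- table(factor(x, levels = 0:5))
  cat(sprintf("<layout_segmentation %d x %d px>\n", ncol(x), nrow(x)))
  leg <- attr(x, "legend")
  for (k in names(cnt)) {
    if (cnt[[k]] > 0) cat(sprintf("  %s: %d px\n", leg[[k]], cnt[[k]]))
  }
  invisible(x)
}

# First intersection of the ray p + t*d (t > 0) with the frame's outer
# pixel boundary, in centered coordinates; NULL if the ray never enters.
ray_frame_exit <- function(p, d, frame) {
  bx <- frame$width_px / 2
  by <- frame$height_px / 2
  ts <- c(if (d[1] != 0) c((-bx - p[1]) / d[1], (bx - p[1]) / d[1]),
          if (d[2] != 0) c((-by - p[2]) / d[2], (by - p[2]) / d[2]))
  ts <- sort(ts[ts > 1e-12])
  for (t in ts) {
    q <- p + t * d
    if (q[1] >= -bx - 1e-9 && q[1] <= bx + 1e-9 &&
        q[2] >= -by - 1e-9 && q[2] <= by + 1e-9) {
      return(q)
    }
  }
  NULL
}

in_frame <- function(p, frame) {
  abs(p[1]) <= frame$width_px / 2 && abs(p[2]) <= frame$height_px / 2
}

#' Outline all side walls from one wall annotation
#'
#' Implements the corner construction: Va is the intersection of L1 with
#' the horizon; lines from Va through the endpoints of L2 are the annotated
#' wall's ceiling and floor junctions; lines from the vertical vanishing
#' point V3 through the endpoints of L1 are its junctions with the
#' neighbouring walls; their pairwise intersections give the annotated
#' wall's corners p2, p3, p6, p7. The orthogonal walls' vanishing point Vo
#' lies on the horizon at distance `h^2 / |OhVa|` from Oh opposite Va;
#' rays from the corners away from Vo, clipped to the frame boundary, give
#' the outer corners p1, p5 (left neighbour) and p4, p8 (right neighbour).
#' A frontal annotated wall (L1 parallel to the horizon) puts Va at
#' infinity and Vo at Oh; both are handled homogeneously.
#'
#' @param wall A [wall_annotation()] (0-based pixel coordinates).
#' @param geom A `vanishing_geometry` object; V3 is located on the fly if absent.
#' @return Object of class `layout_corners` with corner [hpoint()]s
#'   `p1`..`p8` (outer corners `NULL` when the corresponding wall is absent
#'   or out of frame), the boundary lines, `va`, `vo`, `v3` and the
#'   annotated wall's `position`. All coordinates centered.
#' @export
outline_walls <- function(wall, geom) {
  stopifnot(inherits(wall, "wall_annotation"),
            inherits(geom, "vanishing_geometry"))
  if (is.null(geom$v3)) geom <- locate_v3(geom)
  frame <- geom$frame
  l1 <- seg_shift(wall$L1, frame$cx, frame$cy)
  l2 <- seg_shift(wall$L2, frame$cx, frame$cy)
  if (l1[1, 1] > l1[2, 1]) l1 <- segment2d(l1[2, ], l1[1, ])  # left-to-right
  if (l2[1, 2] > l2[2, 2]) l2 <- segment2d(l2[2, ], l2[1, ])  # top first

  hl <- geom$h_line
  u <- hline_dir(hl)
  va <- hline_intersect(seg_line(l1), hl)
  ca <- hline_through(va, hpoint(l2[1, 1], l2[1, 2]))  # ceiling junction
  cf <- hline_through(va, hpoint(l2[2, 1], l2[2, 2]))  # floor junction
  wl <- hline_through(geom$v3, hpoint(l1[1, 1], l1[1, 2]))
  wr <- hline_through(geom$v3, hpoint(l1[2, 1], l1[2, 2]))

  p2 <- hline_intersect(ca, wl); p3 <- hline_intersect(ca, wr)
  p6 <- hline_intersect(cf, wl); p7 <- hline_intersect(cf, wr)
  for (p in list(p2, p3, p6, p7)) {
    if (is_infinite_point(p)) stop("invalid corner set: wall corner at infinity")
  }

  # Vo: |OhVo| = h^2 / |OhVa|, opposite side of Oh from Va.
  if (is_infinite_point(va)) {
    vo <- hpoint(geom$oh[1], geom$oh[2])
  } else {
    s_va <- sum((hpoint_xy(va) - geom$oh) * u)
    if (abs(s_va) < 1e-12 * max(1, geom$h)) {
      vo <- hpoint_inf(u[1], u[2])
    } else {
      xy <- geom$oh - sign(s_va) * (geom$h^2 / abs(s_va)) * u
      vo <- hpoint(xy[1], xy[2])
    }
  }

  # Outer corners: ray from the annotated wall's corner away from Vo,
  # clipped to the frame; absent when the corner is outside the frame or
  # the neighbouring wall does not exist.
  outer_corner <- function(p, away_from) {
    pxy <- hpoint_xy(p)
    if (!in_frame(pxy, frame)) return(NULL)
    if (is_infinite_point(vo)) {
      d <- hpoint_dir(vo)
      if (sum(d * away_from) < 0) d <- -d
    } else {
      d <- pxy - hpoint_xy(vo)
      nd <- sqrt(sum(d^2))
      if (nd < 1e-9) return(NULL)
      d <- d / nd
      if (sum(d * away_from) < 0) d <- -d
    }
    q <- ray_frame_exit(pxy, d, frame)
    if (is.null(q)) NULL else hpoint(q[1], q[2])
  }
  dir_left <- hpoint_xy(p2) - hpoint_xy(p3)
  has_left <- wall$position %in% c("middle", "right")
  has_right <- wall$position %in% c("middle", "left")
  p1 <- if (has_left) outer_corner(p2, dir_left) else NULL
  p5 <- if (has_left) outer_corner(p6, dir_left) else NULL
  p4 <- if (has_right) outer_corner(p3, -dir_left) else NULL
  p8 <- if (has_right) outer_corner(p7, -dir_left) else NULL

  # Sanity: ceiling junction above floor junction at the annotated wall.
  if (hpoint_xy(p2)[2] >= hpoint_xy(p6)[2] ||
      hpoint_xy(p3)[2] >= hpoint_xy(p7)[2]) {
    stop("invalid corner set: ceiling and floor junctions cross")
  }

  structure(list(p1 = p1, p2 = p2, p3 = p3, p4 = p4,
                 p5 = p5, p6 = p6, p7 = p7, p8 = p8,
                 va = va, vo = vo, v3 = geom$v3,
                 lines = list(ca = ca, cf = cf, wl = wl, wr = wr),
                 h_line = geom$h_line, oh = geom$oh, h = geom$h,
                 position = wall$position, frame = frame),
            class = "layout_corners")
}

#' @export
print.layout_corners <- function(x, ...) {
  fmt <- function(p) {
    if (is.null(p)) return("-")
    xy <- hpoint_xy(p); sprintf("(%.1f, %.1f)", xy[1], xy[2])
  }
  cat(sprintf("<layout_corners  %s wall annotated>\n", x$position))
  cat("  top:   ", fmt(x$p1), fmt(x$p2), fmt(x$p3), fmt(x$p4), "\n")
  cat("  bottom:", fmt(x$p5), fmt(x$p6), fmt(x$p7), fmt(x$p8), "\n")
  invisible(x)
}

# Signed line evaluation over the full pixel grid (centered coords),
# returned as an height x width matrix.
line_field <- function(l, frame) {
  xs <- (0:(frame$width_px - 1)) - frame$cx
  ys <- (0:(frame$height_px - 1)) - frame$cy
  outer(l[2] * ys, l[1] * xs, "+") + l[3]
}

#' Rasterize a layout corner set into a segmentation map
#'
#' Pixel-center sampling against the exact boundary lines: the region above
#' the ceiling junction of the wall under each pixel is ceiling, below the
#' floor junction is floor, and the in-between band is split into left,
#' middle and right walls by the vertical wall-wall junction lines.
#' Boundary pixels whose center lies exactly on a line are assigned to the
#' wall band, and on wall-wall boundaries to the lower (leftmost) label,
#' so re-rasterizing is bit-exact. Labels: 0 unknown, 1 ceiling, 2 floor,
#' 3 left wall, 4 middle wall, 5 right wall (positional, left to right).
#'
#' @param corners A [outline_walls()] result.
#' @return A `layout_segmentation` (integer matrix, rows = image rows).
#' @export
rasterize_segmentation <- function(corners) {
  stopifnot(inherits(corners, "layout_corners"))
  frame <- corners$frame
  ln <- corners$lines
  p2 <- hpoint_xy(corners$p2); p3 <- hpoint_xy(corners$p3)
  p6 <- hpoint_xy(corners$p6); p7 <- hpoint_xy(corners$p7)
  mid_ref <- (p2 + p3 + p6 + p7) / 4

  sgn_at <- function(l, p) hline_eval(l, p[1], p[2])
  # Wall-role labels: the annotated wall takes its position's label and the
  # outlined neighbours take the adjacent ones.
  lab_ann <- switch(corners$position, left = 3L, middle = 4L, right = 5L)

  S_wl <- line_field(ln$wl, frame)
  S_wr <- line_field(ln$wr, frame)
  s_mid_wl <- sgn_at(ln$wl, mid_ref)
  s_mid_wr <- sgn_at(ln$wr, mid_ref)
  left_mask <- S_wl * s_mid_wl <= 0   # ties toward the lower label
  right_mask <- (S_wr * s_mid_wr < 0) & !left_mask
  mid_mask <- !(left_mask | right_mask)

  lab <- matrix(0L, frame$height_px, frame$width_px)

  band_fill <- function(mask, cl, fl, ref, wall_label) {
    if (is.null(cl) || is.null(fl)) {
      lab[mask] <<- 0L
      return(invisible())
    }
    s_c <- sgn_at(cl, ref); s_f <- sgn_at(fl, ref)
    S_c <- line_field(cl, frame); S_f <- line_field(fl, frame)
    ceiling_m <- mask & (S_c * s_c < 0)
    floor_m <- mask & (S_f * s_f < 0) & !ceiling_m
    wall_m <- mask & !ceiling_m & !floor_m
    lab[ceiling_m] <<- 1L
    lab[floor_m] <<- 2L
    lab[wall_m] <<- wall_label
  }

  band_fill(mid_mask, ln$ca, ln$cf, mid_ref, lab_ann)

  side_lines <- function(pc, pf) {
    # Junction lines of a neighbour wall: through Vo and the shared corners.
    list(cl = hline_through(corners$vo, corners[[pc]]),
         fl = hline_through(corners$vo, corners[[pf]]))
  }
  side_ref <- function(pa, pb, toward) {
    m <- (hpoint_xy(corners[[pa]]) + hpoint_xy(corners[[pb]])) / 2
    step <- min(1, 0.01 * sqrt(sum((hpoint_xy(corners[[pa]]) -
                                      hpoint_xy(corners[[pb]]))^2)))
    m + step * toward / sqrt(sum(toward^2))
  }

  has_left <- corners$position %in% c("middle", "right")
  has_right <- corners$position %in% c("middle", "left")
  dir_left <- p2 - p3

  if (any(left_mask)) {
    if (has_left) {
      sl <- side_lines("p2", "p6")
      band_fill(left_mask, sl$cl, sl$fl, side_ref("p2", "p6", dir_left),
                if (lab_ann == 5L) 4L else 3L)
    } else {
      # No wall beyond the annotated wall's left edge: extend the ceiling
      # and floor junctions and leave the band unknown.
      band_fill(left_mask, ln$ca, ln$cf, mid_ref, 0L)
    }
  }
  if (any(right_mask)) {
    if (has_right) {
      sr <- side_lines("p3", "p7")
      band_fill(right_mask, sr$cl, sr$fl, side_ref("p3", "p7", -dir_left),
                if (lab_ann == 3L) 4L else 5L)
    } else {
      band_fill(right_mask, ln$ca, ln$cf, mid_ref, 0L)
    }
  }
  new_layout_segmentation(lab, frame)
}

#' Percentage of misclassified pixels between two segmentation maps
#'
#' @param seg,truth `layout_segmentation` rasters of identical dimensions.
#' @return Percentage in \[0, 100\].
#' @export
pixel_error <- function(seg, truth) {
  if (!all(dim(seg) == dim(truth))) {
    stop("dimension mismatch between segmentation maps")
  }
  100 * mean(unclass(seg) != unclass(truth))
}

#' Orientation angles of the annotated and orthogonal walls
#'
#' `theta_a = atan(|OhVa| / h)` and `theta_o = atan(|OhVo| / h)`; the two
#' are exact complements (`tan(theta_a) tan(theta_o) = 1`). These are the
#' angles of the walls' *edge directions*; the wall-plane angle relative to
#' frontal (0 deg = facing the observer) is `90 - theta`. A frontal
#' annotated wall has Va at infinity, `theta_a = 90` by the formula's
#' limit, and plane angle 0.
#'
#' @param geom A `vanishing_geometry` object.
#' @param wall A [wall_annotation()] (or a bare [segment2d()] taken as L1)
#'   locating Va.
#' @return List with `theta_a_deg`, `theta_o_deg`.
#' @export
wall_orientations <- function(geom, wall) {
  stopifnot(inherits(geom, "vanishing_geometry"))
  l1 <- if (inherits(wall, "wall_annotation")) wall$L1 else wall
  l1 <- seg_shift(l1, geom$frame$cx, geom$frame$cy)
  va <- hline_intersect(seg_line(l1), geom$h_line)
  if (is_infinite_point(va)) {
    return(list(theta_a_deg = 90, theta_o_deg = 0))
  }
  u <- hline_dir(geom$h_line)
  s_va <- abs(sum((hpoint_xy(va) - geom$oh) * u))
  theta_a <- atan(s_va / geom$h) * 180 / pi
  list(theta_a_deg = theta_a, theta_o_deg = 90 - theta_a)
}

#' Aerial-view wall descriptions: orientation and angular span
#'
#' Converts a corner set into observer-centred wall descriptions. Each
#' wall's angular span runs between the world azimuths of its vertical
#' junction lines (where those meet the horizon), with outer walls
#' extended to the frame edge and all spans clipped to `[-FOV/2, +FOV/2]`.
#' Azimuths are obtained by mapping horizon points back to world-horizontal
#' directions through the recovered camera rotation, which reduces to the
#' horizon-distance form `phi = atan(u / h)` at zero roll and stays exact
#' for rolled cameras. Orientations are wall-plane angles relative to
#' frontal (0 deg = facing the observer): `90 - |azimuth(Va edge
#' direction)|` for the annotated wall and its complement for the
#' neighbours.
#'
#' @param corners A [outline_walls()] result.
#' @param camera A `camera_model` (field of view and rotation).
#' @return List of class `aerial_view`; each element has `label`,
#'   `orientation_deg`, `phi_start_deg`, `phi_end_deg`.
#' @export
build_aerial_view <- function(corners, camera) {
  stopifnot(inherits(corners, "layout_corners"))
  frame <- corners$frame
  fov2 <- camera$fov_h_deg / 2
  rt <- t(camera$rotation)  # camera -> world
  azim <- function(p) {
    # p: image point (or direction) on the horizon -> world azimuth.
    d <- rt %*% kinv_dir(p, camera$focal_length_px)
    atan2(d[1], d[2]) * 180 / pi
  }
  az_on_h <- function(l) azim(hline_intersect(l, corners$h_line))

  a2 <- az_on_h(corners$lines$wl)
  a3 <- az_on_h(corners$lines$wr)
  if (a2 > a3) { tmp <- a2; a2 <- a3; a3 <- tmp }
  # Azimuths of the frame's side edges on the horizon line.
  a_edge_l <- az_on_h(c(1, 0, frame$width_px / 2))
  a_edge_r <- az_on_h(c(1, 0, -frame$width_px / 2))
  lo <- max(-fov2, min(a_edge_l, a_edge_r))
  hi <- min(fov2, max(a_edge_l, a_edge_r))

  # Wall-plane angle of the annotated wall: fold the edge-direction azimuth
  # into (-90, 90] and take the complement of its magnitude.
  b <- azim(corners$va)
  if (b > 90) b <- b - 180
  if (b <= -90) b <- b + 180
  ori_ann <- 90 - abs(b)
  ori_orth <- 90 - ori_ann

  lab_ann <- switch(corners$position, left = 3L, middle = 4L, right = 5L)
  walls <- list()
  add_wall <- function(label, ori, lo_w, hi_w) {
    lo_w <- max(lo_w, lo); hi_w <- min(hi_w, hi)
    if (hi_w - lo_w <= 1e-12) {
      if (hi_w - lo_w >= 0 && hi_w >= lo && lo_w <= hi) {
        warning("wall with zero horizontal extent dropped from aerial view")
      }
      return(invisible())
    }
    walls[[length(walls) + 1]] <<- structure(
      list(label = label, orientation_deg = ori,
           phi_start_deg = lo_w, phi_end_deg = hi_w),
      class = "aerial_wall")
  }
  if (corners$position %in% c("middle", "right")) {
    add_wall(if (lab_ann == 5L) 4L else 3L, ori_orth, lo, a2)
  }
  add_wall(lab_ann, ori_ann, a2, a3)
  if (corners$position %in% c("middle", "left")) {
    add_wall(if (lab_ann == 3L) 4L else 5L, ori_orth, a3, hi)
  }
  structure(walls, class = "aerial_view", fov_deg = camera$fov_h_deg)
}

#' @export
print.aerial_view <- function(x, ...) {
  cat(sprintf("<aerial_view  FOV %.1f deg, %d wall(s)>\n",
              attr(x, "fov_deg"), length(x)))
  for (w in x) {
    cat(sprintf("  wall %d: orientation %.2f deg, span [%.2f, %.2f] deg\n",
                w$label, w$orientation_deg, w$phi_start_deg, w$phi_end_deg))
  }
  invisible(x)
}

#' Horizontally mirror a segmentation map
#'
#' Flips the raster left-right and swaps the left/right wall labels; useful
#' for symmetry checks of the feature models.
#'
#' @param seg A `layout_segmentation`.
#' @export
mirror_segmentation <- function(seg) {
  frame <- attr(seg, "frame")
  m <- unclass(seg)[, ncol(seg):1]
  flipped <- m
  flipped[m == 3L] <- 5L
  flipped[m == 5L] <- 3L
  new_layout_segmentation(flipped, frame)
}
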