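#' Homogeneous 2D points and lines
#'
#' All projective arithmetic in the package runs on homogeneous 3-vectors so
#' that points at infinity (pure directions, third component zero) are
#' first-class values rather than special cases: the left-right vanishing
#' point at zero roll, the orthogonal-wall vanishing point for a side-on
#' annotated wall, and the vertical vanishing point when the horizon passes
#' through the principal point all live at infinity in perfectly legal
#' scenes.
#'
#' @param x,y Cartesian coordinates (finite point) or direction components
#'   (point at infinity).
#' @return A numeric 3-vector of class `hpoint`.
#' @examples
#' hpoint(3, -2)
#' hpoint_inf(1, 0)   # the horizontal direction
#' @export
hpoint <- function(x, y) {
  structure(c(as.numeric(x), as.numeric(y), 1), class = "hpoint")
}

#' @rdname hpoint
#' @export
hpoint_inf <- function(x, y) {
  if (x == 0 && y == 0) stop("direction of a point at infinity cannot be zero")
  structure(c(as.numeric(x), as.numeric(y), 0), class = "hpoint")
}

as_hpoint <- function(p) {
  if (inherits(p, "hpoint")) return(p)
  p <- as.numeric(p)
  if (length(p) == 2) return(hpoint(p[1], p[2]))
  if (length(p) == 3) {
    if (all(p == 0)) stop("all-zero homogeneous point")
    return(structure(p, class = "hpoint"))
  }
  stop("cannot interpret object as a homogeneous point")
}

#' Test whether a homogeneous point lies at infinity
#' @param p An `hpoint`.
#' @export
is_infinite_point <- function(p) {
  p <- as_hpoint(p)
  p[3] == 0
}

#' Cartesian coordinates of a finite homogeneous point
#' @param p An `hpoint`.
#' @return Length-2 numeric vector.
#' @export
hpoint_xy <- function(p) {
  p <- as_hpoint(p)
  if (p[3] == 0) stop("point at infinity has no Cartesian coordinates")
  c(p[1] / p[3], p[2] / p[3])
}

#' @export
print.hpoint <- function(x, ...) {
  if (x[3] == 0) {
    cat(sprintf("<point at infinity, direction (%g, %g)>\n", x[1], x[2]))
  } else {
    xy <- hpoint_xy(x)
    cat(sprintf("<point (%g, %g)>\n", xy[1], xy[2]))
  }
  invisible(x)
}

# Unit direction of a point at infinity (or of a finite point from origin).
hpoint_dir <- function(p) {
  d <- c(p[1], p[2])
  d / sqrt(sum(d^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Homogeneous line through two homogeneous points.
hline_through <- function(p, q) {
  l <- cross3(as.numeric(p), as.numeric(q))
  if (all(abs(l) < .Machine$double.eps)) stop("points are identical; no unique line")
  l
}

# Homogeneous line from two Cartesian endpoints.
hline_through_xy <- function(a, b) hline_through(hpoint(a[1], a[2]), hpoint(b[1], b[2]))

# Intersection of two homogeneous lines, as an hpoint.
hline_intersect <- function(l1, l2) {
  p <- cross3(l1, l2)
  if (all(abs(p) < .Machine$double.eps * max(abs(l1)) * max(abs(l2)) * 4) ||
      all(p == 0)) {
    stop("degenerate annotation: lines are coincident")
  }
  structure(p, class = "hpoint")
}

# Signed evaluation of line at a finite point (for side tests).
hline_eval <- function(l, x, y) l[1] * x + l[2] * y + l[3]

# Foot of the perpendicular from the origin to line l = (a, b, c).
hline_foot_origin <- function(l) {
  nrm2 <- l[1]^2 + l[2]^2
  if (nrm2 == 0) stop("line at infinity has no foot point")
  c(-l[1] * l[3], -l[2] * l[3]) / nrm2
}

# Unit direction along line l.
hline_dir <- function(l) {
  d <- c(-l[2], l[1])
  d / sqrt(sum(d^2))
}
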