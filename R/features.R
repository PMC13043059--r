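#' Boundary orientation soft-histogram feature
#'
#' The horizontal field of view is divided into `n_bins` equal angular
#' bins with triangular (tent) kernels
#' `Fi(phi) = max(0, (sigma - |phi - phi_ic|) / sigma)`, `sigma` the bin
#' width and `phi_ic` the bin centers. The piecewise-constant wall
#' orientation field `O(phi)` (wall-plane angle at viewing direction `phi`,
#' degrees; 0 where no side wall is visible) is integrated against each
#' kernel by the midpoint rule on a fixed grid of 2000 steps:
#' `Ri = integral O(phi) Fi(phi) dphi` (degree * degree units).
#'
#' @param walls An `aerial_view` (list of walls with `orientation_deg`,
#'   `phi_start_deg`, `phi_end_deg`) or a plain list of such walls.
#' @param fov_deg Horizontal field of view in degrees.
#' @param n_bins Number of location bins (default 5).
#' @return Numeric feature vector of length `n_bins`, class
#'   `feature_vector`, kind "orientation".
#' @export
orientation_feature <- function(walls, fov_deg, n_bins = 5) {
  stopifnot(fov_deg > 0, n_bins >= 1)
  spans <- lapply(walls, function(w) c(w$phi_start_deg, w$phi_end_deg))
  if (length(spans) > 1) {
    ord <- order(vapply(spans, `[`, 0, 1))
    for (k in seq_len(length(spans) - 1)) {
      if (spans[[ord[k + 1]]][1] < spans[[ord[k]]][2] - 1e-9) {
        stop("inconsistent aerial view: overlapping wall spans")
      }
    }
  }
  n_steps <- 2000L
  dphi <- fov_deg / n_steps
  phi <- -fov_deg / 2 + (seq_len(n_steps) - 0.5) * dphi
  o <- numeric(n_steps)
  for (w in walls) {
    idx <- phi >= w$phi_start_deg & phi < w$phi_end_deg
    o[idx] <- w$orientation_deg
  }
  sigma <- fov_deg / n_bins
  centers <- -fov_deg / 2 + (seq_len(n_bins) - 0.5) * sigma
  r <- vapply(centers, function(cc) {
    fi <- pmax(0, (sigma - abs(phi - cc)) / sigma)
    sum(o * fi) * dphi
  }, 0)
  structure(r, class = "feature_vector", kind = "orientation")
}

#' Boundary relative-distance feature
#'
#' The image is divided into `n_bins` vertical strips with integer
#' boundaries `round(k * W / n_bins)`; the value of each strip is the
#' proportion of its pixels labeled as any side wall. Larger proportions
#' indicate nearer walls under perspective. The `area_difference` variant
#' reports instead the per-strip difference between the side-wall and the
#' ceiling-plus-floor pixel proportions.
#'
#' @param seg A `layout_segmentation`.
#' @param n_bins Number of strips (default 5); the image must be at least
#'   `n_bins` pixels wide.
#' @param method "proportion" (side-wall pixel proportion, the primary
#'   definition) or "area_difference".
#' @return Numeric vector of length `n_bins`, class `feature_vector`, kind
#'   "reldist"; proportions lie in \[0, 1\].
#' @export
reldist_feature <- function(seg, n_bins = 5,
                            method = c("proportion", "area_difference")) {
  method <- match.arg(method)
  w <- ncol(seg)
  if (w < n_bins) stop("image narrower than the number of strips")
  bounds <- round((0:n_bins) * w / n_bins)
  m <- unclass(seg)
  r <- vapply(seq_len(n_bins), function(k) {
    cols <- (bounds[k] + 1):bounds[k + 1]
    strip <- m[, cols, drop = FALSE]
    if (method == "proportion") {
      mean(strip >= 3L)
    } else {
      mean(strip >= 3L) - mean(strip == 1L | strip == 2L)
    }
  }, 0)
  structure(r, class = "feature_vector", kind = "reldist")
}

#' Representational dissimilarity matrix
#'
#' @param mat Square symmetric matrix with zero diagonal.
#' @param ids Condition labels (defaults to rownames or 1..n).
#' @return Object of class `rdm`.
#' @export
rdm <- function(mat, ids = NULL) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  stopifnot(n == ncol(mat), n >= 3)
  if (max(abs(mat - t(mat))) > 1e-8 * max(1, max(abs(mat)))) {
    stop("RDM must be symmetric")
  }
  if (max(abs(diag(mat))) > 1e-8) stop("RDM must have a zero diagonal")
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 0
  if (is.null(ids)) ids <- rownames(mat)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  dimnames(mat) <- list(ids, ids)
  structure(mat, class = c("rdm", "matrix"))
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm  %d conditions, dissimilarity range [%.4g, %.4g]>\n",
              nrow(x), min(x[lower.tri(x)]), max(x[lower.tri(x)])))
  invisible(x)
}

#' Lower-triangle vectorization of an RDM
#'
#' Fixed column-major lower-triangle ordering (excluding the diagonal), the
#' pair ordering shared by every correlation in the package.
#'
#' @param x An [rdm()].
#' @return Numeric vector of length `n (n - 1) / 2`.
#' @export
rdm_vec <- function(x) {
  m <- unclass(as.matrix(x))
  m[lower.tri(m)]
}

# Rebuild an rdm from a lower-triangle vector (inverse of rdm_vec).
rdm_from_vec <- function(v, n, ids = NULL) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  rdm(m, ids)
}

#' Model RDM from a feature matrix
#'
#' @param features Numeric matrix, one row per condition.
#' @param metric "cityblock" (layout feature models), "euclidean"
#'   (image-statistics models) or "cosine" (semantic models).
#' @return An [rdm()].
#' @export
model_rdm <- function(features,
                      metric = c("cityblock", "euclidean", "cosine")) {
  metric <- match.arg(metric)
  features <- as.matrix(features)
  stopifnot(nrow(features) >= 3)
  ids <- rownames(features)
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(features^2))
    if (any(nrm == 0)) {
      stop("cosine distance undefined for all-zero feature row(s): ",
           paste(which(nrm == 0), collapse = ", "))
    }
    cs <- (features %*% t(features)) / outer(nrm, nrm)
    m <- 1 - cs
    diag(m) <- 0
    return(rdm(m, ids))
  }
  d <- stats::dist(features,
                   method = if (metric == "cityblock") "manhattan" else "euclidean")
  rdm(as.matrix(d), ids)
}

#' Neural RDM from condition-by-channel activation patterns
#'
#' Dissimilarity between conditions is one minus the Pearson correlation of
#' their multichannel patterns. Averaging repeated presentations into one
#' pattern per condition is the caller's responsibility.
#'
#' @param patterns Numeric matrix, one row per condition, one column per
#'   channel/voxel.
#' @return An [rdm()].
#' @export
neural_rdm <- function(patterns) {
  patterns <- as.matrix(patterns)
  stopifnot(nrow(patterns) >= 3)
  v <- apply(patterns, 1, stats::var)
  if (any(v == 0)) {
    bad <- rownames(patterns)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("zero-variance pattern for condition(s): ", paste(bad, collapse = ", "))
  }
  m <- 1 - stats::cor(t(patterns))
  diag(m) <- 0
  rdm(m, rownames(patterns))
}
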