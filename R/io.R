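#' Annotation, camera, segmentation and RDM file formats
#'
#' All text formats round-trip exactly: integers as integers, reals with 17
#' significant digits. Segmentation maps are written as 8-bit grayscale PNG
#' whose pixel value is the label integer (and equivalently as CSV).
#'
#' @name file-formats
NULL

seg_to_json <- function(s) lapply(1:2, function(i) as.numeric(s[i, ]))
seg_from_json <- function(x) segment2d(unlist(x[[1]]), unlist(x[[2]]))

#' Read per-image annotation records from JSON
#'
#' One object per image:
#' `{"image": {"id", "width", "height"},
#'   "calibration": {"pair_u": [[[x,y],[x,y]], ...], "pair_v": [...]},
#'   "wall": {"L1": [[x,y],[x,y]], "L2": [...], "position": "left|middle|right"}}`
#' with coordinates as floats in 0-based pixel units.
#'
#' @param path JSON file.
#' @return List of records: `id`, `frame`, `calibration`
#'   ([calibration_annotation()]), `wall` ([wall_annotation()] or NULL).
#' @export
read_annotations <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(recs$image)) recs <- list(recs)  # single object
  lapply(recs, function(r) {
    if (is.null(r$image$width) || is.null(r$image$height)) {
      stop("malformed annotation JSON: missing image.width / image.height")
    }
    frame <- image_frame(r$image$width, r$image$height)
    cal <- NULL
    if (!is.null(r$calibration)) {
      if (length(r$calibration$pair_u) != 2 || length(r$calibration$pair_v) != 2) {
        stop("malformed annotation JSON: calibration.pair_u / pair_v must hold two segments")
      }
      cal <- calibration_annotation(
        pair_u = lapply(r$calibration$pair_u, seg_from_json),
        pair_v = lapply(r$calibration$pair_v, seg_from_json),
        frame = frame)
    }
    wl <- NULL
    if (!is.null(r$wall)) {
      if (is.null(r$wall$L1) || is.null(r$wall$L2)) {
        stop("malformed annotation JSON: wall.L1 / wall.L2 required")
      }
      wl <- wall_annotation(seg_from_json(r$wall$L1), seg_from_json(r$wall$L2),
                            position = if (is.null(r$wall$position)) "middle"
                                       else r$wall$position)
    }
    list(id = if (is.null(r$image$id)) NA_character_ else r$image$id,
         frame = frame, calibration = cal, wall = wl)
  })
}

#' @rdname read_annotations
#' @param records List of records as returned by [read_annotations()].
#' @export
write_annotations <- function(records, path) {
  out <- lapply(records, function(r) {
    o <- list(image = list(id = r$id, width = r$frame$width_px,
                           height = r$frame$height_px))
    if (!is.null(r$calibration)) {
      o$calibration <- list(pair_u = lapply(r$calibration$pair_u, seg_to_json),
                            pair_v = lapply(r$calibration$pair_v, seg_to_json))
    }
    if (!is.null(r$wall)) {
      o$wall <- list(L1 = seg_to_json(r$wall$L1), L2 = seg_to_json(r$wall$L2),
                     position = r$wall$position)
    }
    o
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Write / read a recovered camera as JSON
#'
#' Fields: `f_px`, `pitch_deg`, `roll_deg`, `fov_h_deg`, `h_px`, plus the
#' frame dimensions.
#'
#' @param camera A `camera_model`.
#' @param path Output path.
#' @export
write_camera_json <- function(camera, path) {
  jsonlite::write_json(
    list(f_px = camera$focal_length_px, pitch_deg = camera$pitch_deg,
         roll_deg = camera$roll_deg, fov_h_deg = camera$fov_h_deg,
         h_px = camera$h_px, width = camera$frame$width_px,
         height = camera$frame$height_px),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_camera_json
#' @export
read_camera_json <- function(path) {
  o <- jsonlite::fromJSON(path)
  frame <- image_frame(o$width, o$height)
  structure(list(frame = frame, focal_length_px = o$f_px,
                 pitch_deg = o$pitch_deg, roll_deg = o$roll_deg,
                 rotation = make_rotation(o$pitch_deg, o$roll_deg),
                 h_px = o$h_px, fov_h_deg = o$fov_h_deg),
            class = "camera_model")
}

#' Write / read segmentation rasters
#'
#' PNG: 8-bit grayscale, pixel value = label integer (0 unknown, 1 ceiling,
#' 2 floor, 3/4/5 left/middle/right wall). CSV: plain integer matrix.
#'
#' @param seg A `layout_segmentation`.
#' @param path Output path.
#' @export
write_segmentation_png <- function(seg, path) {
  png::writePNG(unclass(seg) / 255, path)
  invisible(path)
}

#' @rdname write_segmentation_png
#' @export
read_segmentation_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  new_layout_segmentation(m, image_frame(ncol(m), nrow(m)))
}

#' @rdname write_segmentation_png
#' @export
write_segmentation_csv <- function(seg, path) {
  utils::write.table(unclass(seg), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_segmentation_png
#' @export
read_segmentation_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  new_layout_segmentation(m, image_frame(ncol(m), nrow(m)))
}

fmt17 <- function(x) formatC(x, digits = 17, format = "g")

#' Write / read an RDM as CSV (square matrix, condition ids as header)
#'
#' @param x An [rdm()].
#' @param path Output path.
#' @export
write_rdm_csv <- function(x, path) {
  m <- matrix(fmt17(unclass(x)), nrow(x))
  df <- data.frame(condition = rownames(x), m, check.names = FALSE)
  colnames(df) <- c("condition", rownames(x))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rdm_csv
#' @export
read_rdm_csv <- function(path) {
  df <- utils::read.table(path, sep = ",", header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- list(ids, ids)
  rdm(m, ids)
}

#' Write / read a feature matrix as CSV (one row per condition)
#'
#' @param features Numeric matrix with column names (e.g. ori_1..ori_5,
#'   dist_1..dist_5, pitch, roll) and condition rownames.
#' @param path Output path.
#' @export
write_features_csv <- function(features, path) {
  features <- as.matrix(features)
  df <- data.frame(condition = if (is.null(rownames(features))) {
    as.character(seq_len(nrow(features)))
  } else rownames(features),
  matrix(fmt17(features), nrow(features)), check.names = FALSE)
  colnames(df) <- c("condition", colnames(features))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.table(path, sep = ",", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}
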