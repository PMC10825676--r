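# Internode length measurement from node annotations of calibrated
# stalk images.
#
# Stalks are photographed lying on a grid of known physical size with
# the stalk base at the top of the image; an object detector marks each
# node with a bounding box (normalized center-size records, one text
# file per image, named by the StalkID). Internode lengths are the
# Euclidean pixel distances between midpoints of vertically sorted node
# boxes, divided by the pixels-per-cm calibration of the grid.

#' Construct a node annotation set for one stalk image
#'
#' @param annotations data.frame with normalized columns \code{x_center},
#'   \code{y_center}, \code{width}, \code{height} (all in [0, 1]; pixel
#'   origin top-left, y increasing downward) and optionally
#'   \code{confidence}.
#' @param image_width_px,image_height_px Image dimensions in pixels.
#' @param calibration_px_per_cm Pixels per centimetre from the grid.
#' @param stalk_id Identifier string (usually from the image filename).
#' @return A \code{node_annotation_set}.
#' @export
node_annotation_set <- function(annotations, image_width_px, image_height_px,
                                calibration_px_per_cm, stalk_id = NA_character_) {
  stopifnot(image_width_px > 0, image_height_px > 0)
  if (calibration_px_per_cm <= 0) {
    stop("calibration must be positive", call. = FALSE)
  }
  need <- c("x_center", "y_center", "width", "height")
  stopifnot(all(need %in% names(annotations)))
  vals <- unlist(annotations[need])
  if (length(vals) && (any(vals < 0) || any(vals > 1))) {
    stop("annotations must be normalized to [0, 1]", call. = FALSE)
  }
  if (!"confidence" %in% names(annotations)) annotations$confidence <- NA_real_
  structure(list(annotations = annotations,
                 image_width_px = image_width_px,
                 image_height_px = image_height_px,
                 calibration_px_per_cm = calibration_px_per_cm,
                 stalk_id = stalk_id),
            class = "node_annotation_set")
}

#' @export
print.node_annotation_set <- function(x, ...) {
  cat(sprintf("%s: %d node boxes on %d x %d px image (%.2f px/cm)\n",
              x$stalk_id, nrow(x$annotations), x$image_width_px,
              x$image_height_px, x$calibration_px_per_cm))
  invisible(x)
}

#' Read one detector annotation file (normalized center-size records)
#'
#' Each line is \code{class x_center y_center width height [confidence]}
#' with coordinates normalized to the image; only the requested class is
#' kept.
#'
#' @param path Annotation text file.
#' @param image_width_px,image_height_px Image dimensions.
#' @param calibration_px_per_cm Grid calibration.
#' @param node_class Integer class id of node boxes (default 0).
#' @param stalk_id Identifier; defaults to the file's base name.
#' @return A [node_annotation_set()].
#' @export
read_annotation_file <- function(path, image_width_px, image_height_px,
                                 calibration_px_per_cm, node_class = 0L,
                                 stalk_id = NULL) {
  tab <- utils::read.table(path, header = FALSE, fill = TRUE)
  if (ncol(tab) < 5L) stop(sprintf("%s: expected at least 5 columns", path),
                           call. = FALSE)
  names(tab)[1:5] <- c("class", "x_center", "y_center", "width", "height")
  if (ncol(tab) >= 6L) names(tab)[[6L]] <- "confidence"
  tab <- tab[tab$class == node_class, , drop = FALSE]
  node_annotation_set(tab[-1L], image_width_px, image_height_px,
                      calibration_px_per_cm,
                      stalk_id %||% tools::file_path_sans_ext(basename(path)))
}

# Intersection-over-union of two center-size boxes in pixel units.
box_iou <- function(b1, b2) {
  ix <- max(0, min(b1$x + b1$w / 2, b2$x + b2$w / 2) -
                 max(b1$x - b1$w / 2, b2$x - b2$w / 2))
  iy <- max(0, min(b1$y + b1$h / 2, b2$y + b2$h / 2) -
                 max(b1$y - b1$h / 2, b2$y - b2$h / 2))
  inter <- ix * iy
  inter / (b1$w * b1$h + b2$w * b2$h - inter)
}

#' Internode lengths from a node annotation set
#'
#' Node boxes are sorted by image y (stalk base at the image top, so
#' basal nodes first; ties broken by x), duplicate detections
#' (IoU above \code{iou_threshold}) are collapsed to their first box with
#' a warning, and each internode length is the Euclidean pixel distance
#' between consecutive box midpoints divided by the calibration.
#'
#' @param set A [node_annotation_set()].
#' @param iou_threshold Overlap above which two boxes are treated as
#'   duplicate detections of one node.
#' @return An \code{internode_lengths} object: data.frame with
#'   \code{stalk_id}, \code{internode_index} (1 = most basal interval)
#'   and \code{length_cm}.
#' @export
internode_lengths <- function(set, iou_threshold = 0.5) {
  ann <- set$annotations
  if (nrow(ann) < 2L) {
    stop(sprintf("%s: fewer than 2 node annotations (%d)",
                 set$stalk_id, nrow(ann)), call. = FALSE)
  }
  px <- data.frame(x = ann$x_center * set$image_width_px,
                   y = ann$y_center * set$image_height_px,
                   w = ann$width * set$image_width_px,
                   h = ann$height * set$image_height_px)
  px <- px[order(px$y, px$x), ]
  keep <- rep(TRUE, nrow(px))
  for (i in seq_len(nrow(px))[-1L]) {
    if (keep[[i - 1L]] &&
        box_iou(px[i - 1L, ], px[i, ]) > iou_threshold) {
      keep[[i]] <- FALSE
    }
  }
  if (any(!keep)) {
    warning(sprintf("%s: collapsed %d duplicate node box(es) (IoU > %g)",
                    set$stalk_id, sum(!keep), iou_threshold), call. = FALSE)
    px <- px[keep, , drop = FALSE]
    if (nrow(px) < 2L) {
      stop(sprintf("%s: fewer than 2 nodes after duplicate collapse",
                   set$stalk_id), call. = FALSE)
    }
  }
  d_px <- sqrt(diff(px$x)^2 + diff(px$y)^2)
  structure(data.frame(stalk_id = set$stalk_id,
                       internode_index = seq_along(d_px),
                       length_cm = d_px / set$calibration_px_per_cm,
                       stringsAsFactors = FALSE),
            class = c("internode_lengths", "data.frame"))
}

#' Pixels-per-centimetre calibration from the imaging grid
#'
#' The imaging background is a grid of known physical size (e.g. the
#' 48 x 36 inch board). The scale is the pixel extent divided by the
#' physical extent; if the x and y scales differ by more than 1\% an
#' anisotropy warning is raised and the mean is used.
#'
#' @param grid_physical_cm Numeric length-2: grid width and height, cm.
#' @param grid_pixels Numeric length-2: corresponding extents in pixels.
#' @return Scale in px/cm.
#' @export
calibration_from_grid <- function(grid_physical_cm, grid_pixels) {
  stopifnot(length(grid_physical_cm) == 2L, length(grid_pixels) == 2L)
  if (any(grid_physical_cm <= 0) || any(grid_pixels <= 0)) {
    stop("grid dimensions must be positive", call. = FALSE)
  }
  scales <- grid_pixels / grid_physical_cm
  if (abs(diff(scales)) > 0.01 * mean(scales)) {
    warning(sprintf(
      "anisotropic calibration: %.4g vs %.4g px/cm; using the mean",
      scales[[1L]], scales[[2L]]), call. = FALSE)
  }
  mean(scales)
}

#' Collect annotation sets for a directory of per-stalk files
#'
#' Annotation files are named by StalkID (one per image). Image
#' dimensions come from a dimension index: a data.frame (or CSV path)
#' with columns \code{filename}, \code{width_px}, \code{height_px}.
#' Filenames that do not parse as a StalkID are skipped with a warning.
#'
#' @param directory Directory of annotation \code{.txt} files.
#' @param dimension_index data.frame or CSV path mapping file base names
#'   to pixel dimensions.
#' @param calibration_px_per_cm Grid calibration applied to every image.
#' @param node_class Detector class id of nodes.
#' @return List of [node_annotation_set()] objects, one per parseable
#'   stalk.
#' @export
associate_filenames <- function(directory, dimension_index,
                                calibration_px_per_cm, node_class = 0L) {
  if (is.character(dimension_index)) {
    dimension_index <- utils::read.csv(dimension_index,
                                       stringsAsFactors = FALSE)
  }
  files <- list.files(directory, pattern = "\\.txt$", full.names = TRUE)
  out <- list()
  for (f in files) {
    base <- tools::file_path_sans_ext(basename(f))
    ok <- tryCatch({ parse_stalk_id(base); TRUE },
                   error = function(e) FALSE)
    if (!ok) {
      warning(sprintf("skipping %s: filename is not a valid StalkID",
                      basename(f)), call. = FALSE)
      next
    }
    row <- dimension_index[dimension_index$filename == base, , drop = FALSE]
    if (nrow(row) == 0L) {
      warning(sprintf("skipping %s: no image dimensions in the index",
                      basename(f)), call. = FALSE)
      next
    }
    out[[base]] <- read_annotation_file(
      f, row$width_px[[1L]], row$height_px[[1L]], calibration_px_per_cm,
      node_class = node_class, stalk_id = base)
  }
  out
}

#' Internode length table for a directory of annotation files
#'
#' Convenience wrapper: [associate_filenames()] then
#' [internode_lengths()] per stalk, bound into one tidy table (the
#' "single spreadsheet" output of the imaging workflow).
#'
#' @inheritParams associate_filenames
#' @param ... Passed to [internode_lengths()].
#' @return data.frame: stalk_id, internode_index, length_cm.
#' @export
process_annotation_dir <- function(directory, dimension_index,
                                   calibration_px_per_cm, node_class = 0L,
                                   ...) {
  sets <- associate_filenames(directory, dimension_index,
                              calibration_px_per_cm, node_class)
  do.call(rbind, c(lapply(sets, internode_lengths, ...),
                   make.row.names = FALSE))
}
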