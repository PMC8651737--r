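# Cell counting: local maxima of the smoothed edge map accepted by
# topographic prominence, minimum-separation suppression, per-cell crop
# extraction, and the intact-cell / fragment split.

#' Find cell locations as prominent local maxima
#'
#' Every local maximum of the (preprocessed) edge map whose topographic
#' prominence -- its height above the highest saddle connecting it to
#' higher terrain -- reaches \code{min_prominence} marks one cell.
#' Maxima closer together than \code{min_distance} are reduced to the
#' most prominent one (ties broken by lower (row, col) lexicographic
#' order), suppressing double detections on a single cell rim.
#'
#' @param map an \code{edge_map} from \code{\link{preprocess_frame}}, or a
#'   numeric matrix. Prominence is measured in the map's own grayscale
#'   units; with the default chain these are Sobel units of the 8-bit
#'   contrast-enhanced frame.
#' @param min_prominence minimum topographic prominence accepted
#'   (default 50 grayscale units over the noise floor).
#' @param min_distance minimum separation between accepted points in
#'   pixels (default 20, about one cell diameter at 40x).
#' @param frame_index frame index recorded on each detection.
#' @return data.frame of detection points: \code{row}, \code{col},
#'   \code{height}, \code{prominence}, \code{frame_index}; zero rows for
#'   an empty or degenerate map.
#' @export
find_cell_maxima <- function(map, min_prominence = 50, min_distance = 20,
                             frame_index = 0L) {
  if (min_prominence <= 0) stop("`min_prominence` must be positive")
  if (min_distance < 1) stop("`min_distance` must be >= 1")
  m <- as_magnitude(map)
  empty <- data.frame(row = integer(0), col = integer(0),
                      height = numeric(0), prominence = numeric(0),
                      frame_index = integer(0))
  if (diff(range(m)) == 0) return(empty)
  peaks <- cpp_peak_prominence(m)
  peaks <- peaks[peaks$prominence >= min_prominence, , drop = FALSE]
  if (nrow(peaks) == 0) return(empty)
  # greedy minimum-distance suppression, most prominent first
  ord <- order(-peaks$prominence, peaks$row, peaks$col)
  peaks <- peaks[ord, , drop = FALSE]
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!any(keep)) { keep[i] <- TRUE; next }
    d2 <- (peaks$row[keep] - peaks$row[i])^2 +
          (peaks$col[keep] - peaks$col[i])^2
    keep[i] <- all(d2 >= min_distance^2)
  }
  out <- peaks[keep, , drop = FALSE]
  out <- out[order(out$row, out$col), , drop = FALSE]
  out$frame_index <- as.integer(frame_index)
  rownames(out) <- NULL
  out
}

#' Extract a square crop around a detection point
#'
#' The window should be at least twice the longest expected cell major
#' axis so the whole cell, including an asymmetric lobe, fits. Crops that
#' would extend past the frame are truncated and flagged; truncated crops
#' are excluded from morphometry by default (partial cells corrupt the
#' radial profile) and tallied separately.
#'
#' @param frame the source \code{\link{intensity_frame}} or matrix.
#' @param point one detection row (list/data.frame with \code{row},
#'   \code{col}) or a numeric \code{c(row, col)}.
#' @param window crop side length in pixels (default 64).
#' @return a \code{cell_crop}: list with \code{patch}, \code{origin}
#'   (row, col of patch\[1,1\] in the frame), \code{center} (the detection
#'   point), \code{boundary_truncated}.
#' @export
extract_crop <- function(frame, point, window = 64) {
  px <- as_pixels(frame)
  if (is.numeric(point) && length(point) == 2) {
    pr <- point[1]; pc <- point[2]
  } else {
    pr <- point$row; pc <- point$col
  }
  nr <- nrow(px); nc <- ncol(px)
  if (pr < 1 || pr > nr || pc < 1 || pc > nc)
    stop("detection point lies outside the frame")
  half <- floor(window / 2)
  r1 <- round(pr) - half; r2 <- r1 + window - 1L
  c1 <- round(pc) - half; c2 <- c1 + window - 1L
  truncated <- r1 < 1 || c1 < 1 || r2 > nr || c2 > nc
  rr <- max(r1, 1L):min(r2, nr)
  cc <- max(c1, 1L):min(c2, nc)
  structure(
    list(patch = px[rr, cc, drop = FALSE],
         origin = c(row = rr[1], col = cc[1]),
         center = c(row = pr, col = pc),
         boundary_truncated = truncated),
    class = "cell_crop")
}

#' @export
print.cell_crop <- function(x, ...) {
  cat(sprintf("<cell_crop> %d x %d px at (%d, %d)%s\n",
              nrow(x$patch), ncol(x$patch), x$origin[1], x$origin[2],
              if (x$boundary_truncated) " [truncated]" else ""))
  invisible(x)
}

#' Split detected objects into intact cells and fragments
#'
#' Objects whose binary-mask area falls below \code{min_cell_area} are
#' fragments/extracellular vesicles: they are tallied separately and
#' excluded from asymmetry and elongation analysis.
#'
#' @param masks list of \code{binary_mask} objects (from
#'   \code{\link{binarize_crop}}), or of logical matrices.
#' @param min_cell_area minimum foreground area (px^2) of an intact cell.
#' @return list with integer index vectors \code{cells} and
#'   \code{fragments} into \code{masks}, plus \code{areas}.
#' @export
split_cells_fragments <- function(masks, min_cell_area = 60) {
  areas <- vapply(masks, function(m) {
    if (inherits(m, "binary_mask")) m$area else sum(m)
  }, numeric(1))
  list(cells = which(areas >= min_cell_area),
       fragments = which(areas < min_cell_area),
       areas = areas)
}
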