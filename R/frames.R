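# IntensityFrame: one grayscale micrograph plus acquisition metadata.
# Pixels are stored as a plain numeric matrix (rows x cols, row 1 at top)
# on the 8-bit grayscale scale [0, 255]; processing stays in floating
# point and is only quantized on export.

#' Construct an intensity frame
#'
#' Wraps a grayscale pixel matrix with acquisition metadata. Pixels are
#' held in floating point on the 8-bit scale \code{[0, 255]} regardless of
#' the source bit depth; 16-bit input is rescaled by 255/65535 so the
#' detection thresholds (stated in 8-bit grayscale units) apply uniformly.
#'
#' @param pixels numeric matrix of grayscale values, rows x cols, row 1 at
#'   the top of the image.
#' @param bit_depth source bit depth, 8 or 16.
#' @param pixel_size optional pixel size in micrometres per pixel.
#' @param timestamp optional acquisition time in seconds.
#' @param frame_index integer frame index within its sequence (0-based).
#' @return an \code{intensity_frame} object.
#' @export
intensity_frame <- function(pixels, bit_depth = 8L, pixel_size = NULL,
                            timestamp = NULL, frame_index = 0L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (any(!is.finite(pixels)))
    stop("`pixels` must be finite")
  if (!bit_depth %in% c(8L, 16L))
    stop("`bit_depth` must be 8 or 16")
  if (!is.null(pixel_size) && pixel_size <= 0)
    stop("`pixel_size` must be positive")
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         pixel_size = pixel_size, timestamp = timestamp,
         frame_index = as.integer(frame_index)),
    class = "intensity_frame")
}

#' @export
print.intensity_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<intensity_frame> %d x %d px, %d-bit, frame %d\n",
              d[1], d[2], x$bit_depth, x$frame_index))
  cat(sprintf("  intensity range [%.1f, %.1f]",
              min(x$pixels), max(x$pixels)))
  if (!is.null(x$pixel_size))
    cat(sprintf(", %.3f um/px", x$pixel_size))
  cat("\n")
  invisible(x)
}

#' @export
dim.intensity_frame <- function(x) dim(x$pixels)

# Accept either an intensity_frame or a bare matrix everywhere.
as_pixels <- function(frame) {
  if (inherits(frame, "intensity_frame")) frame$pixels
  else if (is.matrix(frame)) frame
  else stop("expected an intensity_frame or a numeric matrix")
}

rewrap_frame <- function(frame, pixels) {
  if (inherits(frame, "intensity_frame")) {
    frame$pixels <- pixels
    frame
  } else pixels
}

#' Read micrograph frames
#'
#' Reads a multi-page TIFF, a single PNG, or a directory of numbered
#' PNG/TIFF frames into a list of \code{\link{intensity_frame}} objects.
#' RGB input is converted to grayscale by channel averaging.
#'
#' @param path file or directory path.
#' @param pixel_size optional micrometres per pixel, attached to every frame.
#' @param fps frames per second used to derive timestamps (default 10, the
#'   acquisition rate assumed throughout the package).
#' @return list of \code{intensity_frame} objects, frame_index 0-based.
#' @export
read_frames <- function(path, pixel_size = NULL, fps = 10) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("no PNG/TIFF frames found in ", path)
    arrays <- lapply(files, read_one_image)
  } else if (file.exists(path)) {
    ext <- tolower(tools::file_ext(path))
    arrays <- if (ext %in% c("tif", "tiff")) {
      imgs <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(imgs)) imgs <- list(imgs)
      imgs
    } else if (ext == "png") {
      list(png::readPNG(path))
    } else stop("unsupported frame format: .", ext)
  } else stop("input path does not exist: ", path)

  lapply(seq_along(arrays), function(i) {
    m <- to_gray_matrix(arrays[[i]])
    intensity_frame(m * 255, bit_depth = 8L, pixel_size = pixel_size,
                    timestamp = (i - 1) / fps, frame_index = i - 1L)
  })
}

read_one_image <- function(f) {
  ext <- tolower(tools::file_ext(f))
  if (ext == "png") png::readPNG(f) else tiff::readTIFF(f)
}

to_gray_matrix <- function(a) {
  if (length(dim(a)) == 3) a <- apply(a[, , seq_len(min(3, dim(a)[3])),
                                        drop = FALSE], c(1, 2), mean)
  a
}

#' Write frames as an 8-bit multi-page TIFF or numbered PNGs
#'
#' @param frames list of \code{intensity_frame} objects (or matrices on the
#'   \code{[0, 255]} scale).
#' @param path output path; a \code{.tif}/\code{.tiff} path produces one
#'   multi-page TIFF, any other path is treated as a directory of numbered
#'   \code{frame_0000.png} files.
#' @return invisibly, the path written.
#' @export
write_frames <- function(frames, path) {
  if (inherits(frames, "intensity_frame") || is.matrix(frames))
    frames <- list(frames)
  mats <- lapply(frames, function(f) {
    m <- pmax(pmin(as_pixels(f), 255), 0) / 255
    round(m * 255) / 255  # quantize to 8-bit levels
  })
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(mats, path, bits.per.sample = 8L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(mats))
      png::writePNG(mats[[i]], file.path(path,
        sprintf("frame_%04d.png", i - 1)))
  }
  invisible(path)
}
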