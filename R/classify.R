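# Threshold calibration (mean + 2 SD of reference ellipsoidal cells),
# per-cell classification, per-frame summaries and time series.

#' Calibrate the symmetric/asymmetric decision threshold
#'
#' The critical threshold separating normal from aberrant cells is the
#' sample mean plus twice the sample standard deviation (n - 1
#' denominator) of asymmetry scores from cells asserted to be normal --
#' e.g. cells from low-shear control frames, or a labelled subset. Under
#' an approximately Gaussian reference population this puts the expected
#' false-positive rate near the one-sided 2-sigma tail, about 2.3
#' percent.
#'
#' @param reference_scores numeric vector (>= 2 finite values) of scores
#'   (percent) from reference normal cells.
#' @param source free-text provenance recorded in the model.
#' @return a \code{calibration_model}: list with \code{mean_score},
#'   \code{sd_score}, \code{threshold}, \code{n_reference},
#'   \code{source}.
#' @export
calibrate_threshold <- function(reference_scores, source = "unspecified") {
  if (any(!is.finite(reference_scores)))
    stop("reference scores must all be finite")
  if (length(reference_scores) < 2)
    stop("need at least 2 reference scores")
  m <- mean(reference_scores)
  s <- sd(reference_scores)
  structure(
    list(mean_score = m, sd_score = s, threshold = m + 2 * s,
         n_reference = length(reference_scores), source = source),
    class = "calibration_model")
}

#' A fixed-threshold calibration preset
#'
#' Wraps an externally determined threshold (for example a value
#' published for a particular instrument and cell population) as a
#' \code{calibration_model}. Such presets are specific to the optics and
#' cells they were derived on; calibrating on your own reference
#' population with \code{\link{calibrate_threshold}} is preferred.
#'
#' @param threshold threshold in percent.
#' @param source provenance string.
#' @return a \code{calibration_model} with \code{n_reference = 0}.
#' @export
fixed_threshold <- function(threshold, source = "external preset") {
  structure(
    list(mean_score = NA_real_, sd_score = NA_real_, threshold = threshold,
         n_reference = 0L, source = source),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> threshold %.3f%%", x$threshold))
  if (x$n_reference > 0)
    cat(sprintf(" (mean %.3f + 2 x sd %.3f, n = %d)",
                x$mean_score, x$sd_score, x$n_reference))
  cat("\n  source:", x$source, "\n")
  invisible(x)
}

#' Write / read a calibration model
#'
#' Serialized as human-readable key-value YAML with provenance.
#'
#' @param model a \code{calibration_model}.
#' @param path file path.
#' @return \code{write_calibration} invisibly returns \code{path};
#'   \code{read_calibration} returns the model.
#' @export
write_calibration <- function(model, path) {
  yaml::write_yaml(unclass(model), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- yaml::read_yaml(path)
  structure(list(mean_score = as.numeric(x$mean_score %||% NA),
                 sd_score = as.numeric(x$sd_score %||% NA),
                 threshold = as.numeric(x$threshold),
                 n_reference = as.integer(x$n_reference %||% 0L),
                 source = x$source %||% "file"),
            class = "calibration_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify one cell as symmetric or asymmetric
#'
#' A cell is asymmetric iff its score strictly exceeds the calibrated
#' threshold; a score exactly at the threshold is symmetric (boundary
#' convention). Invalid results are excluded upstream and tallied as
#' skipped.
#'
#' @param result an \code{asymmetry_result}, a one-row result from
#'   \code{\link{score_cell}}, or a bare numeric score in percent.
#' @param model a \code{calibration_model}.
#' @return \code{"symmetric"} or \code{"asymmetric"}.
#' @export
classify_cell <- function(result, model) {
  score <- if (is.numeric(result)) result
           else if (!is.null(result$score)) result$score
           else stop("`result` carries no score")
  if (!isTRUE(is.finite(score))) stop("cannot classify an invalid result")
  if (score > model$threshold) "asymmetric" else "symmetric"
}

#' Summarize one frame's classified cells
#'
#' @param cell_results data.frame of per-cell results for the frame
#'   (columns \code{score}, \code{EI}, \code{valid}, and
#'   \code{classified_as} for valid rows).
#' @param n_fragments fragment tally for the frame.
#' @param frame_index 0-based frame index.
#' @param fps frames per second (time_s = frame_index / fps).
#' @return one-row data.frame: \code{frame_index}, \code{time_s},
#'   \code{n_cells}, \code{n_fragments}, \code{n_asymmetric},
#'   \code{n_skipped}, \code{fraction_asymmetric} (percent of cells in
#'   the frame), \code{EI_mean}, \code{EI_median}, \code{empty_frame}.
#' @export
summarize_frame <- function(cell_results, n_fragments = 0L,
                            frame_index = 0L, fps = 10) {
  valid <- cell_results[isTRUE_vec(cell_results$valid), , drop = FALSE]
  n_cells <- nrow(cell_results)
  n_skip <- n_cells - nrow(valid)
  n_asym <- sum(valid$classified_as == "asymmetric")
  data.frame(
    frame_index = as.integer(frame_index),
    time_s = frame_index / fps,
    n_cells = n_cells,
    n_fragments = as.integer(n_fragments),
    n_asymmetric = n_asym,
    n_skipped = n_skip,
    fraction_asymmetric = if (n_cells > 0) 100 * n_asym / n_cells else 0,
    EI_mean = if (nrow(valid) > 0) mean(valid$EI) else NA_real_,
    EI_median = if (nrow(valid) > 0) median(valid$EI) else NA_real_,
    empty_frame = n_cells == 0)
}

isTRUE_vec <- function(x) if (is.null(x)) logical(0) else x %in% TRUE

#' Detect the onset frame of a sustained rise in asymmetric fraction
#'
#' The onset is the first frame index at which the trailing mean of the
#' asymmetric fraction over \code{window} consecutive frames exceeds
#' \code{cutoff}. Intended for step-like rises well above the calibrated
#' false-positive floor.
#'
#' @param fractions per-frame asymmetric fractions, percent.
#' @param cutoff percent; a sensible choice is halfway between the
#'   baseline and the expected post-onset level.
#' @param window frames that must jointly exceed the cutoff.
#' @return 0-based frame index of onset, or \code{NA} if never reached.
#' @export
detect_onset <- function(fractions, cutoff = 10, window = 3L) {
  n <- length(fractions)
  if (n < window) return(NA_integer_)
  for (i in seq_len(n - window + 1L)) {
    if (mean(fractions[i:(i + window - 1L)]) > cutoff)
      return(i - 1L)
  }
  NA_integer_
}
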