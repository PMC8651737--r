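# Per-cell morphometry: binarize, align to the principal axis, build the
# per-degree centroid-to-edge radial profile, split it at the central
# nadir, and compute the radial-asymmetry score and elongation index.

new_binary_mask <- function(mask, flags = character(0)) {
  area <- sum(mask)
  centroid <- if (area > 0) {
    idx <- which(mask, arr.ind = TRUE)
    c(row = mean(idx[, 1]), col = mean(idx[, 2]))
  } else c(row = NA_real_, col = NA_real_)
  structure(list(mask = mask, area = area, centroid = centroid,
                 valid = area > 0, flags = flags),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, area %d, centroid (%.1f, %.1f)%s\n",
              nrow(x$mask), ncol(x$mask), x$area,
              x$centroid[1], x$centroid[2],
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

#' Binarize a cell crop
#'
#' Global histogram threshold by Otsu's criterion on the crop; cells are
#' darker than the background, so foreground is everything below the
#' threshold. The component at the crop centre (the largest 8-connected
#' component within 10 px of it) is retained, interior holes are filled
#' (the lighter cell interior must count as foreground), and the
#' centroid is the sub-pixel foreground centre of mass.
#'
#' @param crop a \code{cell_crop} from \code{\link{extract_crop}}, or a
#'   numeric matrix on the \code{[0, 255]} scale.
#' @return a \code{binary_mask}; \code{valid = FALSE} (never an error)
#'   when thresholding leaves no foreground.
#' @export
binarize_crop <- function(crop) {
  if (inherits(crop, "cell_crop") && crop$boundary_truncated)
    stop("boundary-truncated crops are excluded from morphometry")
  px <- if (inherits(crop, "cell_crop")) crop$patch else crop
  rng <- range(px)
  if (diff(rng) == 0) return(new_binary_mask(px < 0, flags = "empty"))
  thr <- EBImage::otsu(px / 255, range = c(0, 1), levels = 256L) * 255
  med <- median(px)
  if (thr > med - 0.2 * (med - rng[1])) {
    # a crop dominated by background (e.g. around a small fragment) has
    # a near-unimodal histogram and Otsu lands inside the background
    # mode; fall back to the midpoint of the dark tail
    thr <- (rng[1] + med) / 2
  }
  fg <- px < thr
  if (!any(fg)) return(new_binary_mask(fg, flags = "empty"))
  # when the threshold lands between the dark rim and the lighter
  # interior the foreground is a thin ring; close small noise breaks so
  # the ring stays one component before hole filling
  fg <- EBImage::closing(fg, EBImage::makeBrush(5, "disc")) > 0
  lab <- EBImage::bwlabel(fg)
  # the crop is centred on the detected object, so keep the component
  # at the centre: the largest component within 10 px of it, falling
  # back to the nearest one (a degenerate threshold on a mostly-empty
  # crop can make a background-noise blob the globally largest object)
  idx <- which(lab > 0, arr.ind = TRUE)
  ctr <- (dim(px) + 1) / 2
  d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
  labs_near <- unique(lab[idx[d2 <= 100, , drop = FALSE]])
  pick <- if (length(labs_near)) {
    sizes <- tabulate(lab[lab > 0])
    labs_near[which.max(sizes[labs_near])]
  } else lab[idx[which.min(d2), , drop = FALSE]]
  mask <- lab == pick
  mask <- EBImage::fillHull(mask) > 0
  out <- new_binary_mask(matrix(as.logical(mask), nrow(px), ncol(px)))
  # keep the intensity patch and the segmentation level: the radial
  # profile refines each boundary crossing sub-pixel from the intensity
  # ramp of the cell rim (see radial_profile)
  out$patch <- px
  out$threshold <- thr
  out
}

# Second-order central moments of a mask in math coordinates
# (x = col, y = -row), about the centroid.
mask_moments <- function(mask) {
  idx <- which(mask$mask, arr.ind = TRUE)
  x <- idx[, 2] - mask$centroid["col"]
  y <- -(idx[, 1] - mask$centroid["row"])
  list(mu20 = mean(x^2), mu02 = mean(y^2), mu11 = mean(x * y),
       x = x, y = y)
}

#' Align a cell mask apex-up
#'
#' Rotates the mask about its centroid so that the principal (major)
#' axis, from second-order central moments, is vertical, and the apex --
#' the major-axis extreme point farther from the centroid -- points up.
#' The rotated mask is re-binarized after bilinear interpolation (area
#' is preserved to within about 2 percent). Nearly isotropic masks
#' (principal-moment ratio below \code{iso_tol}) have no unique major
#' axis and are returned unrotated with an \code{"isotropic"} flag.
#'
#' @param mask a \code{binary_mask}.
#' @param iso_tol minimum major/minor moment ratio for a defined axis.
#' @return a \code{binary_mask} on a grid recentred on the centroid, with
#'   attribute fields \code{rotation_deg} recorded in \code{flags} via
#'   \code{attr}; isotropic masks carry the \code{"isotropic"} flag.
#' @export
align_apex <- function(mask, iso_tol = 1.02) {
  if (!mask$valid) return(mask)
  mo <- mask_moments(mask)
  tr <- mo$mu20 + mo$mu02
  det <- mo$mu20 * mo$mu02 - mo$mu11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  ev <- c(tr / 2 + disc, tr / 2 - disc)
  if (ev[2] <= 0 || ev[1] / ev[2] < iso_tol) {
    mask$flags <- union(mask$flags, "isotropic")
    attr(mask, "rotation_deg") <- 0
    return(mask)
  }
  phi <- 0.5 * atan2(2 * mo$mu11, mo$mu20 - mo$mu02)  # major-axis angle
  e <- c(cos(phi), sin(phi))
  proj <- mo$x * e[1] + mo$y * e[2]
  apex_dir <- if (max(proj) >= -min(proj)) e else -e
  delta <- pi / 2 - atan2(apex_dir[2], apex_dir[1])   # rotate apex to +y

  r_max <- sqrt(max(mo$x^2 + mo$y^2))
  n <- 2L * ceiling(r_max) + 7L
  cen <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  xo <- cols - cen
  yo <- -(rows - cen)
  # inverse map: rotate output coords by -delta back into the input
  xi <- xo * cos(delta) + yo * sin(delta)
  yi <- -xo * sin(delta) + yo * cos(delta)
  src_col <- mask$centroid["col"] + xi
  src_row <- mask$centroid["row"] - yi
  rotated <- bilinear_mask(mask$mask, src_row, src_col) >= 0.5
  out <- new_binary_mask(matrix(rotated, n, n))
  out$flags <- mask$flags
  attr(out, "rotation_deg") <- delta * 180 / pi
  out
}

# Bilinear interpolation of a logical matrix at arbitrary coordinates;
# out-of-range samples are background.
bilinear_mask <- function(mask, r, c) {
  m <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  m[1 + seq_len(nrow(mask)), 1 + seq_len(ncol(mask))] <- mask
  r <- as.vector(r) + 1; c <- as.vector(c) + 1
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r0 <- pmax(pmin(r0, nrow(m) - 1L), 1L)
  c0 <- pmax(pmin(c0, ncol(m) - 1L), 1L)
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
    m[i01] * (1 - fr) * fc + m[i11] * fr * fc
}

#' Per-degree radial profile of a cell mask
#'
#' For each angle the radius is the distance from the sub-pixel centroid
#' to the first background crossing along the outward ray. The mask
#' indicator is lightly smoothed (Gaussian, sigma 1 px by default) to de-noise
#' the pixelated boundary, sampled bilinearly every 0.25 px along the
#' ray, and the radius is the linearly interpolated 0.5-crossing between
#' the last foreground and first background sample, so radii are
#' continuous (sub-pixel) rather than quantized. For masks produced by
#' \code{\link{binarize_crop}}, which carry their source intensity patch
#' and segmentation level, each crossing is further refined from the
#' intensity image itself: the smooth ramp of the cell rim localizes the
#' threshold level to a small fraction of a pixel, removing the
#' half-pixel quantization a binary boundary imposes on grid-tangent
#' edges. Angles run
#' counterclockwise with 0 degrees pointing rightward. With
#' \code{angle_offset} the rays are rotated instead of the mask: the
#' profile of a cell aligned apex-up is obtained exactly, without the
#' boundary damage of resampling the mask itself. A centroid that falls
#' outside the foreground (an extremely concave object) makes the
#' profile invalid.
#'
#' @param mask a \code{binary_mask}.
#' @param angular_resolution degrees per profile sample (default 1, i.e.
#'   360 radii).
#' @param angle_offset degrees; reported angle theta samples the mask
#'   along direction \code{theta - angle_offset}, i.e. the profile of
#'   the mask rotated counterclockwise by \code{angle_offset}.
#' @param boundary_sigma Gaussian sigma (px) of the indicator smoothing;
#'   0 samples the raw binary mask.
#' @return a \code{radial_profile}: list with \code{radii},
#'   \code{step_deg}, \code{normalized}, \code{equivalent_radius},
#'   \code{centroid_inside}, \code{valid}.
#' @export
radial_profile <- function(mask, angular_resolution = 1, angle_offset = 0,
                           boundary_sigma = 1) {
  if (!mask$valid)
    return(structure(list(radii = numeric(0), step_deg = angular_resolution,
                          normalized = FALSE, equivalent_radius = NA_real_,
                          centroid_inside = FALSE, valid = FALSE),
                     class = "radial_profile"))
  cr <- mask$centroid["row"]; cc <- mask$centroid["col"]
  inside <- mask$mask[round(cr), round(cc)]
  if (!isTRUE(inside))
    return(structure(list(radii = numeric(0), step_deg = angular_resolution,
                          normalized = FALSE, equivalent_radius = NA_real_,
                          centroid_inside = FALSE, valid = FALSE),
                     class = "radial_profile"))
  field <- mask$mask * 1
  if (boundary_sigma > 0) {
    k <- max(1L, ceiling(3 * boundary_sigma))
    g <- exp(-(seq(-k, k))^2 / (2 * boundary_sigma^2))
    g <- g / sum(g)
    field <- EBImage::filter2(pad_reflect(field, k), outer(g, g),
                              boundary = "circular")
    field <- unpad(field, k, nrow(mask$mask), ncol(mask$mask))
  }
  idx <- which(mask$mask, arr.ind = TRUE)
  r_max <- sqrt(max((idx[, 1] - cr)^2 + (idx[, 2] - cc)^2)) + 2.5
  step_px <- 0.25
  rs <- seq(step_px, r_max, by = step_px)
  theta <- (seq(0, 360 - angular_resolution, by = angular_resolution) -
              angle_offset) * pi / 180
  dcol <- cos(theta); drow <- -sin(theta)  # counterclockwise as displayed
  sr <- outer(rs, drow) + cr
  sc <- outer(rs, dcol) + cc
  v <- matrix(bilinear_mask(field, sr, sc), length(rs), length(theta))
  fg <- v >= 0.5
  first_bg <- apply(!fg, 2, which.max)  # guaranteed: rays end outside
  i1 <- pmax(first_bg - 1L, 1L)
  v_in <- v[cbind(i1, seq_along(theta))]
  v_out <- v[cbind(first_bg, seq_along(theta))]
  frac <- ifelse(v_in > v_out, (v_in - 0.5) / (v_in - v_out), 0.5)
  radii <- ifelse(first_bg > 1L,
                  rs[i1] + step_px * frac,
                  step_px * 0.5)

  if (!is.null(mask$patch) && !is.null(mask$threshold)) {
    # Sub-pixel refinement from the intensity image: the binary boundary
    # quantizes grid-tangent edges to +-0.5 px, but the smooth intensity
    # ramp of the cell rim localizes the segmentation level to a small
    # fraction of a pixel. Around each ray's binary crossing, find the
    # first upward crossing of the threshold level and interpolate.
    iv <- matrix(bilinear_mask(mask$patch, sr, sc),
                 length(rs), length(theta))
    win <- 6L  # +-1.5 px around the binary crossing
    for (j in seq_along(theta)) {
      i0 <- first_bg[j]
      if (i0 <= 1L) next
      lo <- max(i0 - win, 1L); hi <- min(i0 + win, length(rs))
      seg <- iv[lo:hi, j]
      below <- seg < mask$threshold
      cross <- which(below[-length(seg)] & !below[-1])
      if (!length(cross)) next
      k <- cross[which.min(abs(cross + lo - 1L - i0))]
      a_in <- seg[k]; a_out <- seg[k + 1L]
      f <- (mask$threshold - a_in) / (a_out - a_in)
      radii[j] <- rs[lo + k - 1L] + step_px * f
    }
  }

  structure(list(radii = radii, step_deg = angular_resolution,
                 normalized = FALSE, equivalent_radius = NA_real_,
                 centroid_inside = TRUE, valid = TRUE),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  if (!x$valid) { cat("<radial_profile> invalid\n"); return(invisible(x)) }
  cat(sprintf("<radial_profile> %d radii @ %g deg, %s, range [%.2f, %.2f]\n",
              length(x$radii), x$step_deg,
              if (x$normalized) "area-normalized" else "raw pixels",
              min(x$radii), max(x$radii)))
  invisible(x)
}

#' Area-normalize a radial profile
#'
#' Divides every radius by the equivalent-circle radius
#' \code{sqrt(area / pi)}, making profiles comparable across
#' magnifications and cell volumes. The asymmetry score is scale-free, so
#' it is unchanged by this operation; normalization matters when
#' comparing or plotting profiles directly.
#'
#' @param profile a \code{radial_profile}.
#' @param area foreground area of the mask, px^2 (> 0).
#' @return the normalized \code{radial_profile}.
#' @export
normalize_profile <- function(profile, area) {
  if (area <= 0) stop("`area` must be positive")
  req <- sqrt(area / pi)
  profile$radii <- profile$radii / req
  profile$normalized <- TRUE
  profile$equivalent_radius <- req
  profile
}

# Circular moving average of window w (odd).
circular_ma <- function(x, w) {
  k <- (w - 1) %/% 2
  n <- length(x)
  xp <- c(x[(n - k + 1):n], x, x[1:k])
  out <- stats::filter(xp, rep(1 / w, w), sides = 2)
  as.numeric(out[(k + 1):(k + n)])
}

# Refine a valley cut from a bare argmin to the depth-weighted circular
# centroid of the surrounding valley (every contiguous sample within
# `frac` of the profile range above the valley floor, capped at
# `max_span` samples each side). Radial profiles of elongated cells have
# wide, flat valleys, so the bare argmin wanders by many degrees under
# sub-pixel boundary noise while the valley centre is stable; the split
# of the two half-curves uses the centre.
refine_valley_cut <- function(sm, i0, frac = 0.3, max_span = 60L) {
  n <- length(sm)
  rng <- diff(range(sm))
  if (rng == 0) return(as.numeric(i0))
  tau <- sm[i0] + frac * rng
  l <- 0L
  while (l < max_span && sm[((i0 - l - 2) %% n) + 1L] <= tau) l <- l + 1L
  r <- 0L
  while (r < max_span && sm[((i0 + r) %% n) + 1L] <= tau) r <- r + 1L
  run <- ((i0 - l - 1L):(i0 + r - 1L)) %% n + 1L
  w <- tau - sm[run]
  if (all(w <= 0)) return(as.numeric(i0))
  phi <- 2 * pi * (run - 1) / n
  ang <- atan2(sum(w * sin(phi)), sum(w * cos(phi)))
  # continuous (fractional) 1-based index of the valley centre
  (ang / (2 * pi) * n) %% n + 1
}

# Trapezoid integral of the periodic profile r (samples at angles
# (i-1)*step) over the counterclockwise arc [from_idx, to_idx] given as
# continuous 1-based indices; r is linearly interpolated at the
# fractional endpoints. to_idx may exceed n (wrap).
integrate_arc <- function(r, step, from_idx, to_idx) {
  n <- length(r)
  at <- function(x) {
    x <- (x - 1) %% n + 1
    i <- floor(x); f <- x - i
    i2 <- i %% n + 1
    r[i] * (1 - f) + r[i2] * f
  }
  if (to_idx <= from_idx) to_idx <- to_idx + n
  ks <- seq(ceiling(from_idx), floor(to_idx))
  xs <- unique(c(from_idx, ks, to_idx))
  vs <- at(xs)
  sum((vs[-1] + vs[-length(vs)]) / 2 * diff(xs)) * step
}

# Choose the start cut of the circular profile: the global-minimum
# valley, made canonical for (near-)degenerate profiles. Elongated cells
# aligned apex-up have two near-equal valleys (left and right of the
# major axis); sub-pixel noise decides which is the literal argmin, which
# would flip the A1/A2 ordering at random. Among all valleys within
# `tol_frac` of the range above the global minimum, the one closest to
# 0 degrees (rightward in the aligned pose) is chosen, so A1 always
# traverses the apex half first. Profiles with a unique global minimum
# are unaffected.
choose_start_cut <- function(sm, tol_frac = 0.01, max_span = 60L) {
  n <- length(sm)
  rng <- diff(range(sm))
  if (rng == 0) return(1L)
  cand <- sm <= min(sm) + tol_frac * rng
  # split candidate set into circular contiguous runs
  runs <- cumsum(c(1L, diff(which(cand)) > 1L))
  idx <- which(cand)
  reps <- vapply(split(idx, runs), function(run) {
    refine_valley_cut(sm, run[which.min(sm[run])], max_span = max_span)
  }, numeric(1))
  if (cand[1] && cand[n] && length(unique(runs)) > 1) {
    # first and last runs wrap into one valley; drop the duplicate rep
    reps <- reps[-length(reps)]
  }
  dist0 <- pmin(reps - 1, n - (reps - 1))
  reps[order(dist0, reps)][1]
}

# Locate both cut points of a circular profile. The start cut is the
# canonical global-minimum valley of the POINT-SYMMETRIZED profile
# (sm(theta) + sm(theta + 180))/2, whose minimum over the interior
# 90-270 degree window then falls exactly diametrically opposite, so the
# nadir cut is pinned at start + 180 degrees. For a mirror-symmetric
# cell this is exact; for aberrant cells it regularizes the split
# against the profile noise that otherwise wanders the nadir across the
# wide flat valleys of elongated cells (the half-area difference is
# first-order sensitive to the nadir-offset error). Returns continuous
# 1-based indices: c1 (start), off (nadir offset in samples) and i1
# (integer anchor of the start, for the shifted-profile view).
locate_profile_cuts <- function(sm, step) {
  n <- length(sm)
  span <- round(60 / step)
  smp <- if (n %% 2 == 0)
    (sm + sm[(seq_len(n) - 1 + n / 2) %% n + 1]) / 2
  else sm
  c1 <- choose_start_cut(smp, max_span = span)
  i1 <- (as.integer(round(c1)) - 1L) %% n + 1L
  sm_s <- if (i1 > 1) c(sm[i1:n], sm[1:(i1 - 1)]) else sm
  list(c1 = c1, off = n / 2, i1 = i1, shifted_sm = sm_s)
}

# Number of strict circular local maxima after collapsing equal runs.
count_circular_peaks <- function(x) {
  n <- length(x)
  rle_v <- rle(x)$values
  m <- length(rle_v)
  if (m < 2) return(0L)
  if (rle_v[1] == rle_v[m]) { rle_v <- rle_v[-m]; m <- m - 1L }
  if (m < 3) return(if (m == 2) 1L else 0L)
  prv <- rle_v[c(m, 1:(m - 1))]
  nxt <- rle_v[c(2:m, 1)]
  sum(rle_v > prv & rle_v > nxt)
}

#' Locate the central nadir of a radial profile
#'
#' The profile is circularly shifted to start at its global-minimum
#' valley so that the two peaks of an elongated cell's bimodal profile
#' lie in the interior; the central nadir is the minimum over the
#' interior 90-270 degree window. Extrema are located on a lightly
#' smoothed copy (circular moving average, 5 degree window) of the
#' point-symmetrized profile, (sm(theta) + sm(theta + 180))/2, with two
#' consequences. First, the start valley is refined from the bare argmin
#' to the depth-weighted valley centre, and among the two near-equal
#' valleys of an aligned elongated cell the one nearest 0 degrees is
#' chosen, so A1 always traverses the apex side and the A1/A2 ordering
#' cannot flip on sub-pixel noise. Second, the interior minimum of the
#' symmetrized profile falls exactly diametrically opposite the start,
#' pinning the nadir at start + 180 degrees: exact for mirror-symmetric
#' cells, and a stabilizing regularization for aberrant ones, whose wide
#' flat valleys otherwise let the nadir wander by several degrees under
#' boundary noise (the half-area difference is first-order sensitive to
#' that wander). The areas downstream always use the raw radii.
#' Profiles without two peaks after smoothing (e.g. a circle's flat
#' profile) are not bimodal and come back invalid.
#'
#' @param profile a \code{radial_profile}.
#' @param smooth_window smoothing window for extremum location, degrees.
#' @return list with \code{nadir_index} (1-based, in the shifted
#'   profile), \code{nadir_deg}, \code{shift} (samples removed from the
#'   front), \code{shifted} (raw radii, shifted), \code{valid}.
#' @export
find_central_nadir <- function(profile, smooth_window = 5) {
  if (!profile$valid)
    return(list(nadir_index = NA_integer_, nadir_deg = NA_real_,
                shift = NA_integer_, shifted = numeric(0), valid = FALSE))
  r <- profile$radii
  n <- length(r)
  w <- max(3L, round(smooth_window / profile$step_deg))
  if (w %% 2 == 0) w <- w + 1L
  sm <- circular_ma(r, w)
  cuts <- locate_profile_cuts(sm, profile$step_deg)
  i1 <- cuts$i1
  raw_s <- if (i1 > 1) c(r[i1:n], r[1:(i1 - 1)]) else r
  if (count_circular_peaks(cuts$shifted_sm) < 2)
    return(list(nadir_index = NA_integer_, nadir_deg = NA_real_,
                shift = i1 - 1L, shifted = raw_s,
                cut1 = NA_real_, cut_offset = NA_real_, valid = FALSE))
  list(nadir_index = as.integer(round(cuts$off)) + 1L,
       nadir_deg = cuts$off * profile$step_deg,
       shift = i1 - 1L, shifted = raw_s,
       cut1 = cuts$c1, cut_offset = cuts$off, valid = TRUE)
}

#' Radial-asymmetry score of one cell
#'
#' Splits the radius-versus-angle curve at the start valley and the
#' central nadir into two half-curves, integrates each by the trapezoid
#' rule (A1 from the start cut to the nadir, A2 from the nadir back to
#' the start; the continuous cut positions are used, with the profile
#' linearly interpolated at the fractional endpoints), and reports
#' \code{|(A1 - A2)/A1| * 100} in percent. A perfectly mirror-symmetric
#' cell scores zero. The ordering of A1 and A2 is pinned by the
#' start-at-global-minimum shift plus counterclockwise traversal, so the
#' printed-formula denominator A1 is reproducible; set
#' \code{symmetric_denominator = TRUE} for the order-free variant
#' dividing by \code{max(A1, A2)} instead.
#'
#' @param profile a \code{radial_profile}.
#' @param nadir result of \code{\link{find_central_nadir}} for the same
#'   profile (computed when omitted).
#' @param symmetric_denominator divide by \code{max(A1, A2)} instead of
#'   A1 (default \code{FALSE}).
#' @return an \code{asymmetry_result}: list with \code{nadir_index},
#'   \code{nadir_deg}, \code{A1}, \code{A2}, \code{score} (percent),
#'   \code{valid}.
#' @export
asymmetry_score <- function(profile, nadir = NULL,
                            symmetric_denominator = FALSE) {
  if (is.null(nadir)) nadir <- find_central_nadir(profile)
  invalid <- list(nadir_index = NA_integer_, nadir_deg = NA_real_,
                  A1 = NA_real_, A2 = NA_real_, score = NA_real_,
                  valid = FALSE)
  class(invalid) <- "asymmetry_result"
  if (!isTRUE(nadir$valid) || !profile$valid) return(invalid)
  r <- profile$radii
  n <- length(r)
  c1 <- nadir$cut1
  c2 <- c1 + nadir$cut_offset
  a1 <- integrate_arc(r, profile$step_deg, c1, c2)
  a2 <- integrate_arc(r, profile$step_deg, c2, c1 + n)
  if (a1 <= 0) return(invalid)
  k <- nadir$nadir_index
  denom <- if (symmetric_denominator) max(a1, a2) else a1
  out <- list(nadir_index = k, nadir_deg = nadir$nadir_deg,
              A1 = a1, A2 = a2,
              score = abs((a1 - a2) / denom) * 100, valid = TRUE)
  class(out) <- "asymmetry_result"
  out
}

#' @export
print.asymmetry_result <- function(x, ...) {
  if (!x$valid) { cat("<asymmetry_result> invalid\n"); return(invisible(x)) }
  cat(sprintf(
    "<asymmetry_result> score %.2f%% (A1 %.1f, A2 %.1f, nadir %g deg)\n",
    x$score, x$A1, x$A2, x$nadir_deg))
  invisible(x)
}

#' Elongation index of an aligned cell mask
#'
#' EI = (A - B)/(A + B) with A the extent along the principal
#' (post-alignment, vertical) axis and B the extent across it, both as
#' the span of foreground pixel centres. Zero for a circle, approaching 1
#' for a needle.
#'
#' @param mask an aligned \code{binary_mask}.
#' @return an \code{ei_result}: list with \code{major_axis_A},
#'   \code{minor_axis_B} (px), \code{EI}, \code{valid}.
#' @export
elongation_index <- function(mask) {
  if (!mask$valid || mask$area < 4)
    return(list(major_axis_A = NA_real_, minor_axis_B = NA_real_,
                EI = NA_real_, valid = FALSE))
  idx <- which(mask$mask, arr.ind = TRUE)
  A <- diff(range(idx[, 1]))
  B <- diff(range(idx[, 2]))
  if (A == 0 || B == 0)
    return(list(major_axis_A = A, minor_axis_B = B, EI = NA_real_,
                valid = FALSE))
  list(major_axis_A = A, minor_axis_B = B, EI = (A - B) / (A + B),
       valid = TRUE)
}

#' Score one cell end to end
#'
#' Composition of the per-cell chain: binarize (when given a crop), align
#' apex-up, profile, area-normalize, find the nadir, score, and measure
#' the elongation index.
#'
#' @param x a \code{cell_crop}, \code{binary_mask}, or logical matrix.
#' @param angular_resolution degrees per profile sample.
#' @param symmetric_denominator passed to \code{\link{asymmetry_score}}.
#' @return one-row data.frame: \code{score}, \code{A1}, \code{A2},
#'   \code{nadir_deg}, \code{EI}, \code{A_px}, \code{B_px},
#'   \code{area_px2}, \code{valid}, \code{flags}.
#' @export
score_cell <- function(x, angular_resolution = 1,
                       symmetric_denominator = FALSE) {
  mask <- if (inherits(x, "binary_mask")) x
          else if (is.logical(x) && is.matrix(x)) new_binary_mask(x)
          else binarize_crop(x)
  bad <- function(flags) data.frame(
    score = NA_real_, A1 = NA_real_, A2 = NA_real_, nadir_deg = NA_real_,
    EI = NA_real_, A_px = NA_real_, B_px = NA_real_,
    area_px2 = mask$area, valid = FALSE,
    flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
  if (!mask$valid) return(bad(mask$flags))
  aligned <- align_apex(mask)
  # profile in the aligned pose, via rotated rays over the original mask
  # (no resampling damage to the boundary)
  prof <- radial_profile(mask, angular_resolution,
                         angle_offset = attr(aligned, "rotation_deg") %||% 0)
  if (!prof$valid) return(bad(union(aligned$flags, "centroid_outside")))
  prof <- normalize_profile(prof, mask$area)
  nad <- find_central_nadir(prof)
  res <- asymmetry_score(prof, nad,
                         symmetric_denominator = symmetric_denominator)
  ei <- elongation_index(aligned)
  if (!res$valid) return(bad(union(aligned$flags, "not_bimodal")))
  data.frame(score = res$score, A1 = res$A1, A2 = res$A2,
             nadir_deg = res$nadir_deg,
             EI = ei$EI, A_px = ei$major_axis_A, B_px = ei$minor_axis_B,
             area_px2 = aligned$area, valid = TRUE,
             flags = paste(aligned$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}
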