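# Synthetic micrograph generator: ground-truthed fixtures with the optical
# structure of halogen bright-field video of RBC in shear flow -- bright
# background with a smooth illumination ramp, dark-rimmed ellipsoidal
# cells with a lighter (but still sub-background) interior, two-lobe
# asymmetric cells, small fragments/vesicles, and additive Gaussian noise.
#
# Geometry conventions (used package-wide): pixel (row, col), row 1 at the
# top; orientations in degrees counterclockwise as displayed, 0 degrees =
# image-horizontal. In matrix coordinates the math frame is x = col - c0,
# y = -(row - r0), so counterclockwise angles behave as on paper.

#' Specify one synthetic cell
#'
#' Three shape classes are supported: \code{symmetric_ellipse} (a healthy
#' shear-deformed RBC), \code{two_lobe} (an aberrant cell built from two
#' half-ellipses that share the minor axis: the apex lobe has semi-major
#' \code{semi_major * lobe_factor}, the base lobe \code{semi_major}), and
#' \code{fragment} (a small vesicle/fragment, capped in size). The
#' two-lobe construction is the package's canonical asymmetric shape
#' because its radial profile has a closed form, giving an exact oracle
#' for the asymmetry score.
#'
#' @param kind one of \code{"symmetric_ellipse"}, \code{"two_lobe"},
#'   \code{"fragment"}.
#' @param center numeric \code{c(row, col)} of the lobe-junction centre in
#'   pixels.
#' @param semi_major,semi_minor semi-axes in pixels; \code{semi_major >=
#'   semi_minor > 0}.
#' @param lobe_factor ratio (>= 1) of the apex lobe's semi-major to the
#'   base lobe's; 1 reduces \code{two_lobe} to \code{symmetric_ellipse}.
#' @param orientation degrees counterclockwise from image-horizontal; the
#'   apex lobe points along this direction.
#' @param edge_drop grayscale units subtracted along the cell rim.
#' @param fragment_cap maximum \code{semi_major} allowed for fragments.
#' @return a \code{cell_spec} object.
#' @export
cell_spec <- function(kind = c("symmetric_ellipse", "two_lobe", "fragment"),
                      center, semi_major, semi_minor,
                      lobe_factor = 1, orientation = 0,
                      edge_drop = 150, fragment_cap = 4) {
  kind <- match.arg(kind)
  if (semi_minor <= 0 || semi_major < semi_minor)
    stop("need semi_major >= semi_minor > 0")
  if (lobe_factor < 1) stop("`lobe_factor` must be >= 1")
  if (kind == "fragment" && semi_major > fragment_cap)
    stop("fragment semi_major exceeds the fragment cap (", fragment_cap, " px)")
  if (kind != "two_lobe") lobe_factor <- 1
  structure(
    list(kind = kind, center = as.numeric(center),
         semi_major = semi_major, semi_minor = semi_minor,
         lobe_factor = lobe_factor, orientation = orientation,
         edge_drop = edge_drop),
    class = "cell_spec")
}

# Radius of the smallest centre-based disk containing the footprint.
cell_bound_radius <- function(spec) {
  max(spec$semi_major * spec$lobe_factor, spec$semi_major, spec$semi_minor)
}

# Ground-truth elongation index of a spec: extent along the major axis is
# a*(lobe_factor + 1), across it 2b.
cell_true_ei <- function(spec) {
  A <- spec$semi_major * (spec$lobe_factor + 1)
  B <- 2 * spec$semi_minor
  (A - B) / (A + B)
}

#' Render the binary footprint of one cell
#'
#' Pixel (r, c) is foreground when its centre lies inside the continuous
#' shape (boundary inclusive). Two-lobe cells are two half-ellipses glued
#' along the shared minor axis.
#'
#' @param spec a \code{\link{cell_spec}}.
#' @param grid \code{c(rows, cols)} of the target grid.
#' @param allow_boundary if \code{FALSE} (default), a footprint leaving the
#'   grid is an error; set \code{TRUE} for deliberate boundary tests.
#' @return logical matrix of dimensions \code{grid}.
#' @export
render_cell_mask <- function(spec, grid, allow_boundary = FALSE) {
  nr <- grid[1]; nc <- grid[2]
  r0 <- spec$center[1]; c0 <- spec$center[2]
  rb <- cell_bound_radius(spec)
  if (!allow_boundary &&
      (r0 - rb < 1 || r0 + rb > nr || c0 - rb < 1 || c0 + rb > nc))
    stop("cell footprint exceeds the grid; set allow_boundary = TRUE to force")
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  x <- cols - c0
  y <- -(rows - r0)
  th <- spec$orientation * pi / 180
  u <- x * cos(th) + y * sin(th)   # along the apex direction
  v <- -x * sin(th) + y * cos(th)
  a <- spec$semi_major; b <- spec$semi_minor
  a_apex <- a * spec$lobe_factor
  amaj <- ifelse(u >= 0, a_apex, a)
  inside <- (u / amaj)^2 + (v / b)^2 <= 1
  matrix(inside, nr, nc)
}

#' Specify one synthetic frame
#'
#' @param height,width frame dimensions in pixels.
#' @param background_level mean illumination, grayscale units (8-bit scale).
#' @param gradient_amplitude peak-to-peak amplitude of a smooth linear
#'   illumination ramp across the frame.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param cells list of \code{\link{cell_spec}} objects.
#' @param seed integer seed; generation is bit-reproducible for a fixed
#'   seed.
#' @param interior_drop_frac interior darkening as a fraction of each
#'   cell's \code{edge_drop} (bright-field cells have a dark rim and a
#'   lighter, but still sub-background, interior).
#' @param rim_width rim thickness in pixels.
#' @param psf_sigma Gaussian optical blur (point-spread) applied to the
#'   cell absorption field, px; gives cell edges the smooth sub-pixel
#'   intensity ramp of real bright-field optics. The background and
#'   illumination gradient are not blurred (they are already smooth), so
#'   a cell-free frame is exactly background plus gradient.
#' @param allow_boundary passed to \code{\link{render_cell_mask}}.
#' @return a \code{frame_spec} object.
#' @export
frame_spec <- function(height = 256, width = 256, background_level = 200,
                       gradient_amplitude = 20, noise_sd = 6,
                       cells = list(), seed = 1L,
                       interior_drop_frac = 0.35, rim_width = 2,
                       psf_sigma = 0.8,
                       allow_boundary = FALSE) {
  if (height < 1 || width < 1) stop("frame dimensions must be positive")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(
    list(height = height, width = width,
         background_level = background_level,
         gradient_amplitude = gradient_amplitude, noise_sd = noise_sd,
         cells = cells, seed = as.integer(seed),
         interior_drop_frac = interior_drop_frac, rim_width = rim_width,
         psf_sigma = psf_sigma, allow_boundary = allow_boundary),
    class = "frame_spec")
}

# Evaluate code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Render one synthetic frame with ground truth
#'
#' Background plus illumination ramp, minus per-cell rim and interior
#' darkening, plus additive Gaussian noise clipped to \code{[0, 255]}.
#' Overlapping cell footprints void the detection guarantees and are
#' flagged in the ground truth (with a warning).
#'
#' @param spec a \code{\link{frame_spec}}.
#' @param frame_index frame index recorded in the output frame.
#' @return list with elements \code{frame} (an
#'   \code{\link{intensity_frame}}) and \code{truth} (a data.frame with one
#'   row per cell: id, kind, centre, axes, lobe_factor, orientation, mask
#'   area, true EI, overlap flag).
#' @export
render_frame <- function(spec, frame_index = 0L) {
  nr <- spec$height; nc <- spec$width
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  img <- spec$background_level +
    spec$gradient_amplitude * ((rows / nr + cols / nc) / 2 - 0.5)
  drop <- matrix(0, nr, nc)

  ncell <- length(spec$cells)
  overlaps <- rep(FALSE, ncell)
  if (ncell > 1) {
    for (i in seq_len(ncell - 1)) for (j in (i + 1):ncell) {
      ci <- spec$cells[[i]]; cj <- spec$cells[[j]]
      d <- sqrt(sum((ci$center - cj$center)^2))
      if (d < cell_bound_radius(ci) + cell_bound_radius(cj)) {
        overlaps[i] <- TRUE; overlaps[j] <- TRUE
      }
    }
    if (any(overlaps))
      warning("overlapping cell footprints: detection guarantees void")
  }

  areas <- integer(ncell)
  for (i in seq_len(ncell)) {
    cs <- spec$cells[[i]]
    mask <- render_cell_mask(cs, c(nr, nc),
                             allow_boundary = spec$allow_boundary)
    areas[i] <- sum(mask)
    rim_px <- max(1L, round(spec$rim_width))
    interior <- mask
    for (k in seq_len(rim_px)) interior <- erode_once(interior)
    rim <- mask & !interior
    drop[rim] <- drop[rim] + cs$edge_drop
    drop[interior] <- drop[interior] + cs$edge_drop * spec$interior_drop_frac
  }
  if (spec$psf_sigma > 0 && length(spec$cells) > 0) {
    kk <- max(1L, ceiling(3 * spec$psf_sigma))
    g <- exp(-(seq(-kk, kk))^2 / (2 * spec$psf_sigma^2))
    g <- g / sum(g)
    drop <- EBImage::filter2(pad_reflect(drop, kk), outer(g, g),
                             boundary = "circular")
    drop <- unpad(drop, kk, nr, nc)
  }
  img <- img - drop

  if (spec$noise_sd > 0) {
    img <- img + with_seed(spec$seed,
      matrix(rnorm(nr * nc, sd = spec$noise_sd), nr, nc))
  }
  img <- pmax(pmin(img, 255), 0)

  truth <- data.frame(
    cell_id = seq_len(ncell),
    kind = vapply(spec$cells, function(c) c$kind, character(1)),
    center_row = vapply(spec$cells, function(c) c$center[1], numeric(1)),
    center_col = vapply(spec$cells, function(c) c$center[2], numeric(1)),
    semi_major = vapply(spec$cells, function(c) c$semi_major, numeric(1)),
    semi_minor = vapply(spec$cells, function(c) c$semi_minor, numeric(1)),
    lobe_factor = vapply(spec$cells, function(c) c$lobe_factor, numeric(1)),
    orientation = vapply(spec$cells, function(c) c$orientation, numeric(1)),
    area_px = areas,
    true_ei = vapply(spec$cells, cell_true_ei, numeric(1)),
    overlaps = overlaps,
    stringsAsFactors = FALSE)
  if (ncell == 0) truth <- truth[0, ]

  list(frame = intensity_frame(img, frame_index = frame_index),
       truth = truth)
}

# One step of binary erosion, 4-connected (shrinks a mask by ~1 px).
erode_once <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  up <- rbind(mask[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, mask[-nr, , drop = FALSE])
  lf <- cbind(mask[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, mask[, -nc, drop = FALSE])
  mask & up & dn & lf & rt
}

#' Specify a synthetic frame sequence
#'
#' Emulates a sheared-suspension video: every frame holds a fresh draw of
#' cells (flow replaces the field of view between frames), and the
#' probability that a cell is asymmetric follows
#' \code{asymmetric_fraction_schedule}.
#'
#' @param n_frames number of frames (>= 1).
#' @param fps acquisition rate, frames per second (default 10).
#' @param asymmetric_fraction_schedule function of 0-based frame index
#'   returning the expected asymmetric fraction in \code{[0, 1]}, or a
#'   vector of length \code{n_frames}.
#' @param cells_per_frame intact cells placed per frame.
#' @param fragments_per_frame fragments/vesicles placed per frame.
#' @param seed master seed; per-frame seeds are derived from it.
#' @param height,width,background_level,gradient_amplitude,noise_sd frame
#'   parameters, as in \code{\link{frame_spec}}.
#' @param semi_major_range uniform sampling range for the semi-major
#'   axis, px; the default 15-19 px matches a shear-elongated RBC (about
#'   10 um long) at a 40x video pixel scale of roughly 0.3 um/px.
#' @param aspect_ratio_range uniform range for semi-minor/semi-major;
#'   the default 0.42-0.52 gives true elongation indices near 0.3-0.4,
#'   typical of RBC under high viscous shear.
#' @param lobe_factor_range uniform range of the two-lobe ratio for
#'   aberrant cells; the default 2.0-2.5 produces clearly aberrant
#'   outlines whose asymmetry scores sit far above the normal baseline.
#' @param normal_lobe_mean,normal_lobe_sd normal cells are only
#'   approximately ellipsoidal: each receives a mild lobe irregularity
#'   lambda = 1 + max(N(normal_lobe_mean, normal_lobe_sd), 0), giving a
#'   roughly Gaussian baseline asymmetry-score population bounded away
#'   from zero (scores near 1.5 +/- 0.6 percent), as real reference
#'   populations are. Set the mean to 0 for perfect ellipses.
#' @param fragment_radius_range uniform range of fragment radii, px.
#' @param min_separation minimum centre-to-centre distance between placed
#'   objects, px.
#' @param edge_margin minimum distance of object centres from the frame
#'   border, px; generous enough that per-cell crops are not truncated.
#' @return a \code{sequence_spec} object.
#' @export
sequence_spec <- function(n_frames, fps = 10,
                          asymmetric_fraction_schedule = function(i) 0,
                          cells_per_frame = 14, fragments_per_frame = 2,
                          seed = 1L,
                          height = 768, width = 768,
                          background_level = 200, gradient_amplitude = 20,
                          noise_sd = 6,
                          semi_major_range = c(15, 19),
                          aspect_ratio_range = c(0.42, 0.52),
                          lobe_factor_range = c(2.0, 2.5),
                          fragment_radius_range = c(2, 3.5),
                          normal_lobe_mean = 0.27, normal_lobe_sd = 0.15,
                          min_separation = 100, edge_margin = 88) {
  if (n_frames < 1) stop("`n_frames` must be >= 1")
  sched <- if (is.function(asymmetric_fraction_schedule))
    vapply(seq_len(n_frames) - 1L, asymmetric_fraction_schedule, numeric(1))
  else rep_len(asymmetric_fraction_schedule, n_frames)
  if (any(sched < 0 | sched > 1))
    stop("schedule values must lie in [0, 1]")
  structure(
    list(n_frames = as.integer(n_frames), fps = fps, schedule = sched,
         cells_per_frame = cells_per_frame,
         fragments_per_frame = fragments_per_frame,
         seed = as.integer(seed),
         height = height, width = width,
         background_level = background_level,
         gradient_amplitude = gradient_amplitude, noise_sd = noise_sd,
         semi_major_range = semi_major_range,
         aspect_ratio_range = aspect_ratio_range,
         lobe_factor_range = lobe_factor_range,
         fragment_radius_range = fragment_radius_range,
         normal_lobe_mean = normal_lobe_mean,
         normal_lobe_sd = normal_lobe_sd,
         min_separation = min_separation, edge_margin = edge_margin),
    class = "sequence_spec")
}

# Rejection-sample n well-separated centres with the given margin.
sample_centers <- function(n, nr, nc, margin, min_sep) {
  for (restart in 1:50) {
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < n && tries <= 5000L) {
      cand <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin))
      ok <- nrow(centers) == 0 ||
        all(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                           byrow = TRUE))^2)) >= min_sep)
      if (ok) centers <- rbind(centers, cand)
      tries <- tries + 1L
    }
    if (nrow(centers) == n) return(centers)
  }
  stop("could not place ", n, " objects with separation ", min_sep)
}

#' Render a synthetic frame sequence with ground truth
#'
#' Each cell is asymmetric (two-lobe) with probability given by the
#' schedule at its frame; the ground truth records the realized fraction.
#'
#' @param spec a \code{\link{sequence_spec}}.
#' @return list with \code{frames} (list of \code{intensity_frame}),
#'   \code{truth} (per-frame data.frame: frame_index, time_s, n_cells,
#'   n_fragments, n_asymmetric, realized_fraction, scheduled_fraction) and
#'   \code{cells} (row-bound per-cell truth tables with frame_index).
#' @export
render_sequence <- function(spec) {
  frames <- vector("list", spec$n_frames)
  truth <- vector("list", spec$n_frames)
  cells <- vector("list", spec$n_frames)
  for (i in seq_len(spec$n_frames)) {
    fseed <- (spec$seed + 977L * i) %% .Machine$integer.max
    fr <- with_seed(fseed, make_sequence_frame(spec, i - 1L, fseed))
    frames[[i]] <- fr$frame
    n_asym <- sum(fr$truth$aberrant)
    n_cell <- sum(fr$truth$kind != "fragment")
    truth[[i]] <- data.frame(
      frame_index = i - 1L, time_s = (i - 1L) / spec$fps,
      n_cells = n_cell,
      n_fragments = sum(fr$truth$kind == "fragment"),
      n_asymmetric = n_asym,
      realized_fraction = if (n_cell > 0) 100 * n_asym / n_cell else 0,
      scheduled_fraction = 100 * spec$schedule[i])
    ct <- fr$truth
    if (nrow(ct) > 0) ct$frame_index <- i - 1L
    cells[[i]] <- ct
  }
  list(frames = frames, truth = do.call(rbind, truth),
       cells = do.call(rbind, cells))
}

make_sequence_frame <- function(spec, frame_index, fseed) {
  n_cells <- spec$cells_per_frame
  n_frag <- spec$fragments_per_frame
  margin <- max(spec$edge_margin,
                max(spec$semi_major_range) * max(spec$lobe_factor_range) + 3)
  centers <- sample_centers(n_cells + n_frag, spec$height, spec$width,
                            margin, spec$min_separation)
  p_asym <- spec$schedule[frame_index + 1L]
  cell_list <- vector("list", n_cells + n_frag)
  aberrant <- logical(n_cells + n_frag)
  for (k in seq_len(n_cells)) {
    a <- runif(1, spec$semi_major_range[1], spec$semi_major_range[2])
    b <- a * runif(1, spec$aspect_ratio_range[1], spec$aspect_ratio_range[2])
    asym <- runif(1) < p_asym
    aberrant[k] <- asym
    lam <- if (asym)
      runif(1, spec$lobe_factor_range[1], spec$lobe_factor_range[2])
    else
      1 + max(rnorm(1, spec$normal_lobe_mean, spec$normal_lobe_sd), 0)
    cell_list[[k]] <- cell_spec(
      kind = if (lam > 1) "two_lobe" else "symmetric_ellipse",
      center = centers[k, ], semi_major = a, semi_minor = b,
      lobe_factor = lam,
      orientation = runif(1, 0, 180))
  }
  for (k in seq_len(n_frag)) {
    r <- runif(1, spec$fragment_radius_range[1], spec$fragment_radius_range[2])
    cell_list[[n_cells + k]] <- cell_spec(
      kind = "fragment", center = centers[n_cells + k, ],
      semi_major = r, semi_minor = r, fragment_cap = r + 0.5)
  }
  fs <- frame_spec(height = spec$height, width = spec$width,
                   background_level = spec$background_level,
                   gradient_amplitude = spec$gradient_amplitude,
                   noise_sd = spec$noise_sd, cells = cell_list,
                   seed = fseed)
  out <- render_frame(fs, frame_index = frame_index)
  out$truth$aberrant <- aberrant
  out
}

#' Write a ground-truth table as CSV
#'
#' @param truth a ground-truth data.frame from \code{\link{render_frame}}
#'   or \code{\link{render_sequence}}.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
write_ground_truth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
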