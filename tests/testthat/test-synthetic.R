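# Synthetic micrograph generator: footprints, frames, sequences, and
# the closed-form oracles derived from the two-lobe shape family.

test_that("cell footprints have the analytic areas", {
  # disk
  disk <- render_cell_mask(cell_spec("symmetric_ellipse", c(41, 41), 20, 20),
                           c(81, 81))
  expect_lt(abs(sum(disk) - pi * 20^2) / (pi * 20^2), 0.02)
  # two_lobe with lobe_factor 1 reduces to the ellipse
  e1 <- render_cell_mask(cell_spec("symmetric_ellipse", c(61, 61), 40, 20,
                                   orientation = 30), c(121, 121))
  e2 <- render_cell_mask(cell_spec("two_lobe", c(61, 61), 40, 20,
                                   lobe_factor = 1, orientation = 30),
                         c(121, 121))
  expect_identical(e1, e2)
  # two half-ellipse area: pi/2 * b * (a + a*lambda)
  tl <- render_cell_mask(cell_spec("two_lobe", c(81, 81), 40, 20,
                                   lobe_factor = 1.5, orientation = 90),
                         c(161, 161))
  target <- pi / 2 * 20 * (40 + 60)
  expect_lt(abs(sum(tl) - target) / target, 0.02)
})

test_that("cell_spec enforces its invariants", {
  expect_error(cell_spec("symmetric_ellipse", c(1, 1), 5, 10),
               "semi_major")
  expect_error(cell_spec("two_lobe", c(1, 1), 10, 5, lobe_factor = 0.8),
               "lobe_factor")
  expect_error(cell_spec("fragment", c(1, 1), 8, 8), "fragment cap")
  # footprint leaving the grid
  sp <- cell_spec("symmetric_ellipse", c(5, 5), 10, 8)
  expect_error(render_cell_mask(sp, c(64, 64)), "exceeds the grid")
  expect_silent(render_cell_mask(sp, c(64, 64), allow_boundary = TRUE))
})

test_that("frames are background + gradient exactly when empty, and seeded", {
  fs <- frame_spec(height = 96, width = 96, noise_sd = 0, cells = list())
  fr <- render_frame(fs)
  rows <- matrix(1:96, 96, 96); cols <- t(rows)
  expected <- 200 + 20 * ((rows / 96 + cols / 96) / 2 - 0.5)
  expect_equal(fr$frame$pixels, expected, tolerance = 1e-12)
  # bit-reproducibility under a fixed seed
  fs2 <- frame_spec(height = 96, width = 96, noise_sd = 5, seed = 42,
                    cells = list(cell_spec("symmetric_ellipse",
                                           c(48, 48), 10, 6)))
  expect_identical(render_frame(fs2)$frame$pixels,
                   render_frame(fs2)$frame$pixels)
})

test_that("ground truth matches construction", {
  fr <- compact_cell_frame(n_cells = 7, seed = 5)
  expect_equal(nrow(fr$truth), 7)
  expect_equal(fr$truth$true_ei,
               (fr$truth$semi_major - fr$truth$semi_minor) /
                 (fr$truth$semi_major + fr$truth$semi_minor))
  # overlapping footprints are flagged with a warning
  cells <- list(cell_spec("symmetric_ellipse", c(50, 50), 12, 8),
                cell_spec("symmetric_ellipse", c(58, 58), 12, 8))
  expect_warning(out <- render_frame(frame_spec(height = 128, width = 128,
                                                cells = cells, noise_sd = 0)),
                 "overlap")
  expect_true(all(out$truth$overlaps))
})

test_that("sequences follow the asymmetric-fraction schedule", {
  sq0 <- sequence_spec(n_frames = 3, cells_per_frame = 4,
                       fragments_per_frame = 1, seed = 9,
                       asymmetric_fraction_schedule = function(i) 0)
  s0 <- render_sequence(sq0)
  expect_equal(s0$truth$n_asymmetric, rep(0L, 3))
  expect_equal(s0$truth$time_s, (0:2) / 10)
  # reproducibility
  s0b <- render_sequence(sq0)
  expect_identical(s0$frames[[2]]$pixels, s0b$frames[[2]]$pixels)
  expect_identical(s0$cells, s0b$cells)
  # single frame degenerates to one rendered frame
  s1 <- render_sequence(sequence_spec(n_frames = 1, cells_per_frame = 3,
                                      fragments_per_frame = 0, seed = 2))
  expect_length(s1$frames, 1)
  expect_equal(nrow(s1$truth), 1)
  # step schedule: realized fraction lands in the binomial band
  sq <- sequence_spec(n_frames = 24, cells_per_frame = 14, seed = 31,
                      asymmetric_fraction_schedule =
                        function(i) if (i >= 8) 0.3 else 0)
  s <- render_sequence(sq)
  expect_equal(sum(s$truth$n_asymmetric[1:8]), 0)
  post <- s$truth[s$truth$frame_index >= 8, ]
  n <- sum(post$n_cells)
  p_hat <- sum(post$n_asymmetric) / n
  expect_lt(abs(p_hat - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  expect_error(sequence_spec(5, asymmetric_fraction_schedule = rep(1.4, 5)),
               "schedule")
})

test_that("two-lobe centroid offset matches direct integration", {
  for (lam in c(1, 1.3, 1.8, 2.4)) {
    sp <- cell_spec("two_lobe", c(151, 151), 40, 20, lobe_factor = lam,
                    orientation = 90)
    m <- render_cell_mask(sp, c(301, 301))
    idx <- which(m, arr.ind = TRUE)
    offset_measured <- 151 - mean(idx[, 1])  # apex points up (row decreases)
    expect_lt(abs(offset_measured - two_lobe_centroid_offset(40, lam)), 0.05)
  }
})

test_that("analytic radial profile matches geometry and is monotone in lobe factor", {
  # ellipse closed form
  sp <- cell_spec("symmetric_ellipse", c(0, 0), 40, 20)
  r <- analytic_radial_profile(sp, 1)
  theta <- seq(0, 359) * pi / 180
  expect_equal(r, 1 / sqrt(cos(theta)^2 / 400 + sin(theta)^2 / 1600),
               tolerance = 1e-12)
  # two-lobe: cardinal directions have exact values
  lam <- 1.5
  sp2 <- cell_spec("two_lobe", c(0, 0), 40, 20, lobe_factor = lam)
  r2 <- analytic_radial_profile(sp2, 1)
  yc <- two_lobe_centroid_offset(40, lam)
  expect_equal(r2[91], 40 * lam - yc, tolerance = 1e-9)   # up through apex
  expect_equal(r2[271], 40 + yc, tolerance = 1e-9)        # down through base
  # the analytic score increases strictly with the lobe factor
  grid <- seq(1, 2, by = 0.1)
  scores <- vapply(grid, function(l)
    analytic_asymmetry_score(cell_spec("two_lobe", c(0, 0), 40, 20,
                                       lobe_factor = l)), numeric(1))
  expect_equal(scores[1], 0, tolerance = 1e-9)
  expect_true(all(diff(scores) > 0))
})

test_that("frames round-trip through 8-bit TIFF and PNG", {
  fr <- compact_cell_frame(n_cells = 3, seed = 8)
  tmp <- withr::local_tempdir()
  tif <- file.path(tmp, "seq.tif")
  write_frames(list(fr$frame, fr$frame), tif)
  back <- read_frames(tif)
  expect_length(back, 2)
  expect_equal(back[[1]]$pixels, round(fr$frame$pixels),
               tolerance = 0.51)  # 8-bit quantization
  png_dir <- file.path(tmp, "frames")
  write_frames(list(fr$frame), png_dir)
  back2 <- read_frames(png_dir)
  expect_equal(back2[[1]]$pixels, back[[1]]$pixels, tolerance = 0.51)
})
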