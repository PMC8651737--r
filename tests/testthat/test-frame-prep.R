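# Preprocessing chain: background correction, contrast stretch, Sobel
# magnitude, Gaussian smoothing.

# Brute-force grayscale closing (independent oracle for the background
# estimator): nested per-offset max then min sweeps over the disc
# structuring element, on a reflectively padded image.
brute_closing <- function(m, radius) {
  off <- which(EBImage::makeBrush(2L * radius + 1L, "disc") == 1,
               arr.ind = TRUE) - (radius + 1L)
  padded <- rbcasym:::pad_reflect(m, radius)
  np <- nrow(padded); npc <- ncol(padded)
  pad2 <- function(x, k) {
    ri <- pmin(pmax(1:(np + 2 * k) - k, 1), np)
    ci <- pmin(pmax(1:(npc + 2 * k) - k, 1), npc)
    x[ri, ci]
  }
  stage <- function(x, mx) {
    xp <- pad2(x, radius)
    out <- matrix(if (mx) -Inf else Inf, np, npc)
    for (i in seq_len(nrow(off))) {
      sh <- xp[radius + off[i, 1] + 1:np, radius + off[i, 2] + 1:npc]
      out <- if (mx) pmax(out, sh) else pmin(out, sh)
    }
    out
  }
  closed <- stage(stage(padded, TRUE), FALSE)
  rbcasym:::unpad(closed, radius, nrow(m), ncol(m))
}

test_that("background subtraction flattens illumination, keeps cell contrast", {
  flat <- matrix(200, 64, 64)
  out <- subtract_background(flat, ball_radius = 10)
  expect_equal(diff(range(out)), 0)
  # linear ramp: peak-to-peak strongly attenuated
  ramp <- matrix(rep(seq(150, 220, length.out = 64), each = 64), 64, 64)
  out_r <- subtract_background(ramp, ball_radius = 10)
  expect_lt(diff(range(out_r)), 0.5 * diff(range(ramp)))
  # agrees with the brute-force grayscale-morphology oracle
  set.seed(3)
  m <- ramp + matrix(rnorm(64 * 64, 0, 3), 64, 64)
  bg_oracle <- brute_closing(m, 10)
  oracle <- pmax(pmin(m - bg_oracle + mean(bg_oracle), 255), 0)
  out_m <- subtract_background(m, ball_radius = 10)
  expect_lt(max(abs(out_m - oracle)), 0.02)  # 8-bit scaling round-trip
  expect_error(subtract_background(m, ball_radius = 0), "ball_radius")
})

test_that("cell rim contrast survives background subtraction", {
  sp <- cell_spec("symmetric_ellipse", c(65, 65), 12, 7)
  fr <- render_frame(frame_spec(height = 128, width = 128, cells = list(sp),
                                noise_sd = 0))
  px <- fr$frame$pixels
  rim_before <- max(px) - min(px)
  out <- subtract_background(px, ball_radius = 30)
  rim_after <- max(out) - min(out)
  expect_gt(rim_after, 0.9 * rim_before)
})

test_that("contrast stretch is a monotone percentile mapping", {
  # full-range frame with zero saturation is unchanged
  f <- matrix(seq(0, 255, length.out = 64 * 64), 64, 64)
  expect_equal(enhance_contrast(f, 0), f, tolerance = 1e-12)
  # two-valued frame maps onto the range endpoints
  tv <- matrix(c(100, 150), 32, 32)
  out <- enhance_contrast(tv, 0)
  expect_setequal(unique(as.vector(out)), c(0, 255))
  # monotone over random frames
  set.seed(7)
  for (i in 1:5) {
    x <- matrix(runif(400, 50, 180), 20, 20)
    y <- enhance_contrast(x, 0.01)
    ord <- order(x)
    expect_true(all(diff(y[ord]) >= -1e-9))
  }
  expect_warning(enhance_contrast(matrix(7, 10, 10)), "degenerate")
  expect_error(enhance_contrast(f, 0.6), "saturation_fraction")
})

test_that("Sobel magnitude matches direct convolution and is equivariant", {
  expect_equal(max(sobel_magnitude(matrix(42, 8, 8))$magnitude), 0)
  # vertical step edge of height h: direct 3x3 convolution oracle
  h <- 37
  step <- cbind(matrix(0, 5, 3), matrix(h, 5, 2))
  em <- sobel_magnitude(step)$magnitude
  expect_equal(which.max(colSums(em)), 3)   # transition column wins
  expect_equal(max(em), 4 * h)              # [1 2 1] * step height
  # rotating the frame 90 degrees rotates the magnitude map
  set.seed(2)
  x <- matrix(runif(144, 0, 255), 12, 12)
  m1 <- sobel_magnitude(x)$magnitude
  rot90 <- function(m) t(m)[, nrow(m):1]
  m2 <- sobel_magnitude(rot90(x))$magnitude
  expect_equal(m2, rot90(m1), tolerance = 1e-9)
  expect_true(all(m1 >= 0))
})

test_that("Gaussian smoothing conserves mass and obeys the semigroup", {
  # impulse response is the normalized kernel
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  sm <- gaussian_smooth(imp, 3)
  expect_equal(sum(sm), 1, tolerance = 1e-3)
  expect_equal(which(sm == max(sm)), which(imp == 1))
  # constant map unchanged; maximum never increases
  expect_equal(gaussian_smooth(matrix(5, 30, 30), 5), matrix(5, 30, 30),
               tolerance = 1e-9)
  set.seed(4)
  x <- matrix(rnorm(64 * 64, 100, 20), 64, 64)
  expect_lte(max(gaussian_smooth(x, 5)), max(x))
  expect_equal(sum(gaussian_smooth(x, 5)), sum(x), tolerance = 1e-3)
  # sigma 3 then 4 ~ sigma 5 within 1% rms of the dynamic range
  a34 <- gaussian_smooth(gaussian_smooth(x, 3), 4)
  a5 <- gaussian_smooth(x, 5)
  expect_lt(sqrt(mean((a34 - a5)^2)) / diff(range(a5)), 0.01)
  expect_error(gaussian_smooth(x, 0), "sigma")
})

test_that("the full chain preserves dimensions and is deterministic", {
  fr <- compact_cell_frame(n_cells = 3, seed = 13)
  cfg <- pipeline_config(ball_radius = 30)
  p1 <- preprocess_frame(fr$frame, cfg)
  p2 <- preprocess_frame(fr$frame, cfg)
  expect_identical(dim(p1$edges$magnitude), dim(fr$frame$pixels))
  expect_identical(p1$edges$magnitude, p2$edges$magnitude)
  # the alternative order (smooth the frame, then detect edges) runs too
  p3 <- preprocess_frame(fr$frame,
                         pipeline_config(ball_radius = 30,
                                         smooth_target = "frame"))
  expect_identical(dim(p3$edges$magnitude), dim(fr$frame$pixels))
  expect_false(identical(p3$edges$magnitude, p1$edges$magnitude))
})
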