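# Per-cell morphometry: binarization, alignment, radial profile,
# central nadir, asymmetry score and elongation index.

test_that("binarization recovers the rendered footprint", {
  sp <- cell_spec("symmetric_ellipse", c(51.4, 50.7), 40, 20,
                  orientation = 25)
  truth <- render_cell_mask(sp, c(101, 101))
  crop <- matrix(200, 101, 101)
  crop[truth] <- 80
  bm <- binarize_crop(crop)
  expect_lt(abs(bm$area - pi * 40 * 20) / (pi * 40 * 20), 0.02)
  expect_lt(abs(bm$centroid["row"] - 51.4), 0.5)
  expect_lt(abs(bm$centroid["col"] - 50.7), 0.5)
  expect_gt(sum(bm$mask & truth) / sum(truth | bm$mask), 0.97)
  # degenerate crop: valid = FALSE, never an error
  expect_false(binarize_crop(matrix(100, 32, 32))$valid)
})

test_that("alignment turns the principal axis vertical, apex up", {
  bm <- as_mask(render_cell_mask(
    cell_spec("symmetric_ellipse", c(101.3, 100.6), 40, 20,
              orientation = 37), c(203, 203)))
  al <- align_apex(bm)
  mo <- rbcasym:::mask_moments(al)
  phi <- 0.5 * atan2(2 * mo$mu11, mo$mu20 - mo$mu02) * 180 / pi
  expect_lt(abs(abs(phi) - 90), 1)          # major axis vertical
  expect_lt(abs(al$area - bm$area) / bm$area, 0.02)
  # circle: isotropic, returned unrotated
  circ <- as_mask(render_cell_mask(
    cell_spec("symmetric_ellipse", c(41, 41), 20, 20), c(81, 81)))
  expect_true("isotropic" %in% align_apex(circ)$flags)
  # two-lobe: the long lobe ends up above the centroid
  tl <- as_mask(render_cell_mask(
    cell_spec("two_lobe", c(101, 101), 30, 15, lobe_factor = 1.5,
              orientation = 120), c(203, 203)))
  altl <- align_apex(tl)
  idx <- which(altl$mask, arr.ind = TRUE)
  up <- altl$centroid["row"] - min(idx[, 1])
  down <- max(idx[, 1]) - altl$centroid["row"]
  expect_gt(up, down)
})

test_that("radial profiles match closed-form geometry", {
  # disk with sub-pixel centre: constant profile
  disk <- as_mask(render_cell_mask(
    cell_spec("symmetric_ellipse", c(41.4, 41.7), 20, 20), c(83, 83)))
  pd <- radial_profile(disk)
  expect_true(all(abs(pd$radii - 20) <= 0.5))
  # aligned ellipse: within 0.6 px everywhere, within 1% rms
  m <- as_mask(render_cell_mask(
    cell_spec("symmetric_ellipse", c(101.4, 101.7), 40, 20,
              orientation = 90), c(203, 203)))
  pr <- radial_profile(m)
  ana <- analytic_radial_profile(cell_spec("symmetric_ellipse",
                                           c(0, 0), 40, 20), 1)
  expect_lt(max(abs(pr$radii - ana)), 0.6)
  expect_lt(sqrt(mean(((pr$radii - ana) / ana)^2)), 0.01)
  # a 180-degree rotation shifts the profile by 180 entries
  p180 <- radial_profile(m, angle_offset = 180)
  expect_equal(p180$radii, c(pr$radii[181:360], pr$radii[1:180]),
               tolerance = 1e-12)
})

test_that("normalization is scale-free and leaves the score unchanged", {
  m1 <- as_mask(render_cell_mask(
    cell_spec("two_lobe", c(101.3, 101.5), 25, 12, lobe_factor = 1.5,
              orientation = 40), c(203, 203)))
  p1 <- radial_profile(m1)
  n1 <- normalize_profile(p1, m1$area)
  # disk normalizes to ~1
  disk <- as_mask(render_cell_mask(
    cell_spec("symmetric_ellipse", c(41.4, 41.7), 20, 20), c(83, 83)))
  nd <- normalize_profile(radial_profile(disk), disk$area)
  expect_true(all(abs(nd$radii - 1) < 0.05))
  # the score cancels the common factor exactly
  expect_equal(asymmetry_score(p1)$score, asymmetry_score(n1)$score,
               tolerance = 1e-12)
  # doubling the shape changes the normalized profile only by pixelation
  m2 <- as_mask(render_cell_mask(
    cell_spec("two_lobe", c(201.6, 201.0), 50, 24, lobe_factor = 1.5,
              orientation = 40), c(403, 403)))
  n2 <- normalize_profile(radial_profile(m2), m2$area)
  expect_lt(max(abs(n1$radii - n2$radii)), 0.08)
  expect_error(normalize_profile(p1, 0), "area")
})

test_that("the central nadir sits opposite the start valley", {
  m <- as_mask(render_cell_mask(
    cell_spec("symmetric_ellipse", c(101, 101), 40, 20, orientation = 90),
    c(201, 201)))
  nd <- find_central_nadir(radial_profile(m))
  expect_true(nd$valid)
  expect_lt(abs(nd$nadir_deg - 180), 2)
  # constant profile: not bimodal
  const <- structure(list(radii = rep(5, 360), step_deg = 1,
                          normalized = FALSE, equivalent_radius = NA,
                          centroid_inside = TRUE, valid = TRUE),
                     class = "radial_profile")
  expect_false(find_central_nadir(const)$valid)
})

test_that("the score follows |(A1 - A2)/A1| x 100", {
  # construct a profile whose halves integrate to 120 and 90 exactly
  # r = m + d sin(theta): the upper half integrates to 180 m + d * 360/pi,
  # the lower to 180 m - d * 360/pi (degree units); solve for 120 and 90
  th <- seq(0, 359) * pi / 180
  r <- 105 / 180 + (15 / (360 / pi)) * sin(th)
  prof <- structure(list(radii = r, step_deg = 1, normalized = TRUE,
                         equivalent_radius = 1, centroid_inside = TRUE,
                         valid = TRUE), class = "radial_profile")
  nadir <- list(nadir_index = 181L, nadir_deg = 180, shift = 0L,
                shifted = r, cut1 = 1, cut_offset = 180, valid = TRUE)
  res <- asymmetry_score(prof, nadir)
  expect_equal(res$A1, 120, tolerance = 1e-3)
  expect_equal(res$A2, 90, tolerance = 1e-3)
  expect_equal(res$score, 25, tolerance = 0.02)
  # order-free variant divides by the larger half
  res_sym <- asymmetry_score(prof, nadir, symmetric_denominator = TRUE)
  expect_equal(res_sym$score, 25, tolerance = 0.02)
  # mirror-symmetric cell scores (near) zero
  ell <- as_mask(render_cell_mask(
    cell_spec("symmetric_ellipse", c(101, 101), 40, 20, orientation = 90),
    c(201, 201)))
  expect_lt(score_cell(ell)$score, 0.5)
})

test_that("scores are non-negative, rotation- and scale-stable", {
  set.seed(19)
  # rotation invariance: one shape at 12 orientations
  s_rot <- vapply(seq(0, 330, 30) + 7.3, function(o)
    score_cell(render_cell_mask(
      cell_spec("two_lobe", c(201.37, 201.61), 50, 20, lobe_factor = 1.5,
                orientation = o), c(403, 403)))$score, numeric(1))
  expect_true(all(s_rot >= 0))
  expect_lt(diff(range(s_rot)), 1)
  # scale invariance across a random family
  for (i in 1:4) {
    a <- runif(1, 30, 40); rat <- runif(1, 0.4, 0.6)
    lam <- runif(1, 1, 1.6); ori <- runif(1, 0, 180)
    s1 <- score_cell(render_cell_mask(
      cell_spec("two_lobe", c(101.3, 101.5), a, a * rat, lobe_factor = lam,
                orientation = ori), c(203, 203)))$score
    s2 <- score_cell(render_cell_mask(
      cell_spec("two_lobe", c(201.3, 201.5), 2 * a, 2 * a * rat,
                lobe_factor = lam, orientation = ori), c(403, 403)))$score
    expect_lt(abs(s1 - s2), 0.5)
  }
})

test_that("pipeline scores increase strictly with the lobe factor", {
  scores <- vapply(seq(1, 2, 0.1), function(l)
    score_cell(render_cell_mask(
      cell_spec("two_lobe", c(201.37, 201.61), 50, 20, lobe_factor = l,
                orientation = 37), c(403, 403)))$score, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("elongation index matches (a - b)/(a + b)", {
  circ <- as_mask(render_cell_mask(
    cell_spec("symmetric_ellipse", c(41, 41), 20, 20), c(81, 81)))
  expect_equal(elongation_index(circ)$EI, 0)
  ell <- align_apex(as_mask(render_cell_mask(
    cell_spec("symmetric_ellipse", c(101, 101), 40, 20, orientation = 90),
    c(201, 201))))
  ei <- elongation_index(ell)
  expect_equal(ei$EI, 1 / 3, tolerance = 0.02)
  # rotated circle stays round
  rot <- align_apex(as_mask(render_cell_mask(
    cell_spec("symmetric_ellipse", c(101.2, 101.8), 30, 30), c(203, 203))))
  expect_lte(abs(elongation_index(rot)$EI), 0.02)
  # degenerate mask
  tiny <- as_mask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_false(elongation_index(tiny)$valid)
})
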