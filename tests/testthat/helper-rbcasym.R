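# Shared fixtures. Expensive objects (rendered sequences, pipeline
# calibrations) are built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# a mask wrapped the way the morphometry layer expects
as_mask <- function(m) rbcasym:::new_binary_mask(m)

# compact-cell frame (cells ~16-22 px across): the sigma = 5 smoothed
# edge ring of cells this size peaks at the cell centre, which the
# detector's position-accuracy checks rely on
compact_cell_frame <- function(n_cells = 7, seed = 11, noise_sd = 2) {
  set.seed(seed)
  pos <- expand.grid(row = c(60, 130, 200), col = c(60, 130, 200))
  pos <- pos[sample(nrow(pos), n_cells), ]
  cells <- lapply(seq_len(n_cells), function(k) {
    cell_spec("symmetric_ellipse",
              center = c(pos$row[k], pos$col[k]) + runif(2, -6, 6),
              semi_major = runif(1, 8, 11),
              semi_minor = runif(1, 5, 6.5),
              orientation = runif(1, 0, 180))
  })
  render_frame(frame_spec(height = 260, width = 260, cells = cells,
                          noise_sd = noise_sd, seed = seed))
}

# pipeline calibration on reference (all-normal) frames at the fixture
# study conditions; shared by the classification and acceptance tests
fixture_calibration <- function() {
  cached("calibration", {
    s0 <- render_sequence(sequence_spec(n_frames = 8, seed = 77))
    calibrate_from_frames(s0$frames, fixture_config(),
                          source = "reference frames, seed 77")
  })
}
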