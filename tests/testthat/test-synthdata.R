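test_that("all generators are bit-deterministic under a fixed seed", {
  f1 <- gen_filaments(5, shape = c(64, 64), seed = 81)
  f2 <- gen_filaments(5, shape = c(64, 64), seed = 81)
  expect_identical(f1$stack$pixels, f2$stack$pixels)

  c1 <- gen_comet_field(5, 4, shape = c(128, 128), seed = 82)
  c2 <- gen_comet_field(5, 4, shape = c(128, 128), seed = 82)
  expect_identical(c1$comet$pixels, c2$comet$pixels)
  expect_identical(c1$junction$pixels, c2$junction$pixels)

  m1 <- gen_comet_movie(n_spots = 10, n_frames = 10, shape = c(64, 64),
                        seed = 83)
  m2 <- gen_comet_movie(n_spots = 10, n_frames = 10, shape = c(64, 64),
                        seed = 83)
  expect_identical(m1$stack$pixels, m2$stack$pixels)

  d1 <- gen_drift_movie(c(0, 0.5), 1, n_frames = 12, shape = c(48, 48),
                        seed = 84, line_spacing = 30)
  d2 <- gen_drift_movie(c(0, 0.5), 1, n_frames = 12, shape = c(48, 48),
                        seed = 84, line_spacing = 30)
  expect_identical(d1$stack$pixels, d2$stack$pixels)
  expect_error(gen_filaments(3, shape = c(64, 64)), "seed")
})

test_that("filament truth is self-consistent and nested across counts", {
  sim <- gen_filaments(6, shape = c(96, 96), seed = 85)
  polys <- sim$truth$truth$polylines
  expect_length(polys, 6)
  lens <- vapply(polys, function(p)
    sum(sqrt(diff(p$y)^2 + diff(p$x)^2)), numeric(1))
  expect_equal(sum(lens), sim$truth$truth$total_length, tolerance = 1e-9)
  expect_true(all(vapply(polys, function(p)
    all(p$y >= 0 & p$y <= 95 & p$x >= 0 & p$x <= 95), logical(1))))

  # matched-seed nesting: first 3 filaments of n=6 equal those of n=3
  sim3 <- gen_filaments(3, shape = c(96, 96), seed = 85)
  expect_identical(sim3$truth$truth$polylines, polys[1:3])

  blank <- gen_filaments(0, noise_sd = 5, shape = c(64, 64), seed = 86)
  p <- ridge_params_from_contrast(100, 1.8, 1.5, min_length = 10)
  expect_length(detect_ridges(blank$stack$pixels, p)$polylines, 0)
})

test_that("comet-field truth stores per-comet geometry inside cells", {
  sim <- gen_comet_field(8, 5, true_ar = 2.5, shape = c(220, 220), seed = 87)
  tr <- sim$truth$truth$comets
  expect_gte(nrow(tr), 0.5 * 8 * 5)
  expect_true(all(tr$ar >= 1))
  # each comet's stored cell matches the tessellation label at its centre
  labs <- sim$labels[cbind(round(tr$y) + 1, round(tr$x) + 1)]
  expect_equal(labs, tr$cell)
  expect_error(gen_comet_field(4, 50, true_ar = 3, shape = c(100, 100),
                               seed = 88), "packing")
})

test_that("comet-movie kinematics follow the configured calibration", {
  sim <- gen_comet_movie(n_spots = 12, speed_um_s = 0.13,
                         pixel_size_um = 0.1, n_frames = 20, seed = 89)
  expect_equal(sim$stack$frame_interval, 2)
  expect_equal(unique(sim$truth$truth$spots$speed_px_frame), 2.6)
  expect_false(sim$truth$truth$warning_too_fast)
  fast <- gen_comet_movie(n_spots = 3, speed_um_s = 5, shape = c(48, 48),
                          n_frames = 6, seed = 90)
  expect_true(fast$truth$truth$warning_too_fast)

  # a rendered mid-life spot sits where the truth says it should
  tr <- sim$truth$truth$spots[1, ]
  t_probe <- tr$t0 + 2
  if (t_probe <= 20) {
    y_exp <- tr$y0 + 2 * tr$speed_px_frame * sin(tr$direction) + 1
    x_exp <- tr$x0 + 2 * tr$speed_px_frame * cos(tr$direction) + 1
    if (y_exp > 4 && x_exp > 4 && y_exp < 124 && x_exp < 124) {
      fr <- get_plane(sim$stack, t = t_probe)
      win <- fr[round(y_exp) + (-3:3), round(x_exp) + (-3:3)]
      expect_gt(max(win), 0.5 * max(fr))
    }
  }
})

test_that("drift-movie truth reproduces the cumulative offsets", {
  sim <- gen_drift_movie(c(0.3, -0.2), jitter_amplitude_px = 1.5,
                         n_frames = 15, shape = c(64, 64), seed = 91,
                         line_spacing = 40)
  tr <- sim$truth$truth
  expect_equal(tr$jitter[1, ], c(0, 0))
  expect_true(all(abs(tr$jitter) <= 1.5))
  recon <- cbind(0.3 * (0:14) + tr$jitter[, 1],
                 -0.2 * (0:14) + tr$jitter[, 2])
  expect_equal(unname(tr$cumulative_offset), unname(recon),
               tolerance = 1e-12)
})

test_that("generator output survives a TIFF round-trip", {
  sim <- gen_filaments(3, shape = c(64, 64), seed = 92)
  rounded <- with_pixels(sim$stack, round(sim$stack$pixels))
  tmp <- tempfile(fileext = ".tif")
  write_stack(rounded, tmp, bits = 16)
  expect_identical(read_stack(tmp)$pixels, rounded$pixels)

  gt_tmp <- tempfile(fileext = ".json")
  write_ground_truth(sim$truth, gt_tmp)
  gt <- read_ground_truth(gt_tmp)
  expect_equal(gt$kind, "filaments")
  expect_equal(gt$truth$total_length, sim$truth$truth$total_length,
               tolerance = 1e-9)
})
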