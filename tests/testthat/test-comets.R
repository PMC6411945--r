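test_that("a blank junction image segments to a single frame-wide region", {
  cells <- segment_cells(matrix(5, 64, 64))
  expect_equal(cells$n_cells, 1L)
  expect_true(all(cells$labels == 1L))
})

test_that("a tessellation segments into its true cells; erased boundaries merge", {
  sim <- gen_comet_field(n_cells = 10, comets_per_cell = 4, true_ar = 2,
                         snr = 20, shape = c(200, 200), seed = 41)
  cells <- segment_cells(sim$junction, min_cell_area = 50)
  expect_equal(cells$n_cells, 10L)
  seeds <- sim$truth$truth$seeds
  labs <- cells$labels[cbind(round(seeds$y) + 1, round(seeds$x) + 1)]
  expect_length(unique(labs), 10)

  # erase the boundary between one pair of adjacent cells: they must merge
  lab_true <- sim$labels
  A_h <- lab_true[, -1]; B_h <- lab_true[, -ncol(lab_true)]
  A_v <- lab_true[-1, ]; B_v <- lab_true[-nrow(lab_true), ]
  pair <- NULL
  for (cand in 2:10) {
    touches <- any((A_h == 1 & B_h == cand) | (A_h == cand & B_h == 1)) ||
      any((A_v == 1 & B_v == cand) | (A_v == cand & B_v == 1))
    if (touches) { pair <- c(1, cand); break }
  }
  expect_false(is.null(pair))
  erased <- lab_true
  erased[erased == pair[2]] <- pair[1]
  jn <- render_junction(erased)
  cells2 <- segment_cells(jn, min_cell_area = 50)
  expect_equal(cells2$n_cells, 9L)
})

test_that("particle aspect ratio measures spot anisotropy", {
  one <- segment_cells(matrix(0, 96, 96))
  img <- add_gaussian_spot(matrix(0, 96, 96), 48, 48, sigma_y = 4,
                           sigma_x = 8)
  parts <- detect_comet_particles(img, one, min_area = 10)
  expect_equal(nrow(parts), 1)
  expect_equal(parts$aspect_ratio, 2, tolerance = 0.05)
  expect_equal(parts$cell_label, 1L)

  iso <- add_gaussian_spot(matrix(0, 96, 96), 40, 60, sigma_y = 5)
  pi_ <- detect_comet_particles(iso, one, min_area = 10)
  expect_equal(pi_$aspect_ratio, 1, tolerance = 0.03)
})

test_that("particle detection applies size gates and degenerate-input rules", {
  one <- segment_cells(matrix(0, 32, 32))
  img <- matrix(0, 32, 32); img[16, 16] <- 100
  expect_equal(nrow(detect_comet_particles(img, one, min_area = 4,
                                           threshold_method = "fixed",
                                           threshold_value = 50)), 0)
  expect_equal(nrow(detect_comet_particles(matrix(0, 32, 32), one)), 0)
  expect_error(detect_comet_particles(img, one, threshold_method = "bogus"))

  # doublet gate: two touching spots exceed max_area and are rejected
  img2 <- add_gaussian_spot(matrix(0, 64, 64), 32, 28, sigma_y = 4)
  img2 <- add_gaussian_spot(img2, 32, 40, sigma_y = 4)
  one64 <- segment_cells(matrix(0, 64, 64))
  all_parts <- detect_comet_particles(img2, one64, min_area = 10)
  gated <- detect_comet_particles(img2, one64, min_area = 10,
                                  max_area = max(all_parts$area) - 1)
  expect_lt(nrow(gated), nrow(all_parts))
})

test_that("aspect ratio is invariant to rotation and intensity scaling", {
  one <- segment_cells(matrix(0, 128, 128))
  ars <- vapply(c(0, 30, 75) * pi / 180, function(th) {
    img <- add_gaussian_spot(matrix(0, 128, 128), 64, 64, sigma_y = 6,
                             sigma_x = 12, theta = th)
    detect_comet_particles(img, one, min_area = 10)$aspect_ratio
  }, numeric(1))
  expect_lt(max(abs(ars - ars[1])) / ars[1], 0.03)

  one <- segment_cells(matrix(0, 96, 96))
  img <- add_gaussian_spot(matrix(0, 96, 96), 48, 48, sigma_y = 4,
                           sigma_x = 8)
  a <- detect_comet_particles(img, one, min_area = 10,
                              threshold_method = "fixed",
                              threshold_value = 30)
  b <- detect_comet_particles(img * 4, one, min_area = 10,
                              threshold_method = "fixed",
                              threshold_value = 120)
  expect_identical(a$aspect_ratio, b$aspect_ratio)
})

test_that("per-cell means aggregate particles and omit empty cells", {
  cells <- structure(list(labels = matrix(rep(1:2, each = 32), 8, 8),
                          n_cells = 2L, border_labels = 1:2),
                     class = "CellLabelMap")
  parts <- data.frame(y = c(1, 2), x = c(1, 2), area = c(10, 10),
                      major_axis = c(3, 5), minor_axis = c(2, 2),
                      aspect_ratio = c(1.5, 2.5), cell_label = c(1L, 1L))
  pc <- per_cell_mean_ar(parts, cells)
  expect_equal(nrow(pc), 1)
  expect_equal(pc$mean_ar, 2)
  expect_equal(pc$n_comets, 2L)

  withr::with_seed(12, {
    sim_parts <- do.call(rbind, lapply(1:50, function(cl)
      data.frame(y = 0, x = 0, area = 10, major_axis = 1, minor_axis = 1,
                 aspect_ratio = runif(sample(1:6, 1), 1, 3),
                 cell_label = cl)))
  })
  cells50 <- structure(list(labels = matrix(1L, 2, 2), n_cells = 50L,
                            border_labels = integer(0)),
                       class = "CellLabelMap")
  pc50 <- per_cell_mean_ar(sim_parts, cells50)
  oracle <- tapply(sim_parts$aspect_ratio, sim_parts$cell_label, mean)
  expect_equal(pc50$mean_ar,
               as.numeric(oracle[as.character(pc50$cell_label)]))
})

test_that("condition summaries are mean over cells with SEM", {
  s <- condition_summary(c(1, 2, 3), "demo")
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 0.5774, tolerance = 1e-4)
  expect_equal(s$n, 3)
  expect_equal(condition_summary(c(2, 2, 2))$sem, 0)
  expect_error(condition_summary(1.9), "at least 2")
})

test_that("the full morphometry pipeline recovers a known aspect ratio", {
  sim <- gen_comet_field(n_cells = 10, comets_per_cell = 8, true_ar = 2,
                         snr = 10, shape = c(260, 260), seed = 51)
  res <- comet_morphometry(sim$junction, sim$comet, upscale_factor = 3,
                           rolling_ball_radius = 15, min_area = 20,
                           max_area = 900)
  expect_lte(nrow(res$per_cell), res$cells$n_cells)
  expect_equal(mean(res$per_cell$mean_ar), 2, tolerance = 0.05)
  # conservation: every particle is assigned to exactly one cell
  expect_true(all(res$particles$cell_label %in%
                    seq_len(res$cells$n_cells)))
  expect_equal(sum(res$per_cell$n_comets), nrow(res$particles))
})
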