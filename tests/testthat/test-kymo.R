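test_that("kymograph slicing counts lines and preserves time", {
  withr::with_seed(15, {
    frames <- lapply(1:100, function(t) matrix(runif(80 * 80, 0, 9), 80, 80))
  })
  mv <- stack_from_frames(frames, frame_interval = 15)
  kms <- build_kymographs(mv, region = c(10, 10, 30, 40), stride = 10)
  ax <- vapply(kms, function(k) k$line_axis, character(1))
  expect_equal(sum(ax == "x"), 3)  # rows 1, 11, 21 of a 30-px-tall region
  expect_equal(sum(ax == "y"), 4)  # cols 1, 11, 21, 31 of a 40-px-wide one
  expect_true(all(vapply(kms, function(k) nrow(k$pixels), integer(1)) == 100))
  expect_error(build_kymographs(mv, c(70, 10, 30, 40)), "bounds")
  expect_error(build_kymographs(mv, c(10, 10, 30, 40), stride = 0), "stride")

  # a static movie gives kymographs with identical rows
  static <- stack_from_frames(rep(frames[1], 10), frame_interval = 15)
  km <- build_kymographs(static, c(10, 10, 30, 40), stride = 40)[[1]]
  expect_equal(km$pixels, matrix(km$pixels[1, ], 10, ncol(km$pixels),
                                 byrow = TRUE))
})

test_that("a translating movie produces streaks of the right slope", {
  base <- cytoquant:::gaussian_smooth(
    matrix(withr::with_seed(16, runif(120 * 120, 0, 100)), 120, 120), 1.5)
  frames <- lapply(0:29, function(t)
    cytoquant:::translate_image(base, 0, t))  # 1 px/frame along +x
  mv <- stack_from_frames(frames, frame_interval = 15)
  km <- build_kymographs(mv, c(40, 20, 40, 80), stride = 80)[[1]]
  expect_equal(km$line_axis, "x")
  # a tracked local maximum advances by ~1 column per row
  pos <- which.max(km$pixels[1, 10:40]) + 9
  track <- pos
  for (t in 2:30) {
    lo <- max(1, pos - 3); hi <- min(80, pos + 3)
    pos <- which.max(km$pixels[t, lo:hi]) + lo - 1
    track <- c(track, pos)
  }
  fit <- stats::coef(stats::lm(track ~ seq_along(track)))[2]
  expect_equal(unname(fit), 1, tolerance = 0.1)
})

test_that("Feret angle matches the all-pairs oracle and known geometries", {
  vert <- feret(ys = 0:20, xs = rep(3, 21))
  expect_equal(vert$angle_deg, 90)
  diag1 <- feret(ys = 0:20, xs = 0:20)
  expect_equal(diag1$angle_deg, 45)

  withr::with_seed(17, {
    for (i in 1:8) {
      n <- sample(5:40, 1)
      ys <- cumsum(runif(n, 0.5, 1.5))
      xs <- cumsum(runif(n, -1, 1))
      a <- feret(ys, xs)
      b <- oracle_feret(ys, xs)
      expect_equal(a$diameter, b$diameter, tolerance = 1e-12)
      expect_equal(a$angle_deg, b$angle_deg, tolerance = 1e-9)
    }
  })
})

test_that("streak tracing scores deviation from the vertical time axis", {
  # vertical streak -> 0 degrees; slope-1 streak -> 45 degrees
  mk_kymo <- function(slope) {
    K <- matrix(0, 60, 80)
    for (t in 1:60) {
      c0 <- 10 + slope * t
      cols <- pmax(1, pmin(80, round(c0 + (-2:2))))
      K[t, cols] <- pmax(K[t, cols], 100 * exp(-(-2:2)^2 / 2))
    }
    structure(list(pixels = K, line_axis = "x", line_index = 0),
              class = "Kymograph")
  }
  p <- ridge_params(1.5, 3, 1, min_length = 20)
  d0 <- trace_and_score(mk_kymo(0), p)
  expect_gte(length(d0), 1)
  expect_lt(max(d0), 1)
  d1 <- trace_and_score(mk_kymo(1), p)
  expect_gte(length(d1), 1)
  expect_equal(mean(d1), 45, tolerance = 2)
})

test_that("region motility is near zero for a static movie and symmetric in time", {
  sim <- gen_drift_movie(c(0, 0), jitter_amplitude_px = 0, n_frames = 60,
                         shape = c(160, 160), seed = 71, line_spacing = 60)
  r <- region_motility(sim$stack, list(c(16, 16, 128, 128)),
                       stabilize_movie = FALSE, window = 20, stride = 32)
  expect_gte(r$n_traces, 1)
  expect_lt(r$mean_deviation, 2)

  rev_stack <- sim$stack
  rev_stack$pixels <- rev_stack$pixels[60:1, , ]
  r_rev <- region_motility(rev_stack, list(c(16, 16, 128, 128)),
                           stabilize_movie = FALSE, window = 20, stride = 32)
  expect_equal(sort(attr(r, "per_trace")[[1]]),
               sort(attr(r_rev, "per_trace")[[1]]), tolerance = 1e-6)
  expect_true(all(attr(r, "per_trace")[[1]] >= 0 &
                    attr(r, "per_trace")[[1]] <= 90))
})
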