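test_that("max projection equals the per-pixel maximum over z", {
  one <- image_stack(array(runif(64, 0, 9), c(1, 8, 8)),
                     axes = c("z", "y", "x"))
  expect_equal(get_plane(max_project(one)), array(one$pixels[1, , ], c(8, 8)))

  two <- image_stack(array(c(3, 7), c(2, 1, 1)), axes = c("z", "y", "x"))
  expect_equal(as.numeric(max_project(two)$pixels), 7)

  withr::with_seed(3, {
    arr <- array(runif(5 * 12 * 10, 0, 100), c(5, 12, 10))
  })
  st <- image_stack(arr, axes = c("z", "y", "x"), pixel_size = 0.5)
  mp <- max_project(st)
  oracle <- matrix(0, 12, 10)
  for (y in 1:12) for (x in 1:10) oracle[y, x] <- max(arr[, y, x])
  expect_equal(get_plane(mp), oracle)
  expect_equal(mp$pixel_size, 0.5)
  expect_error(max_project(mp), "no z axis")
})

test_that("bilinear upscaling dominates the upscaled projection pointwise", {
  # interpolation is a convex combination, so upscale(max_z) >= max_z(upscale)
  withr::with_seed(4, {
    arr <- array(runif(3 * 16 * 16, 0, 50), c(3, 16, 16))
  })
  st <- image_stack(arr, axes = c("z", "y", "x"))
  a <- upscale(get_plane(max_project(st)), 3)
  b <- Reduce(pmax, lapply(1:3, function(z) upscale(arr[z, , ], 3)))
  expect_true(all(a >= b - 1e-9))
  # with a single slice the two orders agree exactly
  one <- image_stack(arr[1, , , drop = FALSE], axes = c("z", "y", "x"))
  expect_equal(upscale(get_plane(max_project(one)), 3),
               upscale(arr[1, , ], 3), tolerance = 1e-12)
})

test_that("rolling-ball subtraction removes flat background exactly", {
  expect_equal(rolling_ball_subtract(matrix(7.5, 40, 40), 10),
               matrix(0, 40, 40))
  withr::with_seed(5, img <- matrix(runif(32 * 32, 0, 50), 32, 32))
  expect_equal(rolling_ball_subtract(img + 13, 5),
               rolling_ball_subtract(img, 5), tolerance = 1e-12)
  expect_true(all(rolling_ball_subtract(img, 5) >= 0))
  expect_error(rolling_ball_subtract(img, 0), "radius")
})

test_that("a narrow peak survives a large rolling ball, flat base vanishes", {
  img <- matrix(20, 64, 64)
  img[31:33, 31:33] <- 100
  out <- rolling_ball_subtract(img, 25)
  expect_gt(max(out), 0.99 * 80)
  expect_lt(max(out[1:10, 1:10]), 0.01 * 20)
})

test_that("rolling-ball equals the brute-force ball opening oracle", {
  withr::with_seed(6, {
    for (radius in c(3, 5)) {
      img <- matrix(runif(32 * 32, 0, 100), 32, 32)
      expect_equal(rolling_ball_subtract(img, radius),
                   pmax(img - oracle_ball_opening(img, radius), 0),
                   tolerance = 1e-6)
    }
  })
})

test_that("upscale interpolates bilinearly and preserves shape descriptors", {
  img <- matrix(runif(64), 8, 8)
  expect_identical(upscale(img, 1), img)
  expect_error(upscale(img, 2.5), "integer")

  # binary ellipse with axis ratio 2: moment-fit AR is preserved within 2%
  mask <- matrix(0, 64, 64)
  yy <- matrix(1:64, 64, 64); xx <- t(yy)
  mask[((yy - 32) / 10)^2 + ((xx - 32) / 20)^2 <= 1] <- 1
  ar_of <- function(m) {
    idx <- which(m > 0.5, arr.ind = TRUE)
    e <- cytoquant:::moment_ellipse(idx[, 1], idx[, 2])
    unname(e["major"] / e["minor"])
  }
  expect_equal(ar_of(upscale(mask, 3)), ar_of(mask), tolerance = 0.02)

  st <- image_stack(img, pixel_size = 0.3)
  expect_equal(upscale(st, 3)$pixel_size, 0.1)
})

test_that("stabilization recovers injected translations", {
  static <- make_drifting_movie(c(0, 0), 4)
  st <- stabilize(static)
  expect_equal(max(abs(as.matrix(st$shifts[, c("dy", "dx")]))), 0)

  drift <- make_drifting_movie(c(2, 3), 5)
  sh <- stabilize(drift)$shifts
  expect_identical(round(sh$dy), c(0, 2, 4, 6, 8))
  expect_identical(round(sh$dx), c(0, 3, 6, 9, 12))
  expect_lt(max(abs(sh$dy - round(sh$dy))), 0.1)

  sub <- make_drifting_movie(c(0.5, -0.5), 6)
  sh <- stabilize(sub)$shifts
  inc <- apply(as.matrix(sh[, c("dy", "dx")]), 2, diff)
  expect_lt(max(abs(inc[, 1] - 0.5)), 0.25)
  expect_lt(max(abs(inc[, 2] + 0.5)), 0.25)

  blank <- stack_from_frames(list(matrix(0, 16, 16), matrix(0, 16, 16)),
                             frame_interval = 1)
  expect_error(stabilize(blank), "degenerate")
})

test_that("running average is a centred truncated-window mean", {
  withr::with_seed(8, {
    frames <- lapply(1:10, function(i) matrix(runif(36), 6, 6))
  })
  mv <- stack_from_frames(frames, frame_interval = 1)
  expect_identical(running_average(mv, 1)$pixels, mv$pixels)
  ra <- running_average(mv, 5)
  for (t in c(1, 4, 10)) {
    a <- max(1, t - 2); b <- min(10, t + 2)
    oracle <- Reduce(`+`, frames[a:b]) / (b - a + 1)
    expect_equal(get_plane(ra, t = t), oracle, tolerance = 1e-12)
  }
  expect_error(running_average(mv, 0), "window")
})

test_that("running average cuts i.i.d. temporal variance by the window size", {
  withr::with_seed(9, {
    frames <- lapply(1:300, function(i) matrix(rnorm(16, 50, 10) + 50, 4, 4))
  })
  mv <- stack_from_frames(frames, frame_interval = 1)
  ra <- running_average(mv, 20)
  interior <- 20:280
  v_in <- mean(apply(mv$pixels[interior, , ], c(2, 3), var))
  v_out <- mean(apply(ra$pixels[interior, , ], c(2, 3), var))
  expect_equal(v_in / v_out, 20, tolerance = 0.25)
})
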