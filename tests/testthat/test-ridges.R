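make_line_image <- function(ny = 64, nx = 128, y0 = 32.3, sd_cross = 1.5,
                            peak = 100, x_range = c(15, 114)) {
  yy <- matrix(seq_len(ny), ny, nx)
  im <- peak * exp(-(yy - y0)^2 / (2 * sd_cross^2))
  im[, seq_len(x_range[1] - 1)] <- 0
  if (x_range[2] < nx) im[, (x_range[2] + 1):nx] <- 0
  im
}

test_that("a constant image contains no ridges", {
  p <- ridge_params(1.5, 5, 2)
  expect_length(detect_ridges(matrix(40, 32, 32), p)$polylines, 0)
  expect_error(ridge_params(1.5, 1, 2), "lower_threshold")
  expect_error(detect_ridges(matrix(1, 32, 32), ridge_params(20, 5, 2)),
               "sigma too large")
})

test_that("a straight line is recovered with sub-pixel accuracy", {
  im <- make_line_image()
  p <- ridge_params(1.5, 5, 2, min_length = 10)
  rs <- detect_ridges(im, p)
  expect_length(rs$polylines, 1)
  len <- ridge_lengths(rs)
  expect_lt(abs(len - 100) / 100, 0.05)
  df <- rs$polylines[[1]]
  expect_lt(sqrt(mean((df$y - 31.3)^2)), 0.2)
  # consecutive points stay within the 2 px linking bound
  expect_lte(max(sqrt(diff(df$y)^2 + diff(df$x)^2)), 2)
})

test_that("detection is invariant to intensity offsets", {
  im <- make_line_image()
  p <- ridge_params(1.5, 5, 2, min_length = 10)
  a <- detect_ridges(im, p)
  b <- detect_ridges(im + 37, p)
  expect_equal(length(a$polylines), length(b$polylines))
  expect_equal(a$polylines[[1]]$y, b$polylines[[1]]$y, tolerance = 1e-6)
  expect_equal(a$polylines[[1]]$strength, b$polylines[[1]]$strength,
               tolerance = 1e-6)
})

test_that("detection is equivariant to 90-degree rotation", {
  sim <- gen_filaments(n_filaments = 4, noise_sd = 0, shape = c(96, 96),
                       seed = 21)
  im <- sim$stack$pixels
  p <- ridge_params(1.8, 4, 1.5, min_length = 10)
  a <- detect_ridges(im, p)
  rot <- t(im)[, rev(seq_len(nrow(im)))]  # 90-degree rotation
  b <- detect_ridges(rot, p)
  pts_a <- do.call(rbind, a$polylines)
  pts_b <- do.call(rbind, b$polylines)
  # invert the rotation (forward map is y' = x, x' = (ny-1) - y)
  back <- data.frame(y = (nrow(im) - 1) - pts_b$x, x = pts_b$y)
  nn <- vapply(seq_len(nrow(pts_a)), function(i)
    min((back$y - pts_a$y[i])^2 + (back$x - pts_a$x[i])^2), numeric(1))
  expect_lt(sqrt(max(nn)), 1e-4)
  expect_equal(sort(pts_a$strength), sort(pts_b$strength), tolerance = 1e-6)
})

test_that("rendering draws exactly the rasterized polyline pixels", {
  p <- ridge_params(1.5, 5, 2)
  empty <- structure(list(polylines = list(), source_shape = c(32, 32),
                          params = p), class = "RidgeSet")
  expect_equal(render_ridges(empty), matrix(0L, 32, 32))

  one <- structure(list(
    polylines = list(data.frame(y = c(15, 15), x = c(10, 19),
                                strength = c(1, 1))),
    source_shape = c(32, 32), params = p), class = "RidgeSet")
  canvas <- render_ridges(one)
  expect_equal(sum(canvas == 255), 10)
  expect_equal(mean(canvas), 255 * 10 / 1024)
  expect_identical(render_ridges(one), canvas)  # deterministic
  expect_error(render_ridges(one, line_width = 0), "line_width")
})

test_that("microtubule density equals 255 x rendered-pixel fraction", {
  p <- ridge_params(1.8, 4, 1.5, min_length = 8)
  blank <- matrix(30, 96, 96)
  expect_equal(mt_density(blank, p, rolling_ball_radius = 20)$density, 0)

  sim <- gen_filaments(n_filaments = 8, noise_sd = 100 / 8,
                       shape = c(128, 128), seed = 31)
  res <- mt_density(sim$stack$pixels, p, rolling_ball_radius = 30)
  frac <- sum(res$canvas == 255) / length(res$canvas)  # counting oracle
  expect_identical(res$density, 255 * frac)
  expect_true(res$density > 0 && res$density <= 255)
})
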