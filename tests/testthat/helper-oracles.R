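# Independent oracles used across the suite.  Each is deliberately written
# as a different algorithm from the implementation it checks.

# Grayscale opening by a ball structuring element, via shift-and-min /
# shift-and-max over explicit offsets with +-Inf padding (the package's
# C++ routine scans neighbourhoods instead).
oracle_ball_opening <- function(img, radius) {
  r <- floor(radius)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  offs$h <- sqrt(radius^2 - offs$dy^2 - offs$dx^2)
  nr <- nrow(img); nc <- ncol(img)
  shift_pad <- function(m, dy, dx, fill) {
    out <- matrix(fill, nr, nc)
    ys <- max(1, 1 + dy):min(nr, nr + dy)
    xs <- max(1, 1 + dx):min(nc, nc + dx)
    out[ys - dy, xs - dx] <- m[ys, xs]
    out
  }
  ero <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(offs)))
    ero <- pmin(ero, shift_pad(img, offs$dy[k], offs$dx[k], Inf) - offs$h[k])
  dil <- matrix(-Inf, nr, nc)
  for (k in seq_len(nrow(offs)))
    dil <- pmax(dil, shift_pad(ero, offs$dy[k], offs$dx[k], -Inf) + offs$h[k])
  dil
}

# All-pairs Feret diameter and angle (O(n^2); the implementation uses the
# convex hull).
oracle_feret <- function(ys, xs) {
  n <- length(ys)
  best <- -1; bi <- 1; bj <- 2
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d2 <- (ys[j] - ys[i])^2 + (xs[j] - xs[i])^2
    if (d2 > best) { best <- d2; bi <- i; bj <- j }
  }
  ang <- atan2(ys[bj] - ys[bi], xs[bj] - xs[bi]) * 180 / pi
  list(diameter = sqrt(best), angle_deg = ang %% 180)
}

# Exhaustive minimal-total-displacement assignment between two frames of
# spots (for linking checks on small instances).
oracle_assignment <- function(a, b, gate) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(cbind(integer(0), integer(0)))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  k <- min(na, nb)
  best_cost <- Inf; best_pairs <- NULL
  subsets <- utils::combn(na, k, simplify = FALSE)
  for (sa in subsets) for (p in perms(seq_len(nb))) {
    pb <- p[seq_len(k)]
    d <- sqrt((a[sa, 1] - b[pb, 1])^2 + (a[sa, 2] - b[pb, 2])^2)
    ok <- d <= gate
    cost <- sum(d[ok]) + sum(!ok) * 1e6
    if (cost < best_cost) {
      best_cost <- cost
      best_pairs <- cbind(sa[ok], pb[ok])
    }
  }
  best_pairs
}

# Movie of a translated textured frame (for stabilization checks).
make_drifting_movie <- function(drift, n_frames, shape = c(96, 96),
                                seed = 1) {
  withr::with_seed(seed, {
    base <- matrix(stats::runif(prod(shape), 0, 100), shape[1], shape[2])
  })
  base <- cytoquant:::gaussian_smooth(base, 2)
  frames <- lapply(seq_len(n_frames) - 1, function(t)
    cytoquant:::translate_image(base, drift[1] * t, drift[2] * t))
  stack_from_frames(frames, frame_interval = 1)
}

# Render a junction image directly from a label matrix (no noise).
render_junction <- function(labels, peak = 100, blur = 1.5) {
  b <- matrix(0, nrow(labels), ncol(labels))
  dif_r <- labels[, -1] != labels[, -ncol(labels)]
  dif_d <- labels[-1, ] != labels[-nrow(labels), ]
  b[, -1][dif_r] <- 1; b[, -ncol(b)][dif_r] <- 1
  b[-1, ][dif_d] <- 1; b[-nrow(b), ][dif_d] <- 1
  cytoquant:::gaussian_smooth(b * peak, blur)
}

# Draw one Gaussian spot into an image (for spot/particle unit tests).
add_gaussian_spot <- function(img, cy, cx, sigma_y, sigma_x = sigma_y,
                              theta = 0, peak = 100) {
  nr <- nrow(img); nc <- ncol(img)
  yy <- matrix(seq_len(nr), nr, nc) - cy
  xx <- matrix(rep(seq_len(nc), each = nr), nr, nc) - cx
  u <- xx * cos(theta) + yy * sin(theta)
  v <- -xx * sin(theta) + yy * cos(theta)
  img + peak * exp(-(u^2 / (2 * sigma_x^2) + v^2 / (2 * sigma_y^2)))
}
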