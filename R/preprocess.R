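#' Maximum intensity projection along z
#'
#' Collapses the `z` axis of a stack by taking, for every `(y, x)` (and
#' frame/channel) position, the maximum over all z-slices.  Calibration is
#' preserved.
#'
#' @param stack an [image_stack()] with a `z` axis
#' @return an `ImageStack` without the `z` axis
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "ImageStack"))
  if (!has_axis(stack, "z")) stop("stack has no z axis")
  zi <- axis_index(stack, "z")
  keep <- setdiff(seq_along(stack$axes), zi)
  out <- apply(stack$pixels, keep, max)
  if (is.null(dim(out))) out <- array(out, dim = dim(stack$pixels)[keep])
  image_stack(out, axes = stack$axes[keep], pixel_size = stack$pixel_size,
              frame_interval = stack$frame_interval)
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background of a fluorescence image as the grayscale
#' morphological opening by a ball-shaped structuring element (spherical-cap
#' height profile, intensity scaling 1:1 with pixel units) and subtracts it,
#' clipping at zero.  Structures narrower than the ball (filaments, comets)
#' survive; broad intensity gradients are removed.  Adding a constant offset
#' to the input leaves the output unchanged.
#'
#' @param image 2-D numeric matrix, or an `ImageStack` with only `(y, x)`
#'   axes
#' @param radius ball radius in pixels (>= 1)
#' @return same type as `image`: background-subtracted, non-negative
#' @export
rolling_ball_subtract <- function(image, radius) {
  if (!is.numeric(radius) || length(radius) != 1 || radius < 1)
    stop("radius must be a scalar >= 1 pixel")
  if (inherits(image, "ImageStack")) {
    if (!identical(sort(image$axes), c("x", "y")))
      stop("ImageStack input must be a single 2-D image")
    m <- get_plane(image)
    return(with_pixels(image, rolling_ball_subtract(m, radius)))
  }
  stopifnot(is.matrix(image))
  bg <- ball_opening_cpp(image, radius)
  pmax(image - bg, 0)
}

#' Integer-factor bilinear upscaling
#'
#' Enlarges an image by an integer factor using bilinear interpolation
#' (output pixel centres mapped back into the input grid).  When applied to
#' an `ImageStack` the pixel size is divided by the factor so physical
#' calibration is preserved.
#'
#' @param image 2-D matrix or 2-D `ImageStack`
#' @param factor positive integer magnification (the comet pipeline default
#'   is 3)
#' @return upscaled image of the same type
#' @export
upscale <- function(image, factor = 3) {
  if (length(factor) != 1 || factor < 1 || factor != round(factor))
    stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (inherits(image, "ImageStack")) {
    if (!identical(sort(image$axes), c("x", "y")))
      stop("ImageStack input must be a single 2-D image")
    m <- get_plane(image)
    return(with_pixels(image, upscale(m, factor),
                       pixel_size = image$pixel_size / factor))
  }
  stopifnot(is.matrix(image))
  if (factor == 1L) return(image)
  nr <- nrow(image) * factor; nc <- ncol(image) * factor
  # output pixel centre i (1-based) maps to input coordinate
  # (i - 0.5)/factor + 0.5
  yy <- (seq_len(nr) - 0.5) / factor + 0.5
  xx <- (seq_len(nc) - 0.5) / factor + 0.5
  yy <- clamp(yy, 1, nrow(image)); xx <- clamp(xx, 1, ncol(image))
  Y <- matrix(yy, nr, nc); X <- matrix(rep(xx, each = nr), nr, nc)
  matrix(bilinear_sample(image, as.vector(Y), as.vector(X)), nr, nc)
}

# Translation estimate of img relative to ref: Hann-windowed phase
# correlation for the integer shift (the window suppresses the spurious
# edge response of non-periodic frames), then one Lucas-Kanade least-squares
# step on the interior overlap for the sub-pixel residual.
# Returns (dy, dx) such that img ~ ref translated by (dy, dx).
estimate_translation <- function(ref, img) {
  if (stats::sd(ref) == 0 || stats::sd(img) == 0)
    stop("degenerate (constant) frame: translation is undefined")
  nr <- nrow(ref); nc <- ncol(ref)
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  W <- outer(hann(nr), hann(nc))
  F1 <- stats::fft((ref - mean(ref)) * W)
  F2 <- stats::fft((img - mean(img)) * W)
  X <- F2 * Conj(F1)
  corr <- Re(stats::fft(X / (Mod(X) + 1e-12), inverse = TRUE)) / (nr * nc)
  pk <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  d0 <- c(wrap(pk[1], nr), wrap(pk[2], nc))
  # sub-pixel: align back by the integer shift, then solve
  # B ~ A - r . grad(A) for the residual r on the interior
  shifted <- translate_image(img, -d0[1], -d0[2])
  m <- min(8 + max(abs(d0)), floor(min(nr, nc) / 4))
  ys <- (m + 1):(nr - m); xs <- (m + 1):(nc - m)
  A <- ref[ys, xs]; B <- shifted[ys, xs]
  gy <- (ref[ys + 1, xs] - ref[ys - 1, xs]) / 2
  gx <- (ref[ys, xs + 1] - ref[ys, xs - 1]) / 2
  d <- B - A
  M <- matrix(c(sum(gy * gy), sum(gy * gx), sum(gy * gx), sum(gx * gx)), 2)
  sol <- tryCatch(solve(M, c(sum(gy * d), sum(gx * d))),
                  error = function(e) c(0, 0))
  sol <- clamp(sol, -1, 1)
  c(dy = d0[1] - sol[1], dx = d0[2] - sol[2])
}

#' Translational stabilization of a time-lapse movie
#'
#' Registers every frame to the first frame by a pure translation estimated
#' with phase correlation (sub-pixel refinement by parabolic fit of the
#' correlation peak).  The estimated per-frame displacements are returned
#' and their negatives applied by bilinear resampling, with out-of-frame
#' pixels filled with zero.  Rigid camera/stage jitter is removed; the model
#' is translation-only by design.
#'
#' @param movie an `ImageStack` with a `t` axis (>= 2 frames)
#' @return list with elements `movie` (stabilized `ImageStack`) and `shifts`
#'   (data.frame `frame`, `dy`, `dx`: displacement of each frame relative to
#'   frame 1; frame 1 is `(0, 0)`)
#' @export
stabilize <- function(movie) {
  stopifnot(inherits(movie, "ImageStack"))
  if (!has_axis(movie, "t")) stop("movie must have a t axis")
  nt <- axis_size(movie, "t")
  if (nt < 2) stop("stabilization needs at least 2 frames")
  ref <- get_plane(movie, t = 1)
  out <- movie$pixels
  sh <- matrix(0, nt, 2)
  for (t in 2:nt) {
    fr <- get_plane(movie, t = t)
    s <- estimate_translation(ref, fr)
    sh[t, ] <- s
    out[t, , ] <- translate_image(fr, -s[1], -s[2], fill = 0)
  }
  list(
    movie = with_pixels(movie, out),
    shifts = data.frame(frame = seq_len(nt), dy = sh[, 1], dx = sh[, 2])
  )
}

#' Temporal running average of a movie
#'
#' Each output frame is the mean of the input frames in a centred window,
#' truncated at the sequence boundaries (no padding is invented).  Used to
#' average out fast, jiggling movements of intracellular features so that
#' only steady lateral movement remains before kymograph analysis.  The
#' default window in the kymograph pipeline is 50 frames.
#'
#' @param movie `ImageStack` with a `t` axis
#' @param window window length in frames (>= 1); `1` is the identity
#' @return smoothed `ImageStack`, same number of frames
#' @export
running_average <- function(movie, window = 50) {
  stopifnot(inherits(movie, "ImageStack"))
  if (!has_axis(movie, "t")) stop("movie must have a t axis")
  if (length(window) != 1 || window < 1 || window != round(window))
    stop("window must be a positive integer")
  window <- as.integer(window)
  if (window == 1L) return(movie)
  nt <- axis_size(movie, "t")
  lo_off <- floor((window - 1) / 2)
  hi_off <- floor(window / 2)
  px <- movie$pixels
  ti <- axis_index(movie, "t")
  if (ti != 1) stop("internal: t axis expected first")
  d <- dim(px)
  np <- prod(d[-1])
  out <- array(0, dim = d)
  # sliding sum over the centred, truncated window (memory-lean: one
  # accumulator frame, windows advance monotonically)
  idx <- function(t) seq.int(t, by = nt, length.out = np)
  a <- 1L; b <- min(nt, 1L + hi_off)
  S <- numeric(np)
  for (t in seq(a, b)) S <- S + px[idx(t)]
  for (t in seq_len(nt)) {
    na <- max(1L, t - lo_off); nb <- min(nt, t + hi_off)
    while (b < nb) { b <- b + 1L; S <- S + px[idx(b)] }
    while (a < na) { S <- S - px[idx(a)]; a <- a + 1L }
    out[idx(t)] <- S / (nb - na + 1L)
  }
  with_pixels(movie, out)
}
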