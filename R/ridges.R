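#' Parameters for curvilinear ridge detection
#'
#' The detector works on Gaussian-derivative responses at scale `sigma`.
#' Candidate ridge points need a principal second-directional-derivative
#' magnitude (the "strength", in intensity units per px^2) of at least
#' `lower_threshold`; line construction is seeded only at points with
#' strength at least `upper_threshold` and extended by hysteresis while the
#' strength stays above the lower threshold.  Polylines shorter than
#' `min_length` pixels of arc length are discarded.
#'
#' @param sigma Gaussian derivative scale in pixels.  For a line of
#'   full width `w` the plugin-style convention `sigma = w/(2*sqrt(3)) + 0.5`
#'   is provided by [sigma_from_line_width()].
#' @param upper_threshold seeding strength (> 0)
#' @param lower_threshold continuation strength (0 < lower <= upper)
#' @param min_length minimum polyline arc length in px (>= 0)
#' @return a `RidgeParams` list
#' @export
ridge_params <- function(sigma, upper_threshold, lower_threshold,
                         min_length = 0) {
  if (sigma <= 0) stop("sigma must be positive")
  if (lower_threshold <= 0 || lower_threshold > upper_threshold)
    stop("need 0 < lower_threshold <= upper_threshold")
  if (min_length < 0) stop("min_length must be >= 0")
  structure(list(sigma = sigma, upper_threshold = upper_threshold,
                 lower_threshold = lower_threshold, min_length = min_length),
            class = "RidgeParams")
}

#' Derivative scale from expected line width
#' @param width expected line full width in pixels
#' @return sigma in pixels: `width/(2*sqrt(3)) + 0.5`
#' @export
sigma_from_line_width <- function(width) width / (2 * sqrt(3)) + 0.5

#' Strength thresholds from expected line contrast
#'
#' Converts an expected line peak intensity (contrast above local
#' background) into absolute second-derivative strength thresholds.  For a
#' line with Gaussian cross-section of standard deviation `line_sd` and peak
#' `contrast`, the response magnitude after smoothing at scale `sigma` is
#' `contrast * line_sd / (line_sd^2 + sigma^2)^(3/2)`.
#'
#' @param contrast expected peak intensity of the faintest line to seed
#' @param sigma detection scale (px)
#' @param line_sd Gaussian cross-section sd of the line (px)
#' @param seed_fraction fraction of the ideal response required to seed
#' @param hysteresis lower threshold as a fraction of the upper
#' @param min_length passed through to [ridge_params()]
#' @return a `RidgeParams`
#' @export
ridge_params_from_contrast <- function(contrast, sigma, line_sd = sigma / 2,
                                       seed_fraction = 0.5,
                                       hysteresis = 0.33,
                                       min_length = 0) {
  strength <- contrast * line_sd / (line_sd^2 + sigma^2)^(3 / 2)
  up <- seed_fraction * strength
  ridge_params(sigma, up, hysteresis * up, min_length)
}

# Pointwise Steger analysis: Gaussian-derivative responses, Hessian
# eigen-analysis, sub-pixel localization along the ridge normal.
# Returns per-pixel matrices; valid pixels are bright-line ridge points
# whose sub-pixel offset stays within half a pixel of the centre.
steger_pointwise <- function(image, sigma) {
  k <- gauss_kernels(sigma)
  if (k$half_width >= min(dim(image)))
    stop("sigma too large for image: smoothing kernel exceeds image")
  rx <- conv_sep(image, k$g, k$dg)
  ry <- conv_sep(image, k$dg, k$g)
  rxx <- conv_sep(image, k$g, k$ddg)
  ryy <- conv_sep(image, k$ddg, k$g)
  rxy <- conv_sep(image, k$dg, k$dg)
  # eigen-decomposition of [[ryy, rxy], [rxy, rxx]]; lam1 = most negative
  tr <- ryy + rxx
  disc <- sqrt(pmax((ryy - rxx)^2 + 4 * rxy^2, 0))
  lam1 <- (tr - disc) / 2
  # eigenvector (ny, nx) for lam1
  ny <- rxy
  nx <- lam1 - ryy
  alt <- abs(ny) + abs(nx) < 1e-12
  ny[alt] <- ifelse(ryy[alt] <= rxx[alt], 1, 0)
  nx[alt] <- ifelse(ryy[alt] <= rxx[alt], 0, 1)
  nrm <- sqrt(ny^2 + nx^2)
  ny <- ny / nrm; nx <- nx / nrm
  tnum <- -(ry * ny + rx * nx)
  tden <- lam1
  tt <- ifelse(abs(tden) > 1e-12, tnum / tden, Inf)
  strength <- -lam1
  valid <- strength > 0 & abs(tt * ny) <= 0.5 & abs(tt * nx) <= 0.5
  # exclude a 1-px frame where replicated-border derivatives are unreliable
  valid[1, ] <- FALSE; valid[nrow(image), ] <- FALSE
  valid[, 1] <- FALSE; valid[, ncol(image)] <- FALSE
  list(strength = strength, ny = ny, nx = nx, t = tt, valid = valid)
}

#' Detect bright curvilinear ridges with sub-pixel localization
#'
#' Hessian-based line detection: the image is convolved with Gaussian
#' derivative kernels at scale `params$sigma`; pixels whose Hessian has a
#' large negative principal eigenvalue and whose first directional
#' derivative along the corresponding eigenvector vanishes within half a
#' pixel are ridge points.  Points with strength at least the upper
#' threshold seed polylines, which are extended through 8-neighbours while
#' the strength stays above the lower threshold and the orientation remains
#' continuous.  Junctions split lines; only bright lines are detected.
#'
#' @param image 2-D numeric matrix (at least 8 x 8) or 2-D `ImageStack`
#' @param params a [ridge_params()]
#' @return a `RidgeSet`: list with `polylines` (each a data.frame `y`, `x`,
#'   `strength`, 0-based sub-pixel coordinates), `source_shape` and `params`
#' @export
detect_ridges <- function(image, params) {
  if (inherits(image, "ImageStack")) image <- get_plane(image)
  stopifnot(is.matrix(image), inherits(params, "RidgeParams"))
  if (nrow(image) < 8 || ncol(image) < 8) stop("image must be at least 8x8")
  pw <- steger_pointwise(image, params$sigma)
  cand <- pw$valid & pw$strength >= params$lower_threshold
  polylines <- link_ridge_points(cand, pw, params)
  structure(list(polylines = polylines, source_shape = dim(image),
                 params = params), class = "RidgeSet")
}

# Hysteresis linking of candidate ridge pixels into polylines.
# Seeds are processed in order of decreasing strength; each line is grown
# in both tangent directions through candidate 8-neighbours, choosing the
# neighbour that minimizes sub-pixel distance plus orientation change.
link_ridge_points <- function(cand, pw, params) {
  nr <- nrow(cand); nc <- ncol(cand)
  idx <- which(cand)
  polylines <- list()
  if (length(idx) == 0) return(polylines)
  iy <- ((idx - 1) %% nr) + 1L
  ix <- ((idx - 1) %/% nr) + 1L
  # sub-pixel positions (1-based here; converted to 0-based on output)
  py <- iy + pw$t[idx] * pw$ny[idx]
  px <- ix + pw$t[idx] * pw$nx[idx]
  smap <- matrix(NA_integer_, nr, nc)   # pixel -> candidate index
  smap[idx] <- seq_along(idx)
  strength <- pw$strength[idx]
  ny <- pw$ny[idx]; nx <- pw$nx[idx]
  used <- logical(length(idx))
  seeds <- order(strength, decreasing = TRUE)
  seeds <- seeds[strength[seeds] >= params$upper_threshold]
  noff <- cbind(rep(-1:1, times = 3), rep(-1:1, each = 3))
  noff <- noff[!(noff[, 1] == 0 & noff[, 2] == 0), ]

  grow <- function(start, direction) {
    # direction: +1/-1 multiplier on the tangent at the start point
    path <- integer(0)
    cur <- start
    ty <- -nx[cur] * direction; tx <- ny[cur] * direction
    repeat {
      cy <- iy[cur]; cx <- ix[cur]
      best <- NA_integer_; best_cost <- Inf
      for (k in seq_len(nrow(noff))) {
        yy <- cy + noff[k, 1]; xx <- cx + noff[k, 2]
        if (yy < 1 || xx < 1 || yy > nr || xx > nc) next
        j <- smap[yy, xx]
        if (is.na(j) || used[j]) next
        # step must continue in the current tangent direction
        sy <- py[j] - py[cur]; sx <- px[j] - px[cur]
        sl <- sqrt(sy^2 + sx^2)
        if (sl < 1e-9 || sl > 2) next
        dot <- (sy * ty + sx * tx) / sl
        if (dot < 0.3) next
        # orientation continuity of the ridge normal (mod pi)
        ndot <- abs(ny[cur] * ny[j] + nx[cur] * nx[j])
        if (ndot < 0.7) next
        cost <- sl + 2 * (1 - ndot)
        if (cost < best_cost) { best_cost <- cost; best <- j }
      }
      if (is.na(best)) break
      used[best] <<- TRUE
      path <- c(path, best)
      ty2 <- py[best] - py[cur]; tx2 <- px[best] - px[cur]
      sl <- sqrt(ty2^2 + tx2^2)
      ty <- ty2 / sl; tx <- tx2 / sl
      cur <- best
    }
    path
  }

  for (s in seeds) {
    if (used[s]) next
    used[s] <- TRUE
    fwd <- grow(s, +1)
    bwd <- grow(s, -1)
    line <- c(rev(bwd), s, fwd)
    if (length(line) < 2) next
    df <- data.frame(y = py[line] - 1, x = px[line] - 1,
                     strength = strength[line])
    arc <- sum(sqrt(diff(df$y)^2 + diff(df$x)^2))
    if (arc < params$min_length) next
    polylines[[length(polylines) + 1]] <- df
  }
  polylines
}

#' Arc length of each polyline in a RidgeSet
#' @param ridges a `RidgeSet`
#' @return numeric vector of arc lengths (px)
#' @export
ridge_lengths <- function(ridges) {
  vapply(ridges$polylines, function(df)
    sum(sqrt(diff(df$y)^2 + diff(df$x)^2)), numeric(1))
}

#' Render detected ridges as white lines on a black canvas
#'
#' Rasterizes every polyline at value 255 on a zero canvas using Bresenham
#' segments between consecutive (rounded) points, dilated to the requested
#' line width.  Deterministic: identical inputs give bit-identical canvases.
#'
#' @param ridges a `RidgeSet`
#' @param shape canvas dimensions `c(ny, nx)`; defaults to the source shape
#' @param line_width line width in pixels (>= 1); width 1 draws the bare
#'   Bresenham pixels, making mean intensity an unbiased length-per-area
#'   proxy
#' @return integer matrix of 0/255
#' @export
render_ridges <- function(ridges, shape = ridges$source_shape,
                          line_width = 1) {
  stopifnot(inherits(ridges, "RidgeSet"))
  if (line_width < 1) stop("line_width must be >= 1")
  canvas <- matrix(0L, shape[1], shape[2])
  for (df in ridges$polylines) {
    yy <- clamp(round(df$y) + 1L, 1L, shape[1])
    xx <- clamp(round(df$x) + 1L, 1L, shape[2])
    for (i in seq_len(nrow(df) - 1)) {
      seg <- bresenham(yy[i], xx[i], yy[i + 1], xx[i + 1])
      canvas[seg] <- 255L
    }
  }
  if (line_width > 1) {
    brush <- EBImage::makeBrush(2 * floor(line_width / 2) + 1, shape = "disc")
    canvas <- matrix(as.integer(
      EBImage::dilate(canvas > 0, brush)) * 255L, shape[1], shape[2])
  }
  canvas
}

#' Microtubule density score
#'
#' The microtubule density of a (maximum-projected) tubulin image is scored
#' by detecting ridges after rolling-ball background subtraction, rendering
#' them as 1-px white (255) lines on a black canvas, and taking the mean
#' pixel value of that canvas.  The score therefore equals
#' `255 * (rendered ridge pixels / total pixels)`, in arbitrary units in
#' `[0, 255]`, and grows with total filament length per unit area.
#'
#' @param image 2-D matrix or 2-D `ImageStack` (a maximum projection)
#' @param params a [ridge_params()]
#' @param rolling_ball_radius background-subtraction radius in px (default
#'   50); `NULL` skips subtraction
#' @param line_width rendering width (default 1)
#' @return list with `density` (a.u.), `ridges` (the `RidgeSet`) and
#'   `canvas` (the rendered image)
#' @export
mt_density <- function(image, params, rolling_ball_radius = 50,
                       line_width = 1) {
  if (inherits(image, "ImageStack")) image <- get_plane(image)
  if (!is.null(rolling_ball_radius))
    image <- rolling_ball_subtract(image, rolling_ball_radius)
  rs <- detect_ridges(image, params)
  canvas <- render_ridges(rs, line_width = line_width)
  list(density = mean(canvas), ridges = rs, canvas = canvas)
}
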