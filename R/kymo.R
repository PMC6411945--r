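#' Build x- and y-direction kymographs from a movie region
#'
#' A kymograph is a 2-D image whose rows are time (one row per frame) and
#' whose columns are position along a fixed sampled line.  For every
#' `stride`-th row of the region a kymograph with `line_axis = "x"` is
#' produced, and for every `stride`-th column one with `line_axis = "y"`;
#' stationary features appear as vertical streaks and features moving along
#' the sampled axis as tilted streaks whose slope (columns per row) is the
#' speed in px/frame.
#'
#' The caller applies stabilization and running averaging first;
#' [region_motility()] enforces that order.
#'
#' @param movie `ImageStack` with a `t` axis
#' @param region rectangle `c(y0, x0, height, width)` in 0-based pixel
#'   coordinates, inside the frame
#' @param stride sample every `stride`-th line (>= 1; default 1 slices the
#'   whole region)
#' @return list of `Kymograph` objects: `pixels` (frames x extent matrix),
#'   `line_axis` (`"x"` or `"y"`), `line_index` (0-based row/column sampled)
#' @export
build_kymographs <- function(movie, region, stride = 1) {
  stopifnot(inherits(movie, "ImageStack"))
  if (!has_axis(movie, "t")) stop("movie must have a t axis")
  if (stride < 1 || stride != round(stride))
    stop("stride must be a positive integer")
  nt <- axis_size(movie, "t")
  ny <- axis_size(movie, "y"); nx <- axis_size(movie, "x")
  y0 <- region[1]; x0 <- region[2]; h <- region[3]; w <- region[4]
  if (y0 < 0 || x0 < 0 || h < 1 || w < 1 || y0 + h > ny || x0 + w > nx)
    stop("region outside frame bounds")
  frames <- lapply(seq_len(nt), function(t) get_plane(movie, t = t))
  out <- list()
  for (r in seq(1, h, by = stride)) {
    km <- t(vapply(frames, function(f) f[y0 + r, (x0 + 1):(x0 + w)],
                   numeric(w)))
    out[[length(out) + 1]] <- structure(
      list(pixels = km, line_axis = "x", line_index = y0 + r - 1),
      class = "Kymograph")
  }
  for (c in seq(1, w, by = stride)) {
    km <- t(vapply(frames, function(f) f[(y0 + 1):(y0 + h), x0 + c],
                   numeric(h)))
    out[[length(out) + 1]] <- structure(
      list(pixels = km, line_axis = "y", line_index = x0 + c - 1),
      class = "Kymograph")
  }
  out
}

#' Feret diameter and angle of a point set
#'
#' The Feret (maximum caliper) diameter is the largest pairwise distance
#' among the points; the Feret angle is the orientation of that diameter.
#' Angles are measured from the column (position) axis in degrees in
#' `[0, 180)`; in a kymograph the time axis is vertical, so a stationary
#' streak has a Feret angle of 90 degrees.  The convex hull is used to
#' reduce the candidate pairs; ties are broken toward the first maximal
#' pair in row-major point order (deterministic).
#'
#' @param ys,xs point coordinates (rows = time, columns = position for
#'   kymograph traces)
#' @return list with `diameter` and `angle_deg`
#' @export
feret <- function(ys, xs) {
  n <- length(ys)
  stopifnot(n >= 2, length(xs) == n)
  if (n > 3) {
    hull <- grDevices::chull(xs, ys)
    ys <- ys[hull]; xs <- xs[hull]
    n <- length(ys)
  }
  best <- -1; bi <- 1; bj <- 2
  for (i in seq_len(n - 1)) {
    d2 <- (ys[(i + 1):n] - ys[i])^2 + (xs[(i + 1):n] - xs[i])^2
    j <- which.max(d2)
    if (d2[j] > best) { best <- d2[j]; bi <- i; bj <- i + j }
  }
  dy <- ys[bj] - ys[bi]; dx <- xs[bj] - xs[bi]
  ang <- atan2(dy, dx) * 180 / pi
  ang <- ang %% 180
  list(diameter = sqrt(best), angle_deg = ang)
}

#' Trace kymograph streaks and score their deviation from vertical
#'
#' Ridge polylines are detected in the kymograph (reusing
#' [detect_ridges()]); for each polyline the deviation is
#' `|90 - feret_angle|` degrees, clipped to `[0, 90]` — the absolute angle
#' of the streak away from the vertical time axis.  A stationary feature
#' scores 0; a feature moving at `s` px/frame scores `atan(s)` in degrees.
#'
#' @param kymo a `Kymograph`
#' @param params a [ridge_params()] for streak tracing
#' @return numeric vector of deviations in degrees (empty when no streaks
#'   are found)
#' @export
trace_and_score <- function(kymo, params) {
  stopifnot(inherits(kymo, "Kymograph"))
  rs <- tryCatch(detect_ridges(kymo$pixels, params),
                 error = function(e) NULL)
  if (is.null(rs) || length(rs$polylines) == 0) return(numeric(0))
  vapply(rs$polylines, function(df) {
    f <- feret(df$y, df$x)   # y = time rows, x = position columns
    clamp(abs(90 - f$angle_deg), 0, 90)
  }, numeric(1))
}

#' Lateral-motility score of movie regions by kymograph analysis
#'
#' Full pipeline per region: optional translational stabilization, temporal
#' running average (window default 50 frames) to suppress fast zero-mean
#' jitter, kymograph construction in both x and y directions, ridge tracing
#' of the streaks, and Feret-angle deviation scoring pooled over all
#' kymographs of the region.
#'
#' @param movie `ImageStack` with a `t` axis
#' @param regions list of rectangles `c(y0, x0, height, width)` (0-based),
#'   chosen to lie inside epithelial islands
#' @param stabilize_movie remove rigid translation first (default TRUE;
#'   disable when the movie's drift is itself the signal, e.g. for
#'   whole-scene simulations)
#' @param window running-average window in frames (default 50)
#' @param stride kymograph line stride (default 1)
#' @param params [ridge_params()] for streak tracing; `NULL` (default)
#'   chooses per-kymograph thresholds from the observed ridge-strength
#'   distribution (upper = half the 99.5th percentile of candidate
#'   strengths, lower = 0.4 x upper), which adapts to however much the
#'   temporal averaging has attenuated the streaks
#' @param trace_sigma streak scale in px used when `params` is `NULL`; for
#'   strongly drifting movies the streak broadens to roughly
#'   `window * drift * cos(atan(drift))` px across, so trace at a
#'   correspondingly larger scale
#' @param full_window_only drop the leading/trailing frames whose centred
#'   running-average window is truncated (default TRUE); truncated windows
#'   bend streaks toward the vertical near the sequence ends and bias the
#'   Feret angle
#' @param min_time_span_frac a trace must span at least this fraction of
#'   the kymograph's time axis to be scored (default 0.6); transient
#'   features crossing the sampled line produce short or time-localized
#'   ridges whose orientation does not measure the steady drift
#' @param column_downscale integer block size for box-averaging kymograph
#'   columns before tracing (default 1).  Steep streaks (fast drift) are
#'   traced far more accurately at a reduced column scale, where their
#'   slope `s` becomes `s / k`; measured deviations are converted back
#'   exactly via `atan(k * tan(deviation))`.  Choose `k` so the reduced
#'   slope is at most about 0.5.
#' @return data.frame, one row per region: `region_id`, `mean_deviation`
#'   (degrees in `[0, 90]`), `n_traces`; the per-trace deviations are
#'   attached as attribute `"per_trace"` (a list)
#' @export
region_motility <- function(movie, regions, stabilize_movie = TRUE,
                            window = 50, stride = 1, params = NULL,
                            trace_sigma = 2, full_window_only = TRUE,
                            min_time_span_frac = 0.6,
                            column_downscale = 1) {
  stopifnot(inherits(movie, "ImageStack"))
  if (!has_axis(movie, "t")) stop("movie must have a t axis")
  if (stabilize_movie) movie <- stabilize(movie)$movie
  movie <- running_average(movie, window)
  nt <- axis_size(movie, "t")
  keep <- seq_len(nt)
  if (full_window_only && window > 1) {
    keep <- (floor((window - 1) / 2) + 1):(nt - floor(window / 2))
    if (length(keep) < 8)
      stop("too few full-window frames; reduce window or lengthen movie")
  }
  per_region <- list()
  traces <- list()
  for (i in seq_along(regions)) {
    kms <- build_kymographs(movie, regions[[i]], stride = stride)
    devs <- numeric(0)
    for (km in kms) {
      km$pixels <- km$pixels[keep, , drop = FALSE]
      k <- as.integer(column_downscale)
      if (k > 1) {
        ncb <- floor(ncol(km$pixels) / k)
        if (ncb < 8) next
        km$pixels <- vapply(seq_len(ncb), function(j)
          rowMeans(km$pixels[, ((j - 1) * k + 1):(j * k), drop = FALSE]),
          numeric(nrow(km$pixels)))
      }
      nrk <- nrow(km$pixels)
      p <- params
      if (is.null(p)) {
        pw <- tryCatch(steger_pointwise(km$pixels, trace_sigma),
                       error = function(e) NULL)
        if (is.null(pw)) next
        st <- pw$strength[pw$valid]
        if (length(st) < 10) next
        up <- 0.5 * stats::quantile(st, 0.995)
        if (up <= 0) next
        p <- ridge_params(trace_sigma, up, 0.4 * up, min_length = 10)
      }
      rs <- tryCatch(detect_ridges(km$pixels, p), error = function(e) NULL)
      if (is.null(rs)) next
      for (df in rs$polylines) {
        if (diff(range(df$y)) < min_time_span_frac * nrk) next
        f <- feret(df$y, df$x)
        dv <- clamp(abs(90 - f$angle_deg), 0, 90)
        if (k > 1) dv <- atan(k * tan(dv * pi / 180)) * 180 / pi
        devs <- c(devs, dv)
      }
    }
    per_region[[i]] <- data.frame(
      region_id = i,
      mean_deviation = if (length(devs)) mean(devs) else NA_real_,
      n_traces = length(devs))
    traces[[i]] <- devs
  }
  out <- do.call(rbind, per_region)
  attr(out, "per_trace") <- traces
  out
}
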