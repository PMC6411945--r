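# Synthetic-microscopy generators with serialized ground truth.
# Each generator is fully deterministic under its seed (seeds are mandatory
# arguments, never global state) and returns both the calibrated image data
# and a GroundTruth list from which every summary quantity used in recovery
# tests can be re-derived.

new_ground_truth <- function(kind, parameters, truth) {
  structure(list(kind = kind, parameters = parameters, truth = truth),
            class = "GroundTruth")
}

#' Serialize ground truth to JSON
#' @param gt a `GroundTruth`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read serialized ground truth
#' @param path JSON file written by [write_ground_truth()]
#' @return a `GroundTruth`
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  structure(x, class = "GroundTruth")
}

# Minimum distance from pixels (py, px) to a polyline given as (y, x)
# matrices of vertices; all coordinates 1-based pixel centres.
dist_to_polyline <- function(py, px, vy, vx) {
  d2 <- rep(Inf, length(py))
  for (i in seq_len(length(vy) - 1)) {
    ay <- vy[i]; ax <- vx[i]
    by <- vy[i + 1]; bx <- vx[i + 1]
    ey <- by - ay; ex <- bx - ax
    L2 <- ey^2 + ex^2
    if (L2 < 1e-12) next
    tt <- clamp(((py - ay) * ey + (px - ax) * ex) / L2, 0, 1)
    dd <- (py - (ay + tt * ey))^2 + (px - (ax + tt * ex))^2
    d2 <- pmin(d2, dd)
  }
  sqrt(d2)
}

#' Simulate a field of fluorescent filaments
#'
#' Filaments are bounded-curvature random walks rendered with a Gaussian
#' cross-section (sd = `line_width_px / 2`), emulating a maximum projection
#' of a fluorescently labelled microtubule network.  Additive Gaussian noise
#' of standard deviation `noise_sd` is applied on a baseline of
#' `3 * noise_sd` (so that clipping at zero barely distorts the noise);
#' overlapping filaments combine by maximum.  Filament geometries are drawn
#' sequentially, so the first `k` filaments of a seed are identical for any
#' `n_filaments >= k` (matched-seed nesting for monotonicity experiments).
#'
#' @param n_filaments number of filaments (0 gives pure noise)
#' @param length_dist range `c(min, max)` of filament arc length in px
#' @param line_width_px full line width (Gaussian sd is half this)
#' @param peak_intensity peak intensity of a filament
#' @param noise_sd additive Gaussian noise sd (`peak_intensity / SNR`)
#' @param shape image shape `c(ny, nx)`, at least 64 x 64
#' @param seed integer RNG seed (mandatory)
#' @param max_turn_rad maximum heading change per 1-px step
#' @return list with `stack` (an `ImageStack`) and `truth` (a `GroundTruth`
#'   whose `truth` holds `polylines` (0-based vertex data.frames) and
#'   `total_length`)
#' @export
gen_filaments <- function(n_filaments, length_dist = c(40, 100),
                          line_width_px = 3, peak_intensity = 100,
                          noise_sd = 12.5, shape = c(256, 256), seed,
                          max_turn_rad = 0.08) {
  if (missing(seed)) stop("seed is a mandatory argument")
  stopifnot(all(shape >= 64), n_filaments >= 0, line_width_px > 0,
            peak_intensity > 0, noise_sd >= 0)
  sd_cross <- line_width_px / 2
  withr::with_seed(seed, {
    polys <- list()
    if (n_filaments > 0) for (i in seq_len(n_filaments)) {
      L <- stats::runif(1, length_dist[1], length_dist[2])
      n_steps <- max(2L, ceiling(L))
      margin <- 6
      y <- stats::runif(1, 1 + margin, shape[1] - margin)
      x <- stats::runif(1, 1 + margin, shape[2] - margin)
      th <- stats::runif(1, 0, 2 * pi)
      vy <- numeric(n_steps + 1); vx <- numeric(n_steps + 1)
      vy[1] <- y; vx[1] <- x
      for (s in seq_len(n_steps)) {
        th <- th + stats::runif(1, -max_turn_rad, max_turn_rad)
        y <- y + sin(th); x <- x + cos(th)
        y <- clamp(y, 1 + margin / 2, shape[1] - margin / 2)
        x <- clamp(x, 1 + margin / 2, shape[2] - margin / 2)
        vy[s + 1] <- y; vx[s + 1] <- x
      }
      polys[[i]] <- cbind(vy, vx)
    }
    img <- matrix(0, shape[1], shape[2])
    for (p in polys) {
      reach <- 4 * sd_cross + 1
      y0 <- max(1L, floor(min(p[, 1]) - reach))
      y1 <- min(shape[1], ceiling(max(p[, 1]) + reach))
      x0 <- max(1L, floor(min(p[, 2]) - reach))
      x1 <- min(shape[2], ceiling(max(p[, 2]) + reach))
      ys <- y0:y1; xs <- x0:x1
      py <- rep(ys, times = length(xs))
      px <- rep(xs, each = length(ys))
      d <- dist_to_polyline(py, px, p[, 1], p[, 2])
      val <- peak_intensity * exp(-d^2 / (2 * sd_cross^2))
      img[ys, xs] <- pmax(img[ys, xs], matrix(val, length(ys), length(xs)))
    }
    img <- img + 3 * noise_sd +
      matrix(stats::rnorm(prod(shape), 0, noise_sd), shape[1], shape[2])
    img <- pmax(img, 0)
  })
  truth_polys <- lapply(polys, function(p)
    data.frame(y = p[, 1] - 1, x = p[, 2] - 1))
  total_len <- sum(vapply(polys, function(p)
    sum(sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)), numeric(1)))
  list(
    stack = image_stack(img),
    truth = new_ground_truth("filaments",
      parameters = list(n_filaments = n_filaments,
                        length_dist = length_dist,
                        line_width_px = line_width_px,
                        peak_intensity = peak_intensity,
                        noise_sd = noise_sd, shape = shape, seed = seed,
                        max_turn_rad = max_turn_rad),
      truth = list(polylines = truth_polys, total_length = total_len))
  )
}

# Spread-out cell seed points: dart throwing with a minimum-distance
# constraint that is relaxed geometrically if the target count cannot be
# packed, so exactly n seeds are always produced.
poisson_disc_seeds <- function(n, shape, margin = 4) {
  area <- (shape[1] - 2 * margin) * (shape[2] - 2 * margin)
  dmin <- 0.75 * sqrt(area / n)
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(pts) < n) {
    cand <- c(stats::runif(1, 1 + margin, shape[1] - margin),
              stats::runif(1, 1 + margin, shape[2] - margin))
    ok <- nrow(pts) == 0 ||
      min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= dmin^2
    if (ok) pts <- rbind(pts, cand)
    tries <- tries + 1
    if (tries > 200 * n) { dmin <- dmin * 0.8; tries <- 0 }
  }
  pts
}

#' Simulate a two-channel fixed image of cells with plus-end comets
#'
#' Cells are the Voronoi tessellation of spread-out seed points; the
#' junction channel renders the blurred tessellation boundaries (emulating a
#' tight-junction stain such as ZO-1); the comet channel contains
#' anisotropic Gaussian spots (sd along the major axis = `true_ar *
#' sigma_minor_px`) at uniform random orientations, placed inside cells away
#' from boundaries with a pairwise separation guard.  Per-comet true aspect
#' ratios can be dispersed around `true_ar` with `ar_sd` (truncated below at
#' 1) to emulate biological variability.
#'
#' @param n_cells number of cells
#' @param comets_per_cell comets placed in each cell
#' @param true_ar true mean aspect ratio (>= 1)
#' @param sigma_minor_px Gaussian sd across the comet (px); the default of
#'   2 px is what a diffraction-limited comet width (PSF of roughly 0.25 µm
#'   FWHM at 63x/1.4 NA, convolved with a ~0.3 µm comet) comes to at
#'   ~0.1 µm pixels
#' @param snr peak intensity / noise sd
#' @param shape image shape `c(ny, nx)`
#' @param seed integer RNG seed (mandatory)
#' @param ar_sd sd of per-comet true AR around `true_ar` (default 0)
#' @param peak_intensity comet peak intensity
#' @return list with `junction` and `comet` (`ImageStack`s), `labels`
#'   (true tessellation label matrix) and `truth` (a `GroundTruth` whose
#'   `truth$comets` data.frame holds 0-based positions, true AR,
#'   orientation and owning cell)
#' @export
gen_comet_field <- function(n_cells, comets_per_cell = 8, true_ar = 2,
                            sigma_minor_px = 2, snr = 10,
                            shape = c(256, 256), seed, ar_sd = 0,
                            peak_intensity = 100) {
  if (missing(seed)) stop("seed is a mandatory argument")
  stopifnot(true_ar >= 1, n_cells >= 1, sigma_minor_px > 0)
  withr::with_seed(seed, {
    seeds <- poisson_disc_seeds(n_cells, shape)
    # Voronoi labels: running nearest-seed minimum over the pixel grid
    yy <- rep(seq_len(shape[1]), times = shape[2])
    xx <- rep(seq_len(shape[2]), each = shape[1])
    best <- rep(Inf, length(yy)); lab <- integer(length(yy))
    for (i in seq_len(n_cells)) {
      d2 <- (yy - seeds[i, 1])^2 + (xx - seeds[i, 2])^2
      sel <- d2 < best
      best[sel] <- d2[sel]; lab[sel] <- i
    }
    labels <- matrix(lab, shape[1], shape[2])
    # junction channel: tessellation boundaries, blurred
    b <- matrix(0, shape[1], shape[2])
    dif_r <- labels[, -1] != labels[, -ncol(labels)]
    dif_d <- labels[-1, ] != labels[-nrow(labels), ]
    b[, -1][dif_r] <- 1; b[, -ncol(b)][dif_r] <- 1
    b[-1, ][dif_d] <- 1; b[-nrow(b), ][dif_d] <- 1
    junction_peak <- 100
    jun <- gaussian_smooth(b * junction_peak, 1.5)
    jn_sd <- junction_peak / snr
    jun <- pmax(jun + 3 * jn_sd +
      matrix(stats::rnorm(prod(shape), 0, jn_sd), shape[1], shape[2]), 0)

    # distance to the nearest boundary pixel, for interior placement
    dist_b <- EBImage::distmap(EBImage::Image(1 - b))
    dist_b <- matrix(as.numeric(dist_b), shape[1], shape[2])

    sig_major_mean <- true_ar * sigma_minor_px
    margin <- 2.5 * sig_major_mean
    # thresholded masks reach ~2 sd from the centre; keep centres far
    # enough apart that masks cannot merge even major-axis to major-axis
    min_sep <- 2.2 * (sig_major_mean + sigma_minor_px)
    # separation is only ever at stake between comets of the same or
    # adjacent cells, so the check is restricted to cells whose seeds lie
    # within three typical cell radii
    nb_radius <- 3 * sqrt(prod(shape) / n_cells)
    seed_d2 <- outer(seeds[, 1], seeds[, 1], `-`)^2 +
      outer(seeds[, 2], seeds[, 2], `-`)^2
    neighbors <- lapply(seq_len(n_cells), function(i)
      which(seed_d2[i, ] <= nb_radius^2))
    placed_by_cell <- vector("list", n_cells)
    ok_px <- which(dist_b >= margin)
    eligible_by_cell <- split(ok_px, labels[ok_px])
    rows <- list()
    for (cell in seq_len(n_cells)) {
      eligible <- eligible_by_cell[[as.character(cell)]]
      if (is.null(eligible) || length(eligible) == 0) next
      near <- do.call(rbind, placed_by_cell[neighbors[[cell]]])
      got <- 0
      while (got < comets_per_cell) {
        # best-candidate sampling: among k random eligible pixels take the
        # one farthest from every nearby comet; a cell that cannot fit
        # another comet is left short (cells vary in size) rather than
        # failing the whole field
        cand <- eligible[sample.int(length(eligible),
                                    min(60, length(eligible)),
                                    replace = TRUE)]
        cyk <- ((cand - 1) %% shape[1]) + 1
        cxk <- ((cand - 1) %/% shape[1]) + 1
        if (!is.null(near) && nrow(near) > 0) {
          D <- outer(cyk, near[, 1], `-`)^2 + outer(cxk, near[, 2], `-`)^2
          mind <- apply(D, 1, min)
          best <- which.max(mind)
          if (mind[best] < min_sep^2) break
        } else best <- 1
        cy <- cyk[best]; cx <- cxk[best]
        near <- rbind(near, c(cy, cx))
        placed_by_cell[[cell]] <- rbind(placed_by_cell[[cell]], c(cy, cx))
        ar_i <- max(1, stats::rnorm(1, true_ar, ar_sd))
        th <- stats::runif(1, 0, pi)
        rows[[length(rows) + 1]] <- data.frame(
          cell = cell, y = cy - 1, x = cx - 1, ar = ar_i, orientation = th)
        got <- got + 1
      }
    }
    comets <- do.call(rbind, rows)
    if (is.null(comets) || nrow(comets) < 0.5 * n_cells * comets_per_cell)
      stop("comets overlapping beyond packing limit; reduce density")
    img <- matrix(0, shape[1], shape[2])
    for (i in seq_len(nrow(comets))) {
      cy <- comets$y[i] + 1; cx <- comets$x[i] + 1
      sa <- comets$ar[i] * sigma_minor_px; sb <- sigma_minor_px
      th <- comets$orientation[i]
      reach <- ceiling(3.5 * sa)
      ys <- max(1, cy - reach):min(shape[1], cy + reach)
      xs <- max(1, cx - reach):min(shape[2], cx + reach)
      py <- rep(ys, times = length(xs)) - cy
      px <- rep(xs, each = length(ys)) - cx
      u <- px * cos(th) + py * sin(th)    # along major axis
      v <- -px * sin(th) + py * cos(th)   # across
      val <- peak_intensity * exp(-(u^2 / (2 * sa^2) + v^2 / (2 * sb^2)))
      img[ys, xs] <- img[ys, xs] + matrix(val, length(ys), length(xs))
    }
    cm_sd <- peak_intensity / snr
    img <- pmax(img + 3 * cm_sd +
      matrix(stats::rnorm(prod(shape), 0, cm_sd), shape[1], shape[2]), 0)
  })
  list(
    junction = image_stack(jun),
    comet = image_stack(img),
    labels = labels,
    truth = new_ground_truth("comet_field",
      parameters = list(n_cells = n_cells,
                        comets_per_cell = comets_per_cell,
                        true_ar = true_ar, sigma_minor_px = sigma_minor_px,
                        snr = snr, shape = shape, seed = seed,
                        ar_sd = ar_sd, peak_intensity = peak_intensity),
      truth = list(comets = comets,
                   seeds = data.frame(y = seeds[, 1] - 1,
                                      x = seeds[, 2] - 1)))
  )
}

#' Simulate a time-lapse movie of constant-velocity fluorescent spots
#'
#' Spots nucleate at random times and positions, move with constant speed in
#' a uniformly random direction for their lifetime, then disappear —
#' emulating EB1-GFP plus-end comets imaged every 2 seconds.  Spots whose
#' speed would carry them out of frame within two frames are flagged with a
#' warning in the truth record.  `pos_jitter_px` adds zero-mean Gaussian
#' displacement to the rendered (not the true) positions, emulating
#' localization error.
#'
#' @param n_spots number of spots over the whole movie
#' @param speed_um_s true speed in micrometres per second
#' @param pixel_size_um micrometres per pixel
#' @param frame_interval_s seconds per frame (default 2)
#' @param n_frames number of frames (default 45, i.e. 90 s every 2 s)
#' @param lifetime_frames mean spot lifetime in frames
#' @param snr peak / noise sd; `Inf` for noiseless movies
#' @param seed integer RNG seed (mandatory)
#' @param pos_jitter_px localization-error emulation (default 0)
#' @param shape frame shape
#' @param sigma_px rendered spot Gaussian sd
#' @return list with `stack` (`ImageStack`, axes `t, y, x`) and `truth`
#'   (`GroundTruth`; `truth$spots` has nucleation frame, start position
#'   (0-based), direction, speed in px/frame and µm/s, lifetime)
#' @export
gen_comet_movie <- function(n_spots = 60, speed_um_s = 0.1,
                            pixel_size_um = 0.1, frame_interval_s = 2,
                            n_frames = 45, lifetime_frames = 20, snr = 10,
                            seed, pos_jitter_px = 0, shape = c(128, 128),
                            sigma_px = 1.3) {
  if (missing(seed)) stop("seed is a mandatory argument")
  stopifnot(speed_um_s >= 0, pixel_size_um > 0, frame_interval_s > 0)
  speed_px_frame <- speed_um_s * frame_interval_s / pixel_size_um
  margin <- 6
  too_fast <- speed_px_frame * 2 > min(shape) - 2 * margin
  peak <- 100
  withr::with_seed(seed, {
    life <- pmax(4L, stats::rpois(n_spots, lifetime_frames))
    t0 <- sample.int(max(1L, n_frames - 4L), n_spots, replace = TRUE)
    dirs <- stats::runif(n_spots, 0, 2 * pi)
    sy <- stats::runif(n_spots, 1 + margin, shape[1] - margin)
    sx <- stats::runif(n_spots, 1 + margin, shape[2] - margin)
    frames <- vector("list", n_frames)
    for (t in seq_len(n_frames)) frames[[t]] <- matrix(0, shape[1], shape[2])
    for (i in seq_len(n_spots)) {
      for (dt in 0:(life[i] - 1L)) {
        t <- t0[i] + dt
        if (t > n_frames) break
        y <- sy[i] + dt * speed_px_frame * sin(dirs[i])
        x <- sx[i] + dt * speed_px_frame * cos(dirs[i])
        if (y < 3 || x < 3 || y > shape[1] - 2 || x > shape[2] - 2) break
        if (pos_jitter_px > 0) {
          y <- y + stats::rnorm(1, 0, pos_jitter_px)
          x <- x + stats::rnorm(1, 0, pos_jitter_px)
        }
        reach <- ceiling(4 * sigma_px)
        ys <- max(1, round(y) - reach):min(shape[1], round(y) + reach)
        xs <- max(1, round(x) - reach):min(shape[2], round(x) + reach)
        py <- rep(ys, times = length(xs)) - y
        px <- rep(xs, each = length(ys)) - x
        val <- peak * exp(-(py^2 + px^2) / (2 * sigma_px^2))
        frames[[t]][ys, xs] <- frames[[t]][ys, xs] +
          matrix(val, length(ys), length(xs))
      }
    }
    noise_sd <- if (is.finite(snr)) peak / snr else 0
    for (t in seq_len(n_frames)) {
      frames[[t]] <- pmax(frames[[t]] + 3 * noise_sd +
        matrix(stats::rnorm(prod(shape), 0, noise_sd),
               shape[1], shape[2]), 0)
    }
  })
  spots <- data.frame(
    spot = seq_len(n_spots), t0 = t0, y0 = sy - 1, x0 = sx - 1,
    direction = dirs, lifetime = life,
    speed_px_frame = speed_px_frame, speed_um_s = speed_um_s)
  list(
    stack = stack_from_frames(frames, pixel_size = pixel_size_um,
                              frame_interval = frame_interval_s),
    truth = new_ground_truth("comet_movie",
      parameters = list(n_spots = n_spots, speed_um_s = speed_um_s,
                        pixel_size_um = pixel_size_um,
                        frame_interval_s = frame_interval_s,
                        n_frames = n_frames,
                        lifetime_frames = lifetime_frames, snr = snr,
                        seed = seed, pos_jitter_px = pos_jitter_px,
                        shape = shape, sigma_px = sigma_px),
      truth = list(spots = spots, warning_too_fast = too_fast))
  )
}

#' Simulate an epithelial-island movie with slow drift and fast jitter
#'
#' The base scene emulates what a transmitted-light or junction-marker view
#' of an epithelial island looks like: a mesh of slightly wavy bright lines
#' (cell-cell junctions, default spacing `line_spacing`) on a noisy
#' baseline.  The whole scene is translated by a constant per-frame drift
#' plus per-frame zero-mean uniform jitter, sampled bilinearly from a base
#' scene large enough that no content ever re-enters at the borders.  This
#' emulates the slow lateral sliding of cells inside an island (drift)
#' superimposed on fast jiggling (jitter) in a 15-s-interval time-lapse
#' (default 120 frames, i.e. 30 min).
#'
#' Extended line features are what make kymograph streaks persistent: a
#' junction line perpendicular to a sampled kymograph line stays on it for
#' the whole movie while drifting along it, which is exactly the structure
#' the Feret-angle analysis scores.
#'
#' @param drift_px_per_frame drift vector `c(dy, dx)` in px/frame
#' @param jitter_amplitude_px uniform jitter amplitude (px)
#' @param n_frames number of frames (>= 100 recommended for window-50
#'   averaging)
#' @param shape frame shape
#' @param seed integer RNG seed (mandatory)
#' @param frame_interval_s seconds per frame (default 15)
#' @param line_spacing junction-mesh spacing in px (default 140); for fast
#'   drifts choose a spacing comfortably larger than
#'   `window * drift` so that motion-smeared streaks do not overlap
#' @param line_sd Gaussian cross-section sd of the junction lines (px)
#' @param peak_intensity junction line peak intensity
#' @param noise_sd additive Gaussian noise sd
#' @return list with `stack` and `truth` (`truth` holds the drift vector,
#'   jitter series and cumulative offsets)
#' @export
gen_drift_movie <- function(drift_px_per_frame = c(0, 0),
                            jitter_amplitude_px = 0, n_frames = 120,
                            shape = c(128, 128), seed,
                            frame_interval_s = 15, line_spacing = 140,
                            line_sd = 3, peak_intensity = 100,
                            noise_sd = 3) {
  if (missing(seed)) stop("seed is a mandatory argument")
  total <- drift_px_per_frame * (n_frames - 1)
  pad <- ceiling(abs(total)) + ceiling(jitter_amplitude_px) + 6
  base_shape <- shape + 2 * pad
  if (any(base_shape > 4000))
    stop("drift so large the analysis region leaves a tractable frame")
  withr::with_seed(seed, {
    base <- matrix(0, base_shape[1], base_shape[2])
    yy_i <- seq_len(base_shape[1]); xx_i <- seq_len(base_shape[2])
    reach <- ceiling(4 * line_sd)
    for (x0 in seq(line_spacing / 2, base_shape[2], by = line_spacing)) {
      amp <- stats::runif(1, 2, 5); ph <- stats::runif(1, 0, 2 * pi)
      per <- stats::runif(1, 150, 300)
      cx <- x0 + amp * sin(2 * pi * yy_i / per + ph)
      for (i in yy_i) {
        lo <- max(1, floor(cx[i] - reach))
        hi <- min(base_shape[2], ceiling(cx[i] + reach))
        if (lo > hi) next
        base[i, lo:hi] <- pmax(base[i, lo:hi],
          peak_intensity * exp(-(lo:hi - cx[i])^2 / (2 * line_sd^2)))
      }
    }
    for (y0 in seq(line_spacing / 2, base_shape[1], by = line_spacing)) {
      amp <- stats::runif(1, 2, 5); ph <- stats::runif(1, 0, 2 * pi)
      per <- stats::runif(1, 150, 300)
      cy <- y0 + amp * sin(2 * pi * xx_i / per + ph)
      for (j in xx_i) {
        lo <- max(1, floor(cy[j] - reach))
        hi <- min(base_shape[1], ceiling(cy[j] + reach))
        if (lo > hi) next
        base[lo:hi, j] <- pmax(base[lo:hi, j],
          peak_intensity * exp(-(lo:hi - cy[j])^2 / (2 * line_sd^2)))
      }
    }
    base <- pmax(base + 3 * noise_sd +
      matrix(stats::rnorm(prod(base_shape), 0, noise_sd),
             base_shape[1], base_shape[2]), 0)
    jit <- matrix(stats::runif(2 * n_frames, -jitter_amplitude_px,
                               jitter_amplitude_px), n_frames, 2)
    jit[1, ] <- 0
    frames <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      off <- drift_px_per_frame * (t - 1) + jit[t, ]
      # content moves by +off: sample base at (grid - off)
      yy <- rep(seq_len(shape[1]), times = shape[2]) + pad[1] - off[1]
      xx <- rep(seq_len(shape[2]), each = shape[1]) + pad[2] - off[2]
      frames[[t]] <- matrix(bilinear_sample(base, yy, xx),
                            shape[1], shape[2])
    }
  })
  cum <- cbind(drift_px_per_frame[1] * (seq_len(n_frames) - 1) + jit[, 1],
               drift_px_per_frame[2] * (seq_len(n_frames) - 1) + jit[, 2])
  list(
    stack = stack_from_frames(frames, pixel_size = 1,
                              frame_interval = frame_interval_s),
    truth = new_ground_truth("drift_movie",
      parameters = list(drift_px_per_frame = drift_px_per_frame,
                        jitter_amplitude_px = jitter_amplitude_px,
                        n_frames = n_frames, shape = shape, seed = seed,
                        frame_interval_s = frame_interval_s,
                        line_spacing = line_spacing, line_sd = line_sd,
                        peak_intensity = peak_intensity,
                        noise_sd = noise_sd),
      truth = list(drift = drift_px_per_frame, jitter = jit,
                   cumulative_offset = cum))
  )
}
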