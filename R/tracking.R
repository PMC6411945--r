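#' Detect fluorescent spots in one frame
#'
#' Laplacian-of-Gaussian blob detection: the frame is convolved with a
#' scale-normalized LoG kernel at scale `sigma`; 8-neighbourhood local
#' maxima of the (negated) response above `min_prominence` are reported with
#' sub-pixel quadratic refinement of the peak position.
#'
#' @param frame_image 2-D matrix
#' @param sigma spot scale in px
#' @param min_prominence minimum negated-LoG response (intensity units)
#' @param border exclusion margin in px (peaks closer to the edge are
#'   dropped)
#' @return data.frame `y`, `x` (0-based sub-pixel), `intensity` (response at
#'   the peak); empty for a blank frame
#' @export
detect_spots <- function(frame_image, sigma = 1.5, min_prominence = 10,
                         border = 3) {
  stopifnot(is.matrix(frame_image), sigma > 0)
  k <- gauss_kernels(sigma)
  # scale-normalized LoG, negated so bright blobs give positive peaks
  resp <- -sigma^2 * (conv_sep(frame_image, k$ddg, k$g) +
                      conv_sep(frame_image, k$g, k$ddg))
  nr <- nrow(resp); nc <- ncol(resp)
  if (nr < 3 || nc < 3) return(data.frame(y = numeric(0), x = numeric(0),
                                          intensity = numeric(0)))
  ctr <- resp[2:(nr - 1), 2:(nc - 1)]
  ismax <- ctr >= min_prominence
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- resp[2:(nr - 1) + dy, 2:(nc - 1) + dx]
    ismax <- ismax & (ctr > nb | (ctr == nb & (dy > 0 | (dy == 0 & dx > 0))))
  }
  pk <- which(ismax, arr.ind = TRUE)
  if (nrow(pk) == 0) return(data.frame(y = numeric(0), x = numeric(0),
                                       intensity = numeric(0)))
  py <- pk[, 1] + 1L; px <- pk[, 2] + 1L
  keep <- py > border & px > border & py <= nr - border & px <= nc - border
  py <- py[keep]; px <- px[keep]
  if (length(py) == 0) return(data.frame(y = numeric(0), x = numeric(0),
                                         intensity = numeric(0)))
  sub1 <- function(a, b, c) {
    den <- a - 2 * b + c
    ifelse(abs(den) < 1e-12, 0, clamp(0.5 * (a - c) / den, -0.5, 0.5))
  }
  dy <- sub1(resp[cbind(py - 1, px)], resp[cbind(py, px)],
             resp[cbind(py + 1, px)])
  dx <- sub1(resp[cbind(py, px - 1)], resp[cbind(py, px)],
             resp[cbind(py, px + 1)])
  data.frame(y = py - 1 + dy, x = px - 1 + dx,
             intensity = resp[cbind(py, px)])
}

#' Link per-frame spots into tracks
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames under
#' a displacement gate: a link is made only when two spots are each other's
#' nearest neighbour across the frame pair and their distance is at most
#' `max_displacement`.  Unlinked spots start or terminate tracks; there is
#' no gap closing, merging or splitting.  Tracks shorter than `min_frames`
#' are discarded.
#'
#' @param spots_by_frame list (one element per frame) of data.frames with
#'   `y`, `x` (and optionally `intensity`)
#' @param max_displacement gate in px (> 0)
#' @param min_frames minimum track length in frames (default 3)
#' @return list of tracks; each a data.frame `frame`, `y`, `x` with strictly
#'   consecutive frames
#' @export
link_tracks <- function(spots_by_frame, max_displacement, min_frames = 3) {
  if (max_displacement <= 0) stop("max_displacement must be positive")
  nt <- length(spots_by_frame)
  open <- list()   # each: data.frame(frame, y, x)
  done <- list()
  for (t in seq_len(nt)) {
    cur <- spots_by_frame[[t]]
    ncur <- if (is.null(cur)) 0 else nrow(cur)
    matched_cur <- rep(FALSE, max(ncur, 0))
    if (length(open) > 0 && ncur > 0) {
      last <- t(vapply(open, function(tr)
        c(tr$y[nrow(tr)], tr$x[nrow(tr)]), numeric(2)))
      D <- outer(last[, 1], cur$y, `-`)^2 + outer(last[, 2], cur$x, `-`)^2
      D <- sqrt(D)
      keep_open <- rep(TRUE, length(open))
      nn_of_open <- apply(D, 1, which.min)
      nn_of_cur <- apply(D, 2, which.min)
      for (i in seq_along(open)) {
        j <- nn_of_open[i]
        if (nn_of_cur[j] == i && D[i, j] <= max_displacement &&
            !matched_cur[j]) {
          open[[i]] <- rbind(open[[i]],
                             data.frame(frame = t, y = cur$y[j],
                                        x = cur$x[j]))
          matched_cur[j] <- TRUE
        } else {
          keep_open[i] <- FALSE
        }
      }
      done <- c(done, open[!keep_open])
      open <- open[keep_open]
    } else if (length(open) > 0) {
      done <- c(done, open)
      open <- list()
    }
    if (ncur > 0) {
      new_idx <- which(!matched_cur)
      for (j in new_idx)
        open[[length(open) + 1]] <- data.frame(frame = t, y = cur$y[j],
                                               x = cur$x[j])
    }
  }
  done <- c(done, open)
  done <- done[vapply(done, nrow, integer(1)) >= min_frames]
  lapply(done, function(tr) { rownames(tr) <- NULL; tr })
}

#' Per-track speed, duration and displacement metrics
#'
#' `duration = (n_spots - 1) * frame_interval`; `path_length` is the sum of
#' Euclidean step lengths in micrometres; `displacement` the net
#' start-to-end distance; `mean_speed = path_length / duration` (the mean
#' frame-to-frame speed).
#'
#' @param track data.frame `frame`, `y`, `x` (positions in px)
#' @param pixel_size micrometres per pixel
#' @param frame_interval seconds per frame
#' @return one-row data.frame `n_spots`, `duration_s`, `path_length_um`,
#'   `displacement_um`, `mean_speed_um_s`
#' @export
track_metrics <- function(track, pixel_size, frame_interval) {
  stopifnot(pixel_size > 0, frame_interval > 0)
  n <- nrow(track)
  if (n < 2) stop("track metrics need at least 2 spots")
  steps <- sqrt(diff(track$y)^2 + diff(track$x)^2) * pixel_size
  path <- sum(steps)
  disp <- sqrt((track$y[n] - track$y[1])^2 +
               (track$x[n] - track$x[1])^2) * pixel_size
  dur <- (n - 1) * frame_interval
  data.frame(n_spots = n, duration_s = dur, path_length_um = path,
             displacement_um = disp, mean_speed_um_s = path / dur)
}

#' Full tracking pipeline for a time-lapse movie
#'
#' Runs [detect_spots()] on every frame, [link_tracks()] and
#' [track_metrics()] using the calibration carried on the stack.
#'
#' @param movie `ImageStack` with a `t` axis
#' @param sigma,min_prominence,border spot-detection parameters
#' @param max_displacement,min_frames linking parameters
#' @return list with `tracks` (list of data.frames) and `metrics`
#'   (data.frame, one row per track)
#' @export
track_movie <- function(movie, sigma = 1.5, min_prominence = 10, border = 3,
                        max_displacement = 6, min_frames = 3) {
  stopifnot(inherits(movie, "ImageStack"))
  if (!has_axis(movie, "t")) stop("movie must have a t axis")
  nt <- axis_size(movie, "t")
  spots <- lapply(seq_len(nt), function(t)
    detect_spots(get_plane(movie, t = t), sigma = sigma,
                 min_prominence = min_prominence, border = border))
  tracks <- link_tracks(spots, max_displacement = max_displacement,
                        min_frames = min_frames)
  metrics <- do.call(rbind, lapply(tracks, track_metrics,
                                   pixel_size = movie$pixel_size,
                                   frame_interval = movie$frame_interval))
  if (is.null(metrics))
    metrics <- data.frame(n_spots = integer(0), duration_s = numeric(0),
                          path_length_um = numeric(0),
                          displacement_um = numeric(0),
                          mean_speed_um_s = numeric(0))
  list(tracks = tracks, metrics = metrics)
}
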