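#' Segment cells from a junction-stain channel
#'
#' Cell regions are recovered from an image in which cell-cell boundaries
#' are bright (e.g. a tight-junction stain).  The junction image is
#' Gaussian-smoothed; pixels below an Otsu threshold form interior basins,
#' connected basins of at least `min_cell_area` become markers, and markers
#' are grown to the boundary ridges by seeded region growing
#' (`EBImage::propagate`, a marker-based watershed).  A near-constant image
#' (no junction signal) yields a single region covering the frame.
#'
#' @param junction_image 2-D matrix or 2-D `ImageStack`
#' @param min_cell_area minimum marker area in px^2
#' @param smooth_sigma smoothing scale before thresholding (px)
#' @return a `CellLabelMap`: list with `labels` (integer matrix, 0 =
#'   boundary/background pixels claimed by no marker — none after growing),
#'   `n_cells`, and `border_labels` (labels touching the image frame)
#' @export
segment_cells <- function(junction_image, min_cell_area = 50,
                          smooth_sigma = 2) {
  if (inherits(junction_image, "ImageStack"))
    junction_image <- get_plane(junction_image)
  stopifnot(is.matrix(junction_image))
  sm <- gaussian_smooth(junction_image, smooth_sigma)
  rng <- max(sm) - min(sm)
  if (rng < 1e-9 * max(1, max(sm))) {
    labels <- matrix(1L, nrow(sm), ncol(sm))
    return(structure(list(labels = labels, n_cells = 1L,
                          border_labels = 1L), class = "CellLabelMap"))
  }
  norm <- (sm - min(sm)) / rng
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  markers <- label_components(norm < thr, connectivity = 4)
  sizes <- tabulate(markers[markers > 0])
  keep <- which(sizes >= min_cell_area)
  if (length(keep) == 0) stop("no markers found: no interior basins of the requested area")
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  seeds <- matrix(0L, nrow(sm), ncol(sm))
  pos <- markers > 0 & remap[pmax(markers, 1)] > 0
  seeds[pos] <- remap[markers[pos]]
  grown <- EBImage::propagate(EBImage::Image(norm), seeds = seeds)
  labels <- matrix(as.integer(grown), nrow(sm), ncol(sm))
  n <- max(labels)
  border <- sort(unique(c(labels[1, ], labels[nrow(labels), ],
                          labels[, 1], labels[, ncol(labels)])))
  border <- border[border > 0]
  structure(list(labels = labels, n_cells = n, border_labels = border),
            class = "CellLabelMap")
}

# Ellipse axes from the central second moments of a pixel set:
# full axes = 4 * sqrt(eigenvalues of the coordinate covariance).
moment_ellipse <- function(ys, xs) {
  n <- length(ys)
  my <- mean(ys); mx <- mean(xs)
  cyy <- sum((ys - my)^2) / n
  cxx <- sum((xs - mx)^2) / n
  cxy <- sum((ys - my) * (xs - mx)) / n
  tr <- cyy + cxx
  disc <- sqrt(max((cyy - cxx)^2 + 4 * cxy^2, 0))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  c(major = 4 * sqrt(max(l1, 0)), minor = 4 * sqrt(max(l2, 0)),
    cy = my, cx = mx)
}

#' Detect comet particles and measure their aspect ratio
#'
#' The comet channel (already upscaled and background-subtracted per the
#' pipeline configuration) is thresholded (Otsu by default), 8-connected
#' components are labelled, components smaller than `min_area` are
#' discarded, and each surviving particle is assigned to the cell containing
#' its centroid (particles whose centroid falls on label 0 are discarded).
#' Ellipse axes come from the central second moments of the member pixels
#' (full axes = 4 x sqrt of the covariance eigenvalues), and the aspect
#' ratio — the proxy for comet length at near-constant comet width — is
#' major/minor.
#'
#' @param comet_image 2-D matrix or 2-D `ImageStack`
#' @param cells a `CellLabelMap` from [segment_cells()] (same shape)
#' @param min_area minimum particle area in px^2 (default 4)
#' @param max_area maximum particle area in px^2 (default `Inf`); an upper
#'   size gate, as in ImageJ's Analyze Particles size range, rejects
#'   merged comet doublets whose ellipse fit reports a spurious elongation
#' @param threshold_method `"otsu"` or `"fixed"`
#' @param threshold_value threshold when `threshold_method = "fixed"`
#' @param exclude_border_cells drop particles in frame-touching cells
#' @return data.frame of particles: `y`, `x` (0-based centroid), `area`,
#'   `major_axis`, `minor_axis`, `aspect_ratio`, `cell_label`
#' @export
detect_comet_particles <- function(comet_image, cells, min_area = 4,
                                   max_area = Inf,
                                   threshold_method = c("otsu", "fixed"),
                                   threshold_value = NULL,
                                   exclude_border_cells = FALSE) {
  if (inherits(comet_image, "ImageStack")) comet_image <- get_plane(comet_image)
  threshold_method <- match.arg(threshold_method)
  stopifnot(is.matrix(comet_image), inherits(cells, "CellLabelMap"))
  if (!all(dim(comet_image) == dim(cells$labels)))
    stop("comet image and cell label map shapes differ")
  mx <- max(comet_image)
  if (mx <= 0) return(empty_particles())
  thr <- switch(threshold_method,
    otsu = EBImage::otsu(EBImage::Image(comet_image / mx),
                         range = c(0, 1)) * mx,
    fixed = {
      if (is.null(threshold_value)) stop("threshold_value required")
      threshold_value
    })
  mask <- comet_image > thr
  if (!any(mask)) return(empty_particles())
  lab <- label_components(mask, connectivity = 8)
  np <- max(lab)
  px_idx <- which(lab > 0)
  comp <- lab[px_idx]
  ys <- ((px_idx - 1) %% nrow(lab)) + 1
  xs <- ((px_idx - 1) %/% nrow(lab)) + 1
  rows <- vector("list", np)
  for (i in seq_len(np)) {
    sel <- comp == i
    if (sum(sel) < min_area || sum(sel) > max_area) next
    me <- moment_ellipse(ys[sel], xs[sel])
    if (me["minor"] <= 0) next
    cy <- me["cy"]; cx <- me["cx"]
    cl <- cells$labels[clamp(round(cy), 1, nrow(lab)),
                       clamp(round(cx), 1, ncol(lab))]
    if (cl == 0) next
    if (exclude_border_cells && cl %in% cells$border_labels) next
    rows[[i]] <- data.frame(
      y = cy - 1, x = cx - 1, area = sum(sel),
      major_axis = unname(me["major"]), minor_axis = unname(me["minor"]),
      aspect_ratio = unname(me["major"] / me["minor"]), cell_label = cl)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) empty_particles() else { rownames(out) <- NULL; out }
}

empty_particles <- function() {
  data.frame(y = numeric(0), x = numeric(0), area = numeric(0),
             major_axis = numeric(0), minor_axis = numeric(0),
             aspect_ratio = numeric(0), cell_label = integer(0))
}

#' Mean comet aspect ratio per cell
#'
#' One record per cell containing at least one comet; the cell mean is the
#' arithmetic mean of its particles' aspect ratios.  Cells with zero comets
#' are omitted (their AR is undefined), matching aggregation with the cell
#' as the experimental unit.
#'
#' @param particles data.frame from [detect_comet_particles()]
#' @param cells the `CellLabelMap` the particles were assigned against
#' @return data.frame `cell_label`, `n_comets`, `mean_ar`
#' @export
per_cell_mean_ar <- function(particles, cells) {
  stopifnot(inherits(cells, "CellLabelMap"))
  if (nrow(particles) == 0)
    return(data.frame(cell_label = integer(0), n_comets = integer(0),
                      mean_ar = numeric(0)))
  if (any(!particles$cell_label %in% seq_len(cells$n_cells)))
    stop("particle cell assignments inconsistent with the label map")
  agg <- stats::aggregate(particles$aspect_ratio,
                          by = list(cell_label = particles$cell_label),
                          FUN = function(v) c(n = length(v), m = mean(v)))
  data.frame(cell_label = agg$cell_label,
             n_comets = as.integer(agg$x[, "n"]),
             mean_ar = agg$x[, "m"])
}

#' Summary of per-cell values for one condition
#'
#' @param cell_values numeric vector of per-cell means (n >= 2)
#' @param label condition name
#' @return data.frame `condition`, `mean`, `sem`, `n` (mean of cell means,
#'   standard error over cells, number of cells)
#' @export
condition_summary <- function(cell_values, label = "condition") {
  s <- summarize(cell_values)
  if (s$n < 2) stop("condition summary needs at least 2 cells for a SEM")
  data.frame(condition = label, mean = s$mean, sem = s$sem, n = s$n,
             stringsAsFactors = FALSE)
}

# Expand a cell label map to an integer-factor finer grid (nearest label).
expand_labels <- function(cells, factor) {
  if (factor == 1) return(cells)
  lab <- cells$labels[rep(seq_len(nrow(cells$labels)), each = factor),
                      rep(seq_len(ncol(cells$labels)), each = factor)]
  structure(list(labels = lab, n_cells = cells$n_cells,
                 border_labels = cells$border_labels),
            class = "CellLabelMap")
}

#' Full comet-morphometry pipeline for one two-channel image
#'
#' Upscales the comet channel (bilinear, integer factor) and applies
#' rolling-ball background subtraction to it; segments cells from the
#' junction channel at the acquisition resolution (segmentation gains
#' nothing from interpolated pixels) and expands the label map to the
#' upscaled grid; detects comet particles and aggregates the per-cell mean
#' aspect ratio.
#'
#' @param junction 2-D `ImageStack` or matrix (junction channel)
#' @param comet 2-D `ImageStack` or matrix (comet channel)
#' @param upscale_factor integer magnification (default 3)
#' @param rolling_ball_radius background radius at the upscaled resolution
#'   (default 15); `NULL` skips
#' @param min_cell_area marker area for segmentation in px^2 at the
#'   acquisition resolution
#' @param min_area particle area filter (at upscaled resolution)
#' @param max_area upper particle size gate (at upscaled resolution);
#'   rejects merged doublets
#' @param threshold_method,threshold_value passed to
#'   [detect_comet_particles()]
#' @param exclude_border_cells drop frame-touching cells
#' @return list with `particles`, `cells` (label map on the upscaled
#'   grid) and `per_cell` (per-cell mean AR)
#' @export
comet_morphometry <- function(junction, comet, upscale_factor = 3,
                              rolling_ball_radius = 15,
                              min_cell_area = 50, min_area = 4,
                              max_area = Inf,
                              threshold_method = "otsu",
                              threshold_value = NULL,
                              exclude_border_cells = FALSE) {
  if (inherits(junction, "ImageStack")) junction <- get_plane(junction)
  if (inherits(comet, "ImageStack")) comet <- get_plane(comet)
  cm <- upscale(comet, upscale_factor)
  if (!is.null(rolling_ball_radius))
    cm <- rolling_ball_subtract(cm, rolling_ball_radius)
  cells_native <- segment_cells(junction, min_cell_area = min_cell_area)
  cells <- expand_labels(cells_native, upscale_factor)
  parts <- detect_comet_particles(cm, cells, min_area = min_area,
                                  max_area = max_area,
                                  threshold_method = threshold_method,
                                  threshold_value = threshold_value,
                                  exclude_border_cells = exclude_border_cells)
  list(particles = parts, cells = cells,
       per_cell = per_cell_mean_ar(parts, cells))
}
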