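#' Calibrated image stack
#'
#' The basic image container used throughout the package: a non-negative
#' intensity array with named axes drawn from `t`, `z`, `channel`, `y`, `x`,
#' plus the spatial calibration (micrometres per pixel) and, for time series,
#' the frame interval in seconds.  All pipelines consume and produce
#' `ImageStack` objects so that calibration is carried along and never has to
#' be re-supplied downstream.
#'
#' Coordinate convention: pixel indices are 0-based in all reported
#' coordinates (centroids, ridge points, spot positions), with pixel centres
#' at integer coordinates, `y` increasing downward and `x` rightward.
#' Internally R's 1-based matrix indexing is used; conversion happens at the
#' reporting boundary.
#'
#' @param pixels numeric array; `length(dim(pixels))` must equal
#'   `length(axes)`.  A plain matrix is interpreted as `(y, x)`.
#' @param axes character vector naming each array dimension; subset of
#'   `c("t", "z", "channel", "y", "x")`.  `y` and `x` are mandatory.
#' @param pixel_size micrometres per pixel (> 0).
#' @param frame_interval seconds per frame (> 0); required when a `t` axis is
#'   present.
#' @return An object of class `ImageStack`: a list with elements `pixels`,
#'   `axes`, `pixel_size`, `frame_interval`.
#' @export
image_stack <- function(pixels, axes = c("y", "x"), pixel_size = 1,
                        frame_interval = NULL) {
  if (is.matrix(pixels) && missing(axes)) axes <- c("y", "x")
  if (is.null(dim(pixels))) stop("'pixels' must be a matrix or array")
  axes <- as.character(axes)
  if (length(dim(pixels)) != length(axes))
    stop("length(axes) must match the number of array dimensions")
  if (!all(axes %in% c("t", "z", "channel", "y", "x")))
    stop("axes must be drawn from {t, z, channel, y, x}")
  if (anyDuplicated(axes)) stop("duplicated axis names")
  if (!all(c("y", "x") %in% axes)) stop("axes 'y' and 'x' are mandatory")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a positive scalar (µm per pixel)")
  if ("t" %in% axes) {
    if (is.null(frame_interval))
      stop("frame_interval (seconds) is required when a 't' axis is present")
    if (!is.numeric(frame_interval) || frame_interval <= 0)
      stop("frame_interval must be a positive scalar (seconds)")
  }
  storage.mode(pixels) <- "double"
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("pixel intensities must be finite")
  if (any(pixels < 0)) stop("pixel intensities must be non-negative")
  structure(
    list(pixels = pixels, axes = axes, pixel_size = pixel_size,
         frame_interval = if ("t" %in% axes) frame_interval else NULL),
    class = "ImageStack"
  )
}

#' @export
print.ImageStack <- function(x, ...) {
  dims <- paste(sprintf("%s=%d", x$axes, dim(x$pixels)), collapse = ", ")
  cat(sprintf("ImageStack [%s]  pixel_size=%g µm", dims, x$pixel_size))
  if (!is.null(x$frame_interval))
    cat(sprintf("  frame_interval=%g s", x$frame_interval))
  cat(sprintf("  range=[%g, %g]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

axis_index <- function(stack, axis) {
  i <- match(axis, stack$axes)
  if (is.na(i)) stop(sprintf("stack has no '%s' axis", axis))
  i
}

has_axis <- function(stack, axis) axis %in% stack$axes

#' Number of frames/slices along an axis
#' @param stack an `ImageStack`
#' @param axis axis name
#' @return integer extent of that axis
#' @export
axis_size <- function(stack, axis) dim(stack$pixels)[axis_index(stack, axis)]

#' Extract one 2-D plane from a stack
#'
#' @param stack an `ImageStack`
#' @param t,z,channel 1-based plane index along the respective axis (each
#'   required exactly when the stack has that axis)
#' @return numeric `(y, x)` matrix
#' @export
get_plane <- function(stack, t = NULL, z = NULL, channel = NULL) {
  idx <- rep(list(quote(expr = )), length(stack$axes))
  pick <- list(t = t, z = z, channel = channel)
  for (ax in names(pick)) {
    if (has_axis(stack, ax)) {
      if (is.null(pick[[ax]]))
        stop(sprintf("plane index '%s' required", ax))
      idx[[axis_index(stack, ax)]] <- pick[[ax]]
    }
  }
  plane <- do.call(`[`, c(list(stack$pixels), idx, list(drop = FALSE)))
  m <- array(plane, dim = dim(stack$pixels)[match(c("y", "x"), stack$axes)])
  m
}

#' Replace the pixel data of a stack, keeping calibration
#'
#' @param stack an `ImageStack`
#' @param pixels replacement array (same number of axes)
#' @param axes optionally a new axis vector (e.g. after projection)
#' @param pixel_size optionally a new pixel size (e.g. after upscaling)
#' @return a new `ImageStack`
#' @export
with_pixels <- function(stack, pixels, axes = stack$axes,
                        pixel_size = stack$pixel_size) {
  image_stack(pixels, axes = axes, pixel_size = pixel_size,
              frame_interval = stack$frame_interval)
}

#' Assemble a time-series stack from a list of frames
#' @param frames list of `(y, x)` matrices of identical shape
#' @param pixel_size micrometres per pixel
#' @param frame_interval seconds per frame
#' @return `ImageStack` with axes `(t, y, x)`
#' @export
stack_from_frames <- function(frames, pixel_size = 1, frame_interval = 1) {
  stopifnot(length(frames) >= 1)
  d <- dim(frames[[1]])
  arr <- array(0, dim = c(length(frames), d))
  for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
  image_stack(arr, axes = c("t", "y", "x"), pixel_size = pixel_size,
              frame_interval = frame_interval)
}
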