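#' Read a TIFF file into a calibrated ImageStack
#'
#' Single- and multi-page TIFFs with 8/16-bit integer or 32-bit float samples
#' are supported.  Plain page series carry no axis metadata, so pages are
#' interpreted as time frames when a `frame_interval` is supplied and as
#' z-slices otherwise.  Pages with a third (sample) dimension yield a
#' `channel` axis.
#'
#' @param path path to a readable TIFF
#' @param pixel_size micrometres per pixel (calibration is user-supplied;
#'   it is carried on the returned object and never re-asked downstream)
#' @param frame_interval seconds per frame; supplying it declares the page
#'   series to be a time axis
#' @return an [image_stack()] with axes inferred from the file layout
#' @export
read_stack <- function(path, pixel_size = 1, frame_interval = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop(sprintf("unparseable TIFF '%s': %s", path,
                                   conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) stop(sprintf("TIFF '%s' contains no pages", path))
  d1 <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d1), logical(1))))
    stop("TIFF pages have inconsistent dimensions")

  nchan <- if (length(d1) == 3) d1[3] else 1L
  npage <- length(pages)
  page_axis <- if (!is.null(frame_interval)) "t" else "z"

  if (npage == 1 && nchan == 1) {
    arr <- as.matrix(pages[[1]]); axes <- c("y", "x")
  } else if (npage == 1) {
    arr <- aperm(pages[[1]], c(3, 1, 2)); axes <- c("channel", "y", "x")
  } else if (nchan == 1) {
    arr <- array(0, dim = c(npage, d1[1], d1[2]))
    for (i in seq_len(npage)) arr[i, , ] <- pages[[i]]
    axes <- c(page_axis, "y", "x")
  } else {
    arr <- array(0, dim = c(npage, nchan, d1[1], d1[2]))
    for (i in seq_len(npage)) arr[i, , , ] <- aperm(pages[[i]], c(3, 1, 2))
    axes <- c(page_axis, "channel", "y", "x")
  }
  image_stack(arr, axes = axes, pixel_size = pixel_size,
              frame_interval = frame_interval)
}

#' Write an ImageStack to a (multi-page) TIFF
#'
#' Integer data are written losslessly at the requested bit depth;
#' `read_stack(write_stack(s))` reproduces the pixels bit-identically for
#' 8- and 16-bit integer content.  Float data are written as 32-bit samples
#' scaled into `[0, 1]` by `2^bits - 1` only if they exceed that range.
#' A `t` or `z` axis becomes the page series; a `channel` axis becomes the
#' per-page sample dimension.
#'
#' @param stack an [image_stack()]
#' @param path output path
#' @param bits bits per sample: 8, 16 (integer) or 32 (float)
#' @return `path`, invisibly
#' @export
write_stack <- function(stack, path, bits = 16) {
  stopifnot(inherits(stack, "ImageStack"))
  if (!bits %in% c(8, 16, 32)) stop("bits must be 8, 16 or 32")
  dirok <- dir.exists(dirname(path))
  if (!dirok) stop(sprintf("unwritable path: %s", path))
  page_axis <- if (has_axis(stack, "t")) "t"
               else if (has_axis(stack, "z")) "z" else NULL
  npage <- if (is.null(page_axis)) 1L else axis_size(stack, page_axis)
  scale <- if (bits == 32) 1 else (2^bits - 1)
  mx <- max(stack$pixels)
  if (bits < 32 && mx > scale)
    stop(sprintf("intensities exceed %d-bit range; rescale first", bits))
  if (bits == 32 && mx > 1) scale <- mx  # floats must lie in [0,1] on disk

  make_page <- function(i) {
    if (has_axis(stack, "channel")) {
      nch <- axis_size(stack, "channel")
      pl <- lapply(seq_len(nch), function(ch) {
        if (is.null(page_axis)) get_plane(stack, channel = ch)
        else if (page_axis == "t") get_plane(stack, t = i, channel = ch)
        else get_plane(stack, z = i, channel = ch)
      })
      arr <- array(0, dim = c(dim(pl[[1]]), nch))
      for (ch in seq_len(nch)) arr[, , ch] <- pl[[ch]]
      arr
    } else {
      if (is.null(page_axis)) get_plane(stack)
      else if (page_axis == "t") get_plane(stack, t = i)
      else get_plane(stack, z = i)
    }
  }
  pages <- lapply(seq_len(npage), function(i) make_page(i) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Read per-island cell-class annotations
#'
#' Islands of cultured epithelial cells are scored manually: each peripheral
#' cell is classed as `"epithelial"` (smooth edge, dense concentric
#' microtubules) or `"mesenchymal"` (spread, lamellipodial, microtubules
#' projecting outward).  This reader only parses and validates those manual
#' calls; classification itself is not computational.
#'
#' Accepted formats: CSV with header `island_id,cell_id,class` (and
#' optionally `segment_length_um` for perimeter segments), or a JSON list of
#' objects with fields `island_id`, `cell_classes` and optionally
#' `perimeter_segments` (each `{length_um, class}`).
#'
#' @param path CSV or JSON file
#' @return list of `IslandAnnotation` objects: `island_id`, `cell_classes`
#'   (character vector), `perimeter_segments` (data.frame with `length_um`,
#'   `class`, or `NULL`)
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  is_json <- grepl("\\.json$", path, ignore.case = TRUE)
  if (is_json) {
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (length(recs) == 0) stop("empty annotation file")
    out <- lapply(seq_along(recs), function(i) {
      r <- recs[[i]]
      if (is.null(r$island_id) || is.null(r$cell_classes))
        stop(sprintf("island record %d: island_id and cell_classes required", i))
      cls <- unlist(r$cell_classes)
      bad <- setdiff(unique(cls), c("epithelial", "mesenchymal"))
      if (length(bad))
        stop(sprintf("island record %d: unknown class label '%s'", i, bad[1]))
      segs <- NULL
      if (!is.null(r$perimeter_segments)) {
        segs <- do.call(rbind, lapply(seq_along(r$perimeter_segments),
          function(j) {
            s <- r$perimeter_segments[[j]]
            if (s$length_um <= 0)
              stop(sprintf("island record %d segment %d: non-positive length",
                           i, j))
            if (!s$class %in% c("epithelial", "mesenchymal"))
              stop(sprintf("island record %d segment %d: unknown class '%s'",
                           i, j, s$class))
            data.frame(length_um = s$length_um, class = s$class,
                       stringsAsFactors = FALSE)
          }))
      }
      island_annotation(as.character(r$island_id), cls, segs)
    })
    return(out)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("empty annotation file")
  need <- c("island_id", "cell_id", "class")
  if (!all(need %in% names(tab)))
    stop(sprintf("annotation CSV must have columns %s",
                 paste(need, collapse = ", ")))
  bad <- which(!tab$class %in% c("epithelial", "mesenchymal"))
  if (length(bad))
    stop(sprintf("row %d: unknown class label '%s'", bad[1],
                 tab$class[bad[1]]))
  has_seg <- "segment_length_um" %in% names(tab)
  ids <- unique(tab$island_id)
  lapply(ids, function(id) {
    rows <- tab[tab$island_id == id, , drop = FALSE]
    segs <- NULL
    if (has_seg && any(is.finite(rows$segment_length_um))) {
      keep <- is.finite(rows$segment_length_um)
      if (any(rows$segment_length_um[keep] <= 0)) {
        off <- which(tab$island_id == id)[which(keep)[
          rows$segment_length_um[keep] <= 0][1]]
        stop(sprintf("row %d: non-positive segment length", off))
      }
      segs <- data.frame(length_um = rows$segment_length_um[keep],
                         class = rows$class[keep], stringsAsFactors = FALSE)
    }
    island_annotation(as.character(id), rows$class, segs)
  })
}

#' Construct an island annotation record
#' @param island_id identifier
#' @param cell_classes character vector of `"epithelial"`/`"mesenchymal"`
#' @param perimeter_segments optional data.frame with `length_um`, `class`
#' @return an `IslandAnnotation`
#' @export
island_annotation <- function(island_id, cell_classes,
                              perimeter_segments = NULL) {
  cell_classes <- as.character(cell_classes)
  if (length(cell_classes) < 1) stop("at least 1 cell per island")
  if (!all(cell_classes %in% c("epithelial", "mesenchymal")))
    stop("cell classes must be 'epithelial' or 'mesenchymal'")
  if (!is.null(perimeter_segments)) {
    stopifnot(all(c("length_um", "class") %in% names(perimeter_segments)))
    if (any(perimeter_segments$length_um <= 0))
      stop("segment lengths must be positive")
  }
  structure(list(island_id = island_id, cell_classes = cell_classes,
                 perimeter_segments = perimeter_segments),
            class = "IslandAnnotation")
}
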