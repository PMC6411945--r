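# Internal image helpers: separable convolution with edge replication,
# bilinear sampling, Bresenham rasterization, connected-component labelling.

pad_replicate <- function(m, top, bottom, left, right) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, top), seq_len(nr), rep(nr, bottom))
  ci <- c(rep(1L, left), seq_len(nc), rep(nc, right))
  m[ri, ci, drop = FALSE]
}

# Separable convolution: kernel ky applied along rows (y), kx along columns
# (x); both odd-length, centre in the middle.  Borders replicated.
conv_sep <- function(img, ky, kx) {
  my <- (length(ky) - 1L) / 2L
  mx <- (length(kx) - 1L) / 2L
  p <- pad_replicate(img, my, my, mx, mx)
  nr <- nrow(img); nc <- ncol(img)
  # along y
  tmp <- matrix(0, nr, ncol(p))
  for (k in seq_along(ky))
    tmp <- tmp + ky[k] * p[(k - 1L) + seq_len(nr), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (k in seq_along(kx))
    out <- out + kx[k] * tmp[, (k - 1L) + seq_len(nc), drop = FALSE]
  out
}

# Sampled Gaussian and its derivatives at scale sigma.  The smoothing kernel
# is normalized to unit sum; derivative kernels are adjusted to zero sum so
# that constant images yield exactly zero response (offset invariance).
gauss_kernels <- function(sigma, half_width = NULL) {
  m <- if (is.null(half_width)) max(1L, ceiling(3.5 * sigma)) else half_width
  x <- seq(-m, m)
  g0 <- exp(-x^2 / (2 * sigma^2))
  g <- g0 / sum(g0)
  g1 <- (-x / sigma^2) * g0
  g1 <- g1 / sum(x * g1)           # unit response to a slope-1 ramp
                                   # (conv_sep correlates, so no kernel flip)
  g2 <- ((x^2 - sigma^2) / sigma^4) * g0
  g2 <- g2 - mean(g2)              # zero response to constants
  g2 <- g2 / (sum(x^2 * g2) / 2)   # unit response to curvature x^2/2 -> 1
  list(g = g, dg = g1, ddg = g2, half_width = m)
}

gaussian_smooth <- function(img, sigma) {
  k <- gauss_kernels(sigma)
  conv_sep(img, k$g, k$g)
}

# Bilinear sample of matrix m at fractional 1-based coordinates (yy, xx);
# out-of-range coordinates return `fill`.
bilinear_sample <- function(m, yy, xx, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  y0 <- floor(yy); x0 <- floor(xx)
  fy <- yy - y0; fx <- xx - x0
  ok <- y0 >= 1 & x0 >= 1 & (y0 + 1) <= nr & (x0 + 1) <= nc
  # clamp exact far edge
  edge <- yy >= 1 & xx >= 1 & yy <= nr & xx <= nc & !ok
  out <- rep(fill, length(yy))
  if (any(ok)) {
    i00 <- cbind(y0[ok], x0[ok]); i01 <- cbind(y0[ok], x0[ok] + 1)
    i10 <- cbind(y0[ok] + 1, x0[ok]); i11 <- cbind(y0[ok] + 1, x0[ok] + 1)
    out[ok] <- m[i00] * (1 - fy[ok]) * (1 - fx[ok]) +
      m[i01] * (1 - fy[ok]) * fx[ok] +
      m[i10] * fy[ok] * (1 - fx[ok]) +
      m[i11] * fy[ok] * fx[ok]
  }
  if (any(edge)) {
    ye <- pmin(pmax(round(yy[edge]), 1), nr)
    xe <- pmin(pmax(round(xx[edge]), 1), nc)
    out[edge] <- m[cbind(ye, xe)]
  }
  out
}

# Translate an image by (dy, dx) pixels (content moves down/right for
# positive shifts); bilinear resampling, fill value outside.
translate_image <- function(img, dy, dx, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  yy <- matrix(seq_len(nr), nr, nc) - dy
  xx <- matrix(rep(seq_len(nc), each = nr), nr, nc) - dx
  matrix(bilinear_sample(img, as.vector(yy), as.vector(xx), fill), nr, nc)
}

# Bresenham line between integer pixel coordinates (1-based), inclusive.
bresenham <- function(y0, x0, y1, x1) {
  dy <- abs(y1 - y0); dx <- abs(x1 - x0)
  sy <- if (y0 < y1) 1L else -1L
  sx <- if (x0 < x1) 1L else -1L
  n <- max(dy, dx) + 1L
  ys <- integer(n); xs <- integer(n)
  err <- dx - dy
  y <- y0; x <- x0
  for (i in seq_len(n)) {
    ys[i] <- y; xs[i] <- x
    if (y == y1 && x == x1) { ys <- ys[1:i]; xs <- xs[1:i]; break }
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx) { err <- err + dx; y <- y + sy }
  }
  cbind(ys, xs)
}

# 8-connected component labelling.  EBImage::bwlabel is 4-connected, so
# labels touching diagonally are merged through a union-find pass.
label_components <- function(mask, connectivity = 8) {
  lab <- EBImage::bwlabel(mask > 0)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (connectivity == 4 || n <= 1) return(lab)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  for (off in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(nr - 1L),
             if (off[2] > 0) seq_len(nc - 1L) else 2:nc, drop = FALSE]
    b <- lab[2:nr,
             if (off[2] > 0) 2:nc else seq_len(nc - 1L), drop = FALSE]
    sel <- which(a > 0 & b > 0 & a != b)
    if (length(sel)) {
      pairs <- unique(cbind(a[sel], b[sel]))
      for (i in seq_len(nrow(pairs))) unite(pairs[i, 1], pairs[i, 2])
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
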