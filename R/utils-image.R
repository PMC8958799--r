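## Internal pixel-level helpers. Images are base R matrices indexed [y, x]
## (row = y, growing downwards; column = x), intensities on the 0-255 scale;
## binary masks are integer matrices of 0/1.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

as_mask <- function(x) {
  m <- matrix(as.integer(x != 0), nrow = nrow(x), ncol = ncol(x))
  m
}

#' @noRd
assert_same_dim <- function(a, b, what = "masks") {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf("%s must have identical dimensions (%s vs %s)",
                  what, paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
}

## Offsets (dy, dx) of a raster disk of radius r (r = width/2 gives a tube of
## the requested width for odd widths).
disk_offsets <- function(radius) {
  r <- max(0, radius)
  k <- floor(r)
  g <- expand.grid(dy = -k:k, dx = -k:k)
  g <- g[g$dy^2 + g$dx^2 <= r^2 + 1e-9, , drop = FALSE]
  as.matrix(g)
}

## Stamp value `val` at integer pixel centres (y, x) expanded by a disk.
## Returns the matrix; out-of-canvas pixels are dropped silently.
stamp_disk <- function(canvas, ys, xs, offsets, val) {
  if (length(ys) == 0) return(canvas)
  H <- nrow(canvas); W <- ncol(canvas)
  yy <- rep(ys, each = nrow(offsets)) + rep(offsets[, "dy"], length(ys))
  xx <- rep(xs, each = nrow(offsets)) + rep(offsets[, "dx"], length(xs))
  keep <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
  idx <- yy[keep] + (xx[keep] - 1L) * H
  canvas[idx] <- val
  canvas
}

## Pixel indices covered by a disk stamp (unique, in-canvas, linear indices).
stamp_indices <- function(dim, ys, xs, offsets) {
  if (length(ys) == 0) return(integer(0))
  H <- dim[1]; W <- dim[2]
  yy <- rep(ys, each = nrow(offsets)) + rep(offsets[, "dy"], length(ys))
  xx <- rep(xs, each = nrow(offsets)) + rep(offsets[, "dx"], length(xs))
  keep <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
  unique(yy[keep] + (xx[keep] - 1L) * H)
}

## Fast box mean with edge-replicate padding; window w odd.
box_mean <- function(x, w) {
  if (w <= 1) return(x)
  k <- (w - 1L) %/% 2L
  H <- nrow(x); W <- ncol(x)
  xp <- x[clamp(seq_len(H + 2 * k) - k, 1, H),
          clamp(seq_len(W + 2 * k) - k, 1, W), drop = FALSE]
  S <- rbind(0, apply(xp, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))     # summed-area table, zero border
  i1 <- seq_len(H); j1 <- seq_len(W)
  out <- S[i1 + w, j1 + w, drop = FALSE] - S[i1, j1 + w, drop = FALSE] -
    S[i1 + w, j1, drop = FALSE] + S[i1, j1, drop = FALSE]
  out / (w * w)
}

## Global Otsu threshold on 0-255 integers; returns the cut intensity.
otsu_cut <- function(x) {
  v <- as.vector(x)
  h <- tabulate(pmin(pmax(as.integer(round(v)), 0L), 255L) + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) - 1L
}

## Binary dilation with a disc brush (small radii), via EBImage.
dilate_mask <- function(mask, radius) {
  if (radius <= 0) return(as_mask(mask))
  brush <- EBImage::makeBrush(2L * as.integer(ceiling(radius)) + 1L, shape = "disc")
  as_mask(EBImage::dilate(as_mask(mask), brush))
}

erode_mask <- function(mask, radius) {
  if (radius <= 0) return(as_mask(mask))
  brush <- EBImage::makeBrush(2L * as.integer(ceiling(radius)) + 1L, shape = "disc")
  as_mask(EBImage::erode(as_mask(mask), brush))
}

gauss_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  as.matrix(EBImage::gblur(img, sigma = sigma))
}
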