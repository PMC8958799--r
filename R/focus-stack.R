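#' Focus stack container
#'
#' An ordered set of equally sized grayscale slices taken at increasing
#' focal depth, `z_step_um` apart (e.g. 70 snaps at a 10-um step give a
#' 690-um depth range).
#'
#' @param slices List of grayscale matrices (uniform dimensions) or a
#'   directory of ordered TIFF files.
#' @param z_step_um Distance between slices in micrometres (> 0).
#' @return A `focus_stack`.
#' @export
focus_stack <- function(slices, z_step_um = 10) {
  if (is.character(slices)) {
    files <- list.files(slices, pattern = "\\.(tif|tiff|png)$", full.names = TRUE)
    files <- files[order(basename(files))]
    if (length(files) == 0) abort("no slices found")
    slices <- lapply(files, read_gray_file)
  }
  stopifnot(length(slices) >= 1, z_step_um > 0)
  d <- dim(slices[[1]])
  for (s in slices) assert_same_dim(s, slices[[1]], "stack slices")
  structure(list(slices = slices, z_step_um = z_step_um, dim = d,
                 n = length(slices)),
            class = "focus_stack")
}

#' @export
print.focus_stack <- function(x, ...) {
  cat(sprintf("<focus_stack> %d slices %dx%d px, z-step %g um (range %g um)\n",
              x$n, x$dim[1], x$dim[2], x$z_step_um, (x$n - 1) * x$z_step_um))
  invisible(x)
}

#' Local sharpness map (variance of the Laplacian)
#'
#' The focus measure: Laplacian response of the image, followed by its local
#' variance in a `window_px` window. Non-negative; zero on constant images;
#' translation-equivariant; decreases everywhere under Gaussian blur of an
#' edge.
#'
#' @param image Grayscale matrix.
#' @param window_px Odd window size >= 3 (default 9).
#' @return Numeric matrix of sharpness scores.
#' @export
focus_measure <- function(image, window_px = 9) {
  stopifnot(window_px >= 3, window_px %% 2 == 1)
  H <- nrow(image); W <- ncol(image)
  img <- matrix(as.numeric(image), H, W)
  ## 4-neighbour Laplacian with edge replication
  up <- img[c(1, seq_len(H - 1)), , drop = FALSE]
  dn <- img[c(seq_len(H - 1) + 1, H), , drop = FALSE]
  lf <- img[, c(1, seq_len(W - 1)), drop = FALSE]
  rt <- img[, c(seq_len(W - 1) + 1, W), drop = FALSE]
  lap <- up + dn + lf + rt - 4 * img
  m <- box_mean(lap, window_px)
  pmax(box_mean(lap^2, window_px) - m^2, 0)
}

#' Depth map from a focus stack
#'
#' Per pixel, the height is `z_step_um` times the (0-based) index of the
#' sharpest slice; a pixel is valid where the winning sharpness exceeds
#' `noise_floor`. A single-slice stack yields all-zero heights, all valid.
#'
#' @param stack A [focus_stack()].
#' @param window_px Sharpness window, see [focus_measure()].
#' @param noise_floor Validity threshold on the winning sharpness; default
#'   `1e-6`, or pass the 95th percentile of a flat-field calibration's
#'   sharpness if available.
#' @param smooth Apply a 3x3 median filter to the argmax index map before
#'   scaling (suppresses dust-trail artifacts).
#' @return A `depth_map`: list with `height_um`, `valid`, `index` (1-based
#'   argmax slice), `z_step_um`.
#' @export
depth_map <- function(stack, window_px = 9, noise_floor = 1e-6, smooth = FALSE) {
  stopifnot(inherits(stack, "focus_stack"))
  H <- stack$dim[1]; W <- stack$dim[2]
  best <- matrix(-Inf, H, W)
  idx <- matrix(1L, H, W)
  for (k in seq_len(stack$n)) {
    fm <- focus_measure(stack$slices[[k]], window_px)
    better <- fm > best
    idx[better] <- k
    best[better] <- fm[better]
  }
  if (smooth && stack$n > 1) {
    idx <- matrix(as.integer(round(as.matrix(
      EBImage::medianFilter(idx / stack$n, size = 1)) * stack$n)), H, W)
    idx <- clamp(idx, 1L, stack$n)
  }
  valid <- best > noise_floor
  if (stack$n == 1) valid[] <- TRUE
  structure(list(height_um = (idx - 1) * stack$z_step_um, valid = valid,
                 index = idx, z_step_um = stack$z_step_um),
            class = "depth_map")
}

#' @export
print.depth_map <- function(x, ...) {
  cat(sprintf("<depth_map> %dx%d px, heights %g..%g um, %.1f%% valid\n",
              nrow(x$height_um), ncol(x$height_um), min(x$height_um),
              max(x$height_um), 100 * mean(x$valid)))
  invisible(x)
}

#' All-in-focus composite
#'
#' Each pixel is taken from its sharpest slice, extending the depth of
#' field across the whole stack.
#'
#' @param stack A [focus_stack()].
#' @param depth A [depth_map()] computed from it.
#' @return Grayscale matrix of the stack's dimensions.
#' @export
composite <- function(stack, depth) {
  stopifnot(inherits(stack, "focus_stack"), inherits(depth, "depth_map"))
  assert_same_dim(stack$slices[[1]], depth$index, "stack and depth map")
  H <- stack$dim[1]; W <- stack$dim[2]
  out <- matrix(0, H, W)
  for (k in seq_len(stack$n)) {
    sel <- depth$index == k
    if (any(sel)) out[sel] <- stack$slices[[k]][sel]
  }
  out
}

#' Triangulated surface from a depth map
#'
#' Regular-grid triangulation over the valid region of interest: each quad
#' of four valid pixels becomes two triangles; vertices are in mm (x, y from
#' the pixel scale, z from the height map). Watertight along the interior of
#' the grid; a full w x h ROI yields `(w-1)*(h-1)*2` triangles.
#'
#' @param depth A [depth_map()].
#' @param roi Binary mask of pixels to mesh (default: the valid mask).
#' @param xy_scale_mm_per_px Lateral pixel pitch in mm.
#' @return A `surface_mesh`: `vertices` (n x 3, mm), `faces` (m x 3, 1-based
#'   vertex indices).
#' @export
surface_mesh <- function(depth, roi = NULL, xy_scale_mm_per_px = 0.001) {
  stopifnot(inherits(depth, "depth_map"))
  roi <- if (is.null(roi)) depth$valid else (as_mask(roi) == 1L) & depth$valid
  if (!any(roi)) abort("empty region of interest")
  H <- nrow(roi); W <- ncol(roi)
  vid <- matrix(0L, H, W)
  sel <- which(roi)
  vid[sel] <- seq_along(sel)
  rows <- (sel - 1) %% H + 1
  cols <- (sel - 1) %/% H + 1
  vertices <- cbind(x = (cols - 1) * xy_scale_mm_per_px,
                    y = (rows - 1) * xy_scale_mm_per_px,
                    z = depth$height_um[sel] / 1000)
  faces <- NULL
  if (H > 1 && W > 1) {
    a <- vid[-H, -W]; b <- vid[-H, -1]; c_ <- vid[-1, -W]; d <- vid[-1, -1]
    ok <- a > 0 & b > 0 & c_ > 0 & d > 0
    faces <- rbind(cbind(a[ok], b[ok], c_[ok]),
                   cbind(b[ok], d[ok], c_[ok]))
  }
  structure(list(vertices = vertices,
                 faces = if (is.null(faces)) matrix(0L, 0, 3) else faces),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Write / read a triangulated surface as binary PLY
#'
#' Minimal binary little-endian PLY: float32 vertex coordinates, uchar-count
#' int32 face indices (0-based on disk, 1-based in R). Write-read round
#' trips are byte-stable.
#'
#' @param mesh A `surface_mesh`.
#' @param path Output `.ply` path.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c(
    "ply", "format binary_little_endian 1.0",
    sprintf("element vertex %d", nrow(mesh$vertices)),
    "property float x", "property float y", "property float z",
    sprintf("element face %d", nrow(mesh$faces)),
    "property list uchar int vertex_indices", "end_header")
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4, endian = "little")
  if (nrow(mesh$faces) > 0) {
    for (i in seq_len(nrow(mesh$faces))) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  nv <- nf <- 0
  read_header_line <- function() {       # byte-wise so the binary body stays put
    out <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1)
      if (length(b) == 0) abort("truncated PLY header")
      if (b == as.raw(10)) return(rawToChar(out))
      out <- c(out, b)
    }
  }
  repeat {
    line <- read_header_line()
    if (grepl("^element vertex", line)) nv <- as.integer(strsplit(line, " ")[[1]][3])
    if (grepl("^element face", line)) nf <- as.integer(strsplit(line, " ")[[1]][3])
    if (line == "end_header") break
  }
  v <- matrix(readBin(con, "numeric", n = 3 * nv, size = 4, endian = "little"),
              ncol = 3, byrow = TRUE, dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    cnt <- as.integer(readBin(con, "raw", n = 1))
    faces[i, ] <- readBin(con, "integer", n = cnt, size = 4, endian = "little") + 1L
  }
  structure(list(vertices = v, faces = faces), class = "surface_mesh")
}
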