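#' Split an image into square patches
#'
#' Tiles the image with `patch_size` x `patch_size` patches after padding the
#' right/bottom edges by reflection so the patches tile the padded image
#' exactly; [stitch_patches()] inverts the operation bit-exactly.
#'
#' @param image Matrix (any numeric type).
#' @param patch_size Patch side in pixels (default 256).
#' @return A list with `grid` (a `patch_grid`: offsets, padded and original
#'   dims, patch size) and `patches` (list of matrices, row-major order).
#' @export
extract_patches <- function(image, patch_size = 256) {
  stopifnot(length(dim(image)) == 2, nrow(image) >= 1, patch_size >= 8)
  H <- nrow(image); W <- ncol(image)
  ph <- ceiling(H / patch_size) * patch_size
  pw <- ceiling(W / patch_size) * patch_size
  ridx <- reflect_index(H, ph)
  cidx <- reflect_index(W, pw)
  padded <- image[ridx, cidx, drop = FALSE]
  ys <- seq(1, ph, by = patch_size)
  xs <- seq(1, pw, by = patch_size)
  offsets <- expand.grid(x = xs, y = ys)[, c("y", "x")]   # row-major
  patches <- lapply(seq_len(nrow(offsets)), function(i) {
    y <- offsets$y[i]; x <- offsets$x[i]
    padded[y:(y + patch_size - 1), x:(x + patch_size - 1), drop = FALSE]
  })
  grid <- structure(list(patch_size = as.integer(patch_size),
                         offsets = as.matrix(offsets),
                         padded_dim = c(ph, pw), dim = c(H, W)),
                    class = "patch_grid")
  list(grid = grid, patches = patches)
}

## Index vector realising edge reflection from length n to length m >= n.
reflect_index <- function(n, m) {
  if (m == n) return(seq_len(n))
  extra <- m - n
  refl <- n - seq_len(extra)            # n-1, n-2, ... (mirror, no repeat)
  refl[refl < 1] <- 1
  c(seq_len(n), refl)
}

#' Reassemble patches into a full-size mask
#'
#' @param grid A `patch_grid` from [extract_patches()].
#' @param patches List of patch matrices, one per grid offset.
#' @return Matrix with the original (unpadded) dimensions.
#' @export
stitch_patches <- function(grid, patches) {
  stopifnot(inherits(grid, "patch_grid"))
  if (length(patches) != nrow(grid$offsets)) {
    abort(sprintf("expected %d patches, got %d", nrow(grid$offsets), length(patches)))
  }
  ps <- grid$patch_size
  out <- matrix(vector(typeof(patches[[1]]), 1), grid$padded_dim[1], grid$padded_dim[2])
  for (i in seq_along(patches)) {
    y <- grid$offsets[i, "y"]; x <- grid$offsets[i, "x"]
    out[y:(y + ps - 1), x:(x + ps - 1)] <- patches[[i]]
  }
  out[seq_len(grid$dim[1]), seq_len(grid$dim[2]), drop = FALSE]
}

#' Pixel segmentation model
#'
#' A pluggable seed/root pixel classifier. Two backends are provided:
#' \describe{
#'   \item{classical}{Otsu threshold on a lightly smoothed image, followed by
#'     a morphological opening and a minimum component-size filter. Needs no
#'     training; serves as an independent reference for the learned backend.}
#'   \item{learned}{A trainable pixel classifier: a single-hidden-layer neural
#'     network (via \pkg{nnet}) over local windowed intensity features
#'     (pixel value, 3x3 and 7x7 box means, local contrast), binarized at
#'     `threshold`. Train with [train_segmentation()].}
#' }
#' Seed-targeted models follow the coarse localisation path: each patch is
#' block-averaged down by `downsample`, classified at low resolution and
#' nearest-neighbour upsampled back, since only seed positions are needed.
#'
#' @param target `"seed"` or `"root"`.
#' @param backend `"classical"` or `"learned"`.
#' @param threshold Probability cut for binarisation (learned backend).
#' @param patch_size Patch side used when tiling large images.
#' @param downsample Block-averaging factor for the seed path (default 8 for
#'   seed targets, 1 for root targets).
#' @param smooth_sigma,opening_radius,min_size Classical backend parameters.
#' @param fit Fitted nnet object (filled by [train_segmentation()]).
#' @return A `segmentation_model`.
#' @export
segmentation_model <- function(target = c("seed", "root"),
                               backend = c("classical", "learned"),
                               threshold = 0.5, patch_size = 256,
                               downsample = NULL, smooth_sigma = 0.8,
                               opening_radius = 1, min_size = 5, fit = NULL) {
  target <- match.arg(target)
  backend <- match.arg(backend)
  downsample <- downsample %||% if (target == "seed") 8L else 1L
  structure(list(target = target, backend = backend, threshold = threshold,
                 patch_size = as.integer(patch_size),
                 downsample = as.integer(downsample),
                 smooth_sigma = smooth_sigma, opening_radius = opening_radius,
                 min_size = min_size, fit = fit),
            class = "segmentation_model")
}

#' @export
print.segmentation_model <- function(x, ...) {
  cat(sprintf("<segmentation_model> target=%s backend=%s%s downsample=%d\n",
              x$target, x$backend,
              if (x$backend == "learned" && is.null(x$fit)) " (untrained)" else "",
              x$downsample))
  invisible(x)
}

## Block-average downsample by integer factor (image dims must be multiples).
block_downsample <- function(img, f) {
  if (f <= 1) return(img)
  H <- nrow(img); W <- ncol(img)
  stopifnot(H %% f == 0, W %% f == 0)
  m <- matrix(colMeans(matrix(img, nrow = f)), nrow = H %/% f)
  t(matrix(colMeans(matrix(t(m), nrow = f)), nrow = W %/% f))
}

## Nearest-neighbour upsample by integer factor.
nn_upsample <- function(img, f) {
  if (f <= 1) return(img)
  img[rep(seq_len(nrow(img)), each = f), rep(seq_len(ncol(img)), each = f), drop = FALSE]
}

## Windowed intensity features for the learned pixel classifier.
pixel_features <- function(img) {
  x <- img / 255
  m3 <- box_mean(x, 3)
  m7 <- box_mean(x, 7)
  v3 <- pmax(box_mean(x^2, 3) - m3^2, 0)
  cbind(i = as.vector(x), m3 = as.vector(m3), m7 = as.vector(m7),
        s3 = as.vector(sqrt(v3)))
}

## Classify one full-resolution patch/image with a model (no tiling).
classify_plane <- function(img, model) {
  f <- model$downsample
  work <- if (f > 1) block_downsample(img, f) else img
  mask <- if (model$backend == "classical") {
    classical_mask(work, model)
  } else {
    if (is.null(model$fit)) abort("learned backend is untrained; call train_segmentation() first")
    pr <- predict(model$fit, pixel_features(work))
    matrix(as.integer(pr >= model$threshold), nrow(work), ncol(work))
  }
  if (f > 1) nn_upsample(mask, f) else mask
}

classical_mask <- function(img, model) {
  sm <- gauss_smooth(img, model$smooth_sigma)
  cut <- otsu_cut(sm)
  ## Reject near-unimodal images: foreground must be meaningfully brighter
  ## than the Otsu split, else a blank frame would be split on noise alone.
  fg <- sm > cut
  if (!any(fg) || all(fg) ||
      (mean(sm[fg]) - mean(sm[!fg])) < 4 * max(sd(sm[!fg]), 1e-8)) {
    return(matrix(0L, nrow(img), ncol(img)))
  }
  mask <- as_mask(fg)
  if (model$opening_radius > 0) {
    mask <- dilate_mask(erode_mask(mask, model$opening_radius), model$opening_radius)
  }
  if (model$min_size > 1 && any(mask == 1L)) {
    cc <- .cc_label(mask, 8L)
    if (cc$n > 0) {
      small <- which(cc$area < model$min_size)
      if (length(small)) mask[cc$labels %in% small] <- 0L
    }
  }
  mask
}

#' Segment an image into a binary mask
#'
#' Tiles the image into patches, classifies each patch with the model's
#' backend (seed targets via the downsample/classify/upsample path) and
#' stitches the results back to the original size.
#'
#' @param image Grayscale matrix, 0-255.
#' @param model A [segmentation_model()].
#' @return Integer 0/1 mask with the dimensions of `image`.
#' @export
segment <- function(image, model) {
  stopifnot(inherits(model, "segmentation_model"))
  if (model$backend == "learned" && is.null(model$fit)) {
    abort("learned backend is untrained; call train_segmentation() first")
  }
  if (nrow(image) <= model$patch_size && ncol(image) <= model$patch_size &&
      model$downsample <= 1) {
    return(classify_plane(image, model))
  }
  ep <- extract_patches(image, model$patch_size)
  masks <- lapply(ep$patches, classify_plane, model = model)
  as_mask(stitch_patches(ep$grid, masks))
}

#' Train the learned segmentation backend
#'
#' Samples a balanced set of labelled pixels from the training images,
#' computes windowed intensity features and fits a single-hidden-layer
#' neural-network classifier with foreground weighting (background/foreground
#' pixel ratio, capped at 50). Deterministic for a fixed `rng_seed`.
#'
#' @param images List of grayscale matrices (0-255).
#' @param labels List of binary masks, same dimensions as `images`.
#' @param target `"seed"` or `"root"`.
#' @param epochs Full-batch optimizer iterations.
#' @param hidden Hidden units.
#' @param max_pixels Pixel sample budget across all images.
#' @param rng_seed Seed for sampling and weight initialisation.
#' @param ... Passed to [segmentation_model()] (e.g. `threshold`, `downsample`).
#' @return A trained `segmentation_model` (backend `"learned"`).
#' @export
train_segmentation <- function(images, labels, target = c("seed", "root"),
                               epochs = 10, hidden = 4, max_pixels = 40000,
                               rng_seed = 1, ...) {
  target <- match.arg(target)
  if (length(images) == 0) abort("at least one labelled image is required")
  if (length(images) != length(labels)) abort("images and labels must pair up")
  model <- segmentation_model(target = target, backend = "learned", ...)
  purrr::walk2(images, labels, assert_same_dim, what = "image and label")

  set.seed(rng_seed)
  f <- model$downsample
  per_img <- ceiling(max_pixels / length(images))
  feats <- list(); ys <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]; lab <- as_mask(labels[[i]])
    if (f > 1) {
      img <- block_downsample(img, f)
      lab <- as_mask(block_downsample(lab, f) >= 0.5)
    }
    fx <- pixel_features(img)
    yv <- as.vector(lab)
    fg <- which(yv == 1L); bg <- which(yv == 0L)
    n_fg <- min(length(fg), ceiling(per_img / 2))
    n_bg <- min(length(bg), per_img - n_fg)
    pick <- c(if (n_fg) sample(fg, n_fg), if (n_bg) sample(bg, n_bg))
    feats[[i]] <- fx[pick, , drop = FALSE]
    ys[[i]] <- yv[pick]
  }
  X <- do.call(rbind, feats)
  y <- unlist(ys)
  if (!any(y == 1)) abort("training labels contain no foreground pixels")
  w_fg <- min(sum(y == 0) / max(sum(y == 1), 1), 50)
  w <- ifelse(y == 1, w_fg, 1)
  fit <- nnet::nnet(X, y, size = hidden, weights = w, entropy = TRUE,
                    maxit = epochs, decay = 1e-4, trace = FALSE)
  model$fit <- fit
  model$train_loss <- fit$value
  model
}

#' Save / load a segmentation model with a JSON sidecar
#'
#' The model parameters (backend, target, threshold, patch size, downsample,
#' fitted weights) are serialised to JSON, keeping checkpoints text-only.
#'
#' @param model A `segmentation_model`.
#' @param path JSON file path.
#' @export
write_segmentation_model <- function(model, path) {
  payload <- unclass(model)
  if (!is.null(model$fit)) {
    payload$fit <- list(wts = model$fit$wts, n = model$fit$n)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_segmentation_model
#' @export
read_segmentation_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- NULL
  if (!is.null(p$fit)) {
    n <- as.integer(p$fit$n)
    fit <- nnet::nnet(matrix(runif(n[1] * 4), ncol = n[1]), rep(c(0, 1), 2),
                      size = n[2], maxit = 0, trace = FALSE)
    fit$wts <- as.numeric(p$fit$wts)
    fit$n <- n
  }
  segmentation_model(target = p$target, backend = p$backend,
                     threshold = p$threshold, patch_size = p$patch_size,
                     downsample = p$downsample, smooth_sigma = p$smooth_sigma,
                     opening_radius = p$opening_radius, min_size = p$min_size,
                     fit = fit)
}

#' Pixel-classification scores: precision, sensitivity, F1
#'
#' F1 is the harmonic mean of precision and sensitivity,
#' `2 * p * s / (p + s)`, and 0 when the denominator vanishes.
#'
#' @param pred,truth Binary masks of identical dimensions.
#' @return A one-row tibble with `tp`, `fp`, `fn`, `precision`,
#'   `sensitivity`, `f1`.
#' @export
f1_score <- function(pred, truth) {
  assert_same_dim(pred, truth)
  p <- pred != 0; t <- truth != 0
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + sensitivity > 0) {
    2 * precision * sensitivity / (precision + sensitivity)
  } else 0
  tibble(tp = tp, fp = fp, fn = fn,
         precision = precision, sensitivity = sensitivity, f1 = f1)
}
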