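## Plate series container: an ordered stack of grayscale frames, either held
## in memory (list of integer matrices) or backed by a directory of TIFF/PNG
## files read lazily one frame at a time.

new_plate_series <- function(frames = NULL, dir = NULL, files = NULL,
                             n_frames, dim, hours, scale_px_per_mm,
                             plate_id = NA_character_, genotype = NA_character_) {
  if (is.null(files) && !is.null(dir)) {
    files <- list.files(dir, pattern = "\\.(tif|tiff|png)$", full.names = TRUE)
    files <- files[order(basename(files))]
  }
  structure(list(
    frames = frames, dir = dir, files = files,
    n_frames = as.integer(n_frames), dim = as.integer(dim),
    hours = as.numeric(hours), scale_px_per_mm = scale_px_per_mm,
    plate_id = plate_id, genotype = genotype
  ), class = "plate_series")
}

#' @export
print.plate_series <- function(x, ...) {
  cat(sprintf("<plate_series> %s: %d frames %dx%d px, hours %g..%g, %g px/mm (%s)\n",
              x$plate_id, x$n_frames, x$dim[1], x$dim[2],
              min(x$hours), max(x$hours), x$scale_px_per_mm,
              if (is.null(x$frames)) "directory-backed" else "in-memory"))
  invisible(x)
}

#' @export
length.plate_series <- function(x) x$n_frames

read_gray_file <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  matrix(as.integer(round(img * 255)), nrow = nrow(img), ncol = ncol(img))
}

#' Fetch one frame of a plate series
#'
#' @param series A `plate_series`.
#' @param i Frame index (1-based).
#' @return Integer matrix of 0-255 grey levels.
#' @export
get_frame <- function(series, i) {
  stopifnot(inherits(series, "plate_series"), i >= 1, i <= series$n_frames)
  img <- if (!is.null(series$frames)) {
    series$frames[[i]]
  } else {
    read_gray_file(series$files[[i]])
  }
  if (!identical(dim(img), as.integer(series$dim))) {
    abort(sprintf("frame %d (%s) has dimensions %s, expected %s",
                  i, if (is.null(series$files)) "in-memory" else basename(series$files[[i]]),
                  paste(dim(img), collapse = "x"), paste(series$dim, collapse = "x")))
  }
  img
}

#' Plate configuration
#'
#' Metadata binding a frame directory to an assay: plate identity (standing in
#' for a QR/barcode tag), genotype, expected seed grid, pixel calibration and
#' imaging cadence. Hours are derived from frame order as
#' `start_h + (index - 1) * frame_interval_h`.
#'
#' @param plate_id,genotype Identifying strings.
#' @param rows,cols Expected seed grid.
#' @param scale_px_per_mm Pixels per mm (default the bench calibration
#'   58.4 px/mm).
#' @param frame_interval_h Hours between frames.
#' @param frames_dir Directory containing `frame_%03d.tif` (or PNG) frames.
#' @param start_h Acquisition hour of the first frame.
#' @return A `plate_config` object.
#' @export
plate_config <- function(plate_id, genotype = NA_character_, rows = 8, cols = 8,
                         scale_px_per_mm = 58.4, frame_interval_h = 1,
                         frames_dir = NULL, start_h = 0) {
  stopifnot(scale_px_per_mm > 0, frame_interval_h > 0)
  structure(list(plate_id = plate_id, genotype = genotype,
                 rows = as.integer(rows), cols = as.integer(cols),
                 scale_px_per_mm = scale_px_per_mm,
                 frame_interval_h = frame_interval_h,
                 frames_dir = frames_dir, start_h = start_h),
            class = "plate_config")
}

#' Read / write a plate configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_plate_config()` returns a `plate_config`.
#' @export
read_plate_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(plate_config, y[intersect(names(y), names(formals(plate_config)))])
}

#' @rdname read_plate_config
#' @param config A `plate_config`.
#' @export
write_plate_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Load a time-lapse series from a frame directory
#'
#' Frames are ordered by their sortable file names (`frame_%03d.tif`);
#' acquisition hours follow the config cadence. Frame dimensions are checked
#' against the first frame; a mismatching frame raises an error naming the
#' offending file (on load when `validate = TRUE`, otherwise on access).
#'
#' @param config A [plate_config()] with a valid `frames_dir`.
#' @param validate Read every frame up-front to verify dimensions.
#' @return A `plate_series`.
#' @export
load_series <- function(config, validate = FALSE) {
  stopifnot(inherits(config, "plate_config"))
  dir <- config$frames_dir
  if (is.null(dir) || !dir.exists(dir)) abort("frames_dir does not exist")
  files <- list.files(dir, pattern = "\\.(tif|tiff|png)$", full.names = TRUE)
  if (length(files) == 0) abort(sprintf("no frames found in %s", dir))
  files <- files[order(basename(files))]
  first <- read_gray_file(files[[1]])
  series <- new_plate_series(
    dir = dir, files = files, n_frames = length(files), dim = dim(first),
    hours = config$start_h + (seq_along(files) - 1) * config$frame_interval_h,
    scale_px_per_mm = config$scale_px_per_mm,
    plate_id = config$plate_id, genotype = config$genotype)
  if (validate) for (i in seq_along(files)) invisible(get_frame(series, i))
  series
}

#' Write a plate series to a directory of 8-bit grayscale TIFFs
#'
#' @param series A `plate_series`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_plate_series <- function(series, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(series$n_frames)) {
    tiff::writeTIFF(get_frame(series, i) / 255,
                    file.path(dir, sprintf("frame_%03d.tif", i)),
                    bits.per.sample = 8L)
  }
  invisible(dir)
}

#' Write / read a binary 0-255 mask as PNG
#'
#' @param mask Integer 0/1 matrix.
#' @param path PNG path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(as_mask(mask) * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  as_mask(img >= 0.5)
}

## Schema-versioned CSV: a comment header line, then a regular CSV.
CSV_SCHEMA <- "# schema: rootlapse/v1"

#' Write / read a schema-versioned results CSV
#'
#' All tabular outputs (truth tables, growth summaries, length series,
#' comparison tables) round-trip through these writers.
#'
#' @param df A data frame.
#' @param path CSV path.
#' @export
write_results_csv <- function(df, path) {
  writeLines(CSV_SCHEMA, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# schema:")) {
    abort(sprintf("%s is missing the schema header", path))
  }
  readr::read_csv(path, skip = 1, show_col_types = FALSE, progress = FALSE)
}
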