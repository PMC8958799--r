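#' Run the full plate-analysis pipeline
#'
#' Reproduces the dashboard workflow end to end: segment the first frame for
#' seed pixels, split them into per-seed instances, then for every frame
#' segment root pixels, expand each instance's bounding box through the
#' connected components it touches, measure calibrated skeleton lengths
#' inside each box (with the frame-0 seed body masked out), detect
#' germination, fit per-seed growth rates over the window from germination to
#' the first neighbour overlap (or the series end), and assemble the
#' five-number growth summary and germination index.
#'
#' @param series A `plate_series` (from [load_series()] or
#'   [generate_plate_series()]).
#' @param rows,cols Expected seed grid.
#' @param seed_model,root_model [segmentation_model()]s for the seed and root
#'   targets (default: classical backend; the seed model at full resolution —
#'   pass `downsample = 8` for the coarse localisation path on native-scale
#'   imagery).
#' @param min_len_mm,persist_frames Germination detection parameters, see
#'   [detect_germination()].
#' @param margin_px Box-claiming margin, see [update_tracks()].
#' @param seed_dilate_px Dilation of the frame-0 seed mask used to exclude
#'   the seed body from length measurement.
#' @param root_width_px Assumed root tube width for the hidden-length
#'   calibration; `NULL` (default) estimates it from the measured masks.
#' @param verbose Emit one structured log line per stage.
#' @return A `plate_results` list: `summaries` (per-seed five-number tibble),
#'   `length_series` (long tibble: seed, hour, mm), `germination_index`,
#'   `tracks` (final state), `track_history`, `initial_tracks`, `params`.
#' @export
run_pipeline <- function(series, rows, cols,
                         seed_model = segmentation_model("seed", "classical", downsample = 1),
                         root_model = segmentation_model("root", "classical"),
                         min_len_mm = 0.25, persist_frames = 2, margin_px = 5,
                         seed_dilate_px = 1, root_width_px = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(series, "plate_series"))
  scale <- series$scale_px_per_mm
  say <- function(...) if (verbose) message(sprintf("INFO plate=%s %s", series$plate_id, sprintf(...)))

  frame1 <- get_frame(series, 1)
  seed_mask <- segment(frame1, seed_model)
  seed_cc <- label_components(seed_mask, 8)
  tracks <- detect_seed_instances(seed_mask, rows, cols)
  initial_tracks <- tracks
  say("stage=detect_seeds frames=%d instances=%d", series$n_frames,
      sum(!is.na(tracks$x0)))
  if (all(is.na(tracks$x0))) {
    say("stage=empty_plate")
    return(empty_plate_results(series, tracks))
  }
  seed_excl <- dilate_mask(seed_mask, seed_dilate_px)

  n_seeds <- nrow(tracks)
  lengths_mm <- matrix(NA_real_, n_seeds, series$n_frames)
  areas_px <- matrix(0, n_seeds, series$n_frames)
  history <- vector("list", series$n_frames)

  for (f in seq_len(series$n_frames)) {
    hour <- series$hours[f]
    root_mask <- segment(get_frame(series, f), root_model)
    tracks <- update_tracks(tracks, root_mask, hour, margin_px = margin_px)
    for (i in seq_len(n_seeds)) {
      if (is.na(tracks$x0[i])) next
      sub <- root_pixels_of(tracks[i, ], root_mask)
      excl <- seed_excl[(tracks$y0[i] + 1):tracks$y1[i],
                        (tracks$x0[i] + 1):tracks$x1[i], drop = FALSE]
      sub[excl == 1L] <- 0L
      areas_px[i, f] <- sum(sub)
      lengths_mm[i, f] <- if (any(sub == 1L)) {
        rr <- range(which(rowSums(sub) > 0)); cr <- range(which(colSums(sub) > 0))
        skeleton_length(sub[rr[1]:rr[2], cr[1]:cr[2], drop = FALSE], scale)
      } else 0
    }
    history[[f]] <- dplyr::mutate(tracks[, c("seed_id", "x0", "y0", "x1", "y1", "status")],
                                  frame_h = hour, .before = 1)
  }
  say("stage=track_measure frames=%d overlapped=%d lost=%d", series$n_frames,
      sum(!is.na(tracks$overlap_h)), sum(tracks$status == "lost"))
  if (any(tracks$status == "lost")) {
    say("WARN lost_seeds=%s", paste(tracks$seed_id[tracks$status == "lost"], collapse = ","))
  }

  ## plate-level root width estimate for the hidden-length calibration
  width_px <- root_width_px %||% estimate_root_width(lengths_mm, areas_px, scale)

  summaries <- purrr::map_dfr(seq_len(n_seeds), function(i) {
    ser <- tibble(hours = series$hours, length_mm = lengths_mm[i, ])
    ser <- ser[!is.na(ser$length_mm), ]
    end_h <- if (!is.na(tracks$overlap_h[i])) {
      suppressWarnings(max(series$hours[series$hours < tracks$overlap_h[i]]))
    } else max(series$hours)
    crossing <- if (sum(ser$hours <= end_h) > 0) {
      detect_germination(ser[ser$hours <= end_h, ], min_len_mm, persist_frames)
    } else NA_real_
    fit <- if (!is.na(crossing)) fit_growth_rate(ser, crossing, end_h) else NULL
    germ_h <- if (is.na(crossing)) NA_real_ else {
      hidden <- hidden_length_mm(initial_tracks[i, ], seed_cc, seed_dilate_px,
                                 width_px, scale)
      estimate_onset(fit, hidden, crossing)
    }
    fi <- which(series$hours <= end_h)
    fi <- if (length(fi)) max(fi) else NA_integer_
    tibble(seed_id = tracks$seed_id[i], row = tracks$row[i], col = tracks$col[i],
           germ_h = germ_h, last_h = end_h,
           final_length_mm = if (!is.na(fi)) lengths_mm[i, fi] else NA_real_,
           rate_mm_per_h = if (is.null(fit)) NA_real_ else fit$slope,
           crossing_h = crossing, overlap_h = tracks$overlap_h[i],
           status = tracks$status[i],
           n_fit = if (is.null(fit)) 0L else fit$n)
  })
  gi <- germination_index(summaries)
  say("stage=summarise germination_index=%.2f", gi)

  length_series <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble(seed_id = tracks$seed_id, row = tracks$row, col = tracks$col),
                     as.data.frame(`colnames<-`(lengths_mm, as.character(series$hours)))),
    cols = -c("seed_id", "row", "col"), names_to = "hours",
    values_to = "length_mm", names_transform = as.numeric)

  structure(list(
    summaries = summaries, length_series = length_series,
    germination_index = gi, tracks = tracks, initial_tracks = initial_tracks,
    track_history = dplyr::bind_rows(history),
    params = list(min_len_mm = min_len_mm, persist_frames = persist_frames,
                  margin_px = margin_px, seed_dilate_px = seed_dilate_px,
                  root_width_px = width_px, scale_px_per_mm = scale),
    plate_id = series$plate_id, genotype = series$genotype
  ), class = "plate_results")
}

empty_plate_results <- function(series, tracks) {
  structure(list(
    summaries = tibble(seed_id = character(0), row = integer(0), col = integer(0),
                       germ_h = numeric(0), last_h = numeric(0),
                       final_length_mm = numeric(0), rate_mm_per_h = numeric(0),
                       crossing_h = numeric(0), overlap_h = numeric(0),
                       status = character(0), n_fit = integer(0)),
    length_series = tibble(seed_id = character(0), row = integer(0),
                           col = integer(0), hours = numeric(0), length_mm = numeric(0)),
    germination_index = NA_real_, tracks = tracks, initial_tracks = tracks,
    track_history = NULL, params = list(), plate_id = series$plate_id,
    genotype = series$genotype, empty_plate = TRUE
  ), class = "plate_results")
}

#' @export
print.plate_results <- function(x, ...) {
  cat(sprintf("<plate_results> %s: %d seeds, GI %.1f%%, %d overlapped, %d lost\n",
              x$plate_id, nrow(x$summaries),
              x$germination_index,
              sum(!is.na(x$summaries$overlap_h)),
              sum(x$summaries$status == "lost")))
  invisible(x)
}

## Median root tube width (px) from mask area / skeleton length.
estimate_root_width <- function(lengths_mm, areas_px, scale) {
  sel <- !is.na(lengths_mm) & lengths_mm > 1
  if (!any(sel)) return(3)
  w <- median(areas_px[sel] / (lengths_mm[sel] * scale))
  clamp(round(w), 1, 15)
}

## Hidden root length (mm) between the radicle origin (seed centroid) and the
## start of the measurable skeleton, calibrated by replaying the measurement
## on the seed's own frame-0 component with a synthetic tube of known length
## attached. Uses only observed masks and the package's forward model.
hidden_length_mm <- function(track0, seed_cc, seed_dilate_px, width_px, scale) {
  if (is.na(track0$x0)) return(0)
  lab <- seed_cc$labels[round(track0$cy) + 1L, round(track0$cx) + 1L]
  if (lab == 0) {
    sub <- seed_cc$labels[(track0$y0 + 1):track0$y1, (track0$x0 + 1):track0$x1, drop = FALSE]
    lab <- sub[sub != 0][1]
  }
  if (is.na(lab) || lab == 0) return(0)
  comp <- seed_cc$components[lab, ]
  crop <- seed_cc$labels[(comp$y0 + 1):comp$y1, (comp$x0 + 1):comp$x1, drop = FALSE]
  seed_px <- as_mask(crop == lab)

  tube_mm <- 3
  pad <- ceiling(2 * width_px) + 2L
  H <- nrow(seed_px) + ceiling(tube_mm * scale) + 2L * pad
  W <- ncol(seed_px) + 2L * pad
  canvas <- matrix(0L, H, W)
  canvas[pad + seq_len(nrow(seed_px)), pad + seq_len(ncol(seed_px))] <- seed_px
  cy <- pad + (comp$cy - comp$y0) + 1          # centroid, 1-based canvas rows
  cx <- pad + (comp$cx - comp$x0) + 1
  poly <- cbind(x = c(cx, cx), y = c(cy, cy + tube_mm * scale)) / scale
  tube <- rasterize_root(poly, width_px, scale, c(H, W))
  full <- as_mask(canvas | tube)
  excl <- dilate_mask(canvas, seed_dilate_px)
  full[excl == 1L] <- 0L
  measured <- skeleton_length(full, scale)
  max(tube_mm - measured, 0)
}
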