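#' Configuration for a synthetic plate time-lapse
#'
#' Describes an in-silico germination assay: a `rows` x `cols` grid of seeds
#' sown on dark agar at `spacing_mm` centre spacing, imaged every
#' `frame_interval_h` hours for `n_frames` frames at `scale_px_per_mm`.
#' Each seed independently germinates with probability `germ_prob` after a
#' delay drawn uniformly from `germ_delay_h`, then elongates a root at a
#' per-seed rate drawn uniformly from `rate_mm_per_h`. Defaults mirror a
#' 64-seed Arabidopsis plate imaged hourly for up to five days at
#' 58.4 px/mm, with rates spanning the slow-to-wild-type range
#' 0.03-0.17 mm/h.
#'
#' @param rows,cols Seed grid dimensions.
#' @param spacing_mm Centre-to-centre seed spacing in mm.
#' @param scale_px_per_mm Image calibration, pixels per millimetre.
#' @param frame_interval_h Hours between consecutive frames. The first frame
#'   is exposed one interval after sowing, so frame `f` is at hour
#'   `f * frame_interval_h`, and a root growing from hour 0 has true length
#'   rate x hours at every frame.
#' @param n_frames Number of frames.
#' @param germ_delay_h Length-2 range (hours); per-seed germination delays are
#'   drawn uniformly from it.
#' @param germ_prob Probability that a seed germinates at all.
#' @param rate_mm_per_h Length-2 range; per-seed root elongation rates (mm/h).
#' @param curl Agravitropism parameter, >= 0: standard deviation (radians) of
#'   the Brownian heading perturbation per sqrt(mm) of growth. 0 gives
#'   perfectly vertical (gravitropic) roots; larger values give curled,
#'   wandering roots.
#' @param heading_deg Initial root heading in degrees away from vertical
#'   (positive = towards +x); scalar or one value per seed (row-major).
#'   Non-zero values let tests engineer root collisions at known frames.
#' @param root_width_px Rendered root tube width in pixels.
#' @param seed_axes_mm Ellipse axes (full lengths, mm) of the rendered seed
#'   body, horizontal x vertical. Default 0.45 x 0.30 mm, Arabidopsis-like.
#' @param noise_sd Gaussian pixel-noise standard deviation in grey levels.
#' @param drift_px_per_frame Rigid per-frame translation (pixels) of a seed's
#'   whole object in a random per-seed direction, emulating agar-shrinkage
#'   seed drift.
#' @param margin_mm Blank margin between the outermost seed centres and the
#'   canvas border (also the room left below the lowest row for root growth,
#'   in addition to the maximum possible root extent).
#' @param bg,fg Background and foreground mean intensities (8-bit grey).
#' @param rng_seed Integer seed; identical configurations generate
#'   bit-identical frames and truth.
#' @return A `synthetic_config` object (a validated list).
#' @export
synthetic_config <- function(rows = 8, cols = 8, spacing_mm = 10,
                             scale_px_per_mm = 58.4, frame_interval_h = 1,
                             n_frames = 96, germ_delay_h = c(0, 24),
                             germ_prob = 0.95, rate_mm_per_h = c(0.03, 0.17),
                             curl = 0, heading_deg = 0, root_width_px = 5,
                             seed_axes_mm = c(0.45, 0.30), noise_sd = 8,
                             drift_px_per_frame = 0, margin_mm = 5,
                             bg = 30, fg = 180, rng_seed = 1) {
  stopifnot(rows >= 1, cols >= 1, spacing_mm > 0, scale_px_per_mm > 0,
            frame_interval_h > 0, n_frames >= 1,
            length(germ_delay_h) == 2, all(germ_delay_h >= 0),
            germ_prob >= 0, germ_prob <= 1,
            length(rate_mm_per_h) == 2, all(rate_mm_per_h >= 0),
            curl >= 0, root_width_px >= 1, noise_sd >= 0,
            drift_px_per_frame >= 0, margin_mm > 0)
  germ_delay_h <- sort(as.numeric(germ_delay_h))
  rate_mm_per_h <- sort(as.numeric(rate_mm_per_h))
  n_seeds <- rows * cols
  heading_deg <- rep_len(heading_deg, n_seeds)

  max_root_mm <- rate_mm_per_h[2] * n_frames * frame_interval_h
  width_mm <- spacing_mm * (cols - 1) + 2 * margin_mm
  height_mm <- spacing_mm * (rows - 1) + 2 * margin_mm + max_root_mm
  dim_px <- c(ceiling(height_mm * scale_px_per_mm),
              ceiling(width_mm * scale_px_per_mm))
  if (margin_mm * scale_px_per_mm < 2 * root_width_px) {
    abort("seed grid does not fit the frame with a margin of at least 2 root widths")
  }

  structure(list(
    rows = as.integer(rows), cols = as.integer(cols), spacing_mm = spacing_mm,
    scale_px_per_mm = scale_px_per_mm, frame_interval_h = frame_interval_h,
    n_frames = as.integer(n_frames), germ_delay_h = germ_delay_h,
    germ_prob = germ_prob, rate_mm_per_h = rate_mm_per_h, curl = curl,
    heading_deg = heading_deg, root_width_px = root_width_px,
    seed_axes_mm = seed_axes_mm, noise_sd = noise_sd,
    drift_px_per_frame = drift_px_per_frame, margin_mm = margin_mm,
    bg = bg, fg = fg, rng_seed = as.integer(rng_seed),
    dim_px = as.integer(dim_px)
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> %dx%d seeds, %d frames @ %g h, %g px/mm, canvas %dx%d px\n",
    x$rows, x$cols, x$n_frames, x$frame_interval_h, x$scale_px_per_mm,
    x$dim_px[1], x$dim_px[2]))
  invisible(x)
}

## Seed centre (mm) for grid position (row, col); x right, y down.
seed_centre_mm <- function(config, row, col) {
  c(x = config$margin_mm + (col - 1) * config$spacing_mm,
    y = config$margin_mm + (row - 1) * config$spacing_mm)
}

## Draw per-seed ground-truth geometry. All randomness is consumed in a fixed
## row-major seed order so runs are reproducible for a given rng_seed.
draw_geometry <- function(config) {
  step_mm <- 0.1
  records <- vector("list", config$rows * config$cols)
  k <- 0L
  for (row in seq_len(config$rows)) {
    for (col in seq_len(config$cols)) {
      k <- k + 1L
      centre <- seed_centre_mm(config, row, col)
      germinates <- runif(1) < config$germ_prob
      delay <- runif(1, config$germ_delay_h[1], config$germ_delay_h[2])
      rate <- runif(1, config$rate_mm_per_h[1], config$rate_mm_per_h[2])
      drift_angle <- runif(1, 0, 2 * pi)

      hours <- seq_len(config$n_frames) * config$frame_interval_h
      germ_h <- if (germinates) delay else NA_real_
      len_by_frame <- if (germinates) pmax(0, (hours - delay)) * rate else rep(0, config$n_frames)

      max_len <- max(len_by_frame)
      n_steps <- max(1L, ceiling(max_len / step_mm))
      ## theta[i] is the heading over step i; Brownian perturbation kicks in
      ## after the first step so the radicle always exits the seed on heading
      dtheta <- rnorm(n_steps, 0, config$curl * sqrt(step_mm))
      theta <- config$heading_deg[k] * pi / 180 + c(0, cumsum(dtheta)[-n_steps])

      pts <- matrix(0, nrow = n_steps + 1L, ncol = 2L,
                    dimnames = list(NULL, c("x", "y")))
      pts[1, ] <- centre
      xmin <- config$root_width_px / config$scale_px_per_mm
      xmax <- config$dim_px[2] / config$scale_px_per_mm - xmin
      ymax <- config$dim_px[1] / config$scale_px_per_mm - xmin
      for (i in seq_len(n_steps)) {
        dx <- sin(theta[i]) * step_mm
        dy <- cos(theta[i]) * step_mm
        nx <- pts[i, 1] + dx
        if (nx < xmin || nx > xmax) {         # reflect off lateral walls
          theta[i:n_steps] <- -theta[i:n_steps]
          nx <- pts[i, 1] + sin(theta[i]) * step_mm
        }
        pts[i + 1, ] <- c(nx, min(pts[i, 2] + cos(theta[i]) * step_mm, ymax))
      }
      cum_len <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))

      records[[k]] <- structure(list(
        seed_id = sprintf("%d-%d", row, col), row = row, col = col,
        centre_mm = centre, germ_h = germ_h, rate_mm_per_h = rate,
        polyline_mm = pts, cum_len_mm = cum_len,
        true_length_mm = len_by_frame, hours = hours,
        drift_dir = c(cos(drift_angle), sin(drift_angle)),
        overlapped_from_h = NA_real_, overlap_partner = NA_character_
      ), class = "truth_record")
    }
  }
  records
}

## Truncate a polyline to a given arc length, interpolating the final point.
truncate_polyline <- function(pts, cum_len, at_len) {
  if (at_len <= 0) return(pts[0, , drop = FALSE])
  if (at_len >= cum_len[length(cum_len)]) return(pts)
  i <- findInterval(at_len, cum_len)      # last vertex at or before at_len
  f <- (at_len - cum_len[i]) / (cum_len[i + 1] - cum_len[i])
  rbind(pts[seq_len(i), , drop = FALSE],
        pts[i, ] + f * (pts[i + 1, ] - pts[i, ]))
}

## Integer pixel centres along a polyline (mm), resampled at sub-pixel pitch.
polyline_pixels <- function(pts, scale, pitch_px = 0.35) {
  if (nrow(pts) == 0) return(cbind(y = integer(0), x = integer(0)))
  px <- pts * scale
  if (nrow(px) == 1) {
    return(cbind(y = as.integer(round(px[1, 2])), x = as.integer(round(px[1, 1]))))
  }
  seg <- sqrt(rowSums(diff(px)^2))
  cl <- c(0, cumsum(seg))
  s <- unique(c(seq(0, cl[length(cl)], by = pitch_px), cl[length(cl)]))
  xi <- stats::approx(cl, px[, 1], xout = s, ties = "ordered")$y
  yi <- stats::approx(cl, px[, 2], xout = s, ties = "ordered")$y
  out <- unique(cbind(y = as.integer(round(yi)), x = as.integer(round(xi))))
  out
}

## Pixel centres of a filled ellipse, axes in mm (full lengths).
ellipse_pixels <- function(centre_mm, axes_mm, scale, offset_px = c(0, 0)) {
  cx <- centre_mm[1] * scale + offset_px[2]
  cy <- centre_mm[2] * scale + offset_px[1]
  a <- pmax(axes_mm[1] * scale / 2, 1)    # semi-axes in px, floor of 1 px so
  b <- pmax(axes_mm[2] * scale / 2, 1)    # seeds stay visible at coarse scales
  xs <- floor(cx - a):ceiling(cx + a)
  ys <- floor(cy - b):ceiling(cy + b)
  g <- expand.grid(y = ys, x = xs)
  keep <- ((g$x - cx) / a)^2 + ((g$y - cy) / b)^2 <= 1
  cbind(y = as.integer(g$y[keep]), x = as.integer(g$x[keep]))
}

#' Rasterize a root polyline into a binary tube mask
#'
#' Stamps a disk of diameter `width_px` at sub-pixel-resampled points along
#' the polyline, producing the tube footprint used by the synthetic renderer.
#'
#' @param polyline Two-column matrix of (x, y) points in mm; may be empty.
#' @param width_px Tube width in pixels.
#' @param scale Pixels per mm.
#' @param dim Canvas dimensions `c(height, width)` in pixels.
#' @return An integer 0/1 matrix of size `dim`.
#' @export
rasterize_root <- function(polyline, width_px, scale, dim) {
  mask <- matrix(0L, nrow = dim[1], ncol = dim[2])
  if (is.null(polyline) || nrow(polyline) == 0) return(mask)
  pp <- polyline_pixels(polyline, scale)
  offs <- disk_offsets(width_px / 2)
  stamp_disk(mask, pp[, "y"], pp[, "x"], offs, 1L)
}

## Fully render one frame's geometry: owner raster (seed index per pixel,
## first-come within a frame) and the overlap-dilated owner raster.
render_frame_geometry <- function(records, config, frame) {
  H <- config$dim_px[1]; W <- config$dim_px[2]
  owner <- matrix(0L, H, W)
  owner_dil <- matrix(0L, H, W)
  offs <- disk_offsets(config$root_width_px / 2)
  offs_dil <- disk_offsets(config$root_width_px / 2 + 1)
  conflicts <- list()
  for (k in seq_along(records)) {
    rec <- records[[k]]
    off_px <- seed_drift_px(rec, config, frame)
    sp <- ellipse_pixels(rec$centre_mm, config$seed_axes_mm,
                         config$scale_px_per_mm, off_px)
    pts <- truncate_polyline(rec$polyline_mm, rec$cum_len_mm,
                             rec$true_length_mm[frame])
    rp <- polyline_pixels(pts, config$scale_px_per_mm)
    rp[, "y"] <- rp[, "y"] + as.integer(round(off_px[1]))
    rp[, "x"] <- rp[, "x"] + as.integer(round(off_px[2]))
    idx <- unique(c(stamp_indices(c(H, W), sp[, "y"], sp[, "x"], offs),
                    stamp_indices(c(H, W), rp[, "y"], rp[, "x"], offs)))
    idx_dil <- unique(c(stamp_indices(c(H, W), sp[, "y"], sp[, "x"], offs_dil),
                        stamp_indices(c(H, W), rp[, "y"], rp[, "x"], offs_dil)))
    hit <- owner_dil[idx_dil]
    hit <- unique(hit[hit != 0 & hit != k])
    if (length(hit)) conflicts[[length(conflicts) + 1L]] <- cbind(k, hit)
    owner[idx] <- k
    owner_dil[idx_dil] <- k
  }
  list(owner = owner, owner_dil = owner_dil,
       conflicts = if (length(conflicts)) do.call(rbind, conflicts) else NULL)
}

seed_drift_px <- function(rec, config, frame) {
  if (config$drift_px_per_frame == 0) return(c(0, 0))
  d <- config$drift_px_per_frame * (frame - 1)
  c(d * rec$drift_dir[2], d * rec$drift_dir[1])   # (dy, dx)
}

#' Render the noiseless foreground truth mask of one frame
#'
#' @param truth A `plate_truth` object from [generate_plate_series()].
#' @param frame Frame index (1-based).
#' @param per_seed If `TRUE`, return the integer owner raster (seed index per
#'   pixel) instead of a binary mask.
#' @return Integer matrix: 0/1 mask, or owner labels when `per_seed = TRUE`.
#' @export
truth_frame_mask <- function(truth, frame, per_seed = FALSE) {
  stopifnot(inherits(truth, "plate_truth"), frame >= 1,
            frame <= truth$config$n_frames)
  g <- render_frame_geometry(truth$records, truth$config, frame)
  if (per_seed) g$owner else as_mask(g$owner)
}

#' Generate a synthetic plate time-lapse with exact ground truth
#'
#' Renders dark-agar frames (background `bg`, foreground `fg`, Gaussian pixel
#' noise) of an in-silico germination assay, together with per-seed truth:
#' germination hour, growth rate, root polyline, per-frame true length and
#' the first hour at which a seed's footprint (dilated by 1 px) touches a
#' neighbour's. Identical configurations produce bit-identical output.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional directory; when given, frames are streamed to
#'   `frame_%03d.tif` (8-bit grayscale TIFF) instead of kept in memory, and
#'   the returned series is directory-backed.
#' @return A list with `series` (a `plate_series`) and `truth`
#'   (a `plate_truth` holding the truth records and the config).
#' @export
generate_plate_series <- function(config, dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$rng_seed)
  records <- draw_geometry(config)
  H <- config$dim_px[1]; W <- config$dim_px[2]
  n <- config$n_frames
  incremental <- config$drift_px_per_frame == 0

  frames <- if (is.null(dir)) vector("list", n) else NULL
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  offs <- disk_offsets(config$root_width_px / 2)
  offs_dil <- disk_offsets(config$root_width_px / 2 + 1)
  owner <- matrix(0L, H, W)
  owner_dil <- matrix(0L, H, W)

  register_conflicts <- function(pairs, hour) {
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      if (is.na(records[[a]]$overlapped_from_h)) {
        records[[a]]$overlapped_from_h <<- hour
        records[[a]]$overlap_partner <<- records[[b]]$seed_id
      }
      if (is.na(records[[b]]$overlapped_from_h)) {
        records[[b]]$overlapped_from_h <<- hour
        records[[b]]$overlap_partner <<- records[[a]]$seed_id
      }
    }
  }

  for (f in seq_len(n)) {
    hour <- f * config$frame_interval_h
    if (incremental) {
      for (k in seq_along(records)) {
        rec <- records[[k]]
        if (f == 1) {
          sp <- ellipse_pixels(rec$centre_mm, config$seed_axes_mm,
                               config$scale_px_per_mm)
          new_pts <- polyline_pixels(
            truncate_polyline(rec$polyline_mm, rec$cum_len_mm,
                              rec$true_length_mm[1]),
            config$scale_px_per_mm)
          ys <- c(sp[, "y"], new_pts[, "y"]); xs <- c(sp[, "x"], new_pts[, "x"])
        } else {
          l0 <- rec$true_length_mm[f - 1]; l1 <- rec$true_length_mm[f]
          if (l1 <= l0) next
          seg <- truncate_polyline(rec$polyline_mm, rec$cum_len_mm, l1)
          seg <- tail_polyline(seg, max(0, l0 - 0.05))
          pp <- polyline_pixels(seg, config$scale_px_per_mm)
          ys <- pp[, "y"]; xs <- pp[, "x"]
        }
        if (length(ys) == 0) next
        idx <- stamp_indices(c(H, W), ys, xs, offs)
        idx_dil <- stamp_indices(c(H, W), ys, xs, offs_dil)
        hit <- owner_dil[idx_dil]
        hit <- unique(hit[hit != 0 & hit != k])
        if (length(hit)) register_conflicts(cbind(k, hit), hour)
        keep <- owner[idx] == 0L
        owner[idx[keep]] <- k
        keep_d <- owner_dil[idx_dil] == 0L
        owner_dil[idx_dil[keep_d]] <- k
      }
      mask <- owner != 0L
    } else {
      g <- render_frame_geometry(records, config, f)
      if (!is.null(g$conflicts)) register_conflicts(g$conflicts, hour)
      mask <- g$owner != 0L
    }
    img <- config$bg + (config$fg - config$bg) * mask
    if (config$noise_sd > 0) img <- img + rnorm(H * W, 0, config$noise_sd)
    img <- matrix(as.integer(round(clamp(img, 0, 255))), H, W)
    if (is.null(dir)) {
      frames[[f]] <- img
    } else {
      tiff::writeTIFF(img / 255, file.path(dir, sprintf("frame_%03d.tif", f)),
                      bits.per.sample = 8L)
    }
  }

  series <- new_plate_series(
    frames = frames, dir = dir, n_frames = n, dim = c(H, W),
    hours = seq_len(n) * config$frame_interval_h,
    scale_px_per_mm = config$scale_px_per_mm, plate_id = "synthetic",
    genotype = NA_character_)
  truth <- structure(list(records = records, config = config),
                     class = "plate_truth")
  list(series = series, truth = truth)
}

## Portion of a polyline from arc length `from_len` to its end.
tail_polyline <- function(pts, from_len) {
  cl <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  total <- cl[length(cl)]
  if (from_len <= 0) return(pts)
  if (from_len >= total) return(pts[0, , drop = FALSE])
  i <- findInterval(from_len, cl)
  f <- (from_len - cl[i]) / (cl[i + 1] - cl[i])
  rbind(pts[i, ] + f * (pts[i + 1, ] - pts[i, ]),
        pts[(i + 1):nrow(pts), , drop = FALSE])
}

#' @export
print.plate_truth <- function(x, ...) {
  tt <- truth_table(x)
  cat(sprintf("<plate_truth> %d seeds, %d germinated, %d overlapped\n",
              nrow(tt), sum(!is.na(tt$germ_h)), sum(!is.na(tt$overlapped_from_h))))
  invisible(x)
}

#' Tabulate ground truth as a per-seed five-number summary
#'
#' One row per seed with the dashboard schema: seed id (row, col), the hour
#' germination began, the last viable hour (series end, or one frame before
#' the first neighbour overlap), root length at that hour and the true growth
#' rate. Non-germinated seeds carry `NA` germination fields and zero length.
#'
#' @param truth A `plate_truth`, or a bare list of truth records.
#' @return A tibble.
#' @export
truth_table <- function(truth) {
  records <- if (inherits(truth, "plate_truth")) truth$records else truth
  purrr::map_dfr(records, function(rec) {
    hours <- rec$hours
    last_h <- if (is.na(rec$overlapped_from_h)) max(hours) else
      max(hours[hours < rec$overlapped_from_h])
    fi <- match(last_h, hours)
    tibble(
      seed_id = rec$seed_id, row = rec$row, col = rec$col,
      germ_h = rec$germ_h,
      last_h = last_h,
      final_length_mm = if (is.na(rec$germ_h)) 0 else rec$true_length_mm[fi],
      rate_mm_per_h = if (is.na(rec$germ_h)) NA_real_ else rec$rate_mm_per_h,
      overlapped_from_h = rec$overlapped_from_h,
      overlap_partner = rec$overlap_partner)
  })
}
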