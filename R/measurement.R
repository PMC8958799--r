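#' Skeletonize a binary mask
#'
#' Zhang-Suen thinning to a (mostly) one-pixel-wide, 8-connected medial
#' curve.
#'
#' @param mask Binary matrix.
#' @return Integer 0/1 skeleton matrix.
#' @export
skeletonize <- function(mask) {
  .zs_thin(as_mask(mask))
}

#' Calibrated root length of a binary submask
#'
#' Thins the mask and sums inter-pixel steps along the skeleton: 1 for
#' 4-neighbour steps, sqrt(2) for diagonal steps (skipping diagonal chords
#' that are short-circuited by a 4-neighbour), divided by the pixel scale.
#' Disconnected fragments are summed; the geodesic weights keep diagonal
#' (agravitropic) roots unbiased, where raw pixel counting underestimates
#' them by ~29%.
#'
#' Thinning retracts the skeleton from tube ends by about half the tube
#' width; each skeleton endpoint is therefore extended by its city-block
#' distance to the background minus one. The correction vanishes for
#' one-pixel-wide structures, so ideal digital lines measure exactly.
#'
#' Short thinning artifacts (spurs branching off the medial curve, common on
#' slanted tubes) are pruned before measuring: branches of at most
#' `prune_px` pixels ending at a junction are removed.
#'
#' @param mask Binary matrix (a root submask).
#' @param scale_px_per_mm Pixels per mm.
#' @param prune_px Maximum spur length, in pixels, to prune (0 disables).
#' @return Length in mm (0 for an empty mask).
#' @export
skeleton_length <- function(mask, scale_px_per_mm, prune_px = 4) {
  stopifnot(scale_px_per_mm > 0)
  m <- as_mask(mask)
  if (!any(m == 1L)) return(0)
  ## pad with a background ring so tight crops keep a defined boundary
  H <- nrow(m); W <- ncol(m)
  mp <- matrix(0L, H + 2L, W + 2L)
  mp[2:(H + 1), 2:(W + 1)] <- m
  sk <- .zs_thin(mp)
  if (prune_px > 0) sk <- .prune_spurs(sk, as.integer(prune_px))
  if (!any(sk == 1L)) return(0)
  steps <- .skeleton_steps(sk)
  ## endpoint extension by the distance transform of the full mask
  nb <- box_mean(sk, 3) * 9 - sk               # 8-neighbour counts
  endpoints <- which(sk == 1L & nb == 1)
  corr <- 0
  if (length(endpoints)) {
    dt <- as.matrix(EBImage::distmap(mp, metric = "manhattan"))
    corr <- sum(pmax(dt[endpoints] - 1, 0))
  }
  (steps + corr) / scale_px_per_mm
}

#' Skeleton end-shortening bias of a rendered tube
#'
#' Thinning a tube of finite width retracts the skeleton from the tube ends
#' by roughly half the tube width. This calibrates that deficit from the
#' package's own forward model: a straight vertical tube of known length is
#' rasterized at the given width and scale, and the difference between true
#' and measured skeleton length is returned (mm). Deterministic; no image
#' data involved.
#'
#' @param width_px Tube width in pixels.
#' @param scale_px_per_mm Pixels per mm.
#' @param bar_mm Length of the calibration tube.
#' @return Total end-shortening in mm (both ends combined).
#' @export
skeleton_end_bias <- function(width_px, scale_px_per_mm, bar_mm = 5) {
  x0 <- max(4 * width_px, 10) / scale_px_per_mm
  poly <- cbind(x = c(x0, x0), y = c(x0, x0 + bar_mm))
  dim_px <- ceiling(c(x0 + bar_mm + x0, 2 * x0) * scale_px_per_mm)
  mask <- rasterize_root(poly, width_px, scale_px_per_mm, dim_px)
  bar_mm - skeleton_length(mask, scale_px_per_mm)
}

#' Detect germination in a length series
#'
#' The germination call is the first hour at which the measured length
#' reaches `min_len_mm` and stays there for `persist_frames` consecutive
#' frames — a spurious single-frame spike does not trigger. Returns `NA`
#' (non-germination) when no such run exists.
#'
#' @param series A data frame with `hours` and `length_mm` (e.g. one seed's
#'   rows of a length series), or a numeric vector of lengths with `hours`
#'   supplied separately.
#' @param min_len_mm Detection threshold (default 0.25 mm, about two seed
#'   diameters beyond the seed body).
#' @param persist_frames Consecutive frames required at or above threshold.
#' @param hours Acquisition hours (when `series` is a bare vector).
#' @return The crossing hour, or `NA_real_`.
#' @export
detect_germination <- function(series, min_len_mm = 0.25, persist_frames = 2,
                               hours = NULL) {
  if (is.data.frame(series)) {
    hours <- series$hours
    len <- series$length_mm
  } else {
    len <- series
    hours <- hours %||% seq_along(len)
  }
  stopifnot(length(len) >= 1, length(hours) == length(len))
  above <- len >= min_len_mm
  if (persist_frames <= 1) {
    i <- which(above)[1]
    return(if (is.na(i)) NA_real_ else hours[i])
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= persist_frames)
  if (length(ok) == 0) return(NA_real_)
  hours[ends[ok[1]] - r$lengths[ok[1]] + 1]
}

#' Fit a growth rate over a measurement window
#'
#' Ordinary least-squares line through `(hours, length_mm)` restricted to
#' `[germ_h, end_h]` — the window running from germination to either the
#' first neighbour overlap or the end of the series. Fewer than 3 samples in
#' the window yields an undefined (NA) rate, recorded rather than thrown.
#'
#' @param series Data frame with `hours` and `length_mm`.
#' @param germ_h Window start (hours).
#' @param end_h Window end (hours).
#' @return A list of class `growth_fit`: `slope`, `intercept`, `n`,
#'   `window = c(germ_h, end_h)`, and `x0` (hour at which the fitted line
#'   crosses zero length, NA for flat fits).
#' @export
fit_growth_rate <- function(series, germ_h, end_h) {
  sel <- series$hours >= germ_h & series$hours <= end_h
  h <- series$hours[sel]; l <- series$length_mm[sel]
  if (length(h) < 3) {
    return(structure(list(slope = NA_real_, intercept = NA_real_,
                          n = length(h), window = c(germ_h, end_h),
                          x0 = NA_real_), class = "growth_fit"))
  }
  fit <- lm(l ~ h)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  structure(list(slope = slope, intercept = intercept, n = length(h),
                 window = c(germ_h, end_h),
                 x0 = if (is.na(slope) || slope <= 0) NA_real_ else -intercept / slope),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> slope %.5f mm/h over [%g, %g] h (n=%d)\n",
              x$slope, x$window[1], x$window[2], x$n))
  invisible(x)
}

#' Back-extrapolated germination onset
#'
#' A radicle emerging from under the seed body is invisible until it clears
#' the masked seed region, so the raw threshold crossing is systematically
#' late by (hidden length) / rate. The onset is recovered by extrapolating
#' the fitted early-growth line back to the radicle origin: the hour at which
#' the fitted visible length equals `-hidden_mm`, clamped to
#' `[0, crossing_h]`.
#'
#' @param fit A `growth_fit`.
#' @param hidden_mm Hidden length: seed-mask depth below the seed centroid
#'   plus the skeleton end-shortening (see [skeleton_end_bias()]).
#' @param crossing_h The threshold-crossing hour from [detect_germination()].
#' @return Estimated onset hour (NA when the fit is undefined).
#' @export
estimate_onset <- function(fit, hidden_mm, crossing_h) {
  if (is.na(fit$slope) || fit$slope <= 0 || is.na(fit$x0)) return(crossing_h)
  clamp(fit$x0 - hidden_mm / fit$slope, 0, crossing_h)
}

#' Per-interval (hourly) growth rates
#'
#' First differences `diff(length) / diff(hours)`, aligned to the later
#' timestamp of each pair.
#'
#' @param series Data frame with `hours` and `length_mm` (optionally
#'   `seed_id`, preserved).
#' @return A tibble with `hours` and `rate_mm_per_h`; empty for a
#'   single-sample series.
#' @export
hourly_rates <- function(series) {
  h <- series$hours; l <- series$length_mm
  if (length(h) < 2) return(tibble(hours = numeric(0), rate_mm_per_h = numeric(0)))
  tibble(hours = h[-1], rate_mm_per_h = diff(l) / diff(h))
}

#' Hourly growth-rate table across seeds
#'
#' Applies [hourly_rates()] to every seed of a long length-series table and
#' optionally averages per hour within groups (e.g. genotypes) — the
#' hourly-growth-rate panels of a growth-cycle figure.
#'
#' @param length_series Long tibble with `seed_id`, `hours`, `length_mm`
#'   (e.g. `plate_results$length_series`), optionally extra grouping
#'   columns.
#' @param by Optional column name to average within (per hour).
#' @return A tibble of per-seed hourly rates, or per-`by`-group mean rates.
#' @export
hourly_rate_table <- function(length_series, by = NULL) {
  out <- dplyr::group_modify(
    dplyr::group_by(length_series, .data$seed_id,
                    dplyr::across(dplyr::any_of(by))),
    ~ hourly_rates(.x))
  out <- dplyr::ungroup(out)
  if (!is.null(by)) {
    out <- dplyr::summarise(
      dplyr::group_by(out, dplyr::across(dplyr::all_of(c(by, "hours")))),
      rate_mm_per_h = mean(.data$rate_mm_per_h, na.rm = TRUE), .groups = "drop")
  }
  out
}

#' Germination index
#'
#' Percentage of sown seeds that germinated within the observation window.
#'
#' @param summaries A data frame with a `germ_h` column (NA = never
#'   germinated), e.g. a growth-summary or truth table.
#' @return Percent in `[0, 100]`.
#' @export
germination_index <- function(summaries) {
  if (is.data.frame(summaries)) {
    if (nrow(summaries) == 0) abort("germination index of an empty table is undefined")
    g <- summaries$germ_h
  } else {
    if (length(summaries) == 0) abort("germination index of an empty table is undefined")
    g <- summaries
  }
  100 * mean(!is.na(g))
}

#' Mean absolute percentage error
#'
#' `100 * mean(|measured - reference| / reference)` over paired vectors.
#'
#' @param measured,reference Paired numeric vectors; all reference entries
#'   must be positive.
#' @return Percent.
#' @export
mape <- function(measured, reference) {
  stopifnot(length(measured) == length(reference))
  if (any(reference <= 0)) abort("MAPE is undefined for non-positive reference entries")
  100 * mean(abs(measured - reference) / reference)
}
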