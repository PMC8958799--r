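#' USAF-1951 resolving power
#'
#' Line pairs per millimetre of a resolution-target element:
#' `2^(group + (element - 1) / 6)`. Doubles per group, and increases by a
#' factor `2^(1/6)` per element. A target spanning groups 0-7 thus covers
#' 1 to 228 lp/mm; group 6 element 6 is the conventional 114 lp/mm
#' benchmark.
#'
#' @param group Integer group number (may be negative for coarse targets).
#' @param element Element within the group, 1-6.
#' @param signif_digits Significant figures for the `rounded` value
#'   (chart convention: 3).
#' @return A one-row tibble with `group`, `element`, `lp_per_mm` (raw) and
#'   `rounded`.
#' @export
usaf_lp_per_mm <- function(group, element, signif_digits = 3) {
  if (any(element < 1 | element > 6)) abort("element must be in 1..6")
  raw <- 2^(group + (element - 1) / 6)
  tibble(group = group, element = element, lp_per_mm = raw,
         rounded = signif(raw, signif_digits))
}

#' Modulation contrast of an intensity line probe
#'
#' Contrast of a line-pair pattern scanned along a probe:
#' `(max - min) / (max + min)` where `max` is the mean of detected intensity
#' peaks and `min` the mean of detected valleys, after moving-average
#' smoothing. Plateaus (flat-topped peaks) count once, at their plateau
#' value. When the smoothed probe has no interior extrema the global max/min
#' are used, so a constant probe scores 0.
#'
#' @param probe Numeric vector of grayscale intensities (0-255), length >= 3.
#' @param smoothing_window Moving-average window (odd; 1 = no smoothing).
#' @return A one-row tibble with `modulation` (fraction in `[0, 1]`),
#'   `percent`, `peak_mean`, `valley_mean`, `n_peaks`, `n_valleys`.
#' @export
modulation <- function(probe, smoothing_window = 3) {
  stopifnot(length(probe) >= 3, smoothing_window >= 1)
  s <- as.numeric(stats::filter(probe, rep(1 / smoothing_window, smoothing_window),
                                sides = 2))
  s[is.na(s)] <- probe[is.na(s)]
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  nruns <- length(r$values)
  peaks <- c(); valleys <- c()
  if (nruns >= 3) {
    for (i in 2:(nruns - 1)) {
      if (r$values[i] > r$values[i - 1] && r$values[i] > r$values[i + 1]) {
        peaks <- c(peaks, r$values[i])
      }
      if (r$values[i] < r$values[i - 1] && r$values[i] < r$values[i + 1]) {
        valleys <- c(valleys, r$values[i])
      }
    }
  }
  if (length(peaks) == 0 || length(valleys) == 0) {
    peaks <- max(s); valleys <- min(s)
  }
  M <- mean(peaks); m <- mean(valleys)
  if (M + m == 0) abort("modulation is undefined: max + min = 0")
  mod <- (M - m) / (M + m)
  tibble(modulation = mod, percent = 100 * mod, peak_mean = M,
         valley_mean = m, n_peaks = length(peaks), n_valleys = length(valleys))
}

#' Field of view of a sensor at a given magnification
#'
#' Object-space field dimensions are the sensor dimensions divided by the
#' magnification; e.g. a full-frame 36 x 24 mm sensor gives 36 x 24 mm at
#' 1x and 150 x 100 mm (150 cm^2) at 0.24x.
#'
#' @param width_mm,height_mm Physical sensor size.
#' @param magnification Optical magnification (> 0).
#' @return A one-row tibble with `width_mm`, `height_mm`, `area_cm2`.
#' @export
field_of_view <- function(width_mm = 36, height_mm = 24, magnification = 1) {
  if (magnification <= 0) abort("magnification must be > 0")
  stopifnot(width_mm > 0, height_mm > 0)
  w <- width_mm / magnification
  h <- height_mm / magnification
  tibble(width_mm = w, height_mm = h, area_cm2 = w * h / 100)
}

#' Sensor resolution in megapixels
#'
#' @param px_w,px_h Pixel counts.
#' @return Megapixels, rounded to 2 decimals.
#' @export
megapixels <- function(px_w, px_h) {
  stopifnot(px_w > 0, px_h > 0)
  round(px_w * px_h / 1e6, 2)
}
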