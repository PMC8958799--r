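test_that("skeleton length matches analytic bars and diagonals", {
  scale <- 58.4
  bar <- matrix(0L, 20, 80)
  bar[9:11, 10:68] <- 1L                       # 59 px long, 3 px wide
  expect_lt(abs(skeleton_length(bar, scale) - (59 - 1) / scale), 2 / scale)

  expect_equal(skeleton_length(matrix(0L, 5, 5), scale), 0)

  diag1 <- matrix(0L, 40, 40)
  n <- 30
  diag1[cbind(3 + seq_len(n), 3 + seq_len(n))] <- 1L
  expect_equal(skeleton_length(diag1, 10), (n - 1) * sqrt(2) / 10,
               tolerance = 1e-9)

  ## disconnected fragments sum
  two <- matrix(0L, 30, 30)
  two[5, 5:14] <- 1L
  two[20, 5:14] <- 1L
  expect_equal(skeleton_length(two, 10), 2 * 9 / 10, tolerance = 1e-9)
})

test_that("germination detection requires a persistent threshold crossing", {
  h <- 0:20
  expect_true(is.na(detect_germination(rep(0, 21), hours = h)))

  len <- ifelse(h >= 12, 0.4, 0)
  expect_equal(detect_germination(len, hours = h), 12)

  ## single-frame spike below the persistence requirement is ignored
  spike <- rep(0, 21); spike[8] <- 5
  expect_true(is.na(detect_germination(spike, hours = h, persist_frames = 2)))
  ## exhaustive-scan oracle over all windows agrees
  oracle <- function(len, h, thr, k) {
    for (i in seq_len(length(len) - k + 1)) {
      if (all(len[i:(i + k - 1)] >= thr)) return(h[i])
    }
    NA_real_
  }
  set.seed(2)
  for (rep in 1:25) {
    len <- round(runif(15, 0, 0.6), 2)
    k <- sample(1:3, 1)
    expect_identical(detect_germination(len, 0.25, k, hours = seq_along(len)),
                     oracle(len, seq_along(len), 0.25, k))
  }
})

test_that("growth-rate fitting recovers exact slopes and flags short windows", {
  h <- 0:40
  ser <- tibble::tibble(hours = h, length_mm = pmax(0, 0.15 * (h - 5)))
  fit <- fit_growth_rate(ser, 5, 40)
  expect_equal(fit$slope, 0.15, tolerance = 1e-9)

  flat <- tibble::tibble(hours = h, length_mm = rep(2, 41))
  expect_equal(fit_growth_rate(flat, 0, 40)$slope, 0, tolerance = 1e-12)

  short <- fit_growth_rate(ser, 5, 6)
  expect_true(is.na(short$slope))
  expect_equal(short$n, 2)
})

test_that("mean hourly rate equals the OLS slope for noiseless linear data", {
  h <- 0:30
  ser <- tibble::tibble(hours = h, length_mm = 0.12 * h + 0.3)
  hr <- hourly_rates(ser)
  expect_equal(nrow(hr), 30)
  expect_true(all(abs(hr$rate_mm_per_h - 0.12) < 1e-12))
  expect_equal(mean(hr$rate_mm_per_h), fit_growth_rate(ser, 0, 30)$slope,
               tolerance = 1e-9)
  expect_equal(nrow(hourly_rates(ser[1, ])), 0)

  ## the table form averages per hour within groups
  long <- dplyr::bind_rows(
    tibble::tibble(seed_id = "a", genotype = "WT", hours = 0:5, length_mm = 0.1 * (0:5)),
    tibble::tibble(seed_id = "b", genotype = "WT", hours = 0:5, length_mm = 0.2 * (0:5)))
  tab <- hourly_rate_table(long, by = "genotype")
  expect_equal(nrow(tab), 5)
  expect_true(all(abs(tab$rate_mm_per_h - 0.15) < 1e-12))
})

test_that("germination index counts germinated seeds out of all sown", {
  df <- tibble::tibble(germ_h = c(rep(1, 60), rep(NA, 4)))
  expect_equal(germination_index(df), 93.75)
  expect_equal(germination_index(tibble::tibble(germ_h = 1:5)), 100)
  expect_equal(germination_index(tibble::tibble(germ_h = rep(NA_real_, 5))), 0)
  expect_error(germination_index(df[0, ]), "empty")
  ## permutation invariance and bounds
  set.seed(3)
  g <- sample(df$germ_h)
  expect_equal(germination_index(tibble::tibble(germ_h = g)),
               germination_index(df))
})

test_that("mape follows its definition and rejects bad references", {
  expect_equal(mape(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mape(1.05 * c(2, 4, 8), c(2, 4, 8)), 5, tolerance = 1e-9)
  expect_equal(mape(c(9, 11), c(10, 10)), 10)
  expect_error(mape(c(1, 2), c(1, 0)), "reference")
})

test_that("measured length series are near-monotone on noiseless plates", {
  gen <- noiseless_plate()
  res <- run_pipeline(gen$series, 3, 3)
  tol <- 2 / gen$truth$config$scale_px_per_mm
  for (id in unique(res$length_series$seed_id)) {
    l <- res$length_series$length_mm[res$length_series$seed_id == id]
    l <- l[!is.na(l)]
    expect_true(all(diff(l) >= -tol))
  }
})

test_that("skeleton end bias stays within two pixels and replays consistently", {
  for (w in c(3, 5, 7)) {
    b <- skeleton_end_bias(w, 10)
    expect_lte(abs(b), 2 / 10 + 1e-9)          # |bias| <= 2 px after correction
    expect_identical(b, skeleton_end_bias(w, 10))  # deterministic calibration
  }
  ## the bias really is what a measured bar misses: 8 mm bar measures 8 - bias
  poly <- cbind(x = c(3, 3), y = c(2, 10))
  mask <- rasterize_root(poly, 5, 10, c(140, 60))
  expect_equal(skeleton_length(mask, 10), 8 - skeleton_end_bias(5, 10, bar_mm = 8),
               tolerance = 1e-9)
})
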