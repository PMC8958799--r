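test_that("linear growth truth follows rate x time and respects delays", {
  cfg <- synthetic_config(rows = 2, cols = 2, spacing_mm = 6,
                          scale_px_per_mm = 10, n_frames = 96,
                          germ_delay_h = c(0, 0), germ_prob = 1,
                          rate_mm_per_h = c(0.15, 0.15), root_width_px = 3,
                          noise_sd = 0, margin_mm = 3, rng_seed = 1)
  gen <- generate_plate_series(cfg)
  tt <- truth_table(gen$truth)
  for (rec in gen$truth$records) {
    expect_equal(rec$true_length_mm[96], 14.40, tolerance = 1e-12)
    ## polyline arc length matches the stated length at every frame
    expect_equal(max(rec$cum_len_mm), 14.40, tolerance = 1e-9)
    expect_true(all(diff(rec$true_length_mm) >= 0))
  }
  expect_equal(nrow(tt), 4)
})

test_that("germ_prob = 0 yields no germination, empty root masks, zero lengths", {
  cfg <- synthetic_config(rows = 2, cols = 2, spacing_mm = 6,
                          scale_px_per_mm = 10, n_frames = 5, germ_prob = 0,
                          rate_mm_per_h = c(0.1, 0.1), root_width_px = 3,
                          noise_sd = 0, margin_mm = 3, rng_seed = 3)
  gen <- generate_plate_series(cfg)
  tt <- truth_table(gen$truth)
  expect_true(all(is.na(tt$germ_h)))
  expect_true(all(tt$final_length_mm == 0))
  ## foreground is exactly the 4 seed bodies in every frame
  for (f in c(1, 5)) {
    m <- truth_frame_mask(gen$truth, f)
    expect_equal(label_components(m)$n, 4)
    expect_identical(m, truth_frame_mask(gen$truth, 1))
  }
})

test_that("identical config and seed reproduce bit-identical frames and truth", {
  cfg <- synthetic_config(rows = 2, cols = 2, spacing_mm = 6,
                          scale_px_per_mm = 10, n_frames = 8,
                          germ_delay_h = c(0, 4), germ_prob = 0.8,
                          rate_mm_per_h = c(0.05, 0.15), curl = 0.5,
                          root_width_px = 3, noise_sd = 8, margin_mm = 3,
                          rng_seed = 42)
  a <- generate_plate_series(cfg)
  b <- generate_plate_series(cfg)
  for (f in seq_len(8)) {
    expect_identical(get_frame(a$series, f), get_frame(b$series, f))
  }
  expect_identical(truth_table(a$truth), truth_table(b$truth))
})

test_that("rasterize_root matches analytic geometry and set-union composition", {
  ## straight 10 mm vertical line at 58.4 px/mm, width 3: bbox height ~584 px
  poly <- cbind(x = c(2, 2), y = c(2, 12))
  mask <- rasterize_root(poly, 3, 58.4, c(1000, 300))
  rows <- range(which(rowSums(mask) > 0))
  expect_lt(abs(diff(rows) + 1 - 584), 3 + 1)

  ## zero-length polyline: at most width^2 pixels
  tiny <- rasterize_root(cbind(x = 2, y = 2), 3, 10, c(50, 50))
  expect_lte(sum(tiny), 9)
  expect_gt(sum(tiny), 0)

  ## empty polyline: empty mask, no error
  expect_equal(sum(rasterize_root(poly[0, , drop = FALSE], 3, 10, c(20, 20))), 0)

  ## disjoint tubes compose by set union: no interference, additive area
  p1 <- cbind(x = c(1, 1), y = c(1, 3))
  p2 <- cbind(x = c(4, 4), y = c(1, 3))
  m1 <- rasterize_root(p1, 3, 10, c(60, 60))
  m2 <- rasterize_root(p2, 3, 10, c(60, 60))
  expect_equal(sum(m1 & m2), 0)
  expect_equal(sum(m1 | m2), sum(m1) + sum(m2))
  ## and each tube alone reproduces its part of the union exactly
  expect_identical(((m1 | m2) & !m2) * 1L, m1 * 1L)
})

test_that("truth table carries the five-number schema and round-trips CSV", {
  gen <- small_plate()
  tt <- truth_table(gen$truth)
  expect_equal(nrow(tt), 9)
  expect_true(all(c("seed_id", "germ_h", "last_h", "final_length_mm",
                    "rate_mm_per_h") %in% names(tt)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_csv(tt, path)
  back <- read_results_csv(path)
  ## all-NA columns come back typeless; compare values, not vector classes
  for (col in names(tt)) {
    expect_equal(as.vector(back[[col]], mode = mode(tt[[col]])), tt[[col]],
                 tolerance = 1e-12, label = col)
  }
})

test_that("vertical roots under curl = 0 stay in their seed's column", {
  gen <- noiseless_plate()
  for (rec in gen$truth$records) {
    expect_true(all(abs(rec$polyline_mm[, "x"] - rec$centre_mm["x"]) < 1e-9))
  }
})

test_that("foreground pixel count is non-decreasing without drift and noise", {
  gen <- noiseless_plate()
  counts <- vapply(seq_len(10), function(f) {
    sum(get_frame(gen$series, f) > 100)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("recorded overlap hour matches a brute-force per-frame pixel check", {
  ## two seeds angled towards each other collide at a knowable frame:
  ## lateral gap 4 mm closes at 2*sin(30 deg) = 1 mm per mm of growth,
  ## so contact near root length ~3.7 mm, i.e. hour ~25 at 0.15 mm/h
  cfg <- synthetic_config(rows = 1, cols = 2, spacing_mm = 4,
                          scale_px_per_mm = 10, n_frames = 36,
                          germ_delay_h = c(0, 0), germ_prob = 1,
                          rate_mm_per_h = c(0.15, 0.15),
                          heading_deg = c(30, -30), root_width_px = 3,
                          noise_sd = 0, margin_mm = 4, rng_seed = 5)
  gen <- generate_plate_series(cfg)
  tt <- truth_table(gen$truth)
  expect_true(all(!is.na(tt$overlapped_from_h)))
  expect_equal(tt$overlapped_from_h[1], tt$overlapped_from_h[2])
  expect_lt(abs(tt$overlapped_from_h[1] - 25), 3)

  ## brute force: first frame where the two seeds' dilated footprints meet
  brute <- NA_real_
  for (f in seq_len(36)) {
    owner <- truth_frame_mask(gen$truth, f, per_seed = TRUE)
    m1 <- dilate_mask(owner == 1, 1)
    m2 <- dilate_mask(owner == 2, 1)
    if (sum(m1 & m2) > 0) { brute <- f * cfg$frame_interval_h; break }
  }
  expect_lte(abs(tt$overlapped_from_h[1] - brute), 1 * cfg$frame_interval_h)

  ## parallel vertical roots never overlap
  cfg2 <- synthetic_config(rows = 1, cols = 2, spacing_mm = 5,
                           scale_px_per_mm = 10, n_frames = 30,
                           germ_delay_h = c(0, 0), germ_prob = 1,
                           rate_mm_per_h = c(0.15, 0.15), root_width_px = 3,
                           noise_sd = 0, margin_mm = 4, rng_seed = 5)
  tt2 <- truth_table(generate_plate_series(cfg2)$truth)
  expect_true(all(is.na(tt2$overlapped_from_h)))
})

test_that("incremental and full renders agree, with and without drift", {
  cfg <- synthetic_config(rows = 2, cols = 2, spacing_mm = 6,
                          scale_px_per_mm = 10, n_frames = 12,
                          germ_delay_h = c(0, 2), germ_prob = 1,
                          rate_mm_per_h = c(0.1, 0.15), root_width_px = 3,
                          noise_sd = 0, margin_mm = 3, rng_seed = 9)
  gen <- generate_plate_series(cfg)     # incremental path (drift = 0)
  for (f in c(1, 6, 12)) {
    expect_identical(as_mask(get_frame(gen$series, f) > 100),
                     truth_frame_mask(gen$truth, f))
  }
})

test_that("seed drift translates whole objects and can lose seeds", {
  cfg <- synthetic_config(rows = 1, cols = 2, spacing_mm = 8,
                          scale_px_per_mm = 10, n_frames = 10,
                          germ_prob = 0, drift_px_per_frame = 2,
                          root_width_px = 3, noise_sd = 0, margin_mm = 4,
                          rng_seed = 13)
  gen <- generate_plate_series(cfg)
  m1 <- truth_frame_mask(gen$truth, 1)
  m10 <- truth_frame_mask(gen$truth, 10)
  expect_equal(sum(m1), sum(m10), tolerance = 0.15)  # same objects, moved
  cc1 <- label_components(m1)$components
  cc10 <- label_components(m10)$components
  shift <- sqrt((cc10$cx - cc1$cx)^2 + (cc10$cy - cc1$cy)^2)
  expect_true(all(abs(shift - 18) < 2))   # 9 frames x 2 px
})

test_that("an unfittable grid raises a configuration error", {
  expect_error(
    synthetic_config(rows = 2, cols = 2, margin_mm = 0.1, scale_px_per_mm = 10,
                     root_width_px = 5),
    "margin")
})
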