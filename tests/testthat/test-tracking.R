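test_that("component labelling matches a brute-force flood fill", {
  set.seed(31)
  for (rep in 1:20) {
    mask <- matrix(rbinom(32 * 32, 1, 0.35), 32, 32)
    for (conn in c(4, 8)) {
      mine <- label_components(mask, conn)
      oracle <- flood_fill_label(mask, conn)
      expect_identical(canonical_labels(mine$labels), canonical_labels(oracle))
    }
  }
})

test_that("seed instances get tight boxes and row-major grid identities", {
  mask <- matrix(0L, 40, 40)
  mask[5:7, 5:7] <- 1L
  mask[5:7, 25:27] <- 1L
  inst <- suppressWarnings(detect_seed_instances(mask, 1, 2))
  expect_equal(nrow(inst), 2)
  expect_equal(inst$seed_id, c("1-1", "1-2"))
  expect_equal(inst$x0[1], 4); expect_equal(inst$x1[1], 7)   # 0-based half-open
  expect_equal(inst$y0[1], 4); expect_equal(inst$y1[1], 7)
  expect_equal(inst$x0[2], 24)

  empty <- detect_seed_instances(matrix(0L, 10, 10), 0, 0)
  expect_equal(nrow(empty), 0)

  gen <- small_plate()
  first <- as_mask(get_frame(gen$series, 1) > 100)
  inst2 <- detect_seed_instances(first, 3, 3)
  expect_equal(nrow(inst2), 9)
  expect_true(all(inst2$status == "pre_germination"))
  tt <- truth_table(gen$truth)
  ## centroids sit on the true grid
  cfg <- gen$truth$config
  for (i in seq_len(9)) {
    ctr <- rootlapse:::seed_centre_mm(cfg, inst2$row[i], inst2$col[i]) *
      cfg$scale_px_per_mm
    expect_lt(abs(inst2$cx[i] + 1 - ctr["x"]), 2)
    expect_lt(abs(inst2$cy[i] + 1 - ctr["y"]), 2)
  }
})

test_that("boxes expand by the union of claimed components, monotonically", {
  mask <- matrix(0L, 100, 40)
  mask[10:12, 18:22] <- 1L                      # the seed blob
  tracks <- suppressWarnings(detect_seed_instances(mask, 1, 1))
  grown <- mask
  grown[12:52, 19:21] <- 1L                     # root extends 40 px down
  t2 <- update_tracks(tracks, grown, frame_h = 1)
  expect_gte(t2$y1[1], tracks$y1[1] + 40)
  expect_equal(t2$x0[1], tracks$x0[1])
  expect_equal(t2$status[1], "growing")

  ## empty mask leaves boxes untouched
  t3 <- update_tracks(t2, matrix(0L, 100, 40), frame_h = 2)
  expect_identical(t3[, c("x0", "y0", "x1", "y1")], t2[, c("x0", "y0", "x1", "y1")])

  ## area is monotone over repeated updates with growing masks
  area <- function(tr) (tr$x1 - tr$x0) * (tr$y1 - tr$y0)
  expect_gte(area(t2[1, ]), area(tracks[1, ]))
})

test_that("a component claimed by two instances flags both as overlapped once", {
  mask <- matrix(0L, 60, 120)
  mask[10:12, 20:24] <- 1L
  mask[10:12, 90:94] <- 1L
  tracks <- detect_seed_instances(mask, 1, 2)
  bridge <- mask
  bridge[11, 20:94] <- 1L                       # single component spans both
  t2 <- update_tracks(tracks, bridge, frame_h = 7)
  expect_true(all(t2$status == "overlapped"))
  expect_equal(t2$overlap_h, c(7, 7))
  expect_equal(t2$overlap_partner, c("1-2", "1-1"))
  ## first occurrence wins: later frames do not rewrite overlap_h
  t3 <- update_tracks(t2, bridge, frame_h = 8)
  expect_equal(t3$overlap_h, c(7, 7))
})

test_that("root_pixels_of returns every fragment inside the box, none outside", {
  mask <- matrix(0L, 30, 30)
  mask[5:8, 10] <- 1L                           # fragment A (inside)
  mask[15:18, 12] <- 1L                         # fragment B (inside)
  mask[25:28, 25] <- 1L                         # outside
  track <- tibble::tibble(x0 = 5L, y0 = 2L, x1 = 15L, y1 = 20L)
  sub <- root_pixels_of(track, mask)
  expect_equal(dim(sub), c(18, 10))
  expect_equal(sum(sub), 8)                     # both fragments, nothing else

  expect_equal(sum(root_pixels_of(track, matrix(0L, 30, 30))), 0)
  full <- tibble::tibble(x0 = 0L, y0 = 0L, x1 = 30L, y1 = 30L)
  expect_identical(root_pixels_of(full, mask), as_mask(mask))
})

test_that("tracked boxes contain their own truth pixels and no neighbour's", {
  gen <- noiseless_plate()
  cfg <- gen$truth$config
  first <- as_mask(get_frame(gen$series, 1) > 100)
  tracks <- detect_seed_instances(first, 3, 3)
  for (f in seq(2, 30, by = 4)) {
    mask <- as_mask(get_frame(gen$series, f) > 100)
    tracks <- update_tracks(tracks, mask, f * cfg$frame_interval_h)
    owner <- truth_frame_mask(gen$truth, f, per_seed = TRUE)
    for (i in seq_len(nrow(tracks))) {
      k <- (tracks$row[i] - 1) * 3 + tracks$col[i]
      inside <- owner[(tracks$y0[i] + 1):tracks$y1[i],
                      (tracks$x0[i] + 1):tracks$x1[i]]
      expect_equal(sum(owner == k) - sum(inside == k), 0)  # all own pixels in
      expect_equal(sum(inside != 0 & inside != k), 0)      # no foreign pixels
    }
  }
})

test_that("a drifting, never-germinating seed is declared lost", {
  mask <- matrix(0L, 50, 50)
  mask[10:12, 10:12] <- 1L
  tracks <- suppressWarnings(detect_seed_instances(mask, 1, 1))
  moved <- matrix(0L, 50, 50)
  moved[40:42, 40:42] <- 1L                     # far outside the dilated box
  for (f in 1:3) tracks <- update_tracks(tracks, moved, f)
  expect_equal(tracks$status[1], "lost")
})
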