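test_that("patch extraction follows ceiling arithmetic and stitching inverts it", {
  ## the bench's center-cropped frame size: 4639 x 4480 -> 19 x 18 patches
  big <- matrix(0L, 4639, 4480)
  ep <- extract_patches(big, 256)
  expect_equal(length(ep$patches), 19 * 18)
  expect_equal(ep$grid$padded_dim, c(19 * 256, 18 * 256))
  back <- stitch_patches(ep$grid, ep$patches)
  expect_equal(dim(back), c(4639, 4480))
  rm(big, ep, back)

  ## single-patch case
  img <- matrix(runif(256 * 256), 256, 256)
  ep1 <- extract_patches(img, 256)
  expect_equal(length(ep1$patches), 1)
  expect_equal(unname(ep1$grid$offsets[1, ]), c(1, 1))

  ## roundtrip identity is bit-exact for awkward dims
  for (d in list(c(100, 100), c(300, 257), c(17, 503))) {
    m <- matrix(rnorm(prod(d)), d[1], d[2])
    ep <- extract_patches(m, 256)
    expect_identical(stitch_patches(ep$grid, ep$patches), m)
  }

  ## patch count mismatch errors
  expect_error(stitch_patches(ep1$grid, list()), "expected 1 patches")
})

test_that("disjoint single-hot patches stitch to a mask with that many pixels", {
  img <- matrix(0L, 300, 300)
  ep <- extract_patches(img, 256)                 # 2 x 2 patches
  hot <- lapply(seq_along(ep$patches), function(i) {
    p <- matrix(0L, 256, 256); p[10 + i, 20 + i] <- 1L; p
  })
  out <- stitch_patches(ep$grid, hot)
  ## hot pixels in padded area beyond the image are cropped away; all four
  ## offsets at (10+i, 20+i) lie inside 300 x 300 here
  expect_equal(sum(out), 4)
})

test_that("classical backend recovers noiseless synthetic masks and rejects blanks", {
  gen <- noiseless_plate()
  model <- segmentation_model("root", "classical")
  f <- 20
  pred <- segment(get_frame(gen$series, f), model)
  expect_true(all(pred %in% c(0L, 1L)))
  truth <- truth_frame_mask(gen$truth, f)
  expect_gte(f1_score(pred, truth)$f1, 0.95)

  blank <- matrix(30L, 200, 200)
  expect_equal(sum(segment(blank, model)), 0)
  noisy_blank <- matrix(as.integer(pmax(0, pmin(255, rnorm(200 * 200, 30, 8)))), 200, 200)
  expect_equal(sum(segment(noisy_blank, model)), 0)
})

test_that("f1_score implements the harmonic mean of precision and sensitivity", {
  m <- matrix(0L, 10, 10)
  truth <- m; truth[1:4, 1:4] <- 1L          # 16 positives
  pred <- m; pred[1:4, 1:3] <- 1L; pred[6:8, 6] <- 1L   # tp=12, fp=3, fn=4
  sc <- f1_score(pred, truth)
  expect_equal(sc$precision, 0.8)
  expect_equal(sc$sensitivity, 0.75)
  expect_equal(sc$f1, 2 * 0.8 * 0.75 / (0.8 + 0.75), tolerance = 1e-9)
  expect_equal(round(sc$f1, 6), 0.774194)

  expect_equal(f1_score(truth, truth)$f1, 1)
  disjoint <- m; disjoint[9:10, 9:10] <- 1L
  expect_equal(f1_score(disjoint, truth)$f1, 0)
  expect_error(f1_score(matrix(0L, 2, 2), truth), "dimensions")
})

test_that("training is reproducible, learns separable data, and validates input", {
  gen <- noiseless_plate()
  frames <- lapply(seq(2, 16, by = 2), function(f) get_frame(gen$series, f))
  labels <- lapply(seq(2, 16, by = 2), function(f) truth_frame_mask(gen$truth, f))

  m1 <- train_segmentation(frames, labels, "root", epochs = 10, rng_seed = 4,
                           downsample = 1)
  m2 <- train_segmentation(frames, labels, "root", epochs = 10, rng_seed = 4,
                           downsample = 1)
  expect_identical(m1$fit$wts, m2$fit$wts)    # reproducible weights

  held <- get_frame(gen$series, 20)
  held_truth <- truth_frame_mask(gen$truth, 20)
  expect_gte(f1_score(segment(held, m1), held_truth)$f1, 0.99)

  expect_error(train_segmentation(list(), list(), "root"), "at least one")
  expect_error(train_segmentation(frames[1], list(matrix(0L, 2, 2)), "root"),
               "dimensions")
  expect_error(segment(held, segmentation_model("root", "learned")), "untrained")
})

test_that("classical and learned backends agree on noiseless frames", {
  gen <- noiseless_plate()
  frames <- lapply(c(4, 8, 12), function(f) get_frame(gen$series, f))
  labels <- lapply(c(4, 8, 12), function(f) truth_frame_mask(gen$truth, f))
  learned <- train_segmentation(frames, labels, "root", epochs = 25,
                                rng_seed = 2, downsample = 1)
  classical <- segmentation_model("root", "classical")
  f <- 18
  a <- segment(get_frame(gen$series, f), learned)
  b <- segment(get_frame(gen$series, f), classical)
  expect_gte(f1_score(a, b)$f1, 0.95)
})

test_that("seed-path downsample/upsample is idempotent on blocky masks", {
  ## features aligned to the 8 px block grid survive the 256->32->256 path
  img <- matrix(0, 256, 256)
  img[33:64, 81:112] <- 200          # 32x32 block, aligned to 8 px grid
  img[121:136, 9:24] <- 200
  down <- rootlapse:::block_downsample(img, 8)
  up <- rootlapse:::nn_upsample(down, 8)
  expect_identical(rootlapse:::block_downsample(up, 8), down)
  expect_equal(up, img)              # block-aligned features reconstruct
})

test_that("model checkpoints round-trip through the JSON sidecar", {
  gen <- noiseless_plate()
  frames <- list(get_frame(gen$series, 10))
  labels <- list(truth_frame_mask(gen$truth, 10))
  m <- train_segmentation(frames, labels, "root", epochs = 10, rng_seed = 1,
                          downsample = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_segmentation_model(m, path)
  m2 <- read_segmentation_model(path)
  img <- get_frame(gen$series, 15)
  expect_identical(segment(img, m), segment(img, m2))
})
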