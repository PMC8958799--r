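# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

## Small quiet plate: 3x3, quick to generate and analyse.
small_plate <- function() cached("small_plate", function() {
  cfg <- synthetic_config(rows = 3, cols = 3, spacing_mm = 8,
                          scale_px_per_mm = 10, n_frames = 40,
                          germ_delay_h = c(0, 10), germ_prob = 1,
                          rate_mm_per_h = c(0.08, 0.16), root_width_px = 3,
                          noise_sd = 8, margin_mm = 4, rng_seed = 7)
  generate_plate_series(cfg)
})

## Noiseless variant for segmentation ground-truth comparisons.
noiseless_plate <- function() cached("noiseless_plate", function() {
  cfg <- synthetic_config(rows = 3, cols = 3, spacing_mm = 8,
                          scale_px_per_mm = 10, n_frames = 30,
                          germ_delay_h = c(0, 6), germ_prob = 1,
                          rate_mm_per_h = c(0.08, 0.16), root_width_px = 3,
                          noise_sd = 0, margin_mm = 4, rng_seed = 21)
  generate_plate_series(cfg)
})

## The full-size cohort plate used by the recovery studies: 64 seeds, hourly
## frames for 4 days, rates spanning 0.03-0.17 mm/h, germination delays
## 0-24 h, 10% of seeds never germinating. Generated and analysed once.
cohort_run <- function() cached("cohort_run", function() {
  cfg <- synthetic_config(rows = 8, cols = 8, scale_px_per_mm = 10,
                          n_frames = 96, germ_delay_h = c(0, 24),
                          germ_prob = 0.9, rate_mm_per_h = c(0.03, 0.17),
                          root_width_px = 3, noise_sd = 8, rng_seed = 11)
  gen <- generate_plate_series(cfg)
  t0 <- Sys.time()
  res <- run_pipeline(gen$series, 8, 8)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  list(gen = gen, truth = truth_table(gen$truth), results = res,
       elapsed_s = elapsed)
})

## A focus stack where slice k is sharp (textured) only inside vertical strip
## k and defocused (flat) elsewhere; truth depth is known per strip.
make_region_stack <- function(n = 5, side = 60, z_step = 10, seed = 17) {
  set.seed(seed)
  texture <- matrix(sample(c(40, 220), side * side, replace = TRUE), side, side)
  strips <- split(seq_len(side), cut(seq_len(side), n, labels = FALSE))
  slices <- lapply(seq_len(n), function(k) {
    s <- matrix(128, side, side)
    s[, strips[[k]]] <- texture[, strips[[k]]]
    s
  })
  list(stack = focus_stack(slices, z_step), strips = strips)
}

## Pure-R BFS flood fill: the independent oracle for component labelling.
flood_fill_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8) {
    cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1), dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dy = c(-1, 0, 0, 1), dx = c(0, -1, 1, 0))
  }
  cur <- 0L
  for (x in seq_len(W)) for (y in seq_len(H)) {
    if (mask[y, x] == 0 || lab[y, x] != 0) next
    cur <- cur + 1L
    queue <- list(c(y, x)); lab[y, x] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (i in seq_len(nrow(nb))) {
        yy <- p[1] + nb[i, 1]; xx <- p[2] + nb[i, 2]
        if (yy >= 1 && yy <= H && xx >= 1 && xx <= W &&
            mask[yy, xx] != 0 && lab[yy, xx] == 0) {
          lab[yy, xx] <- cur
          queue[[length(queue) + 1]] <- c(yy, xx)
        }
      }
    }
  }
  lab
}

## Canonicalize a labelling so implementations with different label orders
## compare equal: relabel by first (column-major) occurrence.
canonical_labels <- function(lab) {
  seen <- unique(lab[lab != 0])
  out <- lab
  for (i in seq_along(seen)) out[lab == seen[i]] <- i
  out
}

## Brute-force compact-letter-display checker: two groups share a letter
## iff their adjusted p >= alpha, and no single letter is removable.
letters_consistent <- function(letters, pmat, alpha) {
  k <- length(letters)
  sets <- strsplit(letters, "")
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    share <- length(intersect(sets[[i]], sets[[j]])) > 0
    if (share != (pmat[i, j] >= alpha)) return(FALSE)
  }
  all_letters <- unique(unlist(sets))
  for (L in all_letters) {
    reduced <- lapply(sets, setdiff, y = L)
    if (any(lengths(reduced) == 0)) next
    ok <- TRUE
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      share <- length(intersect(reduced[[i]], reduced[[j]])) > 0
      if (share != (pmat[i, j] >= alpha)) ok <- FALSE
    }
    if (ok) return(FALSE)                 # a removable letter: not minimal
  }
  TRUE
}

## Random symmetric p-value matrix for letter-display property tests.
random_pmat <- function(k) {
  p <- matrix(runif(k * k), k, k)
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  diag(p) <- 1
  dimnames(p) <- list(paste0("g", seq_len(k)), paste0("g", seq_len(k)))
  p
}
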