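#' Label connected components of a binary mask
#'
#' Iterative flood-fill labelling (compiled) with per-component statistics.
#' Coordinates are 0-based half-open pixel boxes, `x` = columns, `y` = rows
#' (image convention, y grows downwards).
#'
#' @param mask Binary matrix.
#' @param connectivity 8 (default; roots are thin, often diagonal structures)
#'   or 4.
#' @return A list: `labels` (integer matrix, 0 = background), `n`, and a
#'   tibble `components` with `label, x0, y0, x1, y1, area, cx, cy`.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  cc <- .cc_label(as_mask(mask), as.integer(connectivity))
  comps <- tibble(label = seq_len(cc$n), x0 = cc$x0, y0 = cc$y0,
                  x1 = cc$x1, y1 = cc$y1, area = cc$area,
                  cx = cc$cx, cy = cc$cy)
  list(labels = cc$labels, n = cc$n, components = comps)
}

#' Detect per-seed instances in a first-frame seed mask
#'
#' Connected components above `min_size` become seed instances; grid identity
#' `(row, col)` is assigned by snapping component centroids to the implied
#' regular grid (row-major). If the component count differs from
#' `rows * cols`, assignment is best-effort with a warning: unmatched grid
#' cells are emitted with status `"lost"` and an empty box; surplus
#' components are dropped.
#'
#' @param seed_mask Binary first-frame seed mask.
#' @param rows,cols Expected grid dimensions.
#' @param min_size Minimum component area in pixels.
#' @return A `seed_tracks` tibble: one row per grid cell with `seed_id`,
#'   `row`, `col`, box columns `x0, y0, x1, y1` (0-based half-open), centroid
#'   `cx, cy`, `status`, `overlap_partner`, `overlap_h`, `missed`.
#' @export
detect_seed_instances <- function(seed_mask, rows, cols, min_size = 5) {
  cc <- label_components(seed_mask, 8)
  comps <- dplyr::filter(cc$components, .data$area >= min_size)
  n_expect <- rows * cols
  if (nrow(comps) != n_expect) {
    warn(sprintf("expected %d seed components, found %d; assigning best-effort",
                 n_expect, nrow(comps)))
  }
  grid <- tidyr::expand_grid(row = seq_len(rows), col = seq_len(cols))
  if (nrow(comps) == 0) {
    out <- dplyr::mutate(grid,
      seed_id = sprintf("%d-%d", .data$row, .data$col),
      x0 = NA_integer_, y0 = NA_integer_, x1 = NA_integer_, y1 = NA_integer_,
      cx = NA_real_, cy = NA_real_, status = "lost",
      overlap_partner = NA_character_, overlap_h = NA_real_, missed = 0L)
    return(structure(out[, track_cols()], class = c("seed_tracks", class(out))))
  }
  ## snap centroids to the implied regular grid
  ry <- range(comps$cy); rx <- range(comps$cx)
  pitch_y <- if (rows > 1) (ry[2] - ry[1]) / (rows - 1) else 1
  pitch_x <- if (cols > 1) (rx[2] - rx[1]) / (cols - 1) else 1
  comps$row <- clamp(round((comps$cy - ry[1]) / pitch_y) + 1, 1, rows)
  comps$col <- clamp(round((comps$cx - rx[1]) / pitch_x) + 1, 1, cols)
  comps <- dplyr::arrange(comps, dplyr::desc(.data$area))
  comps <- comps[!duplicated(comps[, c("row", "col")]), ]

  out <- dplyr::left_join(grid, comps, by = c("row", "col"))
  out <- dplyr::mutate(out,
    seed_id = sprintf("%d-%d", .data$row, .data$col),
    status = ifelse(is.na(.data$x0), "lost", "pre_germination"),
    overlap_partner = NA_character_, overlap_h = NA_real_, missed = 0L)
  structure(out[, track_cols()], class = c("seed_tracks", class(out)))
}

track_cols <- function() {
  c("seed_id", "row", "col", "x0", "y0", "x1", "y1", "cx", "cy",
    "status", "overlap_partner", "overlap_h", "missed")
}

## 0-based half-open box intersection test on track rows a and b.
boxes_intersect <- function(a, b) {
  a$x0 < b$x1 & b$x0 < a$x1 & a$y0 < b$y1 & b$y0 < a$y1
}

#' Advance seed tracks by one frame of root mask
#'
#' Each live instance's box becomes the union of its previous box and the
#' tight boxes of root-mask components having at least one pixel inside the
#' previous box dilated by `margin_px`. A component claimed by two instances,
#' or two instances' boxes coming to intersect, marks both instances
#' `overlapped` (recording `overlap_h`, first occurrence only); overlap is
#' irreversible and later closes the measurement window. An instance whose
#' dilated box catches no component for `lost_after` consecutive frames
#' without ever having grown is marked `lost` (seed drifted away).
#'
#' @param tracks A `seed_tracks` tibble.
#' @param root_mask Binary root mask for this frame.
#' @param frame_h Acquisition hour of this frame.
#' @param margin_px Box dilation for component claiming (default 5: bridges
#'   small discontinuities without reaching neighbouring seeds).
#' @param lost_after Consecutive empty frames before a never-grown instance
#'   is declared lost.
#' @return The updated `seed_tracks` tibble.
#' @export
update_tracks <- function(tracks, root_mask, frame_h, margin_px = 5,
                          lost_after = 3) {
  cc <- label_components(root_mask, 8)
  comps <- cc$components
  H <- nrow(root_mask); W <- ncol(root_mask)
  n <- nrow(tracks)
  claimed_by <- vector("list", max(cc$n, 1))
  live <- which(tracks$status != "lost" & !is.na(tracks$x0))

  for (i in live) {
    dx0 <- max(tracks$x0[i] - margin_px, 0); dy0 <- max(tracks$y0[i] - margin_px, 0)
    dx1 <- min(tracks$x1[i] + margin_px, W); dy1 <- min(tracks$y1[i] + margin_px, H)
    sub <- cc$labels[(dy0 + 1):dy1, (dx0 + 1):dx1, drop = FALSE]
    labs <- unique(sub[sub != 0L])
    if (length(labs) == 0) {
      grown <- tracks$status[i] != "pre_germination"
      tracks$missed[i] <- tracks$missed[i] + 1L
      if (!grown && tracks$missed[i] >= lost_after) tracks$status[i] <- "lost"
      next
    }
    tracks$missed[i] <- 0L
    for (l in labs) claimed_by[[l]] <- c(claimed_by[[l]], i)
    sel <- comps$label %in% labs
    nx0 <- min(tracks$x0[i], comps$x0[sel]); ny0 <- min(tracks$y0[i], comps$y0[sel])
    nx1 <- max(tracks$x1[i], comps$x1[sel]); ny1 <- max(tracks$y1[i], comps$y1[sel])
    if (tracks$status[i] == "pre_germination" &&
        (nx1 - nx0) * (ny1 - ny0) > (tracks$x1[i] - tracks$x0[i]) * (tracks$y1[i] - tracks$y0[i])) {
      tracks$status[i] <- "growing"
    }
    tracks$x0[i] <- nx0; tracks$y0[i] <- ny0
    tracks$x1[i] <- nx1; tracks$y1[i] <- ny1
  }

  mark_overlap <- function(i, j) {
    for (k in c(i, j)) {
      if (is.na(tracks$overlap_h[k])) {
        tracks$overlap_h[k] <<- frame_h
        tracks$overlap_partner[k] <<- tracks$seed_id[if (k == i) j else i]
      }
      tracks$status[k] <<- "overlapped"
    }
  }
  for (l in which(lengths(claimed_by) >= 2)) {
    cl <- claimed_by[[l]]
    for (a in seq_len(length(cl) - 1)) mark_overlap(cl[a], cl[a + 1])
  }
  live <- which(tracks$status != "lost" & !is.na(tracks$x0))
  if (length(live) > 1) {
    for (ai in seq_len(length(live) - 1)) {
      for (bi in (ai + 1):length(live)) {
        i <- live[ai]; j <- live[bi]
        if (boxes_intersect(tracks[i, ], tracks[j, ])) mark_overlap(i, j)
      }
    }
  }
  tracks
}

#' Root pixels inside an instance's bounding box
#'
#' Returns every root-mask pixel within the box, including disconnected
#' fragments, so lengths stay measurable when a root's mask discontinues
#' (e.g. seed-coat occlusion).
#'
#' @param track One row of a `seed_tracks` tibble (or a list with
#'   `x0, y0, x1, y1`).
#' @param root_mask Binary root mask.
#' @return Binary submask of dimensions `(y1 - y0) x (x1 - x0)`.
#' @export
root_pixels_of <- function(track, root_mask) {
  stopifnot(!is.na(track$x0), track$x0 < track$x1, track$y0 < track$y1)
  as_mask(root_mask[(track$y0 + 1):track$y1, (track$x0 + 1):track$x1, drop = FALSE])
}
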