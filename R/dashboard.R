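#' Germination dashboard
#'
#' A grid of per-seed root-length-vs-time panels. Each panel header carries
#' the five-number summary — seed ID (row, col), germination hour, last
#' measured hour, final length (mm) and growth rate (mm/h) — and
#' non-germinated seeds are drawn as a flat red line. Optionally writes the
#' figure and a long-format datasheet CSV with every (seed, hour, mm)
#' triple.
#'
#' @param results A `plate_results` from [run_pipeline()], or a list with
#'   `summaries` and `length_series` in the same schema.
#' @param file Optional figure path (any device \pkg{ggplot2} can write,
#'   e.g. `.pdf` or `.png`).
#' @param csv Optional datasheet CSV path.
#' @param ncol Panels per dashboard row.
#' @return The ggplot object, invisibly when writing to file.
#' @export
render_dashboard <- function(results, file = NULL, csv = NULL, ncol = 8) {
  summaries <- results$summaries
  series <- results$length_series
  if (nrow(summaries) == 0) abort("dashboard needs at least one seed")
  lab <- vapply(seq_len(nrow(summaries)), function(i) {
    s <- summaries[i, ]
    if (is.na(s$germ_h)) {
      sprintf("(%d,%d) no germ", s$row, s$col)
    } else {
      sprintf("(%d,%d) %.0f %.0f %.1f %.3f", s$row, s$col, s$germ_h, s$last_h,
              s$final_length_mm, s$rate_mm_per_h)
    }
  }, character(1))
  summaries$panel <- factor(lab, levels = lab)
  series <- dplyr::left_join(series,
                             summaries[, c("seed_id", "panel", "germ_h")],
                             by = "seed_id")
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$hours, y = .data$length_mm)) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, !is.na(.data$germ_h)),
                       linewidth = 0.4, colour = "grey20", na.rm = TRUE) +
    ggplot2::geom_hline(data = summaries[is.na(summaries$germ_h), ],
                        ggplot2::aes(yintercept = 0), colour = "red",
                        linewidth = 0.6) +
    ggplot2::facet_wrap(~panel, ncol = ncol) +
    ggplot2::labs(x = "time (h)", y = "root length (mm)") +
    ggplot2::theme_minimal(base_size = 7) +
    ggplot2::theme(strip.text = ggplot2::element_text(size = 6))
  if (!is.null(csv)) {
    write_results_csv(results$length_series, csv)
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 2 + 1.2 * ncol,
                    height = 1 + 1.2 * ceiling(nrow(summaries) / ncol),
                    limitsize = FALSE)
    return(invisible(p))
  }
  p
}

#' Plot methods for pipeline results
#'
#' `autoplot()` on a `plate_results` renders the germination dashboard; on a
#' `comparison_table` it draws per-genotype growth rates with Tukey letters;
#' on a `depth_map` an image of surface heights.
#'
#' @param object The object to plot.
#' @param ... Passed through to the underlying plot builders.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.plate_results <- function(object, ...) render_dashboard(object, ...)

#' @rdname autoplot.plate_results
#' @export
autoplot.comparison_table <- function(object, ...) {
  tb <- object$table
  grp <- if ("genotype" %in% names(tb)) "genotype" else "group"
  val <- if ("rate_mm_per_h" %in% names(tb)) "rate_mm_per_h" else "mean"
  tb[[grp]] <- factor(tb[[grp]], levels = tb[[grp]])
  ggplot2::ggplot(tb, ggplot2::aes(x = .data[[grp]], y = .data[[val]])) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters),
                       vjust = -0.5, size = 4) +
    ggplot2::labs(x = NULL, y = "growth rate (mm/h)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.plate_results
#' @export
autoplot.depth_map <- function(object, ...) {
  df <- tidyr::expand_grid(x = seq_len(ncol(object$height_um)),
                           y = seq_len(nrow(object$height_um)))
  df$height_um <- as.vector(object$height_um)
  df$valid <- as.vector(object$valid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = ifelse(.data$valid, .data$height_um, NA))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "height (um)", na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
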