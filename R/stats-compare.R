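#' Shapiro-Wilk normality check
#'
#' @param x Numeric sample, 3 <= n <= 5000 and non-degenerate variance.
#' @return A one-row tibble with `W`, `p` and `n`.
#' @export
shapiro_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3 || length(x) > 5000) {
    abort("Shapiro-Wilk requires 3 <= n <= 5000")
  }
  if (sd(x) == 0) abort("Shapiro-Wilk is undefined for a constant sample")
  s <- shapiro.test(x)
  tibble(W = unname(s$statistic), p = s$p.value, n = length(x))
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Fits `value ~ group`, computes the global F test, all Tukey-adjusted
#' pairwise p-values, and letter labels such that two groups share a letter
#' if and only if their adjusted p-value is at least `alpha`. Groups whose
#' rates fail a Shapiro-Wilk normality check at 0.05 trigger a warning but
#' do not abort.
#'
#' @param data Data frame with the value and group columns.
#' @param value,group Column names (strings).
#' @param alpha Significance level for letter separation.
#' @return A `comparison_table` object; see [tidy.comparison_table()].
#' @export
anova_tukey <- function(data, value = "rate_mm_per_h", group = "genotype",
                        alpha = 0.05) {
  v <- data[[value]]; g <- data[[group]]
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- factor(g[keep], levels = unique(g[keep]))
  counts <- table(g)
  if (length(counts) < 2) abort("at least 2 groups are required")
  if (any(counts < 2)) {
    abort(sprintf("every group needs n >= 2 (offending: %s)",
                  paste(names(counts)[counts < 2], collapse = ", ")))
  }
  for (lev in levels(g)) {
    xi <- v[g == lev]
    if (length(xi) >= 3 && length(xi) <= 5000 && sd(xi) > 0) {
      p <- shapiro.test(xi)$p.value
      if (p < 0.05) {
        warn(sprintf("group %s fails Shapiro-Wilk normality (p = %.3g)", lev, p))
      }
    }
  }
  fit <- stats::aov(v ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  k <- nlevels(g)
  pmat <- matrix(1, k, k, dimnames = list(levels(g), levels(g)))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    pmat[a, b] <- pmat[b, a] <- tk[i, "p adj"]
  }
  letters <- compact_letters(pmat, alpha)
  means <- tapply(v, g, mean)
  structure(list(
    table = tibble(group = levels(g), mean = as.numeric(means[levels(g)]),
                   letters = letters[levels(g)], n = as.integer(counts[levels(g)])),
    anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
    df = an[["Df"]], pairwise = pmat, alpha = alpha,
    value = value, group = group
  ), class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat(sprintf("<comparison_table> F = %.4g, p = %.3g (one-way ANOVA, %d groups)\n",
              x$anova_F, x$anova_p, nrow(x$table)))
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insertion algorithm: starting from one letter covering all groups, each
#' significant pair splits every letter containing both members into two,
#' followed by an absorption sweep that removes letters whose group set is
#' contained in another's. The result satisfies: two groups share a letter
#' iff their adjusted p >= alpha, and no letter can be dropped without
#' breaking that rule.
#'
#' @param pmat Symmetric matrix of adjusted pairwise p-values with group
#'   names as dimnames.
#' @param alpha Significance cut.
#' @return Named character vector of letter strings, in `rownames(pmat)`
#'   order.
#' @export
compact_letters <- function(pmat, alpha = 0.05) {
  groups <- rownames(pmat)
  k <- length(groups)
  cols <- list(rep(TRUE, k))               # letters as membership vectors
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (pmat[i, j] >= alpha) next        # not significantly different
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[i] && col[j]) {            # split this letter
          a <- col; a[j] <- FALSE
          b <- col; b[i] <- FALSE
          cols[[ci]] <- a
          cols[[length(cols) + 1]] <- b
        }
      }
      ## absorption: drop letters contained in another (surviving) letter
      keep <- rep(TRUE, length(cols))
      for (ci in seq_along(cols)) {
        for (cj in seq_along(cols)) {
          if (ci == cj || !keep[cj]) next
          contained <- all(cols[[cj]][cols[[ci]]])
          if (contained && (!identical(cols[[ci]], cols[[cj]]) || ci > cj)) {
            keep[ci] <- FALSE
            break
          }
        }
      }
      cols <- cols[keep]
    }
  }
  ## redundancy sweep: a letter is dropped when every pair it makes share a
  ## letter, and every group it covers, is covered elsewhere
  repeat {
    dropped <- FALSE
    for (ci in seq_along(cols)) {
      others <- cols[-ci]
      if (length(others) == 0) break
      members <- which(cols[[ci]])
      covered_groups <- all(purrr::map_lgl(members, function(m) {
        any(purrr::map_lgl(others, ~ .x[m]))
      }))
      covered_pairs <- TRUE
      if (length(members) > 1) {
        for (a in seq_len(length(members) - 1)) {
          for (b in (a + 1):length(members)) {
            if (!any(purrr::map_lgl(others, ~ .x[members[a]] && .x[members[b]]))) {
              covered_pairs <- FALSE
            }
          }
        }
      }
      if (covered_groups && covered_pairs) {
        cols <- others
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  ord <- order(purrr::map_int(cols, ~ which(.x)[1]))
  cols <- cols[ord]
  out <- vapply(seq_len(k), function(i) {
    paste(letters[which(purrr::map_lgl(cols, ~ .x[i]))], collapse = "")
  }, character(1))
  setNames(out, groups)
}

#' Genotype comparison table from per-seed growth summaries
#'
#' Builds the germination-index / growth-rate comparison: one row per
#' genotype with the germination index over all sown seeds, the mean growth
#' rate over seeds with a defined rate, the Tukey letter and N (seeds with a
#' defined rate only, so N can fall below the sown count). Genotypes with
#' fewer than 2 measurable seeds are excluded with a warning.
#'
#' @param summaries A data frame of per-seed summaries (columns `germ_h`,
#'   `rate_mm_per_h`) with a `genotype` column, or a named list of summary
#'   tables keyed by genotype.
#' @param alpha Significance level for the letter display.
#' @return A `comparison_table` whose `table` has columns `genotype`,
#'   `germination_index`, `rate_mm_per_h`, `letters`, `n`.
#' @export
summarize_genotypes <- function(summaries, alpha = 0.05) {
  if (!is.data.frame(summaries)) {
    summaries <- dplyr::bind_rows(purrr::imap(summaries, function(df, gt) {
      dplyr::mutate(dplyr::select(df, -dplyr::any_of("genotype")), genotype = gt)
    }))
  }
  order_in <- unique(summaries$genotype)
  gi <- vapply(order_in, function(gt) {
    germination_index(summaries[summaries$genotype == gt, ])
  }, numeric(1))
  measurable <- summaries[!is.na(summaries$rate_mm_per_h), ]
  n_ok <- table(factor(measurable$genotype, levels = order_in))
  drop <- names(n_ok)[n_ok < 2]
  if (length(drop)) {
    warn(sprintf("excluding genotypes with < 2 measurable seeds: %s",
                 paste(drop, collapse = ", ")))
    measurable <- measurable[!measurable$genotype %in% drop, ]
    order_in <- setdiff(order_in, drop)
  }
  if (length(order_in) >= 2) {
    cmp <- anova_tukey(measurable, "rate_mm_per_h", "genotype", alpha)
  } else {
    m <- measurable$rate_mm_per_h
    cmp <- structure(list(
      table = tibble(group = order_in, mean = mean(m), letters = "a",
                     n = length(m)),
      anova_F = NA_real_, anova_p = NA_real_, df = NULL,
      pairwise = matrix(1, 1, 1, dimnames = list(order_in, order_in)),
      alpha = alpha, value = "rate_mm_per_h", group = "genotype"
    ), class = "comparison_table")
  }
  tb <- cmp$table[match(order_in, cmp$table$group), ]
  cmp$table <- tibble(genotype = order_in,
                      germination_index = as.numeric(gi[order_in]),
                      rate_mm_per_h = tb$mean, letters = tb$letters, n = tb$n)
  cmp
}

#' Tidy a comparison table
#'
#' broom-style accessors: `tidy()` returns the per-group rows,
#' `glance()` the one-row model summary.
#'
#' @param x A `comparison_table`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.comparison_table <- function(x, ...) x$table

#' @rdname tidy.comparison_table
#' @export
glance.comparison_table <- function(x, ...) {
  tibble(anova_F = x$anova_F, anova_p = x$anova_p,
         n_groups = nrow(x$table), alpha = x$alpha)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plain-text rendering of a comparison table
#'
#' Mirrors the published germination-index / growth-rate table layout.
#'
#' @param x A `comparison_table`.
#' @param path Optional file to write to.
#' @return The text lines, invisibly when writing.
#' @export
format_comparison <- function(x, path = NULL) {
  tb <- x$table
  if ("genotype" %in% names(tb)) {
    lines <- c(
      sprintf("%-16s %22s %18s %6s", "Genotype", "Germination index (%)",
              "Growth rate (mm/h)", "N"),
      sprintf("%-16s %22.2f %15.5f^%s %6d", tb$genotype, tb$germination_index,
              tb$rate_mm_per_h, tb$letters, tb$n),
      sprintf("Tukey; different letters indicate significantly different means (p < %.2g)",
              x$alpha))
  } else {
    lines <- c(sprintf("%-16s %12s %8s %6s", "Group", "Mean", "Letters", "N"),
               sprintf("%-16s %12.5f %8s %6d", tb$group, tb$mean, tb$letters, tb$n))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
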