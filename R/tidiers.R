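#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a permutation test
#'
#' @param x A `perm_test` object.
#' @param ... Unused.
#' @return A one-row tibble: `statistic`, `observed`, `null_mean`,
#'   `null_sd`, `p_value`, `n_perm`, `seed`, `alternative`.
#' @method tidy perm_test
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, observed = x$observed,
                 null_mean = x$null_mean, null_sd = x$null_sd,
                 p_value = x$p_value, n_perm = x$n_perm, seed = x$seed,
                 alternative = x$alternative)
}

#' @rdname tidy.perm_test
#' @method glance perm_test
#' @export
glance.perm_test <- function(x, ...) tidy(x, ...)

#' Tidy a saddle result into long form
#'
#' @param x A `saddle_result`.
#' @param ... Unused.
#' @return A tibble `quantile_1`, `quantile_2`, `mean_oe`, `n_pixels` —
#'   one row per saddle cell.
#' @method tidy saddle_result
#' @export
tidy.saddle_result <- function(x, ...) {
  Q <- x$quantiles
  tibble::tibble(
    quantile_1 = rep(seq_len(Q), Q),
    quantile_2 = rep(seq_len(Q), each = Q),
    mean_oe = as.numeric(x$saddle),
    n_pixels = as.numeric(x$counts))
}

#' One-row saddle summary
#'
#' @param x A `saddle_result`.
#' @param ... Unused.
#' @return A tibble with `AA`, `BB`, `AB`, `enrichment`, `n_quantiles`,
#'   `top_frac`.
#' @method glance saddle_result
#' @export
glance.saddle_result <- function(x, ...) {
  tibble::tibble(AA = x$AA, BB = x$BB, AB = x$AB,
                 enrichment = x$enrichment, n_quantiles = x$quantiles,
                 top_frac = x$top_frac)
}

#' Tidy a pileup into long form
#'
#' @param x A `pileup_result`.
#' @param ... Unused.
#' @return A tibble `row_offset`, `col_offset` (bins from the window
#'   center), `mean_oe`, `n_windows`.
#' @method tidy pileup_result
#' @export
tidy.pileup_result <- function(x, ...) {
  n <- nrow(x$pileup)
  ctr <- (n + 1) / 2
  tibble::tibble(
    row_offset = rep(seq_len(n) - ctr, n),
    col_offset = rep(seq_len(n) - ctr, each = n),
    mean_oe = as.numeric(x$pileup),
    n_windows = as.numeric(x$counts))
}

#' @rdname tidy.pileup_result
#' @method glance pileup_result
#' @export
glance.pileup_result <- function(x, ...) {
  tibble::tibble(enrichment = x$enrichment, n_windows = x$n_windows,
                 n_skipped = x$n_skipped, resolution = x$resolution)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a saddle matrix
#'
#' Quantile-by-quantile mean O/E heatmap on a log2 color scale; the
#' corners carry the AA/BB blocks whose ratio to AB is the
#' compartmentalization score.
#'
#' @param object A `saddle_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot saddle_result
#' @export
autoplot.saddle_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$quantile_2, .data$quantile_1,
                                   fill = log2(.data$mean_oe))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = "log2 O/E") +
    ggplot2::labs(
      x = "E1 quantile", y = "E1 quantile",
      title = sprintf("Saddle: (AA+BB)/2AB = %.3f", object$enrichment)) +
    ggplot2::theme_minimal()
}

#' Plot a pileup matrix
#'
#' @param object A `pileup_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pileup_result
#' @export
autoplot.pileup_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$col_offset, .data$row_offset,
                                   fill = log2(.data$mean_oe))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", name = "log2 O/E") +
    ggplot2::labs(
      x = "offset (bins)", y = "offset (bins)",
      title = sprintf("Pileup: central 3x3 = %.3f (%d windows)",
                      object$enrichment, object$n_windows)) +
    ggplot2::theme_minimal()
}

#' Plot a permutation test
#'
#' Null histogram with the observed statistic marked.
#'
#' @param object A `perm_test`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot perm_test
#' @export
autoplot.perm_test <- function(object, ...) {
  df <- tibble::tibble(null = object$null)
  ggplot2::ggplot(df, ggplot2::aes(.data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, color = "#b2182b",
                        linewidth = 1) +
    ggplot2::labs(
      x = object$statistic, y = "permutations",
      title = sprintf("observed = %.3f, p = %.4g", object$observed,
                      object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot an insulation track
#'
#' @param track An insulation tibble from [insulation_score()] (row-bind
#'   chromosomes as needed).
#' @param boundaries Optional tibble `chrom`, `bin` of boundary positions
#'   to mark.
#' @return A ggplot faceted by chromosome.
#' @export
plot_insulation <- function(track, boundaries = NULL) {
  p <- ggplot2::ggplot(track,
                       ggplot2::aes(.data$start, .data$insulation)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "insulation (log2)") +
    ggplot2::theme_minimal()
  if (!is.null(boundaries)) {
    res <- attr(track, "resolution")
    b <- boundaries
    b$start <- b$bin * res
    p <- p + ggplot2::geom_vline(data = b,
                                 ggplot2::aes(xintercept = .data$start),
                                 linetype = "dashed", color = "grey50")
  }
  p
}

#' Plot a GSEA running sum
#'
#' @param x A `perm_test` from [length_rank_gsea()].
#' @return A ggplot of the running enrichment score over the length rank.
#' @export
plot_gsea <- function(x) {
  stopifnot(!is.null(x$running_sum))
  ggplot2::ggplot(x$running_sum,
                  ggplot2::aes(.data$rank, .data$running_sum)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, color = "grey60") +
    ggplot2::geom_rug(data = x$running_sum[x$running_sum$hit, ],
                      sides = "b", length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(
      x = "loops ranked by decreasing length", y = "running enrichment",
      title = sprintf("ES = %.3f, p = %.4g", x$observed, x$p_value)) +
    ggplot2::theme_minimal()
}
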