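#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_point geom_tile
#'   geom_hline labs scale_x_continuous facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot the positional density of motif hits along the promoter window
#'
#' Histogram of hit starts in TSS-relative coordinates, faceted per TF; the
#' vertical line marks the TSS (between -1 and +1).
#'
#' @param object A `tf_scan` hit table.
#' @param binwidth Histogram bin width in bases (default 250).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tf_scan
#' @export
autoplot.tf_scan <- function(object, binwidth = 250, ...) {
  ggplot(as_tibble(object), aes(x = .data$relative_start, fill = .data$region)) +
    geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    facet_wrap(~tf_name) +
    labs(x = "position relative to TSS (bp)", y = "binding sites",
         title = "Predicted TF binding sites along promoter windows") +
    theme_minimal()
}

#' Plot master-regulator calls as a TF x group tile map
#'
#' @param object A `master_screen` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot master_screen
#' @export
autoplot.master_screen <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(group = paste(.data$hormone, .data$category, sep = "\n"))
  ggplot(d, aes(x = .data$group, y = .data$tf, fill = .data$fraction)) +
    geom_tile(color = "white") +
    labs(x = NULL, y = NULL, fill = "fraction of\ngroup genes hit",
         title = "Master regulatory TF calls") +
    theme_minimal()
}

#' M-D plot of the pairwise differential-expression result
#'
#' Log2 ratio (M) against absolute CPM difference (D), colored by call.
#'
#' @param object A `de_test` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot de_test
#' @export
autoplot.de_test <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$M, y = .data$D, color = .data$call)) +
    geom_point(alpha = 0.6) +
    ggplot2::scale_y_log10() +
    labs(x = "M (log2 CPM ratio)", y = "D (absolute CPM difference)",
         title = "Pairwise differential expression (M-D)") +
    theme_minimal()
}
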