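#' Plot a mutation-rate spectrum
#'
#' Per-bin mutation rates on a log scale with counting-noise error bars.
#'
#' @param object A `"dfe_spectrum"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dfe_spectrum <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$mu_ds > 0, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s_mid, y = .data$mu_ds)) +
    ggplot2::geom_col(width = attr(object, "ds") %||% 0.002,
                      fill = "steelblue", colour = NA) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$mu_ds - .data$err, 1e-14),
                                        ymax = .data$mu_ds + .data$err),
                           width = 0, linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "fitness coefficient s (per generation)",
                  y = expression(mu(s) %.% ds ~ "(per cell per generation)"),
                  title = "Beneficial-mutation rate spectrum")
}

#' Plot a mean-fitness track
#'
#' @param track A `"mean_fitness_track"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mean_fitness_track <- function(track, ...) {
  df <- as_tibble(track)
  ggplot2::ggplot(df[!is.na(df$x_bar), ],
                  ggplot2::aes(x = .data$generation, y = .data$x_bar)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generation", y = "mean fitness (per generation)",
                  title = "Population mean fitness from neutral-band decay")
}

#' Plot barcode trajectories
#'
#' Read frequencies over time for a sample of lineages, the classic
#' lineage-tracking fan plot.
#'
#' @param counts Barcode-count tibble.
#' @param barcodes Optional character vector to display (default: the 100
#'   highest final-frequency lineages).
#' @param highlight Optional barcodes drawn in colour on top.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(counts, barcodes = NULL, highlight = NULL) {
  freq <- count_frequencies(counts)
  if (is.null(barcodes)) {
    barcodes <- rownames(freq)[order(freq[, ncol(freq)], decreasing = TRUE)]
    barcodes <- utils::head(barcodes, 100)
  }
  df <- tibble(
    barcode = rep(barcodes, times = ncol(freq)),
    generation = rep(count_generations(counts), each = length(barcodes)),
    frequency = as.vector(freq[barcodes, , drop = FALSE])
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$frequency,
                                        group = .data$barcode)) +
    ggplot2::geom_line(alpha = 0.3, linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "lineage frequency",
                  title = "Barcode lineage trajectories")
  if (!is.null(highlight)) {
    p <- p + ggplot2::geom_line(data = df[df$barcode %in% highlight, ],
                                colour = "firebrick", linewidth = 0.6)
  }
  p
}

#' Plot the adapted fraction over time
#'
#' @param fraction Tibble from [adapted_fraction()] (optionally with extra
#'   grouping columns).
#' @return A ggplot object.
#' @export
plot_adapted_fraction <- function(fraction) {
  ggplot2::ggplot(fraction, ggplot2::aes(x = .data$generation,
                                         y = .data$adapted_fraction)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "generation", y = "adapted fraction",
                  title = "Fraction of adapted individuals")
}
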