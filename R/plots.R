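#' Plot helpers for path statistics
#'
#' Small ggplot2 wrappers around the descriptive statistics:
#' `plot_path_lengths()` draws the path-length histogram;
#' `plot_distance_ccdf()` and `plot_transit_ccdf()` draw the
#' complementary cumulative distributions of travel distance and days in
#' transit (optionally for several labelled collections);
#' `plot_entry_exit()` draws per-year entry/exit turnover rates;
#' `plot_year_similarity()` draws the year-to-year path-similarity series.
#' Each returns a ggplot object for further styling.
#'
#' @param paths A path tibble, or for the CCDF helpers a named list of path
#'   tibbles to overlay (e.g. `list(FIFO = a, LIFO = b)`).
#' @param coords Coordinate table for [path_distances()].
#' @param rates Output of [entry_exit_rates()].
#' @param sim Output of [year_to_year_similarity()].
#' @name pathtrace-plots
NULL

as_path_list <- function(paths) {
  if (is.data.frame(paths)) list(paths = paths) else paths
}

#' @rdname pathtrace-plots
#' @export
plot_path_lengths <- function(paths) {
  h <- path_length_histogram(paths)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$length, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "path length (distribution steps)", y = "paths") +
    ggplot2::theme_minimal()
}

ccdf_frame <- function(series) {
  dplyr::bind_rows(lapply(names(series), function(nm) {
    dplyr::mutate(empirical_ccdf(series[[nm]]), set = nm)
  }))
}

#' @rdname pathtrace-plots
#' @export
plot_distance_ccdf <- function(paths, coords) {
  pl <- as_path_list(paths)
  df <- ccdf_frame(lapply(pl, function(p) path_distances(p, coords)$per_path$total_km))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$ccdf,
                                   colour = .data$set)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "total travel distance (km)", y = "P(distance > x)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname pathtrace-plots
#' @export
plot_transit_ccdf <- function(paths) {
  pl <- as_path_list(paths)
  df <- ccdf_frame(lapply(pl, function(p) transit_time_distribution(p)$per_path$days))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$ccdf,
                                   colour = .data$set)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "days in transit", y = "P(transit > x)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname pathtrace-plots
#' @export
plot_entry_exit <- function(rates) {
  df <- tidyr::pivot_longer(rates, c("entry_rate", "exit_rate"),
                            names_to = "rate", values_to = "value")
  ggplot2::ggplot(stats::na.omit(df),
                  ggplot2::aes(x = .data$year, y = .data$value,
                               colour = .data$rate)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "year", y = "rate", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname pathtrace-plots
#' @export
plot_year_similarity <- function(sim) {
  ggplot2::ggplot(sim, ggplot2::aes(x = .data$year_to, y = .data$jaccard)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "year", y = "unique Jaccard vs previous year") +
    ggplot2::theme_minimal()
}

#' @rdname pathtrace-plots
#' @param object A `path_reconstruction` object.
#' @param ... Unused.
#' @export
autoplot.path_reconstruction <- function(object, ...) {
  plot_path_lengths(object$paths) +
    ggplot2::ggtitle(paste0("Completed paths (", toupper(object$policy), ")"))
}
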