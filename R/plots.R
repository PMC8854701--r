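# ggplot2 displays for the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.sbs_spectrum <- function(object, ...) {
  d <- as_tibble(object)
  d$sub <- sub(".*\\[(.>.)\\].*", "\\1", d$class)
  d$flanks <- paste0(substr(d$class, 1, 1), ".", substr(d$class, 7, 7))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$flanks, y = .data$count,
                                  fill = .data$sub)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(~sub, scales = "free_x") +
    ggplot2::labs(x = "5'.3' flanking bases", y = "SNV count",
                  title = "96-class mutation spectrum") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = 90, vjust = 0.5, size = 5))
}

#' @exportS3Method ggplot2::autoplot
autoplot.exposure_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$signature, y = .data$exposure,
                                  alpha = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$interval_low,
                                        ymax = .data$interval_high),
                           width = 0.2, alpha = 1) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(y = "exposure (fraction of mutations)",
                  title = "Signature exposures with 90% intervals") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.dnds_fit <- function(object, ...) {
  d <- as_tibble(object)
  xvar <- if ("set" %in% names(d)) "set" else "gene"
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[xvar]], y = .data$omega,
                                  color = .data$class)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.4)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0.2,
                           position = ggplot2::position_dodge(0.4)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "dN/dS (omega)", title = "Selection estimates") +
    ggplot2::theme_minimal()
}

#' Plot expansion / CN-LOH timing estimates
#'
#' @param estimates One or more `timing_estimate` rows (bind them with
#'   `dplyr::bind_rows()`), optionally carrying a `cluster_id` column.
#' @return A ggplot.
#' @export
plot_timing <- function(estimates) {
  d <- as_tibble(estimates)
  if (!"cluster_id" %in% names(d)) d$cluster_id <- as.character(seq_len(nrow(d)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$cluster_id, y = .data$estimate,
                                  color = .data$event)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.15) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$age), linetype = 3) +
    ggplot2::labs(y = "chronological age (years)",
                  title = "Timing of clonal events") +
    ggplot2::theme_minimal()
}

#' Plot clone clusters on the spatial grid
#'
#' @param clusters A `clone_clusters` object.
#' @param glands Gland tibble with `grid_row`, `grid_col`.
#' @return A ggplot tile map of the lattice colored by cluster.
#' @export
plot_cluster_map <- function(clusters, glands) {
  d <- dplyr::left_join(clusters$assignments, as_tibble(glands),
                        by = "gland_id")
  d$cluster_id[is.na(d$cluster_id)] <- "singleton"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$grid_col, y = .data$grid_row,
                                  fill = .data$cluster_id)) +
    ggplot2::geom_tile(color = "white", alpha = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "grid column", y = "grid row", fill = "cluster",
                  title = "Clone clusters on the sampling grid") +
    ggplot2::theme_minimal()
}
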