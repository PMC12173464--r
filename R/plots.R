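#' Manhattan plot of a genome scan
#'
#' @param results A [wald_scan()] tibble.
#' @param threshold Optional genome-wide p-value threshold drawn as a line.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, threshold = NULL) {
  tabs <- qq_manhattan_tables(results)
  d <- tabs$manhattan
  if (is.null(d)) abort("results need chrom and pos_bp columns")
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$cum_bp / 1e6,
                                        y = .data$neglog10p,
                                        colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::labs(x = "cumulative position (Mb)",
                  y = expression(-log[10](p)),
                  subtitle = sprintf("lambda = %.2f", tabs$lambda)) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(threshold),
                                   colour = "red", linetype = 2)
  }
  gg
}

#' QQ plot of scan p-values
#'
#' @param results A tibble with a `p.value` column (or a numeric vector).
#' @return A ggplot object.
#' @export
plot_qq <- function(results) {
  if (is.numeric(results)) results <- tibble(p.value = results)
  tabs <- qq_manhattan_tables(results)
  ggplot2::ggplot(tabs$qq, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(expected ~ -log[10](p)),
                  y = expression(observed ~ -log[10](p)),
                  subtitle = sprintf("lambda = %.2f", tabs$lambda)) +
    ggplot2::theme_minimal()
}

#' Endpoint time-course plot (strain means by day)
#'
#' @param pheno Long-format phenotype tibble.
#' @param endpoint Endpoint column name.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(pheno, endpoint) {
  d <- pheno %>%
    group_by(.data$strain, .data$day) %>%
    summarise(value = mean(.data[[endpoint]], na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$day, .data$value, group = .data$strain)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::stat_summary(ggplot2::aes(group = 1), fun = mean,
                          geom = "line", colour = "red", linewidth = 1) +
    ggplot2::labs(x = "testing day", y = endpoint) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.panel_lmm <- function(object, ...) {
  d <- tidy(object) %>% filter(.data$kind == "variance")
  ggplot2::ggplot(d, ggplot2::aes(.data$term, .data$estimate,
                                  fill = .data$structure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "variance component") +
    ggplot2::theme_minimal()
}
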