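#' Plot a differential-abundance result
#'
#' Log10 fold-change per taxon with its credible interval, coloured by the
#' 95% posterior-difference decision; positive values are taxa more
#' abundant in the first group of the comparison.
#'
#' @param object a `dmm_da` tibble from [compare_groups()].
#' @param flagged_only show only flagged taxa.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dmm_da <- function(object, flagged_only = FALSE, ...) {
  gr <- attr(object, "groups")
  df <- if (flagged_only) dplyr::filter(object, .data$flagged) else object
  df <- dplyr::mutate(df, taxon = stats::reorder(.data$taxon, .data$log10_fc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_fc, y = .data$taxon,
                                   colour = .data$flagged)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lfc_lo,
                                         xmax = .data$lfc_hi), height = 0) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#B2182B",
                                            `FALSE` = "grey65")) +
    ggplot2::labs(x = bquote(log[10] ~ "fold change (" * .(gr[1]) ~ "/" ~
                               .(gr[2]) * ")"),
                  y = NULL, colour = "flagged") +
    ggplot2::theme_minimal()
}

#' Plot a principal-coordinate ordination
#'
#' @param x a `pcoa_result` from [pcoa()].
#' @param meta optional metadata tibble; points are coloured by `group`.
#' @param axes which two axes to draw.
#' @return a ggplot.
#' @export
plot_pcoa <- function(x, meta = NULL, axes = c(1, 2)) {
  df <- x$coordinates
  ax <- paste0("Axis", axes)
  if (!is.null(meta)) {
    df <- dplyr::left_join(df, meta[, c("sample_id", "group")], by = "sample_id")
  } else {
    df$group <- "sample"
  }
  lab <- sprintf("%s (%.1f%%)", ax, 100 * x$rel_eig[axes])
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab[1], y = lab[2], colour = NULL) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot residual biomass by inoculum
#'
#' Bar chart of mean residual response per inoculum (after removing
#' genotype and block effects) with standard-error bars and the Tukey HSD
#' compact letter display.
#'
#' @param tbl a phenotype tibble.
#' @param response response column name.
#' @return a ggplot.
#' @export
plot_residual_means <- function(tbl, response) {
  rs <- residual_summary(tbl, response)
  letters <- tukey_hsd(tbl, response, "inoculum")$letters
  df <- dplyr::left_join(rs, letters, by = c(inoculum = "level"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$inoculum, y = .data$mean_resid,
                                   fill = .data$inoculum)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_resid - .data$se,
                                        ymax = .data$mean_resid + .data$se),
                           width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters,
                                    y = .data$mean_resid +
                                      sign(.data$mean_resid) * 2.5 * .data$se),
                       vjust = 0) +
    ggplot2::labs(x = "soil inoculum",
                  y = paste("residual", gsub("_", " ", response)),
                  fill = NULL) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
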