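#' Plot editing frequencies per category
#'
#' Bar chart of F_S, F_R and F_D per species, the visual companion of
#' [category_frequencies()].
#'
#' @param object An `edit_freq_stats` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.edit_freq_stats <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$category, y = .data$frequency,
                               fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$species)) +
    ggplot2::labs(x = NULL, y = "fraction of potential sites edited") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot editing-level distributions per category
#'
#' Box plots of editing levels (after the read-coverage filter) by category
#' and species, the visual companion of [category_levels()].
#'
#' @param classified Classified editing sites.
#' @param min_coverage Coverage filter (default 400 reads).
#' @return A ggplot object.
#' @export
plot_category_levels <- function(classified, min_coverage = 400) {
  dat <- classified |>
    filter(.data$category %in% c("SYN", "RESTORATIVE", "DIVERSIFYING"),
           .data$coverage >= min_coverage) |>
    mutate(category = factor(.data$category,
                             levels = c("SYN", "RESTORATIVE", "DIVERSIFYING")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$category, y = .data$level,
                                    fill = .data$category)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$species)) +
    ggplot2::labs(x = NULL, y = "editing level") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Plot a bootstrap dN/dS contrast
#'
#' Histogram of the bootstrap distribution of the group difference in
#' pooled dN/dS, with the observed difference marked.
#'
#' @param object A `dnds_boot` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dnds_boot <- function(object, ...) {
  d <- object$boot |>
    mutate(difference = .data$ratio_high - .data$ratio_low)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$difference)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$difference, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "dN/dS (high neural) - dN/dS (low neural)",
                  y = "bootstrap replicates",
                  title = sprintf("%s contrast, two-sided P = %.3g",
                                  object$class_label, object$p_two_sided)) +
    ggplot2::theme_minimal()
}

#' Plot bin-wise frequencies behind an ADP estimate
#'
#' Diversifying and synonymous frequencies per editing-level bin; the
#' excess of F_D over F_S in a bin is the adaptive signal.
#'
#' @param object An `adp_estimate` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.adp_estimate <- function(object, ...) {
  d <- object$bins |>
    mutate(bin = sprintf("%d-%d%%", round(.data$bin_lo * 100),
                         round(.data$bin_hi * 100))) |>
    mutate(bin = factor(.data$bin, levels = unique(.data$bin))) |>
    tidyr::pivot_longer(c("f_diversifying", "f_synonymous"),
                        names_to = "category", values_to = "frequency")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$frequency,
                                  fill = .data$category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(f_diversifying = "#7570b3",
                                          f_synonymous = "grey60"),
                               labels = c("diversifying", "synonymous")) +
    ggplot2::labs(x = "editing level bin", y = "frequency", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
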