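#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a gene-bootstrap dN/dS contrast
#'
#' @param x A `dnds_boot` object.
#' @param ... Unused.
#' @return The bootstrap replicate tibble (`replicate`, `ratio_high`,
#'   `ratio_low`).
#' @export
tidy.dnds_boot <- function(x, ...) x$boot

#' One-row summary of a gene-bootstrap dN/dS contrast
#'
#' @param x A `dnds_boot` object.
#' @param ... Unused.
#' @export
glance.dnds_boot <- function(x, ...) {
  tibble(class = x$class_label,
         dnds_high = x$observed$dnds[1], dnds_low = x$observed$dnds[2],
         difference = x$difference,
         p_two_sided = x$p_two_sided, p_one_sided = x$p_one_sided,
         B = x$B, n_dropped = x$n_dropped)
}

#' Tidy an ADP estimate
#'
#' @param x An `adp_estimate` object.
#' @param ... Unused.
#' @return The per-bin tibble.
#' @export
tidy.adp_estimate <- function(x, ...) x$bins

#' One-row summary of an ADP estimate
#'
#' @param x An `adp_estimate` object.
#' @param ... Unused.
#' @export
glance.adp_estimate <- function(x, ...) {
  tibble(total_adp = x$total_adp, n_diversifying = x$n_diversifying,
         adaptive_fraction = x$adaptive_fraction)
}

#' Tidy a replacement test
#'
#' @param x A `replacement_test` object.
#' @param ... Unused.
#' @return Per-kind counts and replacement fractions.
#' @export
tidy.replacement_test <- function(x, ...) x$fractions

#' One-row summary of a replacement test
#'
#' @param x A `replacement_test` object.
#' @param ... Unused.
#' @export
glance.replacement_test <- function(x, ...) {
  tibble(p_value = x$p_value, control_p = x$control_p,
         fraction_nonsynonymous = x$fractions$fraction_replaced[1],
         fraction_synonymous = x$fractions$fraction_replaced[2],
         diversifying_only = x$diversifying_only)
}
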