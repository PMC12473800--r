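# ggplot2 visualisations. Each assessment object gets an autoplot()
# method; plot_* helpers expose the same figures under explicit names.

#' Plot per-element contamination factors
#'
#' Bar chart of Cf per element, faceted by site, coloured by
#' contamination category, with the Cf = 1 background line.
#'
#' @param object A `sedrisk_indices` tibble from [compute_indices()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sedrisk_indices <- function(object, ...) {
  df <- as_tibble(object)
  facet <- intersect(c("site", "zone"), names(df))[1]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$element, y = .data$cf,
                                   fill = .data$cf_category)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(facet) +
    ggplot2::labs(x = NULL, y = "Contamination factor (Cf)",
                  fill = "Category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @rdname autoplot.sedrisk_indices
#' @param indices A `sedrisk_indices` tibble.
#' @export
plot_contamination_factors <- function(indices, ...) {
  autoplot.sedrisk_indices(indices, ...)
}

#' Plot potential ecological risk by site
#'
#' Bars of RI per site with the four band thresholds (95, 190, 380) as
#' reference lines, coloured by zone.
#'
#' @param object An `eco_risk_assessment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.eco_risk_assessment <- function(object, ...) {
  ggplot2::ggplot(object$sites,
                  ggplot2::aes(x = stats::reorder(.data$site, .data$ri),
                               y = .data$ri, fill = .data$zone)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(95, 190, 380), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Potential ecological risk index (RI)",
                  fill = "Zone") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.eco_risk_assessment
#' @param eco An `eco_risk_assessment`.
#' @export
plot_ecological_risk <- function(eco, ...) {
  autoplot.eco_risk_assessment(eco, ...)
}

#' Plot hazard index and total carcinogenic risk
#'
#' Two-panel summary: HI per site and receptor with the HI = 1 threshold,
#' and TCR on a log scale with the 1e-6 / 1e-4 acceptability band.
#'
#' @param object A `health_risk_assessment`.
#' @param ... Unused.
#' @return A ggplot object, facetted by measure.
#' @exportS3Method ggplot2::autoplot
autoplot.health_risk_assessment <- function(object, ...) {
  df <- object$summary |>
    tidyr::pivot_longer(cols = c("hi", "tcr"), names_to = "measure",
                        values_to = "value") |>
    mutate(measure = ifelse(.data$measure == "hi", "Hazard index",
                            "Total carcinogenic risk"))
  thresholds <- tibble(
    measure = c("Hazard index", "Total carcinogenic risk",
                "Total carcinogenic risk"),
    value = c(1, 1e-6, 1e-4))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$value,
                                   fill = .data$receptor)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(data = thresholds,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::facet_wrap("measure", scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Receptor") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname autoplot.health_risk_assessment
#' @param health A `health_risk_assessment`.
#' @export
plot_health_risk <- function(health, ...) {
  autoplot.health_risk_assessment(health, ...)
}

#' Plot per-metal contribution shares
#'
#' Stacked bars of each element's percentage contribution to HI and TCR
#' per site and receptor.
#'
#' @param health A `health_risk_assessment`.
#' @return A ggplot object.
#' @export
plot_risk_contributions <- function(health) {
  df <- health$by_element |>
    tidyr::pivot_longer(cols = c("hi_share", "tcr_share"),
                        names_to = "measure", values_to = "share") |>
    mutate(measure = ifelse(.data$measure == "hi_share", "HI", "TCR"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$receptor, y = .data$share,
                                   fill = .data$element)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(.data$measure ~ .data$site) +
    ggplot2::labs(x = NULL, y = "Contribution (%)", fill = "Element") +
    ggplot2::theme_minimal()
}
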