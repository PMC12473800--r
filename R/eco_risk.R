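# Ecological risk: per-element risk factor Er = T * Cf, aggregate potential
# ecological risk index RI with its four bands, and the rank-based site
# ranking index SRI with median +/- SD categories across the site set.

ri_band <- function(ri) {
  # printed band closure: low <= 95 < moderate <= 190 < considerable <= 380 < very high
  dplyr::case_when(
    ri <= 95 ~ "low",
    ri <= 190 ~ "moderate",
    ri <= 380 ~ "considerable",
    TRUE ~ "very high")
}

#' Per-element ecological risk factor (Er)
#'
#' `Er = T * Cf`, the product of an element's toxic response factor and
#' its contamination factor.
#'
#' @param tr Named numeric vector of toxic response factors (see
#'   [toxic_response_factors()]).
#' @param cf Contamination factor(s) (>= 0).
#' @param element Element symbol(s), recycled against `cf`.
#' @return Numeric vector of Er values.
#' @export
ecological_risk_factor <- function(tr, cf, element) {
  missing <- setdiff(unique(element), names(tr))
  if (length(missing) > 0) {
    abort(sprintf("no toxic response factor for element(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(cf < 0, na.rm = TRUE)) abort("Cf must be non-negative")
  unname(tr[element]) * cf
}

#' Potential ecological risk index (RI)
#'
#' Sum of per-element ecological risk factors, classified into four bands:
#' low (RI <= 95), moderate (95 < RI <= 190), considerable
#' (190 < RI <= 380), very high (RI > 380).
#'
#' @param er_values Numeric vector (or named vector) of Er values.
#' @return One-row tibble with `ri` and `ri_category`.
#' @export
potential_ecological_risk <- function(er_values) {
  er_values <- er_values[!is.na(er_values)]
  if (length(er_values) == 0) abort("RI requires at least one Er value")
  ri <- sum(er_values)
  tibble(ri = ri, ri_category = ri_band(ri))
}

#' Site ranking index (SRI) from a rank table
#'
#' The pure SRI formula: given each contaminant's ascending rank under the
#' Cf ordering and under the Igeo ordering, the per-contaminant rank
#' `n_i` is the average of the two, the weighted contamination index is
#' `W = sum(n_i) / sum(1:S)` with `S` contaminants, and
#' `SRI = W / S * 100`. Ties are broken by average rank. An identity
#' ranking (`n_i = i`) gives `W = 1` and `SRI = 100 / S`.
#'
#' @param cf_rank,igeo_rank Numeric vectors of ascending ranks over the
#'   `S` contaminants (length >= 2).
#' @return One-row tibble with `sri`, `w`, `s`.
#' @seealso [assess_ecological_risk()] for how per-site ranks are derived
#'   from data.
#' @export
site_ranking_index <- function(cf_rank, igeo_rank = cf_rank) {
  s <- length(cf_rank)
  if (s < 2) abort("SRI requires at least 2 contaminants")
  if (length(igeo_rank) != s) {
    abort("cf_rank and igeo_rank must have the same length")
  }
  n_i <- (cf_rank + igeo_rank) / 2
  w <- sum(n_i) / sum(seq_len(s))
  tibble(sri = w / s * 100, w = w, s = s)
}

#' Categorise SRI values across a site collection
#'
#' Median +/- SD bands over the supplied SRI values: low
#' (SRI < median - SD), moderate ([median - SD, median)), high
#' ([median, median + SD]), severe (> median + SD). When all sites are
#' identical the SD is 0 and every site falls in the "high" band
#' (SRI = median); this degenerate collapse is intentional.
#'
#' @param sri Numeric vector of SRI values (one per site).
#' @return Character vector of category labels.
#' @export
sri_categories <- function(sri) {
  m <- median(sri)
  s <- if (length(sri) > 1) sd(sri) else 0
  dplyr::case_when(
    sri < m - s ~ "low",
    sri < m ~ "moderate",
    sri <= m + s ~ "high",
    TRUE ~ "severe")
}

#' Ecological risk assessment over a sample table
#'
#' Computes site-mean contamination factors against a background, the
#' per-element risk factors Er and their site sum RI with band labels, and
#' the site ranking index SRI with median +/- SD categories.
#'
#' Per-site SRI ranks are derived across the site collection: for each
#' contaminant, sites are ranked ascending by site-mean Cf and (equivalently,
#' since Igeo is monotone in Cf) by Igeo, ties broken by average rank; each
#' site's rank vector then enters [site_ranking_index()].
#'
#' @param samples Validated sample tibble.
#' @param background Background baseline (see [resolve_background()]).
#' @param tr Named toxic response factors; default
#'   [toxic_response_factors()].
#' @param elements Elements entering RI; default [default_risk_elements()]
#'   intersected with the available data and factors.
#' @param sri_elements Elements entering SRI; default
#'   [default_index_elements()] intersected with the data.
#' @return An object of class `eco_risk_assessment`: list with
#'   \describe{
#'     \item{er}{long tibble (site, zone, element, cf, igeo, er)}
#'     \item{sites}{tibble with one row per site: `ri`, `ri_category`,
#'       `sri`, `sri_category`}
#'     \item{background_name, elements}{provenance}
#'   }
#' @export
assess_ecological_risk <- function(samples,
                                   background = "taylor_mclennan_1995",
                                   tr = toxic_response_factors(),
                                   elements = NULL,
                                   sri_elements = NULL) {
  idx <- compute_indices(samples, background = background, per = "site")
  ref_name <- attr(idx, "background_name")
  elements <- elements %||%
    intersect(default_risk_elements(), intersect(unique(idx$element), names(tr)))
  missing_tr <- setdiff(elements, names(tr))
  if (length(missing_tr) > 0) {
    abort(sprintf("no toxic response factor for element(s): %s",
                  paste(missing_tr, collapse = ", ")))
  }
  sri_elements <- sri_elements %||%
    intersect(default_index_elements(), unique(idx$element))

  er <- idx |>
    filter(.data$element %in% elements) |>
    mutate(er = ecological_risk_factor(tr, .data$cf, .data$element)) |>
    select("site", "zone", "element", "cf", "igeo", "er")

  sites_ri <- er |>
    group_by(.data$site, .data$zone) |>
    summarise(ri = sum(.data$er), .groups = "drop") |>
    mutate(ri_category = ri_band(.data$ri))

  # cross-site ascending ranks per contaminant, from Cf and Igeo orderings
  ranked <- idx |>
    filter(.data$element %in% sri_elements) |>
    group_by(.data$element) |>
    mutate(cf_rank = rank(.data$cf, ties.method = "average"),
           igeo_rank = rank(.data$igeo, ties.method = "average")) |>
    ungroup()
  sites_sri <- ranked |>
    group_by(.data$site) |>
    summarise(sri = site_ranking_index(.data$cf_rank, .data$igeo_rank)$sri,
              .groups = "drop") |>
    mutate(sri_category = sri_categories(.data$sri))

  sites <- left_join(sites_ri, sites_sri, by = "site") |>
    arrange(.data$site)

  structure(
    list(er = er, sites = sites, background_name = ref_name,
         elements = elements, sri_elements = sri_elements),
    class = "eco_risk_assessment")
}

#' @export
print.eco_risk_assessment <- function(x, ...) {
  cat(sprintf("<eco_risk_assessment> background: %s; %d element(s)\n",
              x$background_name, length(x$elements)))
  print(x$sites)
  invisible(x)
}

#' @rdname assess_ecological_risk
#' @param x An `eco_risk_assessment`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.eco_risk_assessment <- function(x, ...) {
  x$er
}

#' @rdname assess_ecological_risk
#' @exportS3Method generics::glance
glance.eco_risk_assessment <- function(x, ...) {
  tibble(n_sites = nrow(x$sites),
         n_elements = length(x$elements),
         background = x$background_name,
         max_ri = max(x$sites$ri),
         max_ri_site = x$sites$site[which.max(x$sites$ri)],
         n_above_low = sum(x$sites$ri > 95))
}
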