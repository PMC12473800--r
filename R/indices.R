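# Contamination indices. Scalar kernels are vectorised and return tibbles
# carrying the value and its category label; compute_indices() applies them
# across a sample table against a chosen geochemical background.
#
# Band closure convention: bands are left-closed/right-open except where the
# classification is quoted in strict form (Cf < 1 low, Cf > 6 very high is
# equivalent to Cf >= 6 under the left-closed rule used here for the top
# band; EF > 1.5 anthropogenic is strict).

cf_breaks <- c(-Inf, 1, 3, 6, Inf)
cf_labels <- c("low", "moderate", "high", "very high")

igeo_breaks <- c(-Inf, 0, 1, 2, 3, 4, 5, Inf)
igeo_labels <- c("unpolluted", "unpolluted to moderately polluted",
                 "moderately polluted", "moderately to heavily polluted",
                 "heavily polluted", "heavily to extremely polluted",
                 "extremely polluted")

mcd_breaks <- c(-Inf, 1.5, 2, 4, 8, 16, 32, Inf)
mcd_labels <- c("nil to very low", "low", "moderate", "high", "very high",
                "extremely high", "ultra high")

band_label <- function(value, breaks, labels, right = FALSE) {
  # right = FALSE: left-closed/right-open intervals [a, b)
  as.character(cut(value, breaks = breaks, labels = labels, right = right))
}

# Igeo bands are right-closed per the Muller scheme: class k is (k-1, k].
igeo_label <- function(value) {
  band_label(value, igeo_breaks, igeo_labels, right = TRUE)
}

#' Contamination factor (Cf)
#'
#' Ratio of the measured concentration to its geochemical background.
#' Categories: low (Cf < 1), moderate (1 <= Cf < 3), high (3 <= Cf < 6),
#' very high (Cf >= 6).
#'
#' @param c_sample Measured concentration(s), mg/kg (>= 0).
#' @param c_background Background concentration(s), mg/kg (> 0).
#' @return Tibble with columns `index`, `value`, `category`, one row per
#'   input.
#' @examples
#' contamination_factor(0.4, 0.1) # 4-fold enrichment, "high"
#' @export
contamination_factor <- function(c_sample, c_background) {
  if (any(!is.finite(c_background) | c_background <= 0)) {
    abort("background concentration must be strictly positive")
  }
  if (any(c_sample < 0, na.rm = TRUE)) {
    abort("sample concentration must be non-negative")
  }
  value <- c_sample / c_background
  tibble(index = "Cf", value = value,
         category = band_label(value, cf_breaks, cf_labels))
}

#' Geoaccumulation index (Igeo)
#'
#' `log2(c_sample / (1.5 * c_background))`; the factor 1.5 buffers natural
#' background variability. Seven Muller classes from unpolluted (Igeo <= 0)
#' to extremely polluted (Igeo > 5). A zero concentration is reported as
#' the sentinel category `"below scale"` with `-Inf` value rather than an
#' error.
#'
#' @inheritParams contamination_factor
#' @return Tibble with columns `index`, `value`, `category`.
#' @export
geoaccumulation_index <- function(c_sample, c_background) {
  if (any(!is.finite(c_background) | c_background <= 0)) {
    abort("background concentration must be strictly positive")
  }
  if (any(c_sample < 0, na.rm = TRUE)) {
    abort("sample concentration must be non-negative")
  }
  value <- log2(c_sample / (1.5 * c_background))
  category <- igeo_label(value)
  category[!is.na(c_sample) & c_sample == 0] <- "below scale"
  tibble(index = "Igeo", value = value, category = category)
}

#' Enrichment factor (EF)
#'
#' Double ratio of the element to the reference element (Fe, chosen for its
#' geochemical stability) in the sample versus the background:
#' `(c_sample/fe_sample) / (c_background/fe_background)`. Values strictly
#' greater than 1.5 flag anthropogenic enrichment.
#'
#' @param c_sample,fe_sample Element and Fe concentrations in the sample
#'   (mg/kg, > 0).
#' @param c_background,fe_background Element and Fe background values
#'   (mg/kg, > 0).
#' @return Tibble with columns `index`, `value`, `anthropogenic`,
#'   `category`.
#' @export
enrichment_factor <- function(c_sample, fe_sample, c_background,
                              fe_background) {
  if (any(c(fe_sample, c_background, fe_background) <= 0) ||
      any(!is.finite(c(fe_sample, c_background, fe_background)))) {
    abort("enrichment factor requires strictly positive Fe and background values")
  }
  if (any(c_sample < 0, na.rm = TRUE)) {
    abort("sample concentration must be non-negative")
  }
  value <- (c_sample / fe_sample) / (c_background / fe_background)
  anthropogenic <- value > 1.5
  tibble(index = "EF", value = value, anthropogenic = anthropogenic,
         category = ifelse(anthropogenic, "anthropogenic", "natural"))
}

#' Pollution load index (PLI)
#'
#' Geometric mean of a vector of contamination factors. A PLI above 1
#' flags overall contamination; the stricter site-level criterion
#' `PLI > 1.3` is reported as a secondary flag.
#'
#' @param cf_values Numeric vector of contamination factors (> 0).
#' @return One-row tibble with `index`, `value`, `n_elements`,
#'   `contaminated` (PLI > 1), `exceeds_site_criterion` (PLI > 1.3) and
#'   `category`.
#' @export
pollution_load_index <- function(cf_values) {
  cf_values <- cf_values[!is.na(cf_values)]
  if (length(cf_values) == 0) abort("PLI requires a nonempty Cf vector")
  if (any(cf_values <= 0)) {
    abort("PLI is degenerate for non-positive Cf values")
  }
  value <- exp(mean(log(cf_values)))
  tibble(index = "PLI", value = value, n_elements = length(cf_values),
         contaminated = value > 1,
         exceeds_site_criterion = value > 1.3,
         category = ifelse(value > 1, "polluted", "unpolluted"))
}

#' Modified contamination degree (mCd)
#'
#' Arithmetic mean of a vector of contamination factors, with the
#' Abrahim & Parker doubling bands: nil to very low (< 1.5), low [1.5, 2),
#' moderate [2, 4), high [4, 8), very high [8, 16), extremely high
#' [16, 32), ultra high (>= 32). By the AM-GM inequality mCd >= PLI for
#' any Cf vector.
#'
#' @param cf_values Numeric vector of contamination factors (>= 0).
#' @return One-row tibble with `index`, `value`, `n_elements`, `category`.
#' @export
modified_contamination_degree <- function(cf_values) {
  cf_values <- cf_values[!is.na(cf_values)]
  if (length(cf_values) == 0) abort("mCd requires a nonempty Cf vector")
  value <- mean(cf_values)
  tibble(index = "mCd", value = value, n_elements = length(cf_values),
         category = band_label(value, mcd_breaks, mcd_labels))
}

#' Compute per-element contamination indices over a sample table
#'
#' Applies [contamination_factor()], [geoaccumulation_index()] and, where
#' Fe is available, [enrichment_factor()] to every element with a
#' background value, after aggregating concentrations at the requested
#' level.
#'
#' @param samples Validated sample tibble (see [read_samples()]).
#' @param background Background baseline: built-in name, YAML path, or
#'   `reference_set` (see [resolve_background()]).
#' @param per Aggregation level: `"site"` (default; site means), `"zone"`
#'   (zone means) or `"sample"` (every row).
#' @param elements Element subset; defaults to the elements shared by the
#'   table and the background (Fe is always used for EF when present).
#' @return A `sedrisk_indices` tibble: grouping keys, `element`,
#'   `concentration`, `background`, `cf`, `cf_category`, `igeo`,
#'   `igeo_category`, `ef`, `ef_anthropogenic`. EF is `NA` for Fe itself
#'   and when Fe is absent.
#' @seealso [summarize_site_indices()] for PLI and mCd per group.
#' @export
compute_indices <- function(samples, background = "taylor_mclennan_1995",
                            per = c("site", "zone", "sample"),
                            elements = NULL) {
  per <- match.arg(per)
  samples <- validate_samples(samples)
  ref <- resolve_background(background)

  long <- switch(per,
    site = site_concentrations(samples),
    zone = samples_long(samples) |>
      group_by(.data$zone, .data$element) |>
      summarise(concentration = mean(.data$concentration, na.rm = TRUE),
                .groups = "drop"),
    sample = samples_long(samples))

  avail <- intersect(unique(long$element), names(ref$background))
  elements <- elements %||% avail
  missing_bg <- setdiff(elements, names(ref$background))
  if (length(missing_bg) > 0) {
    abort(sprintf("background '%s' has no value for element(s): %s",
                  ref$name, paste(missing_bg, collapse = ", ")))
  }

  keys <- intersect(names(long), c("site", "zone", "month", "replicate"))
  fe <- NULL
  if ("Fe" %in% long$element) {
    fe <- long |> filter(.data$element == "Fe") |>
      select(all_of(keys), fe_sample = "concentration")
  }

  out <- long |>
    filter(.data$element %in% elements) |>
    mutate(background = unname(ref$background[.data$element]))
  cf_tab <- contamination_factor(out$concentration, out$background)
  ig_tab <- geoaccumulation_index(out$concentration, out$background)
  out$cf <- cf_tab$value
  out$cf_category <- cf_tab$category
  out$igeo <- ig_tab$value
  out$igeo_category <- ig_tab$category

  if (!is.null(fe) && "Fe" %in% names(ref$background)) {
    out <- left_join(out, fe, by = keys)
    ok <- !is.na(out$fe_sample) & out$fe_sample > 0 & out$element != "Fe" &
      !is.na(out$concentration)
    out$ef <- NA_real_
    out$ef[ok] <- (out$concentration[ok] / out$fe_sample[ok]) /
      (out$background[ok] / ref$background[["Fe"]])
    out$ef_anthropogenic <- out$ef > 1.5
    out$fe_sample <- NULL
  } else {
    out$ef <- NA_real_
    out$ef_anthropogenic <- NA
  }

  out <- arrange(out, across(all_of(keys)), .data$element)
  attr(out, "background_name") <- ref$name
  attr(out, "per") <- per
  class(out) <- c("sedrisk_indices", class(out))
  out
}

#' Aggregate contamination indices (PLI, mCd) per group
#'
#' Collapses a [compute_indices()] result to one row per grouping unit
#' with the pollution load index and modified contamination degree over
#' the twelve-element default index set (configurable).
#'
#' @param indices A `sedrisk_indices` tibble.
#' @param elements Elements entering the aggregate; default
#'   [default_index_elements()] intersected with what is present.
#' @return Tibble with grouping keys, `pli`, `pli_category`,
#'   `pli_exceeds_site_criterion`, `mcd`, `mcd_category`, `n_elements`.
#' @export
summarize_site_indices <- function(indices, elements = NULL) {
  elements <- elements %||%
    intersect(default_index_elements(), unique(indices$element))
  keys <- intersect(names(indices), c("site", "zone", "month", "replicate"))
  indices |>
    filter(.data$element %in% elements, !is.na(.data$cf)) |>
    group_by(across(all_of(keys))) |>
    summarise(
      n_elements = n(),
      pli = pollution_load_index(.data$cf)$value,
      pli_category = pollution_load_index(.data$cf)$category,
      pli_exceeds_site_criterion = .data$pli > 1.3,
      mcd = modified_contamination_degree(.data$cf)$value,
      mcd_category = modified_contamination_degree(.data$cf)$category,
      .groups = "drop")
}
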