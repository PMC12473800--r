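# End-to-end orchestration: samples -> indices -> ecological risk ->
# health risk -> report bundle, plus the zone comparison test. Outputs are
# deterministic given inputs; numbers written to disk are rounded to six
# significant digits so golden-file comparisons are stable.

#' Wilcoxon rank-sum comparison of the two zones for one element
#'
#' Exact two-sided test (full enumeration, via the exact distribution of
#' the rank-sum statistic) when the combined sample size is at most 20 and
#' the data are tie-free; otherwise the normal approximation with tie
#' correction and continuity correction. The p-value depends on the data
#' only through ranks, so it is invariant under monotone transforms.
#'
#' @param samples Validated sample tibble with both zones present.
#' @param element Element symbol.
#' @return One-row tibble: `element`, `n_upper`, `n_lower`, `statistic`
#'   (rank-sum W of the upper zone), `p_value`, `method`.
#' @export
zone_compare <- function(samples, element) {
  samples <- validate_samples(samples)
  if (!element %in% sample_elements(samples)) {
    abort(sprintf("element %s not present in sample table", element))
  }
  x <- samples[[element]][samples$zone == "upper"]
  y <- samples[[element]][samples$zone == "lower"]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("both zones need at least one observation")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = !exact))
  tibble(element = element, n_upper = length(x), n_lower = length(y),
         statistic = unname(ht$statistic), p_value = ht$p.value,
         method = if (exact) "exact" else "normal approximation")
}

#' Zone comparison across elements
#'
#' Runs [zone_compare()] for each element; raw p-values by default, with
#' an optional Holm-adjusted column.
#'
#' @param samples Validated sample tibble.
#' @param elements Elements to test; default all element columns.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return Tibble with one row per element (plus `p_adjusted` under Holm).
#' @export
compare_zones <- function(samples, elements = NULL, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  samples <- validate_samples(samples)
  elements <- elements %||% sample_elements(samples)
  out <- bind_rows(lapply(elements, function(el) zone_compare(samples, el)))
  if (adjust == "holm") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "holm")
  }
  out
}

format_sig <- function(x, digits = 6) {
  if (is.numeric(x)) signif(x, digits) else x
}

round_df <- function(df, digits = 6) {
  df[] <- lapply(df, format_sig, digits = digits)
  df
}

#' Run the full sediment risk assessment
#'
#' Orchestrates the pipeline on one sample table: per-element contamination
#' indices and site aggregates, ecological risk (Er, RI, SRI), human
#' health risk per receptor, and the per-element zone comparison. When
#' `out_dir` is given, writes `indices.csv`, `site_indices.csv`,
#' `eco_risk.csv`, `health_risk.csv`, `zone_tests.csv` and `summary.json`
#' (numbers at six significant digits); any stage failure removes partial
#' outputs.
#'
#' @param samples Validated sample tibble.
#' @param background Background baseline (see [resolve_background()]).
#' @param tr Toxic response factors.
#' @param profiles Exposure profiles.
#' @param dose_response Dose-response table.
#' @param out_dir Optional output directory.
#' @return An object of class `risk_report`: list with `indices`,
#'   `site_indices`, `eco` (`eco_risk_assessment`), `health`
#'   (`health_risk_assessment`), `zone_tests`, `background_name`.
#' @export
run_full_assessment <- function(samples,
                                background = "taylor_mclennan_1995",
                                tr = toxic_response_factors(),
                                profiles = builtin_exposure_profiles(),
                                dose_response = dose_response_table(),
                                out_dir = NULL) {
  samples <- validate_samples(samples)
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", label, conditionMessage(e)))
    })
  }
  indices <- stage("indices",
                   compute_indices(samples, background = background))
  site_indices <- stage("indices", summarize_site_indices(indices))
  eco <- stage("eco-risk",
               assess_ecological_risk(samples, background = background,
                                      tr = tr))
  health <- stage("health-risk",
                  assess_health_risk(samples, profiles = profiles,
                                     dose_response = dose_response))
  zone_tests <- if (length(unique(samples$zone)) == 2) {
    stage("compare-zones", compare_zones(samples))
  } else {
    NULL
  }

  bundle <- structure(
    list(indices = indices, site_indices = site_indices, eco = eco,
         health = health, zone_tests = zone_tests,
         background_name = attr(indices, "background_name")),
    class = "risk_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    written <- character(0)
    tryCatch({
      paths <- list(
        indices = as_tibble(indices),
        site_indices = site_indices,
        eco_risk = left_join(eco$sites,
                             tidyr::pivot_wider(
                               select(eco$er, "site", "element", "er"),
                               names_from = "element", values_from = "er",
                               names_prefix = "er_"),
                             by = "site"),
        health_risk = health$doses |>
          left_join(select(health$by_element, "site", "receptor", "element",
                           "hi", "tcr", "hi_share", "tcr_share"),
                    by = c("site", "receptor", "element")),
        zone_tests = zone_tests)
      for (nm in names(paths)) {
        if (is.null(paths[[nm]])) next
        f <- file.path(out_dir, paste0(nm, ".csv"))
        readr::write_csv(round_df(paths[[nm]]), f)
        written <- c(written, f)
      }
      f <- file.path(out_dir, "summary.json")
      jsonlite::write_json(report_summary(bundle), f, auto_unbox = TRUE,
                           digits = 6, pretty = TRUE)
      written <- c(written, f)
    }, error = function(e) {
      unlink(written)
      abort(sprintf("stage 'write' failed: %s", conditionMessage(e)))
    })
  }
  bundle
}

report_summary <- function(bundle) {
  list(
    background = bundle$background_name,
    sites = lapply(split(bundle$eco$sites, bundle$eco$sites$site), function(s) {
      si <- bundle$site_indices[bundle$site_indices$site == s$site, ]
      hh <- bundle$health$summary[bundle$health$summary$site == s$site, ]
      list(zone = s$zone,
           pli = format_sig(si$pli), pli_category = si$pli_category,
           mcd = format_sig(si$mcd), mcd_category = si$mcd_category,
           ri = format_sig(s$ri), ri_category = s$ri_category,
           sri = format_sig(s$sri), sri_category = s$sri_category,
           health = lapply(split(hh, hh$receptor), function(h) {
             list(hi = format_sig(h$hi), hi_category = h$hi_category,
                  tcr = format_sig(h$tcr), tcr_category = h$tcr_category)
           }))
    }))
}

#' Human-readable classification report
#'
#' One row per site (and receptor for the health columns) carrying every
#' category label the pipeline assigns: per-element Cf class, PLI/mCd
#' flags, RI band, SRI band, HI interpretation and TCR band. Labels are
#' re-derived from the bundle's numeric values, so they always agree with
#' them.
#'
#' @param bundle A `risk_report` from [run_full_assessment()].
#' @return Tibble with one row per (site, receptor).
#' @export
classification_report <- function(bundle) {
  stopifnot(inherits(bundle, "risk_report"))
  cf_wide <- bundle$indices |>
    as_tibble() |>
    select("site", "element", "cf_category") |>
    tidyr::pivot_wider(names_from = "element", values_from = "cf_category",
                       names_prefix = "cf_")
  base <- bundle$eco$sites |>
    left_join(select(bundle$site_indices, "site", "pli", "pli_category",
                     "mcd", "mcd_category"), by = "site") |>
    left_join(cf_wide, by = "site")
  bundle$health$summary |>
    select("site", "receptor", "hi", "hi_category", "tcr", "tcr_category") |>
    left_join(base, by = "site") |>
    arrange(.data$site, .data$receptor)
}

#' @export
print.risk_report <- function(x, ...) {
  cat(sprintf("<risk_report> background: %s\n", x$background_name))
  cat("Sites:\n"); print(x$eco$sites)
  cat("Health summary:\n"); print(x$health$summary)
  invisible(x)
}
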