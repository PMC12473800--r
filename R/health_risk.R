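# EPA-style human health risk: chronic daily doses by route, hazard
# quotients / hazard index, carcinogenic risk / total carcinogenic risk,
# and per-metal contribution shares. All quantities are point estimates,
# linear in concentration, and flow entirely from the exposure and
# dose-response configs.

#' Chronic daily dose via incidental ingestion
#'
#' `CDD_ing = CM * IR * ED * EF_days / (ABW * AET) * CFU` (mg/kg/day),
#' with the averaging time chosen by `averaging`: `"nc"` uses `AET_nc`
#' (= ED x 365 under the default convention, so ED cancels), `"ca"` uses
#' the lifetime `AET_ca`.
#'
#' @param cm Sediment concentration(s), mg/kg (>= 0).
#' @param profile An `exposure_profile`.
#' @param averaging `"nc"` (non-carcinogenic) or `"ca"` (carcinogenic).
#' @return Dose(s) in mg/kg/day.
#' @export
cdd_ingestion <- function(cm, profile, averaging = c("nc", "ca")) {
  averaging <- match.arg(averaging)
  if (any(cm < 0, na.rm = TRUE)) abort("concentration must be non-negative")
  aet <- if (averaging == "nc") profile$AET_nc else profile$AET_ca
  cm * profile$IR * profile$ED * profile$EF_days /
    (profile$ABW * aet) * profile$CFU
}

#' Chronic daily dose via particulate inhalation
#'
#' `CDD_inh = CM * IHR * ED * EF_days / (ABW * AET * PEF)` (mg/kg/day).
#' The particle emission factor PEF converts the sediment concentration to
#' an inhalable air concentration, so no mass-unit conversion applies.
#'
#' @inheritParams cdd_ingestion
#' @return Dose(s) in mg/kg/day.
#' @export
cdd_inhalation <- function(cm, profile, averaging = c("nc", "ca")) {
  averaging <- match.arg(averaging)
  if (any(cm < 0, na.rm = TRUE)) abort("concentration must be non-negative")
  aet <- if (averaging == "nc") profile$AET_nc else profile$AET_ca
  cm * profile$IHR * profile$ED * profile$EF_days /
    (profile$ABW * aet * profile$PEF)
}

#' Chronic daily dose via dermal contact
#'
#' `CDD_derm = CM * SA * SAF * DAF * ED * EF_days / (ABW * AET) * CFU`
#' (mg/kg/day), where DAF is the element-specific dermal absorption
#' fraction from the profile. With DAF = 1 this is the ingestion formula
#' with IR replaced by SA x SAF.
#'
#' @inheritParams cdd_ingestion
#' @param element Element symbol(s) used to look up DAF.
#' @return Dose(s) in mg/kg/day.
#' @export
cdd_dermal <- function(cm, profile, element, averaging = c("nc", "ca")) {
  averaging <- match.arg(averaging)
  if (any(cm < 0, na.rm = TRUE)) abort("concentration must be non-negative")
  aet <- if (averaging == "nc") profile$AET_nc else profile$AET_ca
  daf <- profile_daf(profile, element)
  cm * profile$SA * profile$SAF * daf * profile$ED * profile$EF_days /
    (profile$ABW * aet) * profile$CFU
}

#' Hazard quotient
#'
#' `HQ = CDD / RfD` for one element and route.
#'
#' @param cdd Chronic daily dose(s), mg/kg/day.
#' @param rfd Reference dose(s), mg/kg/day (> 0).
#' @return Numeric HQ value(s).
#' @export
hazard_quotient <- function(cdd, rfd) {
  if (any(!is.finite(rfd) | rfd <= 0)) {
    abort("reference dose must be strictly positive")
  }
  cdd / rfd
}

#' Hazard index from a hazard-quotient table
#'
#' Sums HQ over routes within each element and over elements for the
#' total. HI strictly below 1 is labelled "insignificant" (the boundary
#' HI = 1 included); above, "possible chronic adverse effect".
#'
#' @param hq Tibble with columns `element`, `route`, `hq` (extra columns
#'   are treated as grouping keys).
#' @return List with `by_element` (element, hi) and `total` (one-row
#'   tibble: `hi`, `hi_category`).
#' @export
hazard_index <- function(hq) {
  if (nrow(hq) == 0) abort("hazard_index requires a nonempty HQ table")
  by_element <- hq |>
    group_by(.data$element) |>
    summarise(hi = sum(.data$hq), .groups = "drop")
  total <- sum(by_element$hi)
  list(by_element = by_element,
       total = tibble(hi = total, hi_category = hi_category(total)))
}

hi_category <- function(hi) {
  ifelse(hi <= 1, "insignificant", "possible chronic adverse effect")
}

tcr_category <- function(tcr) {
  dplyr::case_when(
    tcr < 1e-6 ~ "no significant risk",
    tcr <= 1e-4 ~ "acceptable",
    TRUE ~ "unacceptable")
}

#' Carcinogenic risk for one element from carcinogenic-averaged doses
#'
#' Route-specific risks: `CR_ing = CDD_ing * SF_ing`,
#' `CR_inh = CDD_inh * IUR` (IUR pre-converted to (mg/kg/day)^-1), and for
#' the dermal route the standard dermally adjusted slope factor
#' `CR_derm = CDD_derm * SF_ing / GIABS` (set
#' `dermal_sf = "unadjusted"` for a plain `CDD_derm * SF_ing`). Routes
#' whose slope factor is absent contribute nothing and are flagged in the
#' output. TCR is the sum over routes, classified as no significant risk
#' (< 1e-6), acceptable (1e-6 to 1e-4), unacceptable (> 1e-4).
#'
#' @param cdd_ing,cdd_inh,cdd_derm Carcinogenic-averaged doses, mg/kg/day.
#' @param dr One row of a dose-response table (see
#'   [dose_response_table()]) or the full table (the row is selected by
#'   `element`).
#' @param element Element symbol.
#' @param dermal_sf `"giabs"` (default) or `"unadjusted"`.
#' @return One-row tibble: `element`, `cr_ing`, `cr_inh`, `cr_derm`,
#'   `tcr`, `tcr_category`, `routes_skipped`.
#' @export
carcinogenic_risk <- function(cdd_ing, cdd_inh, cdd_derm, dr, element,
                              dermal_sf = c("giabs", "unadjusted")) {
  dermal_sf <- match.arg(dermal_sf)
  if (is.data.frame(dr)) {
    dr <- dr[dr$element == element, ]
    if (nrow(dr) != 1) {
      abort(sprintf("no dose-response row for element %s", element))
    }
  }
  skipped <- character(0)
  cr_ing <- cr_inh <- cr_derm <- 0
  if (!is.na(dr$sf_ing)) {
    cr_ing <- cdd_ing * dr$sf_ing
    if (dermal_sf == "giabs") {
      if (is.na(dr$giabs) || dr$giabs <= 0) {
        abort(sprintf("GIABS missing for element %s (needed for dermal risk)",
                      element))
      }
      cr_derm <- cdd_derm * dr$sf_ing / dr$giabs
    } else {
      cr_derm <- cdd_derm * dr$sf_ing
    }
  } else {
    skipped <- c(skipped, "ingestion", "dermal")
  }
  if (!is.na(dr$iur)) {
    cr_inh <- cdd_inh * dr$iur
  } else {
    skipped <- c(skipped, "inhalation")
  }
  tcr <- cr_ing + cr_inh + cr_derm
  tibble(element = element, cr_ing = cr_ing, cr_inh = cr_inh,
         cr_derm = cr_derm, tcr = tcr, tcr_category = tcr_category(tcr),
         routes_skipped = paste(skipped, collapse = ";"))
}

#' Per-metal contribution shares of HI and TCR
#'
#' `share(element) = 100 * value / total`, computed separately for the
#' non-carcinogenic (HI) and carcinogenic (TCR) totals. Shares over
#' elements sum to 100% whenever the total is positive; a zero total
#' yields `NA` shares.
#'
#' @param hi_by_element Tibble with `element`, `hi`.
#' @param tcr_by_element Tibble with `element`, `tcr`.
#' @return Tibble with `element`, `hi_share`, `tcr_share` (percent).
#' @export
risk_contributions <- function(hi_by_element, tcr_by_element) {
  hi_total <- sum(hi_by_element$hi)
  tcr_total <- sum(tcr_by_element$tcr)
  out <- dplyr::full_join(hi_by_element, tcr_by_element, by = "element")
  out$hi_share <- if (hi_total > 0) 100 * out$hi / hi_total else NA_real_
  out$tcr_share <- if (tcr_total > 0) 100 * out$tcr / tcr_total else NA_real_
  select(out, "element", "hi_share", "tcr_share")
}

#' Human health risk assessment over a sample table
#'
#' For each site, receptor and element: chronic daily doses per route
#' under both averaging conventions, hazard quotients and the hazard
#' index, carcinogenic risk and total carcinogenic risk, and per-metal
#' contribution shares. Concentrations default to site means.
#'
#' @param samples Validated sample tibble.
#' @param profiles Named list of `exposure_profile`s; default
#'   [builtin_exposure_profiles()].
#' @param dose_response Dose-response tibble; default
#'   [dose_response_table()].
#' @param elements Elements assessed; default the intersection of
#'   [default_health_elements()], the dose-response table and the data.
#' @param receptors Receptor subset of `names(profiles)`.
#' @param routes Exposure routes, subset of `c("ing", "inh", "derm")`.
#' @param stat Concentration statistic per site: `"mean"` (default) or
#'   `"max"`.
#' @param dermal_sf Dermal slope-factor convention (see
#'   [carcinogenic_risk()]).
#' @return An object of class `health_risk_assessment`: list with
#'   \describe{
#'     \item{doses}{long tibble per (site, receptor, element, route):
#'       `cdd_nc`, `cdd_ca`, `hq`, `cr`}
#'     \item{by_element}{per (site, receptor, element): `hi`, `tcr`,
#'       `hi_share`, `tcr_share`}
#'     \item{summary}{per (site, receptor): total `hi`, `hi_category`,
#'       total `tcr`, `tcr_category`}
#'   }
#' @export
assess_health_risk <- function(samples,
                               profiles = builtin_exposure_profiles(),
                               dose_response = dose_response_table(),
                               elements = NULL,
                               receptors = names(profiles),
                               routes = c("ing", "inh", "derm"),
                               stat = c("mean", "max"),
                               dermal_sf = c("giabs", "unadjusted")) {
  stat <- match.arg(stat)
  dermal_sf <- match.arg(dermal_sf)
  routes <- match.arg(routes, c("ing", "inh", "derm"), several.ok = TRUE)
  conc <- site_concentrations(samples, stat = stat)
  elements <- elements %||%
    intersect(intersect(default_health_elements(), dose_response$element),
              unique(conc$element))
  missing_dr <- setdiff(elements, dose_response$element)
  if (length(missing_dr) > 0) {
    abort(sprintf("no dose-response values for element(s): %s",
                  paste(missing_dr, collapse = ", ")))
  }
  receptors <- intersect(receptors, names(profiles))
  if (length(receptors) == 0) abort("no matching receptor profiles")

  conc <- filter(conc, .data$element %in% elements)
  dr <- dose_response

  dose_rows <- purrr::map(receptors, function(rec) {
    p <- profiles[[rec]]
    grid <- tidyr::crossing(conc, route = routes)
    grid$receptor <- rec
    grid$cdd_nc <- NA_real_
    grid$cdd_ca <- NA_real_
    for (r in routes) {
      ii <- grid$route == r
      f <- switch(r,
        ing = function(a) cdd_ingestion(grid$concentration[ii], p, a),
        inh = function(a) cdd_inhalation(grid$concentration[ii], p, a),
        derm = function(a) cdd_dermal(grid$concentration[ii], p,
                                      grid$element[ii], a))
      grid$cdd_nc[ii] <- f("nc")
      grid$cdd_ca[ii] <- f("ca")
    }
    grid
  })
  doses <- bind_rows(dose_rows) |>
    left_join(select(dr, "element", "rfd_ing", "rfd_inh", "rfd_derm"),
              by = "element") |>
    mutate(rfd = dplyr::case_when(
      .data$route == "ing" ~ .data$rfd_ing,
      .data$route == "inh" ~ .data$rfd_inh,
      .data$route == "derm" ~ .data$rfd_derm),
      hq = hazard_quotient(.data$cdd_nc, .data$rfd)) |>
    select(-"rfd_ing", -"rfd_inh", -"rfd_derm")

  # carcinogenic risk per (site, receptor, element) from ca-averaged doses
  wide_ca <- doses |>
    select("site", "zone", "receptor", "element", "route", "cdd_ca") |>
    tidyr::pivot_wider(names_from = "route", values_from = "cdd_ca",
                       values_fill = 0)
  for (r in c("ing", "inh", "derm")) {
    if (!r %in% names(wide_ca)) wide_ca[[r]] <- 0
  }
  cr_tab <- purrr::pmap(
    list(wide_ca$ing, wide_ca$inh, wide_ca$derm, wide_ca$element),
    function(ing, inh, derm, el) {
      carcinogenic_risk(ing, inh, derm, dr, el, dermal_sf = dermal_sf)
    }) |> bind_rows()
  cr_tab <- dplyr::bind_cols(select(wide_ca, "site", "zone", "receptor"),
                             cr_tab) |>
    select("site", "zone", "receptor", "element", "cr_ing", "cr_inh",
           "cr_derm", "tcr", "tcr_category", "routes_skipped")

  # route-level CR back onto the long dose table
  cr_long <- cr_tab |>
    select("site", "receptor", "element", "cr_ing", "cr_inh", "cr_derm") |>
    tidyr::pivot_longer(cols = c("cr_ing", "cr_inh", "cr_derm"),
                        names_to = "route", values_to = "cr",
                        names_prefix = "cr_")
  doses <- left_join(doses, cr_long, by = c("site", "receptor", "element",
                                            "route"))

  by_element <- doses |>
    group_by(.data$site, .data$zone, .data$receptor, .data$element) |>
    summarise(hi = sum(.data$hq), .groups = "drop") |>
    left_join(select(cr_tab, "site", "receptor", "element", "tcr"),
              by = c("site", "receptor", "element"))

  by_element <- by_element |>
    group_by(.data$site, .data$receptor) |>
    mutate(hi_share = if (sum(.data$hi) > 0) 100 * .data$hi / sum(.data$hi)
           else NA_real_,
           tcr_share = if (sum(.data$tcr) > 0) 100 * .data$tcr / sum(.data$tcr)
           else NA_real_) |>
    ungroup()

  summary <- by_element |>
    group_by(.data$site, .data$zone, .data$receptor) |>
    summarise(hi = sum(.data$hi), tcr = sum(.data$tcr), .groups = "drop") |>
    mutate(hi_category = hi_category(.data$hi),
           tcr_category = tcr_category(.data$tcr)) |>
    arrange(.data$site, .data$receptor)

  structure(
    list(doses = doses, by_element = by_element, summary = summary,
         elements = elements, receptors = receptors, routes = routes,
         dermal_sf = dermal_sf),
    class = "health_risk_assessment")
}

#' @export
print.health_risk_assessment <- function(x, ...) {
  cat(sprintf("<health_risk_assessment> %d element(s), receptors: %s\n",
              length(x$elements), paste(x$receptors, collapse = ", ")))
  print(x$summary)
  invisible(x)
}

#' @rdname assess_health_risk
#' @param x A `health_risk_assessment`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.health_risk_assessment <- function(x, ...) {
  x$doses
}

#' @rdname assess_health_risk
#' @exportS3Method generics::glance
glance.health_risk_assessment <- function(x, ...) {
  tibble(n_sites = length(unique(x$summary$site)),
         n_elements = length(x$elements),
         receptors = paste(x$receptors, collapse = ";"),
         max_hi = max(x$summary$hi),
         max_tcr = max(x$summary$tcr),
         n_hi_exceed = sum(x$summary$hi > 1),
         n_tcr_unacceptable = sum(x$summary$tcr > 1e-4))
}
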