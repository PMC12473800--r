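# Seedable synthetic sample generator for a two-zone, six-site river
# design. Concentrations are drawn from lognormals moment-matched to
# per-zone target means and SDs, reproducing the right-skewed, nonnegative
# character of trace-element data and the downstream enrichment gradient.

#' Construct a zone generator specification
#'
#' @param zone_stats Tibble with columns `zone`, `element`, `mean`, `sd`
#'   (mg/kg; `mean` > 0 where generated, `sd` >= 0).
#' @param sites Tibble with columns `site`, `zone`.
#' @param replicates_per_site Rows generated per site and month.
#' @param months Sampling-month labels.
#' @param site_effect_sd Lognormal-scale SD of an optional multiplicative
#'   site effect (0 disables it, the default, so zone-level moments are
#'   exactly targeted).
#' @param distribution `"lognormal"` (default) or `"truncnorm"` (normal
#'   truncated at zero by rejection).
#' @return A `zone_generator_spec` object.
#' @export
zone_generator_spec <- function(zone_stats, sites, replicates_per_site = 1,
                                months = c("February", "March"),
                                site_effect_sd = 0,
                                distribution = c("lognormal", "truncnorm")) {
  distribution <- match.arg(distribution)
  stopifnot(all(c("zone", "element", "mean", "sd") %in% names(zone_stats)),
            all(c("site", "zone") %in% names(sites)))
  if (any(zone_stats$mean <= 0)) {
    abort("target_mean must be strictly positive for generated elements")
  }
  if (any(zone_stats$sd < 0)) abort("target_sd must be non-negative")
  if (any(zone_stats$sd > 0 & zone_stats$mean == 0)) {
    abort("cannot target sd > 0 with mean = 0")
  }
  check_elements(unique(zone_stats$element), "generator spec")
  structure(
    list(zone_stats = as_tibble(zone_stats), sites = as_tibble(sites),
         replicates_per_site = as.integer(replicates_per_site),
         months = months, site_effect_sd = site_effect_sd,
         distribution = distribution),
    class = "zone_generator_spec")
}

#' Default generator specification for a mining-impacted Andean river
#'
#' Six stations in two altitudinal zones — upper (Yanacancha, San Juan de
#' Jarpa, Colpa) and lower (Angasmayo, San Blas, La Perla) — with per-zone
#' target means and SDs for thirteen elements taken from the package's
#' built-in descriptive-statistics table for the Cunas River basin
#' (per-zone mean/SD of wet-season composite samples, mg/kg dry weight).
#'
#' @inheritParams zone_generator_spec
#' @return A `zone_generator_spec`.
#' @export
default_cunas_spec <- function(replicates_per_site = 2,
                               months = c("February", "March"),
                               site_effect_sd = 0) {
  zone_generator_spec(
    zone_stats = cunas_zone_stats(),
    sites = tibble(
      site = c("Yanacancha", "San Juan de Jarpa", "Colpa",
               "Angasmayo", "San Blas", "La Perla"),
      zone = rep(c("upper", "lower"), each = 3)),
    replicates_per_site = replicates_per_site,
    months = months,
    site_effect_sd = site_effect_sd)
}

#' Built-in per-zone descriptive statistics for the Cunas basin
#'
#' Mean, SD and maximum concentration (mg/kg dry weight) per zone for the
#' thirteen measured elements; the maxima are `NA` where the source
#' compilation reports none (V).
#'
#' @return Tibble with `zone`, `element`, `mean`, `sd`, `max`.
#' @export
cunas_zone_stats <- function() {
  upper <- tibble(
    zone = "upper",
    element = c("Cu", "Cr", "Fe", "Mn", "Mo", "Ni", "V", "Cd", "Hg", "Pb",
                "Zn", "Sb", "As"),
    mean = c(6.2, 7.8, 9094, 316, 0.5, 7.1, 23.4, 0.2, 0.2, 11.1, 35.9,
             0.4, 7.7),
    sd = c(2.2, 2.6, 1939, 140, 0.2, 4.3, 4.5, 0.2, 0.1, 9.2, 48.9, 0.2,
           7.6),
    max = c(10.7, 13.2, 12192, 531, 0.9, 16.4, NA, 0.5, 0.2, 31.8, 156,
            1.3, 23.9))
  lower <- tibble(
    zone = "lower",
    element = upper$element,
    mean = c(8.1, 9.5, 9986, 413, 0.9, 11, 26.9, 0.4, 0.1, 23.1, 101.3,
             1.1, 15.4),
    sd = c(2.6, 3.1, 1607, 197, 0.4, 4.2, 2, 0.1, 0.1, 10.4, 58.7, 0.8,
           7.1),
    max = c(12.8, 13.2, 12192, 752, 1.5, 16.4, NA, 0.5, 0.2, 31.8, 156,
            2.7, 23.9))
  bind_rows(upper, lower)
}

#' Lognormal parameters matching a target mean and SD
#'
#' Moment matching: `meanlog = log(m^2 / sqrt(m^2 + s^2))`,
#' `sdlog = sqrt(log(1 + s^2 / m^2))`. A zero SD degenerates to a point
#' mass at the mean.
#'
#' @param m Target mean (> 0).
#' @param s Target SD (>= 0).
#' @return List with `meanlog`, `sdlog`.
#' @export
lognormal_match <- function(m, s) {
  stopifnot(all(m > 0), all(s >= 0))
  list(meanlog = log(m^2 / sqrt(m^2 + s^2)),
       sdlog = sqrt(log(1 + s^2 / m^2)))
}

draw_element <- function(n, m, s, distribution) {
  if (s == 0) return(rep(m, n))
  if (distribution == "lognormal") {
    p <- lognormal_match(m, s)
    stats::rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog)
  } else {
    # rejection-sampled normal truncated at zero; slight positive bias in
    # mean relative to target when s is comparable to m, documented
    x <- rnorm(n, m, s)
    while (any(x <= 0)) {
      bad <- x <= 0
      x[bad] <- rnorm(sum(bad), m, s)
    }
    x
  }
}

#' Generate a synthetic sample table
#'
#' Draws one concentration per (site, month, replicate, element) from the
#' zone's moment-matched distribution, optionally perturbed by a
#' site-level multiplicative lognormal effect. A fixed seed gives
#' bit-identical output; a zero target SD yields the target mean exactly.
#'
#' @param spec A `zone_generator_spec`.
#' @param seed Integer seed (default 1).
#' @return Validated sample tibble (site, zone, month, replicate, one
#'   column per element).
#' @examples
#' samples <- generate_samples(default_cunas_spec(), seed = 42)
#' summarize_by_zone(samples)
#' @export
generate_samples <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "zone_generator_spec"))
  withr::local_seed(seed)
  sites <- spec$sites
  frame <- tidyr::crossing(sites, month = spec$months,
                           replicate = seq_len(spec$replicates_per_site)) |>
    arrange(.data$zone, .data$site, .data$month, .data$replicate)

  site_effect <- setNames(rep(1, nrow(sites)), sites$site)
  if (spec$site_effect_sd > 0) {
    site_effect <- setNames(
      stats::rlnorm(nrow(sites),
                    meanlog = -spec$site_effect_sd^2 / 2,
                    sdlog = spec$site_effect_sd),
      sites$site)
  }

  elements <- unique(spec$zone_stats$element)
  for (el in elements) {
    vals <- numeric(nrow(frame))
    for (z in unique(frame$zone)) {
      row <- spec$zone_stats[spec$zone_stats$zone == z &
                               spec$zone_stats$element == el, ]
      ii <- which(frame$zone == z)
      if (nrow(row) == 0) {
        vals[ii] <- NA_real_
      } else {
        vals[ii] <- draw_element(length(ii), row$mean, row$sd,
                                 spec$distribution)
      }
    }
    frame[[el]] <- vals * unname(site_effect[frame$site])
  }
  validate_samples(select(frame, all_of(c(metadata_columns(), elements))))
}

#' Deterministic worked fixture with hand-computable index values
#'
#' A tiny three-site, three-element table whose concentrations are simple
#' multiples of the default UCC backgrounds, so every downstream quantity
#' (Cf, Igeo, Er, RI, SRI, HQ, HI, TCR, contribution shares) can be
#' verified by hand arithmetic. Used by the end-to-end tests; not a
#' reconstruction of any field dataset.
#'
#' @return Validated sample tibble with sites `S1` (upper), `S2`, `S3`
#'   (lower) and elements As, Cd, Pb plus Fe.
#' @export
generate_worked_fixture <- function() {
  validate_samples(tibble(
    site = c("S1", "S2", "S3"),
    zone = c("upper", "lower", "lower"),
    month = "February",
    replicate = 1L,
    # As: 1x, 2x, 4x UCC (1.5); Cd: 2x, 4x, 8x UCC (0.1); Pb: 1x, 1x, 2x
    As = c(1.5, 3.0, 6.0),
    Cd = c(0.2, 0.4, 0.8),
    Pb = c(20, 20, 40),
    Fe = c(47200, 47200, 23600)))
}
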