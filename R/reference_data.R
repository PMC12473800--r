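#' Canonical element symbols recognised by the package
#'
#' The thirteen elements of the built-in background tables plus a few
#' symbols that appear in field datasets from Andean rivers (Mg, Ag, Co)
#' and are accepted as valid columns even though no reference values ship
#' for them.
#'
#' @return Character vector of element symbols.
#' @export
canonical_elements <- function() {
  c("As", "Cd", "Cr", "Cu", "Fe", "Hg", "Mn", "Mo", "Ni", "Pb", "Sb", "V",
    "Zn", "Mg", "Ag", "Co")
}

#' Elements used for contamination indices by default
#'
#' The twelve-element index set: all built-in background elements except
#' mercury, which is measured and generated but excluded from the default
#' aggregate indices (PLI, mCd) and ecological risk.
#'
#' @return Character vector of twelve element symbols.
#' @export
default_index_elements <- function() {
  c("Cu", "Cr", "Fe", "Mn", "Mo", "Ni", "Pb", "V", "Zn", "Sb", "As", "Cd")
}

#' Default element set for ecological risk (RI)
#'
#' The ten elements of the default index set that carry a defensible
#' published toxic response factor; Fe (the enrichment-factor reference
#' element) and Mo are excluded.
#'
#' @return Character vector of ten element symbols.
#' @export
default_risk_elements <- function() {
  c("As", "Cd", "Cr", "Cu", "Mn", "Ni", "Pb", "Sb", "V", "Zn")
}

#' Default element set for human health risk
#'
#' The five priority metals with dose-response constants in the shipped
#' config: As, Cd, Cr, Ni, Pb. User-extensible by supplying a larger
#' dose-response table.
#'
#' @return Character vector of five element symbols.
#' @export
default_health_elements <- function() {
  c("As", "Cd", "Cr", "Ni", "Pb")
}

ext_file <- function(name) {
  path <- system.file("extdata", name, package = "sedrisk", mustWork = FALSE)
  if (!nzchar(path)) {
    # during development the package may not be installed yet
    path <- file.path("inst", "extdata", name)
  }
  path
}

check_elements <- function(elements, where) {
  bad <- setdiff(elements, canonical_elements())
  if (length(bad) > 0) {
    abort(sprintf("%s: unknown element symbol(s): %s", where,
                  paste(bad, collapse = ", ")))
  }
  invisible(elements)
}

# ---- reference sets (geochemical backgrounds) -------------------------------

new_reference_set <- function(name, background, source_note = "") {
  stopifnot(is.character(name), length(name) == 1L)
  background <- unlist(background)
  if (anyDuplicated(names(background))) {
    dup <- unique(names(background)[duplicated(names(background))])
    abort(sprintf("reference set '%s': duplicate element(s): %s", name,
                  paste(dup, collapse = ", ")))
  }
  check_elements(names(background), sprintf("reference set '%s'", name))
  nonpos <- names(background)[!is.finite(background) | background <= 0]
  if (length(nonpos) > 0) {
    abort(sprintf(
      "reference set '%s': background must be strictly positive, violated for: %s",
      name, paste(nonpos, collapse = ", ")))
  }
  structure(
    list(name = name,
         background = background[order(names(background))],
         source_note = source_note),
    class = "reference_set")
}

#' Load a geochemical background reference set from a YAML config
#'
#' The config must carry a `name` field and a `background` map of element
#' symbol to concentration (mg/kg dry weight). Element symbols are checked
#' against [canonical_elements()] and all values must be strictly positive.
#'
#' @param path Path to a YAML file (or a parsed list with the same shape).
#' @return A `reference_set` object: list with `name`, a named numeric
#'   `background` vector, and `source_note`.
#' @seealso [builtin_references()], [write_reference_set()]
#' @export
load_reference_set <- function(path) {
  doc <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(doc$name) || is.null(doc$background) ||
      length(doc$background) == 0) {
    abort("reference config must provide 'name' and at least one 'background' entry")
  }
  new_reference_set(doc$name, doc$background, doc$source_note %||% "")
}

#' Write a reference set back to YAML
#'
#' Round-trips with [load_reference_set()]: loading the written file yields
#' an identical object (elements are stored in canonical alphabetical
#' order).
#'
#' @param ref A `reference_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference_set <- function(ref, path) {
  stopifnot(inherits(ref, "reference_set"))
  yaml::write_yaml(
    list(name = ref$name,
         source_note = ref$source_note,
         background = as.list(ref$background)),
    path)
  invisible(path)
}

#' Built-in geochemical background baselines
#'
#' Two published baselines ship with the package: the upper continental
#' crust averages after Taylor & McLennan (1995) — the default, and the
#' more conservative average-shale standard after Turekian & Wedepohl
#' (1961). Both cover the same thirteen elements.
#'
#' @return Named list of two `reference_set` objects
#'   (`taylor_mclennan_1995`, `turekian_wedepohl_1961`).
#' @examples
#' refs <- builtin_references()
#' refs$taylor_mclennan_1995$background[["Fe"]]
#' @export
builtin_references <- function() {
  sets <- list(
    load_reference_set(ext_file("background_taylor_mclennan_1995.yaml")),
    load_reference_set(ext_file("background_turekian_wedepohl_1961.yaml")))
  setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' Resolve a background argument to a reference set
#'
#' Accepts a built-in name, a path to a YAML config, or an already-built
#' `reference_set`.
#'
#' @param background Name, path, or `reference_set`.
#' @return A `reference_set`.
#' @export
resolve_background <- function(background = "taylor_mclennan_1995") {
  if (inherits(background, "reference_set")) return(background)
  builtins <- builtin_references()
  if (is.character(background) && background %in% names(builtins)) {
    return(builtins[[background]])
  }
  if (is.character(background) && file.exists(background)) {
    return(load_reference_set(background))
  }
  abort(sprintf(
    "unknown background '%s' (not a built-in name, file path, or reference_set)",
    background))
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %s (%d elements)\n", x$name,
              length(x$background)))
  print(x$background)
  invisible(x)
}

#' @export
as_tibble.reference_set <- function(x, ...) {
  tibble(element = names(x$background),
         background = unname(x$background))
}

# ---- toxic response factors -------------------------------------------------

#' Load toxic response factors from a YAML config
#'
#' @param path Path to a YAML file with a `factors` map of element symbol
#'   to dimensionless toxic response factor; defaults to the shipped
#'   Hakanson-lineage table.
#' @return Named numeric vector of factors (all strictly positive).
#' @export
load_toxic_response_factors <- function(path = NULL) {
  doc <- yaml::read_yaml(path %||% ext_file("toxic_response_factors.yaml"))
  tr <- unlist(doc$factors)
  check_elements(names(tr), "toxic response factors")
  if (any(!is.finite(tr) | tr <= 0)) {
    abort("toxic response factors must be strictly positive")
  }
  tr
}

#' Default Hakanson-lineage toxic response factors
#'
#' @return Named numeric vector (Hg 40, Cd 30, As 10, Cu/Pb/Ni 5, Sb 7,
#'   Cr/V 2, Zn/Mn/Mo 1).
#' @export
toxic_response_factors <- function() {
  load_toxic_response_factors(NULL)
}

# ---- exposure profiles ------------------------------------------------------

profile_scalar_fields <- function() {
  c("ABW", "IR", "IHR", "SA", "SAF", "ED", "EF_days", "AET_nc", "AET_ca",
    "PEF", "CFU")
}

new_exposure_profile <- function(receptor, fields) {
  need <- profile_scalar_fields()
  missing <- setdiff(need, names(fields))
  if (length(missing) > 0) {
    abort(sprintf("exposure profile '%s' is missing: %s", receptor,
                  paste(missing, collapse = ", ")))
  }
  vals <- vapply(fields[need], as.numeric, numeric(1))
  if (any(!is.finite(vals) | vals <= 0)) {
    abort(sprintf("exposure profile '%s': all parameters must be strictly positive",
                  receptor))
  }
  if (vals[["AET_ca"]] < vals[["AET_nc"]]) {
    abort(sprintf("exposure profile '%s': AET_ca must be >= AET_nc", receptor))
  }
  daf <- unlist(fields$DAF)
  if (is.null(daf) || any(daf <= 0 | daf > 1)) {
    abort(sprintf("exposure profile '%s': DAF values must lie in (0, 1]", receptor))
  }
  structure(c(as.list(vals), list(receptor = receptor, DAF = daf)),
            class = "exposure_profile")
}

#' Dermal absorption fraction for one element under a profile
#'
#' Falls back on the profile's `default` DAF entry; errors if neither an
#' element-specific nor a default value exists.
#'
#' @param profile An `exposure_profile`.
#' @param element Element symbol.
#' @return Dermal absorption fraction in (0, 1].
#' @export
profile_daf <- function(profile, element) {
  daf <- profile$DAF
  out <- ifelse(element %in% names(daf), daf[element], daf["default"])
  if (anyNA(out)) {
    abort(sprintf("no dermal absorption fraction (DAF) for element(s): %s",
                  paste(element[is.na(out)], collapse = ", ")))
  }
  unname(out)
}

#' Load exposure profiles from a YAML config
#'
#' @param path Path to a YAML file with a `profiles` map keyed by receptor
#'   (`child`, `adult`, ...); defaults to the shipped EPA RAGS-style table.
#' @return Named list of `exposure_profile` objects.
#' @export
load_exposure_profiles <- function(path = NULL) {
  doc <- yaml::read_yaml(path %||% ext_file("exposure_profiles.yaml"))
  profs <- lapply(names(doc$profiles), function(r) {
    new_exposure_profile(r, doc$profiles[[r]])
  })
  setNames(profs, names(doc$profiles))
}

#' Built-in child and adult exposure profiles
#'
#' EPA RAGS-style defaults for incidental sediment exposure: adult 70 kg /
#' 100 mg/day ingestion / 24 y duration, child 15 kg / 200 mg/day / 6 y;
#' both 350 days/year, lifetime (70 y) carcinogenic averaging time and a
#' particle emission factor of 1.36e9 m3/kg. All values editable via
#' [load_exposure_profiles()].
#'
#' @return Named list with `child` and `adult` `exposure_profile` objects.
#' @export
builtin_exposure_profiles <- function() {
  load_exposure_profiles(NULL)
}

#' @export
print.exposure_profile <- function(x, ...) {
  cat(sprintf("<exposure_profile> %s\n", x$receptor))
  flds <- profile_scalar_fields()
  print(setNames(vapply(flds, function(f) x[[f]], numeric(1)), flds))
  cat("DAF:\n"); print(x$DAF)
  invisible(x)
}

# ---- dose-response table ----------------------------------------------------

#' Load dose-response constants from a YAML config
#'
#' Reads per-element reference doses, slope factors, inhalation unit risk
#' (pre-converted to (mg/kg/day)^-1) and gastrointestinal absorption
#' fractions. Unless the config gives `RfD_derm` explicitly it is derived
#' as `RfD_ing * GIABS`.
#'
#' @param path Path to a YAML config; defaults to the shipped
#'   IRIS/RAIS-lineage table for As, Cd, Cr, Ni, Pb.
#' @return A tibble with columns `element`, `rfd_ing`, `rfd_inh`,
#'   `rfd_derm`, `sf_ing`, `iur`, `giabs`. Slope factors may be `NA`
#'   (route skipped in carcinogenic risk); reference doses must be present
#'   and positive.
#' @export
load_dose_response <- function(path = NULL) {
  doc <- yaml::read_yaml(path %||% ext_file("dose_response.yaml"))
  rows <- lapply(names(doc$elements), function(el) {
    e <- doc$elements[[el]]
    giabs <- as.numeric(e$GIABS %||% 1)
    if (!is.finite(giabs) || giabs <= 0 || giabs > 1) {
      abort(sprintf("dose-response for %s: GIABS must lie in (0, 1]", el))
    }
    rfd_ing <- as.numeric(e$RfD_ing)
    rfd_inh <- as.numeric(e$RfD_inh)
    if (any(!is.finite(c(rfd_ing, rfd_inh))) || rfd_ing <= 0 || rfd_inh <= 0) {
      abort(sprintf("dose-response for %s: reference doses must be positive", el))
    }
    tibble(
      element = el,
      rfd_ing = rfd_ing,
      rfd_inh = rfd_inh,
      rfd_derm = as.numeric(e$RfD_derm %||% (rfd_ing * giabs)),
      sf_ing = as.numeric(e$SF_ing %||% NA_real_),
      iur = as.numeric(e$IUR %||% NA_real_),
      giabs = giabs)
  })
  out <- bind_rows(rows)
  check_elements(out$element, "dose-response table")
  if (any(!is.na(out$sf_ing) & out$sf_ing <= 0) ||
      any(!is.na(out$iur) & out$iur <= 0)) {
    abort("dose-response slope factors must be strictly positive where present")
  }
  out
}

#' Default dose-response table
#'
#' @return Tibble as documented in [load_dose_response()].
#' @export
dose_response_table <- function() {
  load_dose_response(NULL)
}

# ---- limits of quantification ----------------------------------------------

#' Default limits of quantification (mg/kg)
#'
#' Method LOQs of the analytical protocol the package targets: 0.01 mg/kg
#' for As, Cd, Cr, Cu, Mn and Ni; 0.02 for Pb and Sb; 0.05 for Mo; 0.10
#' for Zn; 0.50 for Fe.
#'
#' @return Named numeric vector of LOQs.
#' @export
default_loq <- function() {
  c(As = 0.01, Cd = 0.01, Cr = 0.01, Cu = 0.01, Mn = 0.01, Ni = 0.01,
    Pb = 0.02, Sb = 0.02, Mo = 0.05, Zn = 0.10, Fe = 0.50)
}
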