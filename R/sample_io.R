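# Sample table I/O and validation. The canonical on-disk form is a wide CSV
# with columns site, zone, month, replicate, then one column per element
# (mg/kg dry weight); in memory a validated tibble of the same shape.

metadata_columns <- function() c("site", "zone", "month", "replicate")

#' Element columns present in a sample table
#'
#' @param samples A sample tibble (see [read_samples()]).
#' @return Character vector of element column names, in table order.
#' @export
sample_elements <- function(samples) {
  setdiff(names(samples), metadata_columns())
}

#' Validate a sediment sample table
#'
#' Checks the schema produced by [read_samples()] or [generate_samples()]:
#' metadata columns present, zones limited to upper/lower, element columns
#' drawn from [canonical_elements()] (unless `strict = FALSE`, which keeps
#' unknown columns with a warning), concentrations non-negative with
#' missing values explicit (`NA`), and unique (site, month, replicate)
#' triples.
#'
#' @param samples Data frame to validate.
#' @param strict Error on unknown element columns (default) rather than
#'   warn-and-keep.
#' @return The validated table as a tibble, row order preserved.
#' @export
validate_samples <- function(samples, strict = TRUE) {
  samples <- as_tibble(samples)
  missing <- setdiff(metadata_columns(), names(samples))
  if (length(missing) > 0) {
    abort(sprintf("sample table is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(samples) == 0) {
    abort("sample table has no rows")
  }
  bad_zone <- setdiff(unique(samples$zone), c("upper", "lower"))
  if (length(bad_zone) > 0) {
    abort(sprintf("zone must be 'upper' or 'lower'; found: %s",
                  paste(bad_zone, collapse = ", ")))
  }
  els <- sample_elements(samples)
  unknown <- setdiff(els, canonical_elements())
  if (length(unknown) > 0) {
    if (strict) {
      abort(sprintf("unknown element column(s): %s (use strict = FALSE to keep)",
                    paste(unknown, collapse = ", ")))
    }
    warn(sprintf("keeping unknown element column(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  for (el in els) {
    v <- samples[[el]]
    if (!is.numeric(v)) {
      abort(sprintf("element column %s is not numeric", el))
    }
    neg <- which(!is.na(v) & v < 0)
    if (length(neg) > 0) {
      abort(sprintf("negative concentration for %s at row %d", el, neg[1]))
    }
  }
  key <- paste(samples$site, samples$month, samples$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate (site, month, replicate) triple at row %d",
                  which(duplicated(key))[1]))
  }
  samples
}

#' Read a sediment sample table from CSV
#'
#' Expects a UTF-8, comma-separated file with a header row naming the
#' metadata columns (`site,zone,month,replicate`) and element symbols; one
#' row per (site, month, replicate). Values at or below an element's limit
#' of quantification are treated as censored and substituted according to
#' `loq_action`.
#'
#' @param path CSV file path.
#' @param strict Error on unknown element columns (see [validate_samples()]).
#' @param loq Named numeric vector of limits of quantification (mg/kg);
#'   `NULL` (default) disables LOQ handling, [default_loq()] enables the
#'   shipped method LOQs.
#' @param loq_action One of `"half"` (substitute LOQ/2, the default),
#'   `"loq"`, `"zero"`, or `"drop"` (set to `NA`).
#' @return Validated sample tibble.
#' @export
read_samples <- function(path, strict = TRUE, loq = NULL,
                         loq_action = c("half", "loq", "zero", "drop")) {
  loq_action <- match.arg(loq_action)
  samples <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  samples <- validate_samples(samples, strict = strict)
  if (!is.null(loq)) {
    samples <- substitute_loq(samples, loq = loq, action = loq_action)
  }
  samples
}

#' Substitute concentrations below the limit of quantification
#'
#' @param samples Validated sample tibble.
#' @param loq Named numeric vector of LOQs (mg/kg).
#' @param action Substitution rule: `"half"` (LOQ/2), `"loq"`, `"zero"`,
#'   or `"drop"` (`NA`).
#' @return Sample tibble with censored values substituted.
#' @export
substitute_loq <- function(samples, loq = default_loq(),
                           action = c("half", "loq", "zero", "drop")) {
  action <- match.arg(action)
  for (el in intersect(sample_elements(samples), names(loq))) {
    lim <- loq[[el]]
    below <- !is.na(samples[[el]]) & samples[[el]] < lim
    samples[[el]][below] <- switch(action,
      half = lim / 2, loq = lim, zero = 0, drop = NA_real_)
  }
  samples
}

#' Write a sample table to CSV
#'
#' Inverse of [read_samples()] on canonical files.
#'
#' @param samples Validated sample tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  readr::write_csv(validate_samples(samples), path)
  invisible(path)
}

#' Pivot a sample table to long (element, concentration) form
#'
#' @param samples Validated sample tibble.
#' @return Tibble with metadata columns plus `element` and `concentration`.
#' @export
samples_long <- function(samples) {
  tidyr::pivot_longer(samples, cols = all_of(sample_elements(samples)),
                      names_to = "element", values_to = "concentration")
}

#' Per-zone descriptive statistics
#'
#' Mean, standard deviation (sample convention, n - 1) and maximum per
#' zone and element, mirroring the layout of a descriptive-statistics
#' table for a two-zone river design. Missing values are dropped per
#' element; the result is invariant under row permutation of the input.
#'
#' @param samples Validated sample tibble.
#' @return Tibble with columns `zone`, `element`, `n`, `mean`, `sd`, `max`;
#'   `sd` is `NA` for a single observation.
#' @export
summarize_by_zone <- function(samples) {
  samples <- validate_samples(samples)
  samples_long(samples) |>
    filter(!is.na(.data$concentration)) |>
    group_by(.data$zone, .data$element) |>
    summarise(n = n(),
              mean = mean(.data$concentration),
              sd = sd(.data$concentration),
              max = max(.data$concentration),
              .groups = "drop") |>
    arrange(.data$zone, .data$element)
}

#' Site-mean concentrations in long form
#'
#' The default concentration statistic feeding the indices and risk
#' modules: the mean over a site's rows, per element.
#'
#' @param samples Validated sample tibble.
#' @param stat Summary statistic: `"mean"` (default) or `"max"`.
#' @return Tibble with `site`, `zone`, `element`, `concentration`.
#' @export
site_concentrations <- function(samples, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  f <- if (stat == "mean") {
    function(x) mean(x, na.rm = TRUE)
  } else {
    function(x) max(x, na.rm = TRUE)
  }
  samples_long(validate_samples(samples)) |>
    group_by(.data$site, .data$zone, .data$element) |>
    summarise(concentration = f(.data$concentration), .groups = "drop")
}
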