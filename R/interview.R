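#' Rice variety information
#'
#' @param name Variety name.
#' @param duration Total growth duration in days (100-160; short-duration
#'   kuruvai varieties run 105-110 d, medium-duration varieties 125-135 d).
#' @param baseline_yield_lo,baseline_yield_hi Baseline varietal yield
#'   window, Mg/ha: the range of yields local experts and past trials
#'   consider attainable for this variety in the delta. Target yields are
#'   clamped into this window.
#' @return An object of class `variety_info`.
#' @export
variety_info <- function(name, duration, baseline_yield_lo, baseline_yield_hi) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_input("variety 'name' must be a non-empty string")
  }
  assert_scalar_num(duration, "duration", lo = 100, hi = 160)
  assert_scalar_num(baseline_yield_lo, "baseline_yield_lo", lo = 0)
  assert_scalar_num(baseline_yield_hi, "baseline_yield_hi", lo = 0)
  if (baseline_yield_lo > baseline_yield_hi) {
    stop_input("'baseline_yield_lo' must not exceed 'baseline_yield_hi'")
  }
  structure(
    list(name = name, duration = duration,
         baseline_yield_lo = baseline_yield_lo,
         baseline_yield_hi = baseline_yield_hi),
    class = "variety_info"
  )
}

#' A farmer's pre-season field interview
#'
#' The sole field-specific input to a recommendation: what the farmer
#' reports before the season about the field, the variety, the
#' establishment plan, past yields and preferred fertilizer products.
#'
#' @param field_id Identifier for the field/farmer.
#' @param field_area Field area in hectares (> 0).
#' @param season One of `"kuruvai"`, `"samba"`, `"thaladi"`.
#' @param irrigation_source One of `"tube_well"`, `"canal"`,
#'   `"rain_plus_canal"`.
#' @param variety A [variety_info()] object (or a list coercible to one).
#' @param establishment One of `"transplanted"`, `"wet_seeded"`,
#'   `"dry_seeded"`.
#' @param seedling_age Age of seedlings at transplanting, days. Required
#'   for transplanted rice and disallowed otherwise.
#' @param sowing_date,establishment_date ISO-8601 dates (`"YYYY-MM-DD"` or
#'   `Date`). Establishment (transplanting or direct seeding) cannot
#'   precede sowing; for direct seeding the two coincide.
#' @param historical_yield Grain yield the farmer reports for previous
#'   seasons, Mg/ha at 14% moisture. Accepted range 3.0-8.0; values
#'   outside it are rejected as implausible for irrigated inbred rice in
#'   this system.
#' @param prev_residue `"removed"` (straw taken off the field) or
#'   `"retained_combine"` (previous crop combine harvested, residue left).
#' @param selected_products Farmer's preferred fertilizer products, in
#'   order of preference; names must resolve in the product catalog used
#'   at recommendation time.
#' @return An object of class `field_interview`.
#' @export
field_interview <- function(field_id,
                            field_area,
                            season,
                            irrigation_source,
                            variety,
                            establishment,
                            sowing_date,
                            establishment_date,
                            historical_yield,
                            prev_residue = "removed",
                            seedling_age = NULL,
                            selected_products = character()) {
  season <- match.arg(season, c("kuruvai", "samba", "thaladi"))
  irrigation_source <- match.arg(irrigation_source,
                                 c("tube_well", "canal", "rain_plus_canal"))
  establishment <- match.arg(establishment,
                             c("transplanted", "wet_seeded", "dry_seeded"))
  prev_residue <- match.arg(prev_residue, c("removed", "retained_combine"))
  assert_scalar_num(field_area, "field_area")
  if (field_area <= 0) stop_input("'field_area' must be > 0")
  assert_scalar_num(historical_yield, "historical_yield", lo = 3.0, hi = 8.0)
  if (!inherits(variety, "variety_info")) {
    if (!is.list(variety)) stop_input("'variety' must be a variety_info object")
    variety <- do.call(variety_info, variety)
  }
  if (establishment == "transplanted") {
    if (is.null(seedling_age)) {
      stop_input("'seedling_age' is required for transplanted rice")
    }
    assert_scalar_num(seedling_age, "seedling_age", lo = 1)
    if (seedling_age >= variety$duration) {
      stop_input("'seedling_age' must be less than the variety's growth duration")
    }
  } else if (!is.null(seedling_age)) {
    stop_input("'seedling_age' applies to transplanted rice only")
  }
  sowing_date <- as_iso_date(sowing_date, "sowing_date")
  establishment_date <- as_iso_date(establishment_date, "establishment_date")
  if (establishment_date < sowing_date) {
    stop_input("'establishment_date' cannot precede 'sowing_date'")
  }
  if (!is.character(selected_products)) {
    selected_products <- as.character(unlist(selected_products))
  }
  structure(
    list(
      field_id = as.character(field_id),
      field_area = field_area,
      season = season,
      irrigation_source = irrigation_source,
      variety = variety,
      establishment = establishment,
      seedling_age = seedling_age,
      sowing_date = sowing_date,
      establishment_date = establishment_date,
      historical_yield = historical_yield,
      prev_residue = prev_residue,
      selected_products = selected_products
    ),
    class = "field_interview"
  )
}

#' Read a field interview from JSON
#'
#' Field names follow the interview schema shipped at
#' `system.file("extdata", "interview.schema.json", package = "ssnmrice")`;
#' dates are ISO-8601 strings. Validation errors name the offending field.
#'
#' @param path Path to an interview JSON file.
#' @return A `field_interview` object.
#' @export
read_interview <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw)) stop_input("interview JSON must be an object")
  raw$selected_products <- as.character(raw$selected_products %||% character())
  if (!is.null(raw$variety) && is.list(raw$variety)) {
    raw$variety <- do.call(variety_info, raw$variety)
  }
  do.call(field_interview, raw)
}

#' Write a field interview to JSON
#'
#' Inverse of [read_interview()]: `read_interview(write_interview(x, f))`
#' reproduces `x`.
#'
#' @param interview A `field_interview`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interview <- function(interview, path) {
  stopifnot(inherits(interview, "field_interview"))
  x <- unclass(interview)
  x$variety <- unclass(x$variety)
  x$sowing_date <- format(x$sowing_date, "%Y-%m-%d")
  x$establishment_date <- format(x$establishment_date, "%Y-%m-%d")
  x <- x[!vapply(x, is.null, logical(1))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.field_interview <- function(x, ...) {
  cat(sprintf("Field interview %s (%s)\n", x$field_id, x$season))
  cat(sprintf("  %.2f ha, %s, irrigation: %s\n",
              x$field_area, x$establishment, x$irrigation_source))
  cat(sprintf("  variety %s (%d d, baseline %.1f-%.1f Mg/ha)\n",
              x$variety$name, as.integer(x$variety$duration),
              x$variety$baseline_yield_lo, x$variety$baseline_yield_hi))
  cat(sprintf("  sown %s, established %s%s\n",
              format(x$sowing_date), format(x$establishment_date),
              if (!is.null(x$seedling_age)) {
                sprintf(" (%d-d seedlings)", as.integer(x$seedling_age))
              } else ""))
  cat(sprintf("  historical yield %.1f Mg/ha, residue %s\n",
              x$historical_yield, x$prev_residue))
  if (length(x$selected_products)) {
    cat("  preferred products:", paste(x$selected_products, collapse = ", "),
        "\n")
  }
  invisible(x)
}
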