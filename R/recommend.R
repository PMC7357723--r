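#' Field-specific fertilizer recommendation
#'
#' The full pre-season pipeline for one field: set the target yield,
#' compute N/P/K rates, place the three applications on the calendar and
#' convert event rates into masses of the farmer-selected products (urea
#' topping up N), scaled to the field area, with a cost summary.
#'
#' @param interview A [field_interview()].
#' @param catalog A [fertilizer_catalog()]; defaults to the shipped
#'   regional catalog.
#' @param params [season_params()] for the interview's season, or a named
#'   list of them keyed by season, or `NULL` for the shipped defaults.
#' @param econ [econ_params()] used for the cost summary.
#' @param yield_without_n Optional direct estimate of the field's yield
#'   without fertilizer N, Mg/ha.
#' @return An object of class `recommendation`: field identity, `season`,
#'   `target_yield`, `rates` ([nutrient_rates()]), `schedule`
#'   (`application_schedule`), `allocation` (`product_allocation`, masses
#'   for the whole field) and `cost` (products, labor and total, US$ for
#'   the field and per ha).
#' @export
recommend <- function(interview,
                      catalog = product_catalog_default(),
                      params = NULL,
                      econ = econ_params(),
                      yield_without_n = NULL) {
  stopifnot(inherits(interview, "field_interview"))
  params <- resolve_params(params, interview$season)
  target <- set_target_yield(interview, params)
  rates <- nutrient_rates(
    n = n_rate(target, params, yield_without_n),
    p = p_rate(target, interview$prev_residue, params),
    k = k_rate(target, interview$prev_residue, params)
  )
  schedule <- ssnm_schedule(rates, interview, params)
  allocation <- allocate(schedule, interview$selected_products, catalog,
                         interview$field_area)
  product_cost <- allocation_cost(allocation, catalog)
  labor_cost <- schedule$n_applications * econ$labor_per_application *
    interview$field_area
  structure(
    list(
      field_id = interview$field_id,
      season = interview$season,
      field_area = interview$field_area,
      variety = interview$variety$name,
      establishment_date = interview$establishment_date,
      target_yield = target,
      rates = rates,
      schedule = schedule,
      allocation = allocation,
      cost = list(
        products_usd = round(product_cost, 2),
        labor_usd = round(labor_cost, 2),
        total_usd = round(product_cost + labor_cost, 2),
        total_usd_per_ha = round((product_cost + labor_cost) /
                                   interview$field_area, 2)
      )
    ),
    class = "recommendation"
  )
}

resolve_params <- function(params, season) {
  if (is.null(params)) return(default_season_params(season))
  if (inherits(params, "season_params")) {
    if (!identical(params$season, season)) {
      stop_input("season parameters are for '", params$season,
                 "' but the interview is for '", season, "'")
    }
    return(params)
  }
  if (is.list(params) && season %in% names(params)) return(params[[season]])
  stop_input("no season parameters available for season '", season, "'")
}

#' Render a recommendation as plain text or JSON
#'
#' The text layout mirrors the one-page farmer hand-out: header, target
#' yield, total rates, then a table of days after establishment, stage,
#' product and exact amount for the field. Output is deterministic (no
#' timestamps), so identical inputs render byte-identical files.
#'
#' @param rec A `recommendation`.
#' @param format `"text"` or `"json"`.
#' @return A character scalar (text) or JSON string.
#' @export
render_recommendation <- function(rec, format = c("text", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    x <- list(
      field_id = rec$field_id,
      season = rec$season,
      field_area_ha = rec$field_area,
      variety = rec$variety,
      establishment_date = format(rec$establishment_date, "%Y-%m-%d"),
      target_yield_mg_ha = rec$target_yield,
      rates_kg_ha = unclass(rec$rates),
      n_applications = rec$schedule$n_applications,
      schedule = rec$schedule$events,
      products = as.data.frame(rec$allocation),
      cost_usd = rec$cost
    )
    return(jsonlite::toJSON(x, dataframe = "rows", auto_unbox = TRUE,
                            digits = NA, pretty = TRUE))
  }
  lines <- c(
    "FIELD-SPECIFIC FERTILIZER RECOMMENDATION (rice)",
    sprintf("Field: %s   Season: %s   Area: %.2f ha   Variety: %s",
            rec$field_id, rec$season, rec$field_area, rec$variety),
    sprintf("Crop established: %s", format(rec$establishment_date)),
    sprintf("Target yield: %.1f Mg/ha", rec$target_yield),
    sprintf("Fertilizer rates: N %g, P %g, K %g kg/ha (elemental)",
            rec$rates$n, rec$rates$p, rec$rates$k),
    "",
    sprintf("%-5s %-20s %-14s %10s", "DAE", "Stage", "Product",
            "kg (field)")
  )
  al <- rec$allocation
  for (i in seq_len(nrow(al))) {
    lines <- c(lines, sprintf("%-5d %-20s %-14s %10.1f",
                              as.integer(al$dae[i]), al$stage[i],
                              al$product[i],
                              round_step(al$mass_kg[i], 0.5)))
  }
  lines <- c(lines, "",
             sprintf("Fertilizer cost: %.2f US$ (products %.2f + labor %.2f)",
                     rec$cost$total_usd, rec$cost$products_usd,
                     rec$cost$labor_usd))
  paste(lines, collapse = "\n")
}

#' @export
print.recommendation <- function(x, ...) {
  cat(render_recommendation(x, "text"), "\n")
  invisible(x)
}
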