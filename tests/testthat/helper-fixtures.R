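# Shared constructors for small test fixtures (built in code, no files).

make_variety <- function(duration = 110, lo = 5.0, hi = 6.5, name = "TEST-1") {
  variety_info(name, duration, lo, hi)
}

make_interview <- function(season = "kuruvai",
                           historical_yield = 4.4,
                           variety = make_variety(),
                           establishment = "transplanted",
                           seedling_age = 25,
                           sowing_date = "2014-06-10",
                           establishment_date = "2014-07-05",
                           prev_residue = "removed",
                           field_area = 1,
                           selected_products = c("DAP", "MOP"),
                           field_id = "test-field") {
  field_interview(
    field_id = field_id, field_area = field_area, season = season,
    irrigation_source = "tube_well", variety = variety,
    establishment = establishment, seedling_age = seedling_age,
    sowing_date = sowing_date, establishment_date = establishment_date,
    historical_yield = historical_yield, prev_residue = prev_residue,
    selected_products = selected_products
  )
}

# Minimal season parameters with a round-number calibration, for tests that
# exercise formulas rather than the shipped regional calibration.
make_params <- function(season = "kuruvai", ...) {
  args <- list(
    season = season, irrigation_k_input = 25, k_drawdown_target = -30,
    agronomic_efficiency = 15, attainable_gain = 1.8
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(season_params, args)
}

# Catalog with the grades used in the worked allocation examples
# (DAP quoted at a flat 20% P).
example_catalog <- function() {
  fertilizer_catalog(data.frame(
    name = c("urea", "DAP", "MOP", "17-17-17"),
    n_frac = c(0.46, 0.18, 0, 0.17),
    p_frac = c(0, 0.20, 0, 0.074),
    k_frac = c(0, 0, 0.498, 0.141),
    price_per_50kg = c(4.3, 18.6, 12.7, 14.3),
    stringsAsFactors = FALSE
  ))
}
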