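#' Specification of a synthetic trial population
#'
#' Describes one season's population of interviewed fields and on-farm
#' trials: how many fields, the distribution of reported historical
#' yields (truncated normal), the dispersion of farmer's-practice
#' fertilizer rates, the yield-response structure and the sowing-date
#' window. Used by [sample_population()] to emulate the structure of the
#' observed trial populations so every downstream module can be exercised
#' without field data.
#'
#' @param season Season name.
#' @param n_fields Number of fields (trials) to generate.
#' @param hist_mean,hist_sd Mean and SD of reported historical yield,
#'   Mg/ha.
#' @param hist_range Truncation range `c(lo, hi)` for historical yield.
#' @param ffp_n_range,ffp_p_range,ffp_k_range Uniform ranges for the
#'   farmer's-practice N/P/K rates, kg/ha; wide enough to produce both
#'   under- and over-application relative to removal.
#' @param attainment Fraction of the target yield the season's conditions
#'   let the crop reach (caps the simulated yield response); 1 means the
#'   target is attainable.
#' @param noise_sd SD of the field-level yield noise, Mg/ha.
#' @param sowing_window `c(from, to)` ISO dates for sowing.
#' @param ffp_zinc_prob Probability a farmer's practice includes zinc
#'   sulfate.
#' @param seed Optional integer; fixes the whole generated stream.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(season,
                            n_fields,
                            hist_mean,
                            hist_sd,
                            hist_range,
                            ffp_n_range = c(95, 150),
                            ffp_p_range = c(8, 34),
                            ffp_k_range = c(20, 80),
                            attainment = 1,
                            noise_sd = 0.4,
                            sowing_window = NULL,
                            ffp_zinc_prob = 0,
                            seed = NULL) {
  season <- match.arg(season, c("kuruvai", "samba", "thaladi"))
  assert_scalar_num(n_fields, "n_fields", lo = 1)
  assert_scalar_num(hist_sd, "hist_sd", lo = 0)
  if (length(hist_range) != 2L || hist_range[1] >= hist_range[2]) {
    stop_input("'hist_range' must be c(lo, hi) with lo < hi")
  }
  for (nm in c("ffp_n_range", "ffp_p_range", "ffp_k_range")) {
    r <- get(nm)
    if (length(r) != 2L || r[1] > r[2]) stop_input("'", nm, "' must be c(lo, hi)")
  }
  assert_scalar_num(attainment, "attainment", lo = 0, hi = 1.5)
  assert_scalar_num(noise_sd, "noise_sd", lo = 0)
  assert_scalar_num(ffp_zinc_prob, "ffp_zinc_prob", lo = 0, hi = 1)
  structure(
    list(season = season, n_fields = as.integer(n_fields),
         hist_mean = hist_mean, hist_sd = hist_sd, hist_range = hist_range,
         ffp_n_range = ffp_n_range, ffp_p_range = ffp_p_range,
         ffp_k_range = ffp_k_range, attainment = attainment,
         noise_sd = noise_sd, sowing_window = sowing_window,
         ffp_zinc_prob = ffp_zinc_prob, seed = seed),
    class = "population_spec"
  )
}

#' Default per-season population specs
#'
#' Historical-yield distributions follow the interviewed populations
#' (kuruvai mean 4.8, SD 0.8, range 3.6-6.1; samba 4.8, 0.8, 3.6-6.4;
#' thaladi 4.4, 0.6, 3.6-5.6 Mg/ha), the field counts the observed trial
#' counts (14/40/20), seasonal attainment the observed measured-to-target
#' ratios (0.98/0.91/0.67) and zinc use in farmer practice 0/15/20% of
#' fields.
#'
#' @param season Season name, or `NULL` for all three.
#' @param n_fields Override of the per-season field count.
#' @param seed Optional seed stored in the spec(s).
#' @return A `population_spec` or named list of them.
#' @export
default_population_spec <- function(season = NULL, n_fields = NULL,
                                    seed = NULL) {
  mk <- function(season, n, mean, sd, range, attainment, sow, zinc) {
    population_spec(season, n_fields = n_fields %||% n, hist_mean = mean,
                    hist_sd = sd, hist_range = range, attainment = attainment,
                    sowing_window = sow, ffp_zinc_prob = zinc, seed = seed)
  }
  all <- list(
    kuruvai = mk("kuruvai", 14, 4.8, 0.8, c(3.6, 6.1), 0.98,
                 c("2014-06-08", "2014-06-23"), 0),
    samba = mk("samba", 40, 4.8, 0.8, c(3.6, 6.4), 0.91,
               c("2014-08-28", "2014-09-30"), 0.15),
    thaladi = mk("thaladi", 20, 4.4, 0.6, c(3.6, 5.6), 0.67,
                 c("2014-10-08", "2014-11-18"), 0.20)
  )
  if (is.null(season)) return(all)
  all[[match.arg(season, names(all))]]
}

# Truncated-normal draws by rejection: exact, and cheap at these n.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) {
    if (mean < lo || mean > hi) stop_input("degenerate truncation: mean outside range")
    return(rep(mean, n))
  }
  if (stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd) < 1e-6) {
    stop_input("truncation range has negligible mass under the normal")
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

season_varieties <- function(season) {
  switch(season,
    kuruvai = list(
      variety_info("ADT 43", 110, 5.0, 6.5),
      variety_info("ADT 36", 105, 5.0, 6.3)),
    samba = list(
      variety_info("CR 1009", 135, 5.5, 6.9),
      variety_info("BPT 5204", 130, 5.5, 6.7)),
    thaladi = list(
      variety_info("ADT 38", 130, 5.2, 6.2),
      variety_info("ADT 46", 125, 5.2, 6.2))
  )
}

#' Sample a synthetic interview and trial population
#'
#' Draws per-field interviews (historical yield from a truncated normal,
#' variety, sowing date, establishment method) and simulates one on-farm
#' trial per field with three treatments: the engine's own
#' recommendation (`ssnm`), the fixed blanket recommendation (`bfr`) and
#' a farmer's practice (`ffp`) with rates drawn from the configured
#' ranges. Simulated yield is `min(attainable, yield_without_n +
#' ae * N/1000) + noise`, where the attainable yield is the target scaled
#' by the season's attainment. Fully deterministic given `seed`.
#'
#' @param spec A [population_spec()] or a list of them (one per season).
#' @param params Season parameters ([season_params()] list or `NULL` for
#'   defaults).
#' @param catalog A [fertilizer_catalog()].
#' @return List with `interviews` (list of [field_interview()]) and
#'   `trials` (data frame in the trial-table layout, product masses in kg
#'   for the field).
#' @export
sample_population <- function(spec, params = NULL,
                              catalog = product_catalog_default()) {
  if (inherits(spec, "population_spec")) spec <- list(spec)
  params <- params %||% default_season_params()
  out_int <- list()
  out_tr <- list()
  for (sp in spec) {
    if (!is.null(sp$seed)) set.seed(sp$seed)
    res <- sample_one_season(sp, params, catalog)
    out_int <- c(out_int, res$interviews)
    out_tr[[length(out_tr) + 1L]] <- res$trials
  }
  trials <- do.call(rbind, out_tr)
  rownames(trials) <- NULL
  list(interviews = out_int, trials = trials)
}

sample_one_season <- function(spec, params, catalog) {
  sp_params <- resolve_params(params, spec$season)
  n <- spec$n_fields
  hist <- round(rtrunc_norm(n, spec$hist_mean, spec$hist_sd,
                            spec$hist_range[1], spec$hist_range[2]), 1)
  varieties <- season_varieties(spec$season)
  sow_win <- spec$sowing_window %||% c("2014-06-08", "2014-06-23")
  sow_from <- as.Date(sow_win[1])
  sow_span <- as.integer(as.Date(sow_win[2]) - sow_from)
  product_sets <- list(c("DAP", "MOP"), c("SSP", "MOP"),
                       c("17-17-17", "MOP"), c("DAP"))

  interviews <- vector("list", n)
  trial_rows <- vector("list", n)
  for (i in seq_len(n)) {
    v <- varieties[[sample.int(length(varieties), 1)]]
    establishment <- if (spec$season == "samba" && stats::runif(1) < 0.075) {
      "wet_seeded"
    } else "transplanted"
    seedling_age <- if (establishment == "transplanted") 25 else NULL
    sowing <- sow_from + sample.int(sow_span + 1L, 1L) - 1L
    est_date <- if (establishment == "transplanted") sowing + seedling_age else sowing
    iv <- field_interview(
      field_id = sprintf("%s-%03d", spec$season, i),
      field_area = round(stats::runif(1, 0.3, 1.0), 2),
      season = spec$season,
      irrigation_source = switch(spec$season, kuruvai = "tube_well",
                                 samba = "canal", thaladi = "rain_plus_canal"),
      variety = v,
      establishment = establishment,
      seedling_age = seedling_age,
      sowing_date = sowing,
      establishment_date = est_date,
      historical_yield = hist[i],
      prev_residue = if (spec$season == "thaladi") "retained_combine" else "removed",
      selected_products = product_sets[[sample.int(length(product_sets), 1)]]
    )
    interviews[[i]] <- iv
    trial_rows[[i]] <- simulate_trial(iv, sp_params, catalog, spec)
  }
  list(interviews = interviews, trials = do.call(rbind, trial_rows))
}

simulate_trial <- function(iv, sp, catalog, spec) {
  rec <- recommend(iv, catalog = catalog, params = sp)
  target <- rec$target_yield
  ywn <- max(0, target - sp$attainable_gain)
  attainable <- target * spec$attainment
  sim_yield <- function(n_applied) {
    response <- ywn + sp$agronomic_efficiency * n_applied / 1000
    max(0, round(min(attainable, response) + stats::rnorm(1, 0, spec$noise_sd), 2))
  }
  area <- iv$field_area

  masses_from_alloc <- function(alloc) {
    if (nrow(alloc) == 0) return(numeric(0))
    tapply(alloc$mass_kg, alloc$product, sum)
  }
  zinc_mass <- round_step(25 * area, 0.5)

  ssnm_products <- masses_from_alloc(rec$allocation)
  ssnm_products["zinc sulfate"] <- zinc_mass

  bfr_alloc <- allocate(bfr_schedule(), c("DAP", "MOP"), catalog, area)
  bfr_products <- masses_from_alloc(bfr_alloc)
  bfr_products["zinc sulfate"] <- zinc_mass

  ffp_rates <- c(
    n = round(stats::runif(1, spec$ffp_n_range[1], spec$ffp_n_range[2])),
    p = round(stats::runif(1, spec$ffp_p_range[1], spec$ffp_p_range[2])),
    k = round(stats::runif(1, spec$ffp_k_range[1], spec$ffp_k_range[2]))
  )
  ffp_products <- c(
    "DAP" = round_step(ffp_rates[["p"]] / 0.201 * area, 0.1),
    "MOP" = round_step(ffp_rates[["k"]] / 0.498 * area, 0.1)
  )
  ffp_n_from_dap <- ffp_products[["DAP"]] / area * 0.18
  ffp_products["urea"] <- round_step(
    max(0, ffp_rates[["n"]] - ffp_n_from_dap) / 0.46 * area, 0.1)
  if (stats::runif(1) < spec$ffp_zinc_prob) {
    ffp_products["zinc sulfate"] <- zinc_mass
  }
  ffp_n_apps <- if (stats::runif(1) < 0.69) 4L else 3L

  row <- function(treatment, yield, n, p, k, n_apps, products) {
    base <- data.frame(
      field_id = iv$field_id, season = iv$season, treatment = treatment,
      grain_yield = yield, n_rate = n, p_rate = p, k_rate = k,
      n_applications = n_apps, field_area = area,
      prev_residue = iv$prev_residue,
      target_yield = target,
      stringsAsFactors = FALSE, check.names = FALSE)
    for (prod in product_catalog_default()$name) {
      base[[prod]] <- if (prod %in% names(products)) products[[prod]] else 0
    }
    base
  }
  rbind(
    row("ssnm", sim_yield(rec$rates$n), rec$rates$n, rec$rates$p,
        rec$rates$k, 3L, ssnm_products),
    row("bfr", sim_yield(150), 150, 22, 42, 4L, bfr_products),
    row("ffp", sim_yield(ffp_rates[["n"]]), ffp_rates[["n"]],
        ffp_rates[["p"]], ffp_rates[["k"]], ffp_n_apps, ffp_products)
  )
}
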