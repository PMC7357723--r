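#' Season and region calibration parameters
#'
#' Bundles every per-season calibration constant used by the recommendation
#' engine: K input from irrigation water, the targeted soil-K drawdown, the
#' agronomic efficiency of fertilizer N, target-yield rules (increment,
#' cap, late-establishment cutoff and penalty) and the crop-removal
#' coefficients shared by the rate equations and the nutrient-balance
#' accounting.
#'
#' @param season Season name; one of `"kuruvai"`, `"samba"`, `"thaladi"`
#'   (the three irrigated rice seasons of the Cauvery Delta).
#' @param irrigation_k_input K delivered by irrigation water over the
#'   season, kg K/ha (>= 0).
#' @param water_k_conc Mean K concentration of irrigation water, mg/L.
#'   Informative only; the seasonal `irrigation_k_input` is what the
#'   equations use.
#' @param k_drawdown_target Targeted seasonal soil-K balance, kg K/ha.
#'   Negative values allow mining of soil K reserves (partial maintenance);
#'   0 means full maintenance.
#' @param agronomic_efficiency Expected kg of extra grain per kg fertilizer
#'   N, used to convert the targeted yield gain into an N rate. The engine
#'   is calibrated for the 14-15 kg/kg range typical of irrigated inbred
#'   rice.
#' @param attainable_gain Default attainable yield gain over the
#'   N-unfertilized yield, Mg/ha. Supplies `yield_without_n` as
#'   `target - attainable_gain` when no direct estimate is given.
#' @param target_increment Yield increment added to the farmer's historical
#'   yield before clamping to the varietal baseline window, Mg/ha.
#' @param target_increment_max Hard cap on how far the target may exceed
#'   the historical yield, Mg/ha.
#' @param late_establishment_cutoff `"MM-DD"` string or `NULL`. When set,
#'   crops established after this date (in the establishment year) have
#'   their target yield reduced by `late_penalty`.
#' @param late_penalty Target-yield reduction for late establishment,
#'   Mg/ha.
#' @param grain_p_removal,straw_p_removal P removed in grain and in straw
#'   per Mg of grain yield, kg P/Mg.
#' @param grain_k_removal,straw_k_removal K removed in grain and in straw
#'   per Mg of grain yield, kg K/Mg. Rice straw carries most (80-85%) of
#'   above-ground plant K, so `straw_k_removal` dominates.
#' @param residue_retention Fraction of straw nutrients effectively
#'   returned to the field when the previous crop was combine harvested
#'   and its residue retained.
#' @param prev_crop_yield Grain yield of the previous crop, Mg/ha; used to
#'   estimate the K input from retained residue. `NULL` where fields enter
#'   the season with residue removed.
#' @param pi_offset Days between panicle initiation and crop maturity
#'   (reproductive + ripening phase), used to place PI from the variety's
#'   growth duration.
#' @param early_dose_day Day after establishment for the early fertilizer
#'   application (must be <= 11).
#' @param early_k_fraction Fraction of total K applied with the early dose
#'   (the remainder goes at panicle initiation); the engine uses 0.50-0.58.
#'
#' @return An object of class `season_params`.
#' @seealso [default_season_params()] for the shipped per-season
#'   calibrations, [read_season_params()] to load a YAML config.
#' @export
season_params <- function(season,
                          irrigation_k_input,
                          k_drawdown_target,
                          agronomic_efficiency,
                          attainable_gain,
                          water_k_conc = 2.6,
                          target_increment = 1.0,
                          target_increment_max = 2.5,
                          late_establishment_cutoff = NULL,
                          late_penalty = 0,
                          grain_p_removal = 2.2,
                          straw_p_removal = 0.39,
                          grain_k_removal = 2.25,
                          straw_k_removal = 13.5,
                          residue_retention = 0.8,
                          prev_crop_yield = NULL,
                          pi_offset = 65,
                          early_dose_day = 7,
                          early_k_fraction = 0.55) {
  season <- match.arg(season, c("kuruvai", "samba", "thaladi"))
  assert_scalar_num(irrigation_k_input, "irrigation_k_input", lo = 0)
  assert_scalar_num(k_drawdown_target, "k_drawdown_target")
  assert_scalar_num(agronomic_efficiency, "agronomic_efficiency")
  if (agronomic_efficiency <= 0) {
    stop_input("'agronomic_efficiency' must be > 0")
  }
  assert_scalar_num(attainable_gain, "attainable_gain", lo = 0)
  assert_scalar_num(target_increment, "target_increment", lo = 0)
  assert_scalar_num(target_increment_max, "target_increment_max", lo = 0)
  if (target_increment > target_increment_max) {
    stop_input("'target_increment' must not exceed 'target_increment_max'")
  }
  assert_scalar_num(late_penalty, "late_penalty", lo = 0)
  for (nm in c("grain_p_removal", "straw_p_removal",
               "grain_k_removal", "straw_k_removal")) {
    assert_scalar_num(get(nm), nm, lo = 0)
  }
  if (straw_k_removal <= straw_p_removal) {
    stop_input("'straw_k_removal' must exceed 'straw_p_removal': straw ",
               "holds most plant K but only a minor share of plant P")
  }
  assert_scalar_num(residue_retention, "residue_retention", lo = 0, hi = 1)
  if (!is.null(prev_crop_yield)) {
    assert_scalar_num(prev_crop_yield, "prev_crop_yield", lo = 0)
  }
  assert_scalar_num(pi_offset, "pi_offset", lo = 1)
  assert_scalar_num(early_dose_day, "early_dose_day", lo = 0, hi = 11)
  assert_scalar_num(early_k_fraction, "early_k_fraction", lo = 0, hi = 1)
  if (!is.null(late_establishment_cutoff)) {
    if (!grepl("^[0-1][0-9]-[0-3][0-9]$", late_establishment_cutoff)) {
      stop_input("'late_establishment_cutoff' must be an \"MM-DD\" string")
    }
  }
  structure(
    list(
      season = season,
      irrigation_k_input = irrigation_k_input,
      water_k_conc = water_k_conc,
      k_drawdown_target = k_drawdown_target,
      agronomic_efficiency = agronomic_efficiency,
      attainable_gain = attainable_gain,
      target_increment = target_increment,
      target_increment_max = target_increment_max,
      late_establishment_cutoff = late_establishment_cutoff,
      late_penalty = late_penalty,
      grain_p_removal = grain_p_removal,
      straw_p_removal = straw_p_removal,
      grain_k_removal = grain_k_removal,
      straw_k_removal = straw_k_removal,
      residue_retention = residue_retention,
      prev_crop_yield = prev_crop_yield,
      pi_offset = pi_offset,
      early_dose_day = early_dose_day,
      early_k_fraction = early_k_fraction
    ),
    class = "season_params"
  )
}

#' Shipped per-season calibrations for the Cauvery Delta
#'
#' Irrigation-water K inputs are 25/8/4 kg K/ha for kuruvai/samba/thaladi
#' (tube-well versus canal versus rain-plus-canal water) and the targeted
#' K drawdowns are -30/-33/-4 kg K/ha. Kuruvai carries a target-yield
#' penalty of 0.4 Mg/ha for transplanting after 15 June; thaladi fields
#' receive combine-harvested residue from the preceding kuruvai crop, so
#' its calibration carries a previous-crop yield for the residue K input.
#'
#' @param season Season name, or `NULL` for a named list of all three.
#' @return A `season_params` object (or a named list of them).
#' @export
default_season_params <- function(season = NULL) {
  all <- list(
    kuruvai = season_params(
      "kuruvai",
      irrigation_k_input = 25,
      k_drawdown_target = -30,
      agronomic_efficiency = 15,
      attainable_gain = 1.8,
      late_establishment_cutoff = "06-15",
      late_penalty = 0.4
    ),
    samba = season_params(
      "samba",
      irrigation_k_input = 8,
      k_drawdown_target = -33,
      agronomic_efficiency = 14,
      attainable_gain = 1.82
    ),
    thaladi = season_params(
      "thaladi",
      irrigation_k_input = 4,
      k_drawdown_target = -4,
      agronomic_efficiency = 14,
      attainable_gain = 1.82,
      prev_crop_yield = 4.8
    )
  )
  if (is.null(season)) return(all)
  season <- match.arg(season, names(all))
  all[[season]]
}

#' Read season parameters from a YAML config
#'
#' The file maps season names to parameter fields as accepted by
#' [season_params()]; fields left out take the function defaults. See
#' `system.file("extdata", "season_params.yaml", package = "ssnmrice")`
#' for the shipped config.
#'
#' @param path Path to a YAML file keyed by season name.
#' @return Named list of `season_params`, one per season in the file.
#' @export
read_season_params <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw))) {
    stop_input("season params config must map season names to fields")
  }
  out <- lapply(names(raw), function(nm) {
    args <- raw[[nm]]
    args$season <- nm
    do.call(season_params, args)
  })
  names(out) <- names(raw)
  out
}

#' @export
print.season_params <- function(x, ...) {
  cat(sprintf("Season parameters: %s\n", x$season))
  cat(sprintf("  irrigation K input:  %g kg/ha (water K %g mg/L)\n",
              x$irrigation_k_input, x$water_k_conc))
  cat(sprintf("  targeted K drawdown: %g kg/ha\n", x$k_drawdown_target))
  cat(sprintf("  agronomic efficiency: %g kg grain/kg N\n",
              x$agronomic_efficiency))
  cat(sprintf("  target increment: +%g Mg/ha (cap +%g)\n",
              x$target_increment, x$target_increment_max))
  if (!is.null(x$late_establishment_cutoff)) {
    cat(sprintf("  late establishment after %s: -%g Mg/ha\n",
                x$late_establishment_cutoff, x$late_penalty))
  }
  cat(sprintf("  removal kg/Mg grain: P %g+%g, K %g+%g (grain+straw)\n",
              x$grain_p_removal, x$straw_p_removal,
              x$grain_k_removal, x$straw_k_removal))
  invisible(x)
}
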