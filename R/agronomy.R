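#' Elemental nutrient rates
#'
#' Container for fertilizer N, P, K rates in kg/ha on an elemental basis
#' (not P2O5/K2O).
#'
#' @param n,p,k Rates in kg/ha, all >= 0.
#' @return An object of class `nutrient_rates`.
#' @export
nutrient_rates <- function(n = 0, p = 0, k = 0) {
  for (nm in c("n", "p", "k")) assert_scalar_num(get(nm), nm, lo = 0)
  structure(list(n = n, p = p, k = k), class = "nutrient_rates")
}

#' @export
print.nutrient_rates <- function(x, ...) {
  cat(sprintf("N %g, P %g, K %g kg/ha (elemental)\n", x$n, x$p, x$k))
  invisible(x)
}

# Estimated crop P removal, kg P/ha, for a given grain yield.  When the
# field carries retained combine-harvested residue, only the unreturned
# share of straw P counts as removed.
p_removal <- function(yield, prev_residue, params) {
  straw_factor <- if (identical(prev_residue, "removed")) 1 else
    (1 - params$residue_retention)
  yield * (params$grain_p_removal + params$straw_p_removal * straw_factor)
}

# Estimated crop K removal, kg K/ha.  Residue K is handled on the input
# side (residue_k_input), not by discounting removal.
k_removal <- function(yield, params) {
  yield * (params$grain_k_removal + params$straw_k_removal)
}

# K input from retained residue of the previous crop, kg K/ha: previous
# grain yield x straw K coefficient x retention efficiency.
residue_k_input <- function(prev_residue, params, prev_yield = NULL) {
  if (identical(prev_residue, "removed")) return(0)
  prev_yield <- prev_yield %||% params$prev_crop_yield
  if (is.null(prev_yield)) {
    stop_input("residue retained but no previous-crop yield available; ",
               "set 'prev_crop_yield' in the season parameters")
  }
  prev_yield * params$straw_k_removal * params$residue_retention
}

#' Set the target yield for a field
#'
#' The target is the farmer's reported historical yield plus a fixed
#' increment, clamped into the varietal baseline yield window, then
#' reduced by the late-establishment penalty where the season defines a
#' cutoff date. The result never drops below the historical yield and
#' never exceeds it by more than `target_increment_max`.
#'
#' @param interview A [field_interview()].
#' @param params [season_params()] for the interview's season.
#' @return Target yield, Mg/ha (rounded to 0.1).
#' @export
set_target_yield <- function(interview, params) {
  stopifnot(inherits(interview, "field_interview"))
  if (!inherits(params, "season_params")) {
    stop_input("no season parameters supplied for season '",
               interview$season, "'")
  }
  v <- interview$variety
  if (is.null(v$baseline_yield_lo) || is.null(v$baseline_yield_hi)) {
    stop_input("variety '", v$name, "' has no baseline yield window")
  }
  hist <- interview$historical_yield
  target <- clamp(hist + params$target_increment,
                  v$baseline_yield_lo, v$baseline_yield_hi)
  if (!is.null(params$late_establishment_cutoff)) {
    yr <- format(interview$establishment_date, "%Y")
    cutoff <- as.Date(paste0(yr, "-", params$late_establishment_cutoff))
    if (interview$establishment_date > cutoff) {
      target <- target - params$late_penalty
    }
  }
  target <- min(target, hist + params$target_increment_max)
  target <- max(target, hist)
  round_step(target, 0.1)
}

#' Fertilizer N rate from the targeted yield gain
#'
#' The yield-gain approach: the N rate is the gain over the yield the
#' field would produce without fertilizer N, divided by the agronomic
#' efficiency of applied N, `1000 * (target - yield_without_n) / AE`.
#'
#' @param target_yield Target yield, Mg/ha.
#' @param params [season_params()] carrying `agronomic_efficiency` and the
#'   default `attainable_gain`.
#' @param yield_without_n Yield without fertilizer N (the indigenous-N
#'   supply yield), Mg/ha. Defaults to `target_yield - attainable_gain`.
#' @return N rate, kg N/ha, rounded to the nearest 1 kg.
#' @export
n_rate <- function(target_yield, params, yield_without_n = NULL) {
  assert_scalar_num(target_yield, "target_yield", lo = 0)
  if (params$agronomic_efficiency <= 0) {
    stop_input("'agronomic_efficiency' must be > 0")
  }
  yield_without_n <- yield_without_n %||%
    max(0, target_yield - params$attainable_gain)
  assert_scalar_num(yield_without_n, "yield_without_n", lo = 0)
  if (yield_without_n > target_yield) {
    stop_input("'yield_without_n' cannot exceed 'target_yield'")
  }
  gain <- target_yield - yield_without_n
  round_step(1000 * gain / params$agronomic_efficiency, 1)
}

#' Fertilizer P rate by full maintenance
#'
#' Sets fertilizer P equal to the estimated crop P removal at the target
#' yield, so that achieving the target leaves the soil P balance at
#' exactly zero. On residue-retained fields only the unreturned share of
#' straw P counts toward removal.
#'
#' @param target_yield Target yield, Mg/ha.
#' @param prev_residue `"removed"` or `"retained_combine"`.
#' @param params [season_params()].
#' @return P rate, kg P/ha (elemental), rounded to the nearest 1 kg.
#' @export
p_rate <- function(target_yield, prev_residue = "removed", params) {
  assert_scalar_num(target_yield, "target_yield", lo = 0)
  prev_residue <- match.arg(prev_residue, c("removed", "retained_combine"))
  round_step(p_removal(target_yield, prev_residue, params), 1)
}

#' Fertilizer K rate by partial maintenance
#'
#' Fertilizer K is the estimated crop K removal at the target yield minus
#' the non-fertilizer K inputs (irrigation water, retained residue of the
#' previous crop) plus the targeted soil-K drawdown (negative values allow
#' mining, reducing the rate), floored at zero. When the floor is not hit
#' and the target yield is achieved, the realized K balance equals the
#' targeted drawdown by construction.
#'
#' @inheritParams p_rate
#' @param prev_yield Previous-crop grain yield for the residue K input,
#'   Mg/ha; defaults to the season's `prev_crop_yield`.
#' @return K rate, kg K/ha (elemental), rounded to the nearest 1 kg.
#' @export
k_rate <- function(target_yield, prev_residue = "removed", params,
                   prev_yield = NULL) {
  assert_scalar_num(target_yield, "target_yield", lo = 0)
  prev_residue <- match.arg(prev_residue, c("removed", "retained_combine"))
  need <- k_removal(target_yield, params) -
    params$irrigation_k_input -
    residue_k_input(prev_residue, params, prev_yield) +
    params$k_drawdown_target
  max(0, round_step(need, 1))
}
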