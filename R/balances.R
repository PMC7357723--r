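#' Post-hoc P and K input-output balance for one field
#'
#' Accounts inputs (fertilizer; for K also irrigation water and retained
#' residue of the previous crop) against the estimated crop removal at
#' the achieved yield, using the same removal coefficients as the rate
#' equations. Irrigation water contributes no P. Organic inputs other
#' than rice residue and losses other than crop removal are excluded.
#'
#' With a full-maintenance P rate and achieved yield equal to the target,
#' the P balance is zero; with a partial-maintenance K rate (floor not
#' hit) the K balance equals the season's targeted drawdown.
#'
#' @param rates [nutrient_rates()] actually applied.
#' @param achieved_yield Measured grain yield, Mg/ha (>= 0).
#' @param params [season_params()] for the field's season.
#' @param prev_residue `"removed"` or `"retained_combine"`.
#' @param prev_yield Previous-crop yield for the residue K input, Mg/ha;
#'   defaults to the season's `prev_crop_yield`.
#' @return An object of class `nutrient_balance`: `p_balance`,
#'   `k_balance` (kg/ha, inputs minus removal) and the individual
#'   components.
#' @export
estimate_balance <- function(rates, achieved_yield, params,
                             prev_residue = "removed", prev_yield = NULL) {
  stopifnot(inherits(rates, "nutrient_rates"))
  assert_scalar_num(achieved_yield, "achieved_yield", lo = 0)
  prev_residue <- match.arg(prev_residue, c("removed", "retained_combine"))
  p_rem <- p_removal(achieved_yield, prev_residue, params)
  k_rem <- k_removal(achieved_yield, params)
  res_k <- residue_k_input(prev_residue, params, prev_yield)
  structure(
    list(
      p_balance = rates$p - p_rem,
      k_balance = rates$k + params$irrigation_k_input + res_k - k_rem,
      fertilizer_p = rates$p,
      fertilizer_k = rates$k,
      irrigation_k = params$irrigation_k_input,
      residue_k = res_k,
      p_removal = p_rem,
      k_removal = k_rem
    ),
    class = "nutrient_balance"
  )
}

#' @export
print.nutrient_balance <- function(x, ...) {
  cat(sprintf("P balance: %6.1f kg/ha  (fertilizer %g - removal %.1f)\n",
              x$p_balance, x$fertilizer_p, x$p_removal))
  cat(sprintf("K balance: %6.1f kg/ha  (fertilizer %g + irrigation %g + residue %.1f - removal %.1f)\n",
              x$k_balance, x$fertilizer_k, x$irrigation_k, x$residue_k,
              x$k_removal))
  invisible(x)
}

#' Per-field balance table for a trial population
#'
#' @param trials Trial data frame (see [summarize_trials()]); requires a
#'   `prev_residue` column.
#' @param params Named list of [season_params()] keyed by season, or
#'   `NULL` for the shipped defaults.
#' @return Data frame with one row per trial row: `field_id`,
#'   `treatment`, `season`, `p_balance`, `k_balance` and component
#'   columns.
#' @export
balance_table <- function(trials, params = NULL) {
  params <- params %||% default_season_params()
  if (!"prev_residue" %in% names(trials)) {
    stop_input("trial table needs a 'prev_residue' column for balances")
  }
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    sp <- resolve_params(params, trials$season[i])
    b <- estimate_balance(
      nutrient_rates(trials$n_rate[i], trials$p_rate[i], trials$k_rate[i]),
      trials$grain_yield[i], sp, trials$prev_residue[i])
    data.frame(field_id = trials$field_id[i],
               treatment = trials$treatment[i],
               season = trials$season[i],
               p_balance = round(b$p_balance, 1),
               k_balance = round(b$k_balance, 1),
               fertilizer_p = b$fertilizer_p,
               fertilizer_k = b$fertilizer_k,
               irrigation_k = b$irrigation_k,
               residue_k = round(b$residue_k, 1),
               p_removal = round(b$p_removal, 1),
               k_removal = round(b$k_removal, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
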