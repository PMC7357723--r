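#' Economic parameters for the financial analysis
#'
#' @param msp Minimum support price of paddy, US$ per Mg (default 222).
#' @param labor_per_application Labor cost of one fertilizer application,
#'   US$ per ha (default 9.5).
#' @param exchange_rate INR per US$ (63, informative; all analysis is in
#'   US$).
#' @return An object of class `econ_params`.
#' @export
econ_params <- function(msp = 222, labor_per_application = 9.5,
                        exchange_rate = 63) {
  for (nm in c("msp", "labor_per_application", "exchange_rate")) {
    v <- get(nm)
    assert_scalar_num(v, nm)
    if (v <= 0) stop_input("'", nm, "' must be > 0")
  }
  structure(list(msp = msp, labor_per_application = labor_per_application,
                 exchange_rate = exchange_rate),
            class = "econ_params")
}

#' One treatment outcome on one trial field
#'
#' @param field_id,season,treatment Identifiers; `treatment` is one of
#'   `"ssnm"`, `"bfr"`, `"ffp"`, `"ssnm_plus_k"`, `"ssnm_reference"`.
#' @param grain_yield Measured grain yield, Mg/ha at 14% moisture.
#' @param rates [nutrient_rates()] applied.
#' @param products Named numeric vector of product masses in kg for the
#'   field (may be empty).
#' @param n_applications Number of fertilizer applications.
#' @param field_area Field/plot area, ha.
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(field_id, season, treatment, grain_yield, rates,
                         products = numeric(), n_applications = 0L,
                         field_area = 1) {
  treatment <- match.arg(treatment, c("ssnm", "bfr", "ffp", "ssnm_plus_k",
                                      "ssnm_reference"))
  assert_scalar_num(grain_yield, "grain_yield", lo = 0)
  stopifnot(inherits(rates, "nutrient_rates"))
  if (length(products) && is.null(names(products))) {
    stop_input("'products' must be a named vector of masses")
  }
  any_fert <- rates$n + rates$p + rates$k > 0 || sum(products) > 0
  if (any_fert && n_applications < 1) {
    stop_input("'n_applications' must be >= 1 when fertilizer is applied")
  }
  structure(list(field_id = as.character(field_id), season = season,
                 treatment = treatment, grain_yield = grain_yield,
                 rates = rates, products = products,
                 n_applications = as.integer(n_applications),
                 field_area = field_area),
            class = "trial_record")
}

#' Total fertilizer cost of a trial record
#'
#' Product cost (mass / 50 x price per 50-kg bag, scaled to per-hectare)
#' plus application labor: `n_applications x labor_per_application`.
#'
#' @param record A [trial_record()].
#' @param catalog A [fertilizer_catalog()] resolving every product used.
#' @param econ [econ_params()].
#' @return Total fertilizer cost, US$ per ha.
#' @export
total_fertilizer_cost <- function(record, catalog = product_catalog_default(),
                                  econ = econ_params()) {
  stopifnot(inherits(record, "trial_record"))
  product_cost <- 0
  if (length(record$products)) {
    idx <- match(names(record$products), catalog$name)
    if (anyNA(idx)) {
      stop_input("unknown product(s): ",
                 paste(names(record$products)[is.na(idx)], collapse = ", "))
    }
    product_cost <- sum(record$products / 50 * catalog$price_per_50kg[idx]) /
      record$field_area
  }
  product_cost + record$n_applications * econ$labor_per_application
}

#' Partial factor productivity of fertilizer N
#'
#' `PFP = 1000 x GY / FN`, kg grain per kg fertilizer N.
#'
#' @param grain_yield Grain yield, Mg/ha.
#' @param fertilizer_n Fertilizer N rate, kg/ha; must be > 0 (PFP is
#'   undefined for unfertilized plots).
#' @return PFP, kg grain per kg N (unrounded; summaries round to
#'   integers).
#' @export
pfp <- function(grain_yield, fertilizer_n) {
  assert_scalar_num(grain_yield, "grain_yield", lo = 0)
  assert_scalar_num(fertilizer_n, "fertilizer_n")
  if (fertilizer_n <= 0) {
    stop_input("PFP is undefined for 'fertilizer_n' <= 0")
  }
  1000 * grain_yield / fertilizer_n
}

#' Gross return above fertilizer cost
#'
#' Grain yield valued at the minimum support price minus the total
#' fertilizer cost; may be negative.
#'
#' @param grain_yield Grain yield, Mg/ha.
#' @param total_cost Total fertilizer cost, US$ per ha.
#' @param econ [econ_params()].
#' @return US$ per ha.
#' @export
gross_return_above_fert <- function(grain_yield, total_cost,
                                    econ = econ_params()) {
  grain_yield * econ$msp - total_cost
}

#' Added net benefit of one treatment over another
#'
#' Difference in gross return above fertilizer cost between two
#' treatments on the same field; antisymmetric under swapping the
#' treatments.
#'
#' @param grf_a,grf_b Gross returns above fertilizer cost, US$ per ha.
#' @return `grf_a - grf_b`, US$ per ha.
#' @export
added_net_benefit <- function(grf_a, grf_b) grf_a - grf_b

#' Empirical exceedance curve of added net benefit
#'
#' For each threshold `t`, the fraction of fields whose added net benefit
#' is at least `t` (ties count as exceeding). The curve is non-increasing
#' in the threshold. The probability of financial loss, `P(ANB < 0)`, is
#' attached as attribute `"loss_probability"`.
#'
#' @param anb_values Added net benefits across fields, US$ per ha
#'   (non-empty).
#' @param thresholds Thresholds to evaluate; defaults to the sorted
#'   unique values.
#' @return Data frame with columns `threshold` and `probability`, with
#'   attribute `"loss_probability"` (also via [loss_probability()]).
#' @export
exceedance_curve <- function(anb_values, thresholds = NULL) {
  if (length(anb_values) == 0 || !is.numeric(anb_values)) {
    stop_input("'anb_values' must be a non-empty numeric vector")
  }
  thresholds <- thresholds %||% sort(unique(anb_values))
  prob <- vapply(thresholds, function(t) mean(anb_values >= t), numeric(1))
  out <- data.frame(threshold = thresholds, probability = prob)
  attr(out, "loss_probability") <- mean(anb_values < 0)
  out
}

#' Probability of financial loss
#'
#' Fraction of fields with negative added net benefit.
#'
#' @param anb_values Added net benefits across fields, US$ per ha.
#' @return A fraction in \[0, 1\].
#' @export
loss_probability <- function(anb_values) {
  if (length(anb_values) == 0) stop_input("'anb_values' must be non-empty")
  mean(anb_values < 0)
}

#' Measured yield as a percentage of the target
#'
#' @param measured Measured grain yield, Mg/ha.
#' @param target Target yield, Mg/ha (> 0).
#' @return `100 * measured / target` (unrounded; summaries round to
#'   integers).
#' @export
percent_of_target <- function(measured, target) {
  assert_scalar_num(measured, "measured", lo = 0)
  assert_scalar_num(target, "target")
  if (target <= 0) stop_input("'target' must be > 0")
  100 * measured / target
}

#' Per-treatment economic summary of a trial population
#'
#' Computes per-field total fertilizer cost, PFP and gross return above
#' fertilizer cost, then averages within season and treatment (per-field
#' first, means second). Added net benefit is computed per field for the
#' field-specific treatment against each reference treatment present and
#' then averaged.
#'
#' @param trials Data frame as produced by [sample_population()] /
#'   [read_trials()]: columns `field_id`, `season`, `treatment`,
#'   `grain_yield`, `n_rate`, `p_rate`, `k_rate`, `n_applications`,
#'   `field_area` and one column per product mass (kg for the field).
#' @param catalog A [fertilizer_catalog()].
#' @param econ [econ_params()].
#' @return List with `summary` (season x treatment means: `cost`,
#'   `grain_yield`, `pfp`, `grf`) and `anb` (per season and treatment
#'   pair: mean added net benefit, loss probability, n fields).
#' @export
summarize_trials <- function(trials, catalog = product_catalog_default(),
                             econ = econ_params()) {
  per <- per_field_economics(trials, catalog, econ)
  summary <- stats::aggregate(
    cbind(cost, grain_yield, pfp, grf) ~ season + treatment,
    data = per, FUN = mean)
  summary$cost <- round(summary$cost)
  summary$pfp <- round(summary$pfp)
  summary$grf <- round(summary$grf)
  summary$grain_yield <- round(summary$grain_yield, 1)
  summary <- summary[order(summary$season, summary$treatment), ]
  rownames(summary) <- NULL

  anb_rows <- list()
  for (ref in intersect(c("ffp", "bfr"), unique(per$treatment))) {
    wide <- merge(per[per$treatment == "ssnm",
                      c("field_id", "season", "grf")],
                  per[per$treatment == ref, c("field_id", "grf")],
                  by = "field_id", suffixes = c("_ssnm", "_ref"))
    if (nrow(wide) == 0) next
    wide$anb <- added_net_benefit(wide$grf_ssnm, wide$grf_ref)
    for (s in unique(wide$season)) {
      v <- wide$anb[wide$season == s]
      anb_rows[[length(anb_rows) + 1L]] <- data.frame(
        season = s, comparison = paste0("ssnm-", ref),
        mean_anb = round(mean(v)), loss_probability = loss_probability(v),
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  anb <- if (length(anb_rows)) do.call(rbind, anb_rows) else NULL
  list(summary = summary, anb = anb, per_field = per)
}

per_field_economics <- function(trials, catalog, econ) {
  fixed <- c("field_id", "season", "treatment", "grain_yield", "n_rate",
             "p_rate", "k_rate", "n_applications", "field_area")
  missing <- setdiff(setdiff(fixed, "field_area"), names(trials))
  if (length(missing)) {
    stop_input("trial table is missing columns: ",
               paste(missing, collapse = ", "))
  }
  if (!"field_area" %in% names(trials)) trials$field_area <- 1
  prod_cols <- setdiff(names(trials), c(fixed, "prev_residue", "target_yield"))
  out <- trials[c("field_id", "season", "treatment", "grain_yield")]
  out$cost <- vapply(seq_len(nrow(trials)), function(i) {
    masses <- unlist(trials[i, prod_cols, drop = FALSE])
    masses <- masses[!is.na(masses) & masses > 0]
    rec <- trial_record(trials$field_id[i], trials$season[i],
                        trials$treatment[i], trials$grain_yield[i],
                        nutrient_rates(trials$n_rate[i], trials$p_rate[i],
                                       trials$k_rate[i]),
                        products = masses,
                        n_applications = trials$n_applications[i],
                        field_area = trials$field_area[i])
    total_fertilizer_cost(rec, catalog, econ)
  }, numeric(1))
  out$pfp <- ifelse(trials$n_rate > 0,
                    1000 * trials$grain_yield / trials$n_rate, NA_real_)
  out$grf <- gross_return_above_fert(trials$grain_yield, out$cost, econ)
  out
}
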