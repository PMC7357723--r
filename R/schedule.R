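new_application_schedule <- function(events, totals = NULL) {
  stopifnot(is.data.frame(events),
            all(c("dae", "stage", "n", "p", "k") %in% names(events)))
  if (is.unsorted(events$dae, strictly = TRUE)) {
    stop_input("event days after establishment must be strictly increasing")
  }
  if (events$stage[1] == "early" && events$dae[1] > 11) {
    stop_input("the early application must fall within 11 days of establishment")
  }
  if (!is.null(totals)) {
    for (nm in c("n", "p", "k")) {
      if (abs(sum(events[[nm]]) - totals[[nm]]) > 0.5) {
        stop_input("scheduled ", toupper(nm), " doses do not conserve the ",
                   "total rate")
      }
    }
  }
  rownames(events) <- NULL
  structure(list(events = events, n_applications = nrow(events)),
            class = "application_schedule")
}

#' @export
print.application_schedule <- function(x, ...) {
  cat(sprintf("Application schedule (%d applications)\n", x$n_applications))
  ev <- x$events
  for (i in seq_len(nrow(ev))) {
    cat(sprintf("  DAE %3d  %-18s N %5.1f  P %5.1f  K %5.1f kg/ha\n",
                as.integer(ev$dae[i]), ev$stage[i],
                ev$n[i], ev$p[i], ev$k[i]))
  }
  invisible(x)
}

#' Days after establishment of the three critical growth stages
#'
#' Panicle initiation is placed by counting back a fixed reproductive-plus-
#' ripening offset from maturity: `PI = duration_in_main_field - pi_offset`,
#' where the in-field duration for transplanted rice is the total growth
#' duration minus the seedling age (days spent in the nursery), and the
#' full duration for direct-seeded rice. The early dose sits at a fixed
#' day (default 7, always within the first 11 days) and active tillering
#' midway between the early dose and PI (rounded down).
#'
#' @param variety A [variety_info()].
#' @param establishment `"transplanted"`, `"wet_seeded"` or `"dry_seeded"`.
#' @param seedling_age Seedling age at transplanting, days (transplanted
#'   only).
#' @param params [season_params()] supplying `pi_offset` and
#'   `early_dose_day`; individual values may be overridden.
#' @param pi_offset,early_dose_day Optional overrides of the season
#'   parameters.
#' @return Named integer vector `c(early, tillering, pi)`, days after
#'   establishment (establishment day = 0).
#' @export
stage_days <- function(variety, establishment, seedling_age = NULL,
                       params = NULL, pi_offset = NULL, early_dose_day = NULL) {
  establishment <- match.arg(establishment,
                             c("transplanted", "wet_seeded", "dry_seeded"))
  pi_offset <- pi_offset %||% params$pi_offset %||% 65
  early <- early_dose_day %||% params$early_dose_day %||% 7
  duration <- variety$duration
  if (establishment == "transplanted") {
    if (is.null(seedling_age)) {
      stop_input("'seedling_age' is required for transplanted rice")
    }
    if (seedling_age >= duration) {
      stop_input("'seedling_age' must be less than the growth duration")
    }
    duration <- duration - seedling_age
  }
  dae_pi <- duration - pi_offset
  if (dae_pi <= early + 1) {
    stop_input("growth duration too short to place panicle initiation ",
               "after the early application")
  }
  dae_till <- floor((early + dae_pi) / 2)
  c(early = as.integer(early), tillering = as.integer(dae_till),
    pi = as.integer(dae_pi))
}

#' Split total fertilizer N across the three applications
#'
#' The standard distribution is 24% early, 38% at active tillering and
#' 38% at panicle initiation. When the estimated PI date falls before 30
#' days after establishment the season is too compressed for a small
#' starter dose, and the split switches to three equal doses (strictly
#' `dae_pi < 30`; PI at exactly 30 keeps 24/38/38). Doses land on a
#' 0.5-kg grid with largest-remainder repair so they sum exactly to the
#' total.
#'
#' @param total_n Total N rate, kg/ha (>= 0).
#' @param dae_pi Estimated panicle-initiation day after establishment.
#' @return Numeric vector of three doses (early, tillering, PI), kg N/ha.
#' @export
split_n <- function(total_n, dae_pi) {
  if (!is.numeric(total_n) || length(total_n) != 1L || is.na(total_n) ||
      total_n < 0) {
    stop_input("'total_n' must be a single non-negative number")
  }
  fractions <- if (dae_pi >= 30) c(0.24, 0.38, 0.38) else rep(1 / 3, 3)
  largest_remainder_split(total_n, fractions, step = 0.5)
}

#' Split P and K between the early and panicle-initiation applications
#'
#' All P goes with the early application. K is split between the early
#' dose and panicle initiation; the early share is 50-58% of total K
#' (default 0.55).
#'
#' @param total_p,total_k Total rates, kg/ha.
#' @param early_k_fraction Fraction of K applied early, in \[0, 1\].
#' @return List with `early = c(p, k)` and `pi = c(p, k)` components,
#'   kg/ha; the per-nutrient sums equal the totals.
#' @export
split_pk <- function(total_p, total_k, early_k_fraction = 0.55) {
  assert_scalar_num(total_p, "total_p", lo = 0)
  assert_scalar_num(total_k, "total_k", lo = 0)
  if (!is.numeric(early_k_fraction) || early_k_fraction < 0 ||
      early_k_fraction > 1) {
    stop_input("'early_k_fraction' must be a fraction in [0, 1]")
  }
  early_k <- round_step(early_k_fraction * total_k, 0.5)
  list(early = c(p = total_p, k = early_k),
       pi = c(p = 0, k = total_k - early_k))
}

#' Build the three-application SSNM schedule
#'
#' Composes [stage_days()], [split_n()] and [split_pk()] into a dated
#' schedule: early (N + all P + the early K share), active tillering
#' (N only) and panicle initiation (N + remaining K). Always exactly
#' three applications.
#'
#' @param rates Total [nutrient_rates()].
#' @param interview A [field_interview()] (supplies variety,
#'   establishment method and seedling age).
#' @param params [season_params()].
#' @return An `application_schedule` with 3 events.
#' @export
ssnm_schedule <- function(rates, interview, params) {
  stopifnot(inherits(rates, "nutrient_rates"))
  days <- stage_days(interview$variety, interview$establishment,
                     interview$seedling_age, params)
  n_doses <- split_n(rates$n, days[["pi"]])
  pk <- split_pk(rates$p, rates$k, params$early_k_fraction)
  events <- data.frame(
    dae = as.integer(days),
    stage = c("early", "active_tillering", "panicle_initiation"),
    n = n_doses,
    p = c(pk$early[["p"]], 0, pk$pi[["p"]]),
    k = c(pk$early[["k"]], 0, pk$pi[["k"]]),
    stringsAsFactors = FALSE
  )
  new_application_schedule(events, totals = rates)
}

#' The blanket fertilizer recommendation schedule
#'
#' The fixed regional reference practice for irrigated inbred rice:
#' 150 kg N/ha and 42 kg K/ha in four equal splits (basal, active
#' tillering, panicle initiation, heading) and all 22 kg P/ha basal.
#'
#' @param dae Days after establishment of the four applications.
#' @return An `application_schedule` with 4 events.
#' @export
bfr_schedule <- function(dae = c(0, 21, 42, 63)) {
  if (length(dae) != 4L) stop_input("'dae' must give four application days")
  events <- data.frame(
    dae = as.integer(dae),
    stage = c("early", "active_tillering", "panicle_initiation", "heading"),
    n = rep(150 / 4, 4),
    p = c(22, 0, 0, 0),
    k = rep(42 / 4, 4),
    stringsAsFactors = FALSE
  )
  new_application_schedule(events,
                           totals = nutrient_rates(n = 150, p = 22, k = 42))
}

#' Total nutrients in a schedule
#'
#' @param schedule An `application_schedule`.
#' @return A [nutrient_rates()] with the per-nutrient event sums.
#' @export
schedule_totals <- function(schedule) {
  ev <- schedule$events
  nutrient_rates(n = sum(ev$n), p = sum(ev$p), k = sum(ev$k))
}
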