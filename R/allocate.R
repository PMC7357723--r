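add_mass <- function(masses, name, mass) {
  cur <- if (name %in% names(masses)) masses[[name]] else 0
  masses[name] <- cur + mass
  masses
}

# Per-hectare product masses for one early-type event (the event that may
# carry P and the farmer-selected sources).  Returns a named numeric
# vector of kg/ha per product plus an attribute with unmet nutrients.
allocate_early_event <- function(n, p, k, selected, catalog) {
  masses <- numeric(0)
  shortfall <- c(n = 0, p = 0, k = 0)
  sel_rows <- lapply(selected, catalog_row, catalog = catalog)

  p_left <- p
  k_left <- k
  n_left <- n

  if (p > 0) {
    p_idx <- which(vapply(sel_rows, function(r) r$p_frac > 0, logical(1)))[1]
    if (is.na(p_idx)) {
      # fall back to DAP if present, else it is an allocation error
      if ("DAP" %in% catalog$name) {
        p_src <- catalog_row(catalog, "DAP")
      } else {
        stop_input("P is required but no P-bearing product is available")
      }
    } else {
      p_src <- sel_rows[[p_idx]]
    }
    mass <- round_step(p / p_src$p_frac, 0.1)
    masses[p_src$name] <- mass
    p_left <- p - mass * p_src$p_frac
    n_left <- n_left - mass * p_src$n_frac
    k_left <- k_left - mass * p_src$k_frac
  }

  if (k_left > 0.05) {
    k_idx <- which(vapply(sel_rows, function(r) r$k_frac > 0 &&
                            !(r$name %in% names(masses)), logical(1)))[1]
    k_src <- if (!is.na(k_idx)) sel_rows[[k_idx]] else catalog_row(catalog, "MOP")
    mass <- round_step(max(0, k_left) / k_src$k_frac, 0.1)
    masses <- add_mass(masses, k_src$name, mass)
    k_left <- k_left - mass * k_src$k_frac
    n_left <- n_left - mass * k_src$n_frac
  }

  if (n_left > 0.05) {
    urea <- catalog_row(catalog, "urea")
    mass <- round_step(n_left / urea$n_frac, 0.1)
    masses <- add_mass(masses, "urea", mass)
    n_left <- n_left - mass * urea$n_frac
  }

  if (p_left < -0.5) {
    warning("early P oversupplied by ", round(-p_left, 2), " kg/ha by the ",
            "selected sources", call. = FALSE)
  }
  shortfall["n"] <- max(0, n_left)
  shortfall["p"] <- max(0, p_left)
  shortfall["k"] <- max(0, k_left)
  attr(masses, "shortfall") <- shortfall
  masses
}

# Later events: N always as urea, K always as muriate of potash.
allocate_later_event <- function(n, p, k, catalog) {
  masses <- numeric(0)
  if (p > 0.05) {
    stop_input("P can only be allocated in the early (basal) application")
  }
  if (n > 0) {
    urea <- catalog_row(catalog, "urea")
    masses["urea"] <- round_step(n / urea$n_frac, 0.1)
  }
  if (k > 0) {
    mop <- catalog_row(catalog, "MOP")
    masses["MOP"] <- round_step(k / mop$k_frac, 0.1)
  }
  attr(masses, "shortfall") <- c(n = 0, p = 0, k = 0)
  masses
}

#' Convert scheduled nutrient rates into fertilizer product masses
#'
#' The early application satisfies P exactly with the first P-bearing
#' product in the farmer's preference order (its N and K contributions
#' are counted), fills remaining K with the farmer's K source (muriate of
#' potash otherwise) and tops up remaining N with urea — never a negative
#' top-up. Later applications use urea for N and muriate of potash for K
#' only. Per-hectare masses are computed to 0.1 kg and scaled by the
#' field area.
#'
#' @param schedule An `application_schedule` of per-hectare rates.
#' @param selected Ordered character vector of farmer-selected product
#'   names (resolved in `catalog`).
#' @param catalog A [fertilizer_catalog()]; must contain `"urea"` and
#'   `"MOP"`.
#' @param field_area Field area, ha.
#' @return A `product_allocation`: data frame with columns `event`, `dae`,
#'   `stage`, `product`, `mass_kg` (kg for the whole field), with the
#'   per-hectare nutrient shortfalls (normally all zero) in attribute
#'   `"shortfall"`.
#' @export
allocate <- function(schedule, selected, catalog, field_area = 1) {
  stopifnot(inherits(schedule, "application_schedule"))
  if (!inherits(catalog, "fertilizer_catalog")) {
    catalog <- fertilizer_catalog(catalog)
  }
  assert_scalar_num(field_area, "field_area")
  if (field_area <= 0) stop_input("'field_area' must be > 0")
  ev <- schedule$events
  rows <- list()
  total_short <- c(n = 0, p = 0, k = 0)
  for (i in seq_len(nrow(ev))) {
    masses <- if (i == 1L) {
      allocate_early_event(ev$n[i], ev$p[i], ev$k[i], selected, catalog)
    } else {
      allocate_later_event(ev$n[i], ev$p[i], ev$k[i], catalog)
    }
    total_short <- total_short + attr(masses, "shortfall")
    if (length(masses)) {
      rows[[length(rows) + 1L]] <- data.frame(
        event = i,
        dae = ev$dae[i],
        stage = ev$stage[i],
        product = names(masses),
        mass_kg = unname(masses) * field_area,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(event = integer(), dae = integer(), stage = character(),
               product = character(), mass_kg = numeric(),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "shortfall") <- total_short
  attr(out, "field_area") <- field_area
  class(out) <- c("product_allocation", "data.frame")
  out
}

#' Nutrients delivered by an allocation
#'
#' Recomputes elemental N, P, K per hectare from the allocated product
#' masses — the inverse check of [allocate()].
#'
#' @param allocation A `product_allocation`.
#' @param catalog The catalog used for allocation.
#' @return Data frame with one row per event and columns `event`, `n`,
#'   `p`, `k` (kg/ha).
#' @export
delivered_nutrients <- function(allocation, catalog) {
  area <- attr(allocation, "field_area") %||% 1
  if (nrow(allocation) == 0) {
    return(data.frame(event = integer(), n = numeric(), p = numeric(),
                      k = numeric()))
  }
  idx <- match(allocation$product, catalog$name)
  per_ha <- allocation$mass_kg / area
  agg <- stats::aggregate(
    cbind(n = per_ha * catalog$n_frac[idx],
          p = per_ha * catalog$p_frac[idx],
          k = per_ha * catalog$k_frac[idx]),
    by = list(event = allocation$event), FUN = sum)
  agg[order(agg$event), ]
}

#' Product cost of an allocation
#'
#' @param allocation A `product_allocation`.
#' @param catalog The catalog with `price_per_50kg`.
#' @return Total product cost in US$ for the field.
#' @export
allocation_cost <- function(allocation, catalog) {
  if (nrow(allocation) == 0) return(0)
  idx <- match(allocation$product, catalog$name)
  if (anyNA(idx)) {
    stop_input("allocation references products missing from the catalog")
  }
  sum(allocation$mass_kg / 50 * catalog$price_per_50kg[idx])
}
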