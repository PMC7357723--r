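#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# Round to the nearest multiple of `step`, halves away from zero.
# base::round() rounds halves to even, which is wrong for doses weighed in
# practical 0.5-kg or 1-kg units.
round_step <- function(x, step = 1) {
  sign(x) * floor(abs(x) / step + 0.5) * step
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Split `total` into doses proportional to `fractions`, each dose on a grid
# of `step`, repairing rounding so the doses sum exactly to `total`
# (largest-remainder method; ties broken by event order).
largest_remainder_split <- function(total, fractions, step = 0.5) {
  stopifnot(total >= 0, all(fractions >= 0), abs(sum(fractions) - 1) < 1e-9)
  target <- fractions * total
  base <- floor(target / step + 1e-9) * step
  units_left <- round((total - sum(base)) / step)
  if (units_left > 0) {
    rem <- target - base
    take <- order(rem, decreasing = TRUE)[seq_len(units_left)]
    base[take] <- base[take] + step
  }
  base
}

stop_input <- function(...) stop(..., call. = FALSE)

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_input(sprintf("'%s' must be a single number", name))
  }
  if (x < lo || x > hi) {
    stop_input(sprintf("'%s' must be in [%s, %s], got %s", name, lo, hi, x))
  }
  invisible(x)
}

as_iso_date <- function(x, name) {
  if (inherits(x, "Date")) return(x)
  d <- tryCatch(as.Date(x, format = "%Y-%m-%d"), error = function(e) NA)
  if (length(d) != 1L || is.na(d)) {
    stop_input(sprintf("'%s' must be an ISO-8601 date (YYYY-MM-DD), got '%s'",
                       name, as.character(x)))
  }
  d
}
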