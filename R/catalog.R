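#' Fertilizer product catalog
#'
#' A catalog is a data frame with columns `name`, `n_frac`, `p_frac`,
#' `k_frac` (elemental mass fractions, decimals) and `price_per_50kg`
#' (US$ per 50-kg bag). Grades quoted as N-P2O5-K2O are converted to the
#' elemental basis with P = P2O5 x 0.436 and K = K2O x 0.830.
#'
#' @param df Data frame with the catalog columns.
#' @return The validated catalog (class `fertilizer_catalog`).
#' @export
fertilizer_catalog <- function(df) {
  needed <- c("name", "n_frac", "p_frac", "k_frac", "price_per_50kg")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_input("catalog is missing columns: ", paste(missing, collapse = ", "))
  }
  df <- df[needed]
  df$name <- as.character(df$name)
  if (anyDuplicated(df$name)) stop_input("catalog product names must be unique")
  for (nm in c("n_frac", "p_frac", "k_frac")) {
    if (any(df[[nm]] < 0 | df[[nm]] > 1)) {
      stop_input("'", nm, "' must be elemental mass fractions in [0, 1]")
    }
  }
  if (any(df$n_frac + df$p_frac + df$k_frac > 1 + 1e-9)) {
    stop_input("elemental fractions of a product cannot sum above 1")
  }
  if (any(df$price_per_50kg < 0)) stop_input("prices must be >= 0")
  rownames(df) <- NULL
  class(df) <- c("fertilizer_catalog", "data.frame")
  df
}

#' Default product catalog for the study region
#'
#' Urea, diammonium phosphate (DAP), muriate of potash (MOP), single
#' superphosphate (SSP), the 17-17-17 and 20-20-0 compound fertilizers
#' and zinc sulfate, with standard elemental contents and the prevailing
#' local prices per 50-kg bag (US$): urea 4.3, DAP 18.6, MOP 12.7,
#' SSP 5.9, both compounds 14.3, zinc sulfate 36.5.
#'
#' @return A `fertilizer_catalog`.
#' @export
product_catalog_default <- function() {
  fertilizer_catalog(data.frame(
    name = c("urea", "DAP", "MOP", "SSP", "17-17-17", "20-20-0",
             "zinc sulfate"),
    n_frac = c(0.46, 0.18, 0, 0, 0.17, 0.20, 0),
    p_frac = c(0, 0.201, 0, 0.070, 0.074, 0.087, 0),
    k_frac = c(0, 0, 0.498, 0, 0.141, 0, 0),
    price_per_50kg = c(4.3, 18.6, 12.7, 5.9, 14.3, 14.3, 36.5),
    stringsAsFactors = FALSE
  ))
}

#' Read a product catalog from CSV
#'
#' Expects the exact columns `name,n_frac,p_frac,k_frac,price_per_50kg`
#' with fractions as decimals on the elemental basis.
#'
#' @param path CSV path.
#' @return A `fertilizer_catalog`.
#' @export
read_product_catalog <- function(path) {
  fertilizer_catalog(utils::read.csv(path, stringsAsFactors = FALSE))
}

catalog_row <- function(catalog, name) {
  i <- match(name, catalog$name)
  if (is.na(i)) stop_input("product '", name, "' not found in the catalog")
  catalog[i, ]
}
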