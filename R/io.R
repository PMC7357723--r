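#' Read and write trial tables
#'
#' The trial CSV layout has the fixed columns `field_id`, `season`,
#' `treatment`, `grain_yield`, `n_rate`, `p_rate`, `k_rate`,
#' `n_applications`, `field_area`, `prev_residue`, `target_yield`; any
#' further columns are fertilizer product masses in kg for the field
#' (column name = product name).
#'
#' @param path CSV path.
#' @return Data frame with product columns left unmangled.
#' @export
read_trials <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_trials
#' @param trials Trial data frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Command-line style recommendation run
#'
#' Reads an interview JSON (optionally a catalog CSV and a season-params
#' YAML), runs [recommend()] and writes the rendered recommendation.
#' Schema violations abort with a field-level message. Output carries no
#' timestamps, so identical inputs give byte-identical files. Progress is
#' logged to stderr.
#'
#' @param interview_path Interview JSON path.
#' @param out Output file path.
#' @param catalog_path Optional catalog CSV (default: shipped catalog).
#' @param params_path Optional season-params YAML (default: shipped
#'   calibrations).
#' @param format `"text"` or `"json"`.
#' @param quiet Suppress the stderr log.
#' @return `out`, invisibly.
#' @export
cli_recommend <- function(interview_path, out, catalog_path = NULL,
                          params_path = NULL, format = c("text", "json"),
                          quiet = FALSE) {
  format <- match.arg(format)
  interview <- read_interview(interview_path)
  catalog <- if (is.null(catalog_path)) product_catalog_default() else
    read_product_catalog(catalog_path)
  params <- if (is.null(params_path)) default_season_params() else
    read_season_params(params_path)
  rec <- recommend(interview, catalog = catalog, params = params)
  if (!quiet) {
    message(sprintf("[ssnmrice] field %s (%s): target %.1f Mg/ha, N %g P %g K %g kg/ha",
                    rec$field_id, rec$season, rec$target_yield,
                    rec$rates$n, rec$rates$p, rec$rates$k))
  }
  writeLines(render_recommendation(rec, format), out)
  invisible(out)
}

#' Command-line style trial evaluation run
#'
#' Reads a trial table, computes the per-treatment economic summary, the
#' added-net-benefit comparisons with exceedance curves, and the
#' per-field P/K balances, and writes them as CSVs into `out_dir`
#' (`summary.csv`, `anb.csv`, `balances.csv`,
#' `exceedance_<comparison>.csv`). A missing reference treatment drops
#' the comparison with a warning, not a failure.
#'
#' @param trials_path Trial CSV path (see [read_trials()]).
#' @param out_dir Output directory (created if needed).
#' @param params_path Optional season-params YAML.
#' @param catalog_path Optional catalog CSV.
#' @param thresholds Thresholds for the exceedance curves, US$ per ha.
#' @param quiet Suppress the stderr log.
#' @return Named character vector of the files written, invisibly.
#' @export
cli_evaluate <- function(trials_path, out_dir, params_path = NULL,
                         catalog_path = NULL,
                         thresholds = seq(-200, 400, by = 25),
                         quiet = FALSE) {
  trials <- read_trials(trials_path)
  catalog <- if (is.null(catalog_path)) product_catalog_default() else
    read_product_catalog(catalog_path)
  params <- if (is.null(params_path)) default_season_params() else
    read_season_params(params_path)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  res <- summarize_trials(trials, catalog = catalog)
  written <- character()
  p <- file.path(out_dir, "summary.csv")
  utils::write.csv(res$summary, p, row.names = FALSE)
  written["summary"] <- p

  if (is.null(res$anb)) {
    warning("no treatment pair available for added net benefit; ",
            "skipping ANB and exceedance outputs", call. = FALSE)
  } else {
    p <- file.path(out_dir, "anb.csv")
    utils::write.csv(res$anb, p, row.names = FALSE)
    written["anb"] <- p
    per <- res$per_field
    for (ref in intersect(c("ffp", "bfr"), unique(per$treatment))) {
      wide <- merge(per[per$treatment == "ssnm", c("field_id", "grf")],
                    per[per$treatment == ref, c("field_id", "grf")],
                    by = "field_id", suffixes = c("_ssnm", "_ref"))
      if (nrow(wide) == 0) next
      curve <- exceedance_curve(wide$grf_ssnm - wide$grf_ref, thresholds)
      p <- file.path(out_dir, sprintf("exceedance_ssnm-%s.csv", ref))
      utils::write.csv(curve, p, row.names = FALSE)
      written[paste0("exceedance_ssnm-", ref)] <- p
    }
  }

  if ("prev_residue" %in% names(trials)) {
    bal <- balance_table(trials, params)
    p <- file.path(out_dir, "balances.csv")
    utils::write.csv(bal, p, row.names = FALSE)
    written["balances"] <- p
  }
  if (!quiet) {
    message(sprintf("[ssnmrice] evaluated %d trial rows; wrote %d files to %s",
                    nrow(trials), length(written), out_dir))
  }
  invisible(written)
}
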