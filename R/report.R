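#' Case-level factor table for correlation analysis
#'
#' One row per case: lesion count, fraction number, PTV volume,
#' perturbation-profile code, mean HU deviations of the PTV, the mean
#' absolute DVH-metric deviation of the PTV (each metric normalised by the
#' prescription where applicable), and optionally the gamma passing rates
#' per criterion.
#'
#' @param cases List of `phantom_case` objects.
#' @param gamma_rates Optional `rates` data.frame from
#'   [passing_rate_table()]; its per-case rates become columns.
#' @param bin_width DVH bin width (Gy).
#' @param renormalize_d95 Passed to [dvh_metric_table()]. With the default
#'   `TRUE` the PTV metrics are compared after D95 renormalisation, which
#'   removes any pure dose-scale difference between the two plans; set
#'   `FALSE` to correlate raw (un-renormalised) dose deviations with the
#'   case factors.
#' @return Data.frame, one row per case.
#' @export
case_factor_table <- function(cases, gamma_rates = NULL, bin_width = 0.01,
                              renormalize_d95 = TRUE) {
  rows <- list()
  for (case in cases) {
    ptv <- ptv_union(case)
    dvh_tab <- dvh_metric_table(case, bin_width = bin_width,
                                renormalize_d95 = renormalize_d95)
    ptv_rows <- dvh_tab[dvh_tab$structure == "PTV" & !dvh_tab$missing, ]
    hu_dev <- NA_real_
    hu_min_dev <- NA_real_
    if (!is.null(case$pct)) {
      hs_ct <- hu_summary(case$ct, ptv)
      hs_pct <- hu_summary(case$pct, ptv)
      dev <- hu_deviation(hs_ct, hs_pct)
      hu_dev <- dev$d_mean
      hu_min_dev <- dev$d_min
    }
    row <- data.frame(
      case_id = case$case_id,
      lesions = case$meta$n_lesions,
      fractions = case$fractions,
      ptv_cc = structure_volume_cc(ptv),
      profile = case$meta$profile,
      hu_mean_dev = hu_dev,
      hu_min_dev = hu_min_dev,
      dvh_abs_dev = mean(ptv_rows$abs_deviation),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  if (!is.null(gamma_rates)) {
    for (cr in unique(gamma_rates$criteria)) {
      sub <- gamma_rates[gamma_rates$criteria == cr, ]
      col <- paste0("gamma_", gsub("[%/]", "_", cr))
      out[[col]] <- sub$passing_rate[match(out$case_id, sub$case_id)]
    }
  }
  out
}

#' Assemble the full report bundle for a cohort
#'
#' Runs every analysis stage over the cases and writes one directory of
#' CSVs plus a JSON summary: per-structure HU comparison, DVH metric table,
#' gamma passing rates with group summaries, TCP/NTCP outcome table, and
#' the Spearman correlation matrix of the case-level factors. Deterministic
#' given its inputs; regenerating from the same cases yields byte-identical
#' CSVs.
#'
#' @param cases List of `phantom_case` objects.
#' @param out_dir Output directory (created if missing).
#' @param criteria_list Gamma criteria (default [standard_criteria()]).
#' @param params Radiobiological parameters ([read_radbio_params()]).
#' @param include_gamma Compute gamma passing rates (the slowest stage).
#' @param bin_width DVH bin width (Gy).
#' @return Invisibly, a list with all computed tables.
#' @export
build_report <- function(cases, out_dir, criteria_list = NULL,
                         params = read_radbio_params(), include_gamma = TRUE,
                         bin_width = 0.01) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hu <- do.call(rbind, lapply(cases, function(cs)
    if (is.null(cs$pct)) NULL else hu_table(cs)))
  dvh <- do.call(rbind, lapply(cases, dvh_metric_table, bin_width = bin_width))
  gamma <- NULL
  if (include_gamma) gamma <- passing_rate_table(cases, criteria_list)
  outcomes <- outcome_table(cases, params, bin_width = bin_width)
  factors <- case_factor_table(cases, if (include_gamma) gamma$rates else NULL,
                               bin_width = bin_width)
  corr_cols <- factors[setdiff(names(factors), "case_id")]
  corr <- if (nrow(factors) >= 3) correlation_report(corr_cols) else NULL

  wr <- function(x, f) if (!is.null(x))
    utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
  wr(hu, "hu_comparison.csv")
  wr(dvh, "dvh_metrics.csv")
  if (!is.null(gamma)) {
    wr(gamma$rates, "gamma_rates.csv")
    wr(gamma$groups, "gamma_groups.csv")
  }
  wr(outcomes, "outcomes.csv")
  wr(outcome_summary(outcomes), "outcome_summary.csv")
  wr(factors, "case_factors.csv")
  if (!is.null(corr)) wr(corr$long, "correlation_long.csv")

  summary <- list(
    n_cases = length(cases),
    mean_abs_hu_mean_dev = if (!is.null(factors$hu_mean_dev))
      mean(abs(factors$hu_mean_dev)) else NULL,
    mean_dvh_abs_dev = mean(factors$dvh_abs_dev),
    gamma_median_by_criteria = if (!is.null(gamma)) {
      sp <- split(gamma$rates$passing_rate, gamma$rates$criteria)
      lapply(sp, stats::median)
    } else NULL,
    tcp_mad = if (any(outcomes$model == "TCP"))
      mean(outcomes$abs_deviation[outcomes$model == "TCP"]) else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(hu = hu, dvh = dvh, gamma = gamma, outcomes = outcomes,
                 factors = factors, correlation = corr, summary = summary))
}
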