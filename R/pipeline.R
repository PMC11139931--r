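# End-to-end study driver: compute every model and baseline from a climate
# table, evaluate the full model set against both baselines, rank, and
# export.

#' Evaluate an ET0 table against one baseline
#'
#' Builds a metric card for every series in the table except the baseline
#' itself, rankings under each key statistic, and Taylor-diagram
#' coordinates per model.
#'
#' @param eto_table A table from [compute_eto_table()] or [table3_fixture()].
#' @param baseline_id `"pan_observed"` or `"fao_pm"` (any row id works).
#' @param ioa_c Scaling constant for the refined index of agreement.
#' @return An object of class `eto_report`: list with `baseline_id`,
#'   `cards` (data frame), `rankings` (named list of model-id vectors, one
#'   per key statistic), `taylor` (data frame).
#' @export
#' @examples
#' rep <- evaluate_models(table3_fixture(), "pan_observed")
#' head(rep$rankings$ioa)
evaluate_models <- function(eto_table, baseline_id = "pan_observed",
                            ioa_c = 2) {
  obs <- eto_series(eto_table, baseline_id)
  ids <- setdiff(eto_table$model_id, baseline_id)
  cards <- do.call(rbind, lapply(ids, function(id)
    metric_card(eto_series(eto_table, id), obs, id, baseline_id,
                ioa_c = ioa_c)))
  if ("category" %in% names(eto_table))
    cards$category <- eto_table$category[match(cards$model_id,
                                               eto_table$model_id)]
  taylor <- do.call(rbind, lapply(ids, function(id)
    cbind(model_id = id, taylor_stats(eto_series(eto_table, id), obs))))
  rankings <- lapply(stats::setNames(nm = names(metric_directions)),
                     function(k) rank_models(cards, key = k)$model_id)
  structure(list(baseline_id = baseline_id, cards = cards,
                 rankings = rankings, taylor = taylor),
            class = "eto_report")
}

#' @export
print.eto_report <- function(x, ...) {
  cat(sprintf("<eto_report> baseline: %s, %d models\n",
              x$baseline_id, nrow(x$cards)))
  cat("IOA ranking (best first):",
      paste(utils::head(x$rankings$ioa, 5), collapse = " > "),
      if (length(x$rankings$ioa) > 5) "> ..." else "", "\n")
  invisible(x)
}

#' Run the full model-comparison study
#'
#' Derives the monthly meteorology, computes both baselines and all 18
#' empirical models, and evaluates the whole set against each baseline
#' (every model is scored against both the pan-observed and the FAO-PM
#' series). Deterministic: the same inputs always give the same outputs.
#'
#' @inheritParams derive_met
#' @return An object of class `eto_study`: list with `eto` (the 20-row
#'   monthly ET0 table), `reports` (list of two `eto_report`s named
#'   `pan_observed` and `fao_pm`), `met` (derived meteorology), and a
#'   `provenance` block recording site, conventions and package version.
#' @export
#' @examples
#' study <- run_study(table1_fixture())
#' study$reports$pan_observed$rankings$ioa[1:3]
run_study <- function(climate, site = udhagamandalam_site(),
                      conventions = eto_conventions()) {
  climate <- validate_climate(climate)
  eto <- compute_eto_table(climate, site, conventions)
  reports <- lapply(stats::setNames(nm = c("pan_observed", "fao_pm")),
                    function(b) evaluate_models(eto, b))
  structure(
    list(eto = eto, reports = reports,
         met = derive_met(climate, site, conventions),
         provenance = list(
           site = unclass(site), conventions = unclass(conventions),
           package_version = as.character(utils::packageVersion("etobench")))),
    class = "eto_study")
}

#' @export
print.eto_study <- function(x, ...) {
  cat(sprintf("<eto_study> %d ET0 series x 12 months\n", nrow(x$eto)))
  for (r in x$reports) print(r)
  invisible(x)
}

#' Correlation of pan evaporation with its meteorological drivers
#'
#' Pearson correlation between monthly class-A pan evaporation and each
#' candidate driver: maximum and minimum temperature, mean relative
#' humidity, wind speed, and Angstrom-derived solar radiation.
#'
#' @inheritParams derive_met
#' @return A data frame with columns `driver` and `r`.
#' @export
#' @examples
#' driver_correlations(table1_fixture())
driver_correlations <- function(climate, site = udhagamandalam_site(),
                                conventions = eto_conventions()) {
  climate <- validate_climate(climate)
  met <- derive_met(climate, site, conventions)
  drivers <- list(tmax = climate$tmax_c, tmin = climate$tmin_c,
                  rh_mean = met$rh_mean, wind = climate$wind_kmh,
                  rs = met$rs)
  data.frame(
    driver = names(drivers),
    r = vapply(drivers, function(d) pearson_r(d, climate$epan_mm),
               numeric(1)),
    row.names = NULL)
}

#' Score the FAO-PM baseline against the pan-observed baseline
#'
#' @param pan,faopm 12-month numeric ET0 series (mm/day).
#' @return A metric card of FAO-PM against pan-observed.
#' @export
#' @examples
#' tab <- table3_fixture()
#' compare_baselines(eto_series(tab, "pan_observed"),
#'                   eto_series(tab, "fao_pm"))
compare_baselines <- function(pan, faopm) {
  metric_card(faopm, pan, model_id = "fao_pm", baseline_id = "pan_observed")
}

#' Export an evaluation report
#'
#' CSV export writes the metric cards with the stable header
#' `model_id,FAC2,MB,MGE,NMB,NMGE,RMSE,r,IOA` rounded to two decimals.
#' JSON export keeps full precision and includes the rankings and Taylor
#' coordinates.
#'
#' @param report An `eto_report`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_report <- function(report, path, format = c("csv", "json")) {
  stopifnot(inherits(report, "eto_report"))
  format <- match.arg(format)
  if (format == "csv") {
    out <- report$cards[c("model_id", "fac2", "mb", "mge", "nmb", "nmge",
                          "rmse", "r", "ioa")]
    names(out) <- c("model_id", "FAC2", "MB", "MGE", "NMB", "NMGE",
                    "RMSE", "r", "IOA")
    out[-1] <- lapply(out[-1], round, 2)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(
      list(baseline_id = report$baseline_id, cards = report$cards,
           rankings = report$rankings, taylor = report$taylor),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
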