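# Packaged station data for Udhagamandalam (Nilgiris, Tamil Nadu): 60-year
# monthly climate normals, the published monthly ET0 series per model, and
# the published evaluation statistics against both baselines. Shipped as
# CSV under inst/extdata so they double as ordinary pipeline inputs.

#' @keywords internal
extdata <- function(name) {
  path <- system.file("extdata", name, package = "etobench", mustWork = FALSE)
  if (!nzchar(path)) {
    # package loaded with pkgload during development
    path <- file.path("inst", "extdata", name)
  }
  if (!file.exists(path)) stop("packaged data file not found: ", name)
  path
}

#' Packaged climate normals for Udhagamandalam
#'
#' Monthly climate normals (1960-2020 averages) for the tropical highland
#' station at Udhagamandalam: temperature extremes, rainfall, humidity
#' extremes, wind, sunshine and class-A pan evaporation. The June-September
#' southwest monsoon shows as high humidity and wind with low sunshine.
#'
#' @return A validated 12-row monthly climate table.
#' @export
#' @examples
#' table1_fixture()[1, ]
table1_fixture <- function() {
  read_climate_csv(extdata("udhagamandalam_climate.csv"))
}

#' Packaged monthly ET0 series per model
#'
#' The published monthly ET0 values (mm/day) for the two baselines and all
#' 18 empirical models at Udhagamandalam, one row per model. Several rows
#' (Schendel, Ivanov, Papadakis, Makkink, Priestley-Taylor, Abtew) are not
#' reproducible from the climate normals under standard conventions - the
#' original solar-radiation source and humidity granularity are unpublished
#' - so this table is the authoritative input for the metric layer rather
#' than a target for the model layer.
#'
#' @return A 20-row data frame: `model_id`, `category`, `jan` ... `dec`.
#' @export
table3_fixture <- function() {
  tab <- utils::read.csv(extdata("udhagamandalam_eto_monthly.csv"))
  stopifnot(nrow(tab) == 20L)
  tab
}

#' Packaged evaluation statistics against the pan-observed baseline
#'
#' The published eight-statistic evaluation of every model (and the FAO-PM
#' baseline) against pan-derived ET0. The FAO-PM row carries the original
#' unrounded values; model rows are printed at two decimals.
#'
#' @return A data frame of metric cards (`model_id`, `category`,
#'   `baseline_id`, `fac2`, `mb`, `mge`, `nmb`, `nmge`, `rmse`, `r`, `ioa`).
#' @export
table4_fixture <- function() {
  utils::read.csv(extdata("udhagamandalam_metrics_pan.csv"))
}

#' Packaged evaluation statistics against the FAO-PM baseline
#'
#' @return A data frame of metric cards, as [table4_fixture()].
#' @export
table5_fixture <- function() {
  utils::read.csv(extdata("udhagamandalam_metrics_faopm.csv"))
}
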