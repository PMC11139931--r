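#' @keywords internal
climate_columns <- c("month", "tmax_c", "tmin_c", "rain_mm", "rhmax_pct",
                     "rhmin_pct", "wind_kmh", "sunshine_h", "epan_mm")

#' Validate a monthly climate table
#'
#' A monthly climate table is a 12-row data frame of climate normals with
#' columns `month` (1-12), `tmax_c`, `tmin_c` (degC), `rain_mm` (mm/month),
#' `rhmax_pct`, `rhmin_pct` (%), `wind_kmh` (km/h), `sunshine_h` (h/day) and
#' `epan_mm` (class-A pan evaporation, mm/day). Validation enforces the
#' physical constraints: Tmax >= Tmin, 0 <= RHmin <= RHmax <= 100,
#' non-negative wind, rainfall and pan evaporation, sunshine within 0-24 h.
#'
#' @param climate A data frame.
#' @return The validated data frame, invisibly ordered by month.
#' @export
#' @examples
#' validate_climate(table1_fixture())
validate_climate <- function(climate) {
  if (!is.data.frame(climate)) stop("climate must be a data frame")
  missing <- setdiff(climate_columns, names(climate))
  if (length(missing))
    stop("climate table lacks columns: ", paste(missing, collapse = ", "))
  climate <- climate[order(climate$month), climate_columns]
  if (nrow(climate) != 12L || !identical(as.integer(climate$month), 1:12))
    stop("climate table must contain months 1..12 exactly once")
  ok <- function(cond, msg) {
    bad <- which(!cond)
    if (length(bad))
      stop(sprintf("%s (month %s)", msg, paste(climate$month[bad], collapse = ", ")))
  }
  ok(climate$tmax_c >= climate$tmin_c, "tmax_c < tmin_c")
  ok(climate$rhmin_pct >= 0 & climate$rhmin_pct <= climate$rhmax_pct &
       climate$rhmax_pct <= 100, "relative humidity outside 0 <= min <= max <= 100")
  ok(climate$wind_kmh >= 0, "negative wind speed")
  ok(climate$sunshine_h >= 0 & climate$sunshine_h <= 24, "sunshine hours outside 0..24")
  ok(climate$epan_mm >= 0, "negative pan evaporation")
  ok(climate$rain_mm >= 0, "negative rainfall")
  ok(is.finite(as.matrix(climate[-1])) |> apply(1, all), "non-finite value")
  rownames(climate) <- NULL
  climate
}

#' Read / write a monthly climate table as CSV
#'
#' The CSV dialect has the header
#' `month,tmax_c,tmin_c,rain_mm,rhmax_pct,rhmin_pct,wind_kmh,sunshine_h,epan_mm`.
#'
#' @param path File path.
#' @return `read_climate_csv()` returns the validated 12-row data frame.
#' @export
read_climate_csv <- function(path) {
  validate_climate(utils::read.csv(path))
}

#' @rdname read_climate_csv
#' @param climate A validated monthly climate table.
#' @export
write_climate_csv <- function(climate, path) {
  climate <- validate_climate(climate)
  utils::write.csv(climate, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
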