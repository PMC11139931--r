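# The two reference baselines: pan-derived ET0 and FAO-56 Penman-Monteith.

#' Class-A pan coefficient (Allen-Pruitt)
#'
#' The Allen-Pruitt regression for the pan coefficient of a class-A pan in
#' a green-cropped upwind fetch:
#' Kpan = 0.108 - 0.0286 u2 + 0.0422 ln(F) + 0.1434 ln(RH)
#'        - 0.000631 (ln F)^2 ln(RH).
#' A circulated `"legacy_print"` variant (wind coefficient 3.31e-4,
#' interaction 6.31 (ln F)^-4 ln RH) is kept behind the flag for audit; it
#' is numerically inconsistent with the published regression and not the
#' default. The result is clamped to the physically plausible 0.3-1.1.
#'
#' @param u2 Wind speed at 2 m (m/s).
#' @param fetch Upwind green-crop fetch F (m), > 1.
#' @param rh Mean relative humidity (%), 1-100.
#' @param variant `"allen_pruitt"` (default) or `"legacy_print"`.
#' @return Pan coefficient (dimensionless).
#' @export
#' @examples
#' pan_coefficient(1.14, 100, 73.0)
pan_coefficient <- function(u2, fetch, rh,
                            variant = c("allen_pruitt", "legacy_print")) {
  variant <- match.arg(variant)
  if (any(fetch <= 1)) stop("fetch must exceed 1 m (ln F must be positive)")
  if (any(rh < 1 | rh > 100)) stop("rh outside 1..100")
  if (any(u2 < 0)) stop("negative wind speed")
  k <- if (variant == "allen_pruitt") {
    0.108 - 0.0286 * u2 + 0.0422 * log(fetch) + 0.1434 * log(rh) -
      0.000631 * log(fetch)^2 * log(rh)
  } else {
    0.108 - 3.31e-4 * u2 + 0.0422 * log(fetch) + 0.1434 * log(rh) -
      6.31 * log(fetch)^-4 * log(rh)
  }
  pmin(pmax(k, 0.3), 1.1)
}

#' Pan-derived reference evapotranspiration
#'
#' ET0 = Kpan x Epan: measured class-A pan evaporation scaled by the pan
#' coefficient.
#'
#' @param kpan Pan coefficient, in (0, 1.2].
#' @param epan Measured pan evaporation (mm/day), >= 0.
#' @return ET0 (mm/day).
#' @export
#' @examples
#' pan_eto(0.8, 3.5)
pan_eto <- function(kpan, epan) {
  if (any(epan < 0)) stop("negative pan evaporation")
  if (any(kpan <= 0 | kpan > 1.2)) stop("kpan outside (0, 1.2]")
  kpan * epan
}

#' FAO-56 Penman-Monteith reference evapotranspiration
#'
#' The standard combination equation for the grass reference surface:
#' ET0 = (0.408 Delta (Rn - G) + gamma 900/(T + 273) u2 (es - ea)) /
#'       (Delta + gamma (1 + 0.34 u2)),
#' with Rn and G in MJ m-2 day-1, T in degC, u2 in m/s and vapour
#' pressures in kPa. Negative results are floored at zero.
#'
#' @param met A derived-meteorology data frame from [derive_met()] (columns
#'   `tmean`, `u2`, `rn`, `g_soil`, `delta`, `gamma`, `es`, `ea`).
#' @return ET0 (mm/day), one value per row of `met`.
#' @export
#' @examples
#' met <- derive_met(table1_fixture(), udhagamandalam_site())
#' fao_penman_monteith(met)
fao_penman_monteith <- function(met) {
  need <- c("tmean", "u2", "rn", "g_soil", "delta", "gamma", "es", "ea")
  missing <- setdiff(need, names(met))
  if (length(missing))
    stop("met lacks columns: ", paste(missing, collapse = ", "))
  denom <- met$delta + met$gamma * (1 + 0.34 * met$u2)
  if (any(denom <= 0)) stop("non-positive Penman-Monteith denominator")
  num <- 0.408 * met$delta * (met$rn - met$g_soil) +
    met$gamma * (900 / (met$tmean + 273)) * met$u2 * (met$es - met$ea)
  pmax(num / denom, 0)
}

#' Pan-observed baseline series for a climate table
#'
#' Computes the monthly pan coefficient from 2-m wind, fetch and mean RH,
#' then scales the measured pan evaporation.
#'
#' @inheritParams derive_met
#' @param met Optional pre-computed [derive_met()] table.
#' @return A numeric vector of 12 monthly ET0 values (mm/day).
#' @export
pan_observed_eto <- function(climate, site = udhagamandalam_site(),
                             conventions = eto_conventions(), met = NULL) {
  climate <- validate_climate(climate)
  if (is.null(met)) met <- derive_met(climate, site, conventions)
  kpan <- pan_coefficient(met$u2, site$pan_fetch, met$rh_mean,
                          variant = conventions$kpan_variant)
  pan_eto(kpan, climate$epan_mm)
}
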