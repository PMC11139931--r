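# Seeded synthetic monthly-climate generator: sinusoidal annual temperature
# cycles peaking in (boreal) spring, a monsoon season with boosted humidity
# and wind, sunshine anti-correlated with humidity, and pan evaporation
# driven by temperature and sunshine. Emulates the structure of tropical
# highland climate normals so every pipeline stage can be exercised on
# realistic inputs without the packaged station data.

#' Parameters for the synthetic monthly-climate generator
#'
#' Defaults imitate the packaged Udhagamandalam normals: maximum
#' temperature around 19.4 degC with a 2 degC annual amplitude peaking in
#' April, minimum around 10.6 degC peaking a month later, a June-September
#' monsoon that raises minimum relative humidity by about 20 points and
#' wind by about 3 km/h, and 74% of annual rainfall in the monsoon.
#'
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param latitude Site latitude (degrees), used for daylight clamping.
#' @param tmax_mean,tmax_amplitude Annual mean and amplitude of the maximum
#'   temperature sinusoid (degC); peak in April.
#' @param tmin_mean,tmin_amplitude Same for minimum temperature; peak in May.
#' @param monsoon_months Integer months of the monsoon regime.
#' @param base_rh Non-monsoon minimum relative humidity (%).
#' @param monsoon_rh_boost Added to `base_rh` in monsoon months (%);
#'   `base_rh + monsoon_rh_boost` must stay <= 100.
#' @param wind_base,wind_monsoon_boost Wind speed (km/h) outside the
#'   monsoon and the monsoon addition.
#' @param sunshine_max Bright-sunshine ceiling (h/day) under the driest
#'   humidity; actual sunshine decreases linearly with minimum RH.
#' @param rain_base,rain_monsoon Monthly rainfall (mm) outside and inside
#'   the monsoon.
#' @param noise_sd Named standard deviations of the Gaussian perturbations:
#'   `temp`, `rh`, `wind`, `sunshine`, `epan`, `rain`. Zero gives the exact
#'   deterministic cycles.
#'
#' @return An object of class `climate_gen_params`.
#' @export
#' @examples
#' climate_gen_params(seed = 7)
climate_gen_params <- function(seed = 1L, latitude = 11.41,
                               tmax_mean = 19.4, tmax_amplitude = 2.0,
                               tmin_mean = 10.6, tmin_amplitude = 2.6,
                               monsoon_months = 6:9,
                               base_rh = 57, monsoon_rh_boost = 21,
                               wind_base = 4.4, wind_monsoon_boost = 3.2,
                               sunshine_max = 9,
                               rain_base = 60, rain_monsoon = 570,
                               noise_sd = c(temp = 0.3, rh = 2, wind = 0.4,
                                            sunshine = 0.4, epan = 0.15,
                                            rain = 25)) {
  stopifnot(
    length(seed) == 1L, is.finite(seed),
    abs(latitude) <= 60,
    tmax_amplitude >= 0, tmin_amplitude >= 0,
    all(monsoon_months %in% 1:12),
    base_rh >= 0, monsoon_rh_boost >= 0,
    base_rh + monsoon_rh_boost <= 100,
    wind_base >= 0, wind_base + wind_monsoon_boost >= 0,
    sunshine_max > 0, sunshine_max <= 24,
    rain_base >= 0, rain_monsoon >= 0
  )
  need <- c("temp", "rh", "wind", "sunshine", "epan", "rain")
  if (!all(need %in% names(noise_sd)) || any(noise_sd[need] < 0))
    stop("noise_sd must name non-negative sds for: ",
         paste(need, collapse = ", "))
  p <- structure(
    list(seed = as.integer(seed), latitude = latitude,
         tmax_mean = tmax_mean, tmax_amplitude = tmax_amplitude,
         tmin_mean = tmin_mean, tmin_amplitude = tmin_amplitude,
         monsoon_months = as.integer(monsoon_months),
         base_rh = base_rh, monsoon_rh_boost = monsoon_rh_boost,
         wind_base = wind_base, wind_monsoon_boost = wind_monsoon_boost,
         sunshine_max = sunshine_max,
         rain_base = rain_base, rain_monsoon = rain_monsoon,
         noise_sd = noise_sd[need]),
    class = "climate_gen_params")
  # the noise-free cycles must keep tmax above tmin in every month
  if (any(gen_cycles(p)$tmax <= gen_cycles(p)$tmin))
    stop("infeasible params: tmin cycle reaches the tmax cycle")
  p
}

#' @keywords internal
gen_cycles <- function(params) {
  m <- 1:12
  list(
    tmax = params$tmax_mean +
      params$tmax_amplitude * cos(2 * pi * (m - 4) / 12),
    tmin = params$tmin_mean +
      params$tmin_amplitude * cos(2 * pi * (m - 5) / 12))
}

#' Generate a synthetic monthly climate table
#'
#' Deterministic given the seed; all outputs are clipped into the valid
#' ranges of a monthly climate table, so generated climates always pass
#' [validate_climate()].
#'
#' @param params A [climate_gen_params()] object.
#' @return A validated 12-row monthly climate table.
#' @export
#' @examples
#' clim <- generate_monthly_climate(climate_gen_params(seed = 42))
#' identical(clim, generate_monthly_climate(climate_gen_params(seed = 42)))
generate_monthly_climate <- function(params = climate_gen_params()) {
  stopifnot(inherits(params, "climate_gen_params"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(params$seed)

  m <- 1:12
  monsoon <- m %in% params$monsoon_months
  sd <- params$noise_sd
  cyc <- gen_cycles(params)

  tmax <- cyc$tmax + stats::rnorm(12, 0, sd["temp"])
  tmin <- cyc$tmin + stats::rnorm(12, 0, sd["temp"])
  tmin <- pmin(tmin, tmax - 0.1)  # preserve a positive diurnal range

  rh_min <- params$base_rh + params$monsoon_rh_boost * monsoon +
    stats::rnorm(12, 0, sd["rh"])
  rh_min <- pmin(pmax(rh_min, 1), 99)
  rh_max <- pmin(pmax(95 + stats::rnorm(12, 0, sd["rh"] / 2), rh_min), 100)

  wind <- pmax(params$wind_base + params$wind_monsoon_boost * monsoon +
                 stats::rnorm(12, 0, sd["wind"]), 0)

  n_day <- daylight_hours(params$latitude, mid_month_doy(m))
  # drier months are sunnier: linear taper from the ceiling with RHmin
  sunshine <- params$sunshine_max * (1.55 - 1.35 * rh_min / 100) +
    stats::rnorm(12, 0, sd["sunshine"])
  sunshine <- pmin(pmax(sunshine, 0), pmin(n_day, 24))

  epan <- 0.1 * tmax + 0.3 * sunshine - 1 + stats::rnorm(12, 0, sd["epan"])
  epan <- pmax(epan, 0.1)

  rain <- ifelse(monsoon, params$rain_monsoon, params$rain_base) +
    stats::rnorm(12, 0, sd["rain"])
  rain <- pmax(rain, 0)

  validate_climate(data.frame(
    month = m, tmax_c = tmax, tmin_c = tmin, rain_mm = rain,
    rhmax_pct = rh_max, rhmin_pct = rh_min, wind_kmh = wind,
    sunshine_h = sunshine, epan_mm = epan))
}
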