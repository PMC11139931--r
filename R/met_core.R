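# FAO-56 meteorological primitives. All functions are vectorised over their
# numeric arguments; units follow FAO-56 (kPa, MJ m-2 day-1, degC, m s-1).

#' Mean daily air temperature
#'
#' Mean of the daily maximum and minimum, the convention under which monthly
#' climate normals are reported.
#'
#' @param tmax,tmin Maximum and minimum air temperature (degC).
#' @return Mean temperature (degC).
#' @export
#' @examples
#' mean_temperature(19.5, 7.3)
mean_temperature <- function(tmax, tmin) {
  if (any(tmax < tmin)) stop("tmax < tmin")
  (tmax + tmin) / 2
}

#' Mean relative humidity
#'
#' @param rh_max,rh_min Daily maximum and minimum relative humidity (%).
#' @return Arithmetic mean (%).
#' @export
mean_relative_humidity <- function(rh_max, rh_min) {
  if (any(rh_min < 0 | rh_min > rh_max | rh_max > 100))
    stop("require 0 <= rh_min <= rh_max <= 100")
  (rh_max + rh_min) / 2
}

#' Wind speed at 2 m in m/s
#'
#' Converts km/h to m/s and, when the anemometer is not at 2 m, applies the
#' FAO-56 logarithmic wind profile factor 4.87 / ln(67.8 z - 5.42).
#'
#' @param wind Wind speed (km/h).
#' @param measurement_height Anemometer height z (m), >= 0.1.
#' @return Wind speed at 2 m (m/s).
#' @export
#' @examples
#' wind_to_2m_ms(4.09)       # measured at 2 m
#' wind_to_2m_ms(4.09, 10)   # measured at 10 m
wind_to_2m_ms <- function(wind, measurement_height = 2) {
  if (any(wind < 0)) stop("negative wind speed")
  if (any(measurement_height < 0.1)) stop("measurement_height < 0.1 m")
  u <- wind / 3.6
  factor <- ifelse(measurement_height == 2, 1,
                   4.87 / log(67.8 * measurement_height - 5.42))
  u * factor
}

#' Representative day-of-year for a month
#'
#' The 15th of each month on a non-leap calendar, the usual representative
#' day for monthly radiation computations.
#'
#' @param month Integer month 1-12.
#' @return Day of year.
#' @export
#' @examples
#' mid_month_doy(1:12)
mid_month_doy <- function(month) {
  if (any(month != as.integer(month) | month < 1 | month > 12))
    stop("month must be an integer in 1..12")
  cum <- c(0L, cumsum(c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L)))
  cum[as.integer(month)] + 15L
}

#' Saturation vapour pressure (Tetens / FAO-56)
#'
#' es(T) = 0.6108 exp(17.27 T / (T + 237.3)).
#'
#' @param t Air temperature (degC), within -40..60.
#' @return Saturation vapour pressure (kPa).
#' @export
#' @examples
#' saturation_vapour_pressure(c(0, 13.4, 19.5))
saturation_vapour_pressure <- function(t) {
  if (any(t < -40 | t > 60)) stop("temperature outside -40..60 degC")
  0.6108 * exp(17.27 * t / (t + 237.3))
}

#' Slope of the saturation vapour pressure curve
#'
#' Delta(T) = 4098 es(T) / (T + 237.3)^2.
#'
#' @inheritParams saturation_vapour_pressure
#' @return Slope Delta (kPa / degC).
#' @export
svp_slope <- function(t) {
  4098 * saturation_vapour_pressure(t) / (t + 237.3)^2
}

#' Actual vapour pressure from relative humidity
#'
#' The default FAO-56 dual-RH form averages RHmax applied to es(Tmin) with
#' RHmin applied to es(Tmax): ea = (es(Tmin) RHmax + es(Tmax) RHmin) / 200.
#' The `"mean_rh"` alternative uses ea = RHmean / 100 * es(Tmean).
#'
#' @param tmax,tmin Daily extreme temperatures (degC).
#' @param rh_max,rh_min Daily extreme relative humidities (%).
#' @param method `"dual_rh"` (default) or `"mean_rh"`.
#' @return Actual vapour pressure ea (kPa).
#' @export
#' @examples
#' actual_vapour_pressure(19.5, 7.3, 95.0, 51.1)
actual_vapour_pressure <- function(tmax, tmin, rh_max, rh_min,
                                   method = c("dual_rh", "mean_rh")) {
  method <- match.arg(method)
  if (any(rh_min < 0 | rh_min > rh_max | rh_max > 100))
    stop("require 0 <= rh_min <= rh_max <= 100")
  if (method == "dual_rh") {
    (saturation_vapour_pressure(tmin) * rh_max +
       saturation_vapour_pressure(tmax) * rh_min) / 200
  } else {
    (rh_max + rh_min) / 200 *
      saturation_vapour_pressure(mean_temperature(tmax, tmin))
  }
}

#' Atmospheric pressure from elevation
#'
#' P(z) = 101.3 ((293 - 0.0065 z) / 293)^5.26, the FAO-56 standard
#' atmosphere.
#'
#' @param z Elevation above sea level (m).
#' @return Pressure (kPa).
#' @export
#' @examples
#' atmospheric_pressure(c(0, 2218))
atmospheric_pressure <- function(z) {
  101.3 * ((293 - 0.0065 * z) / 293)^5.26
}

#' Psychrometric constant
#'
#' gamma = 0.000665 P(z) unless the site carries a fixed override.
#' At high-elevation stations the difference matters: 2218 m gives
#' gamma = 0.0517 kPa/degC versus 0.0674 at sea level.
#'
#' @param site An `eto_site` object.
#' @return gamma (kPa / degC).
#' @export
psychrometric_constant <- function(site) {
  stopifnot(inherits(site, "eto_site"))
  if (!is.null(site$gamma_override)) return(site$gamma_override)
  0.000665 * atmospheric_pressure(site$elevation)
}

#' @keywords internal
solar_geometry <- function(latitude, doy) {
  if (any(abs(latitude) >= 90)) stop("|latitude| must be < 90")
  if (any(doy < 1 | doy > 366)) stop("doy outside 1..366")
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  # clamp for polar day/night where |tan(phi) tan(delta)| > 1
  x <- pmin(pmax(-tan(phi) * tan(delta), -1), 1)
  list(phi = phi, dr = dr, delta = delta, omega_s = acos(x))
}

#' Extraterrestrial radiation
#'
#' Top-of-atmosphere solar radiation for a latitude and day of year, from
#' the FAO-56 astronomical formula (inverse relative Earth-Sun distance,
#' solar declination, sunset hour angle). Polar night returns 0.
#'
#' @param latitude Decimal degrees (north positive).
#' @param doy Day of year, 1-366.
#' @return Ra (MJ m-2 day-1).
#' @export
#' @examples
#' extraterrestrial_radiation(11.41, mid_month_doy(1))
extraterrestrial_radiation <- function(latitude, doy) {
  g <- solar_geometry(latitude, doy)
  (24 * 60 / pi) * 0.0820 * g$dr *
    (g$omega_s * sin(g$phi) * sin(g$delta) +
       cos(g$phi) * cos(g$delta) * sin(g$omega_s))
}

#' Daylight hours
#'
#' N = 24 omega_s / pi from the sunset hour angle; 12 h at the equator,
#' 0 in polar night.
#'
#' @inheritParams extraterrestrial_radiation
#' @return Maximum possible sunshine duration N (h).
#' @export
daylight_hours <- function(latitude, doy) {
  24 * solar_geometry(latitude, doy)$omega_s / pi
}

#' Solar radiation from sunshine duration (Angstrom-Prescott)
#'
#' Rs = (a + b n/N) Ra. The sunshine ratio is clamped to 1 to tolerate
#' records where bright sunshine marginally exceeds astronomical daylight.
#'
#' @param sunshine Bright sunshine duration n (h/day), >= 0.
#' @param n_daylight Maximum daylight N (h).
#' @param ra Extraterrestrial radiation (MJ m-2 day-1).
#' @param a,b Angstrom-Prescott coefficients.
#' @return Rs (MJ m-2 day-1).
#' @export
solar_radiation_angstrom <- function(sunshine, n_daylight, ra,
                                     a = 0.25, b = 0.50) {
  if (any(sunshine < 0)) stop("negative sunshine duration")
  ratio <- ifelse(n_daylight > 0, pmin(sunshine / n_daylight, 1), 0)
  (a + b * ratio) * ra
}

#' Net radiation at the reference surface
#'
#' FAO-56 shortwave/longwave balance: Rn = (1 - albedo) Rs - Rnl with
#' Rnl = sigma (Tmax_K^4 + Tmin_K^4)/2 (0.34 - 0.14 sqrt(ea))
#' (1.35 Rs/Rso - 0.35) and clear-sky Rso = (0.75 + 2e-5 z) Ra.
#' The result is floored at zero.
#'
#' @param tmax,tmin Daily extreme temperatures (degC).
#' @param rs Incoming solar radiation (MJ m-2 day-1).
#' @param ra Extraterrestrial radiation (MJ m-2 day-1).
#' @param ea Actual vapour pressure (kPa).
#' @param elevation Site elevation (m).
#' @param albedo Surface albedo (0.23 for the grass reference).
#' @return Rn (MJ m-2 day-1).
#' @export
net_radiation <- function(tmax, tmin, rs, ra, ea, elevation, albedo = 0.23) {
  if (any(rs < 0) || any(ra < 0)) stop("negative radiation input")
  if (any(ea <= 0)) stop("ea must be positive")
  sigma <- 4.903e-9  # Stefan-Boltzmann, MJ K-4 m-2 day-1
  rso <- (0.75 + 2e-5 * elevation) * ra
  cloud <- ifelse(rso > 0, pmin(rs / rso, 1), 0)
  rnl <- sigma * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(ea)) * (1.35 * cloud - 0.35)
  # net longwave loss cannot be negative: under heavy overcast the balance
  # approaches zero rather than warming the surface
  rnl <- pmax(rnl, 0)
  pmax((1 - albedo) * rs - rnl, 0)
}

# Doorenbos-Pruitt mean daily percentage of annual daytime hours, northern
# latitudes 0..60 deg in 5-deg steps (rows) by month (columns). Southern
# latitudes reuse the table with a six-month shift.
dp_daytime_table <- matrix(c(
  0.27, 0.27, 0.27, 0.27, 0.27, 0.27, 0.27, 0.27, 0.27, 0.27, 0.27, 0.27,  # 0
  0.27, 0.27, 0.27, 0.28, 0.28, 0.28, 0.28, 0.28, 0.28, 0.27, 0.27, 0.27,  # 5
  0.26, 0.27, 0.27, 0.28, 0.28, 0.29, 0.29, 0.28, 0.28, 0.27, 0.26, 0.26,  # 10
  0.26, 0.26, 0.27, 0.28, 0.29, 0.29, 0.29, 0.28, 0.28, 0.27, 0.26, 0.25,  # 15
  0.25, 0.26, 0.27, 0.28, 0.29, 0.30, 0.30, 0.29, 0.28, 0.26, 0.25, 0.25,  # 20
  0.24, 0.26, 0.27, 0.29, 0.30, 0.31, 0.31, 0.29, 0.28, 0.26, 0.25, 0.24,  # 25
  0.24, 0.25, 0.27, 0.29, 0.31, 0.32, 0.31, 0.30, 0.28, 0.26, 0.24, 0.23,  # 30
  0.23, 0.25, 0.27, 0.29, 0.31, 0.32, 0.32, 0.30, 0.28, 0.25, 0.23, 0.22,  # 35
  0.22, 0.24, 0.27, 0.30, 0.32, 0.34, 0.33, 0.31, 0.28, 0.25, 0.22, 0.21,  # 40
  0.20, 0.23, 0.27, 0.30, 0.34, 0.35, 0.34, 0.32, 0.28, 0.24, 0.21, 0.20,  # 45
  0.19, 0.23, 0.27, 0.31, 0.34, 0.36, 0.35, 0.32, 0.28, 0.24, 0.20, 0.18,  # 50
  0.17, 0.21, 0.26, 0.32, 0.36, 0.39, 0.38, 0.33, 0.28, 0.23, 0.18, 0.16,  # 55
  0.15, 0.20, 0.26, 0.32, 0.38, 0.41, 0.40, 0.34, 0.28, 0.22, 0.17, 0.13   # 60
), nrow = 13, ncol = 12, byrow = TRUE)

#' Doorenbos-Pruitt daytime percentage
#'
#' Mean daily percentage p of annual daytime hours for a latitude and
#' month, interpolated linearly in latitude within the Doorenbos-Pruitt
#' table (0-60 deg in 5-deg steps; southern latitudes use the table shifted
#' by six months). This is the p consumed by the Blaney-Criddle and
#' Kharrufa models.
#'
#' @param latitude Decimal degrees, |latitude| <= 60.
#' @param month Integer month 1-12.
#' @return p (percentage expressed as a fraction, e.g. 0.26).
#' @export
#' @examples
#' daytime_percentage(11.41, 1)
daytime_percentage <- function(latitude, month) {
  if (any(abs(latitude) > 60)) stop("latitude outside Doorenbos-Pruitt table range (|lat| <= 60)")
  if (any(month != as.integer(month) | month < 1 | month > 12))
    stop("month must be an integer in 1..12")
  n <- max(length(latitude), length(month))
  latitude <- rep_len(latitude, n)
  month <- rep_len(as.integer(month), n)
  # southern hemisphere: same table, seasons shifted half a year
  month <- ifelse(latitude < 0, (month + 5L) %% 12L + 1L, month)
  alat <- abs(latitude)
  i <- pmin(floor(alat / 5) + 1, 12)
  frac <- alat / 5 - (i - 1)
  lo <- dp_daytime_table[cbind(i, month)]
  hi <- dp_daytime_table[cbind(i + 1, month)]
  lo + frac * (hi - lo)
}

#' Convert solar radiation between unit dialects
#'
#' Several historical models were fitted with Rs in cal cm-2 day-1
#' (langley) or kJ m-2 day-1 rather than MJ m-2 day-1.
#'
#' @param rs Solar radiation (MJ m-2 day-1).
#' @param dialect `"MJ"`, `"cal_cm2"` (x 23.884) or `"kJ_m2"` (x 1000).
#' @return Rs in the requested unit.
#' @export
#' @examples
#' unit_convert_rs(19.29, "cal_cm2")
unit_convert_rs <- function(rs, dialect = c("MJ", "cal_cm2", "kJ_m2")) {
  dialect <- match.arg(dialect)
  switch(dialect, MJ = rs, cal_cm2 = rs * 23.884, kJ_m2 = rs * 1000)
}

#' Derive all intermediate meteorological quantities for a climate table
#'
#' Expands a 12-row monthly climate table into every symbol the ET0
#' equations consume: mean temperature and diurnal range, mean RH, 2-m wind,
#' representative day of year, extraterrestrial and surface solar radiation,
#' net radiation, the saturation-vapour-pressure slope, the psychrometric
#' constant, saturation and actual vapour pressures, the saturation vapour
#' pressure at mean daily maximum temperature (for Papadakis), the
#' Doorenbos-Pruitt daytime percentage and the soil heat flux.
#'
#' @param climate A monthly climate table (see [validate_climate()]).
#' @param site An `eto_site` object.
#' @param conventions An `eto_conventions` object.
#' @return A 12-row data frame with columns `month`, `tmean`, `td`,
#'   `rh_mean`, `u2`, `doy`, `ra`, `n_daylight`, `rs`, `rn`, `delta`,
#'   `gamma`, `es`, `ea`, `ema`, `p_daytime`, `g_soil`.
#' @export
#' @examples
#' met <- derive_met(table1_fixture(), udhagamandalam_site())
#' met[1, c("ra", "rs", "rn")]
derive_met <- function(climate, site = udhagamandalam_site(),
                       conventions = eto_conventions()) {
  climate <- validate_climate(climate)
  stopifnot(inherits(site, "eto_site"), inherits(conventions, "eto_conventions"))
  doy <- mid_month_doy(climate$month)
  ra <- extraterrestrial_radiation(site$latitude, doy)
  n_day <- daylight_hours(site$latitude, doy)
  rs <- solar_radiation_angstrom(climate$sunshine_h, n_day, ra,
                                 site$angstrom_a, site$angstrom_b)
  ea <- actual_vapour_pressure(climate$tmax_c, climate$tmin_c,
                               climate$rhmax_pct, climate$rhmin_pct,
                               method = conventions$ea_method)
  tmean <- mean_temperature(climate$tmax_c, climate$tmin_c)
  data.frame(
    month = climate$month,
    tmean = tmean,
    td = climate$tmax_c - climate$tmin_c,
    rh_mean = mean_relative_humidity(climate$rhmax_pct, climate$rhmin_pct),
    u2 = wind_to_2m_ms(climate$wind_kmh, site$anemometer_height),
    doy = doy,
    ra = ra,
    n_daylight = n_day,
    rs = rs,
    rn = net_radiation(climate$tmax_c, climate$tmin_c, rs, ra, ea,
                       site$elevation, site$albedo),
    delta = svp_slope(tmean),
    gamma = psychrometric_constant(site),
    es = (saturation_vapour_pressure(climate$tmax_c) +
            saturation_vapour_pressure(climate$tmin_c)) / 2,
    ea = ea,
    ema = saturation_vapour_pressure(climate$tmax_c),
    p_daytime = daytime_percentage(site$latitude, climate$month),
    g_soil = conventions$g_soil
  )
}
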