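clim <- table1_fixture()
site <- udhagamandalam_site()

test_that("simple temperature, humidity and wind conversions", {
  expect_equal(mean_temperature(19.5, 7.3), 13.4)
  expect_equal(mean_temperature(0, 0), 0)
  expect_equal(mean_temperature(22.1, 12.0), 17.05)
  expect_error(mean_temperature(5, 10), "tmax")

  expect_equal(mean_relative_humidity(95.0, 51.1), 73.05)
  expect_equal(mean_relative_humidity(100, 100), 100)
  expect_equal(mean_relative_humidity(96.2, 80.3), 88.25)
  expect_error(mean_relative_humidity(50, 60))

  expect_equal(wind_to_2m_ms(4.09), 4.09 / 3.6, tolerance = 1e-12)
  expect_equal(wind_to_2m_ms(0), 0)
  expect_equal(wind_to_2m_ms(8.51), 2.364, tolerance = 1e-3)
  # 10-m measurement reduced by the log profile
  expect_lt(wind_to_2m_ms(10, 10), 10 / 3.6)
  expect_equal(wind_to_2m_ms(10, 10), 10 / 3.6 * 4.87 / log(67.8 * 10 - 5.42))
  # stays vectorised when the height is a scalar
  expect_equal(wind_to_2m_ms(clim$wind_kmh, 2), clim$wind_kmh / 3.6)
})

test_that("mid-month day of year follows the non-leap calendar", {
  expect_identical(mid_month_doy(c(1, 2, 12)), c(15L, 46L, 349L))
  expect_identical(mid_month_doy(7), 196L)
  expect_error(mid_month_doy(0))
  expect_error(mid_month_doy(13))
})

test_that("saturation vapour pressure and its slope", {
  expect_equal(saturation_vapour_pressure(0), 0.6108)
  expect_equal(saturation_vapour_pressure(13.4), 1.5374, tolerance = 1e-4)
  expect_equal(saturation_vapour_pressure(19.5), 2.2668, tolerance = 1e-4)
  expect_equal(svp_slope(13.4), 0.1002, tolerance = 1e-3)
  expect_equal(svp_slope(0), 0.04445, tolerance = 1e-3)
  # strictly increasing and convex over the valid range
  t <- seq(-40, 60, by = 0.5)
  es <- saturation_vapour_pressure(t)
  expect_true(all(diff(es) > 0))
  expect_true(all(diff(es, differences = 2) > 0))
  expect_true(all(svp_slope(t) > 0))
  expect_gt(svp_slope(20), svp_slope(10))
})

test_that("actual vapour pressure conventions", {
  jan <- clim[1, ]
  expect_equal(
    actual_vapour_pressure(jan$tmax_c, jan$tmin_c, jan$rhmax_pct, jan$rhmin_pct),
    1.0649, tolerance = 1e-3)
  expect_equal(
    actual_vapour_pressure(jan$tmax_c, jan$tmin_c, jan$rhmax_pct, jan$rhmin_pct,
                           method = "mean_rh"),
    0.7305 * saturation_vapour_pressure(13.4), tolerance = 1e-10)
  # saturated air gives the mean-of-extremes saturation pressure
  expect_equal(actual_vapour_pressure(20, 10, 100, 100),
               mean(saturation_vapour_pressure(c(20, 10))))
})

test_that("atmospheric pressure and psychrometric constant", {
  expect_equal(atmospheric_pressure(0), 101.3)
  expect_equal(atmospheric_pressure(2218), 77.69, tolerance = 1e-3)
  z <- seq(0, 4000, by = 100)
  expect_true(all(diff(atmospheric_pressure(z)) < 0))
  expect_equal(psychrometric_constant(site_metadata(0, 0)), 0.0674,
               tolerance = 1e-3)
  expect_equal(psychrometric_constant(site), 0.0517, tolerance = 1e-3)
  expect_equal(
    psychrometric_constant(udhagamandalam_site(gamma_override = 0.0677)),
    0.0677)
})

test_that("extraterrestrial radiation and daylight hours", {
  expect_equal(extraterrestrial_radiation(11.41, 15), 31.2, tolerance = 0.01)
  expect_equal(extraterrestrial_radiation(70, 355), 0)
  # equator beats high latitude at the equinox
  expect_gt(extraterrestrial_radiation(0, 80),
            extraterrestrial_radiation(60, 80))
  expect_gt(extraterrestrial_radiation(0, 80),
            extraterrestrial_radiation(-60, 80))
  expect_equal(daylight_hours(0, 100), 12, tolerance = 0.15)
  expect_equal(daylight_hours(11.41, 15), 11.4, tolerance = 0.05)
  expect_equal(daylight_hours(70, 355), 0)
})

test_that("hemispheric symmetry of extraterrestrial radiation", {
  for (lat in c(10, 25, 40, 55)) {
    for (doy in c(15, 105, 196, 288)) {
      mirrored <- (doy + 182.5) %% 365
      expect_equal(extraterrestrial_radiation(lat, doy),
                   extraterrestrial_radiation(-lat, mirrored),
                   tolerance = 0.5, ignore_attr = TRUE)
    }
  }
})

test_that("daylight hours average about 12 h over the year everywhere", {
  doy <- mid_month_doy(1:12)
  for (lat in seq(-60, 60, by = 15)) {
    expect_equal(mean(daylight_hours(lat, doy)), 12, tolerance = 0.2)
  }
})

test_that("Angstrom-Prescott solar radiation", {
  expect_equal(solar_radiation_angstrom(8.5, 11.4, 31.2), 19.43,
               tolerance = 0.01)
  expect_equal(solar_radiation_angstrom(0, 12, 30), 0.25 * 30)
  expect_equal(solar_radiation_angstrom(12, 12, 30), 0.75 * 30)
  # over-long sunshine records are clamped to the (a+b) ceiling
  expect_equal(solar_radiation_angstrom(13, 12, 30), 0.75 * 30)
})

test_that("net radiation stays within the shortwave budget", {
  met <- derive_met(clim, site)
  expect_equal(met$rn[1], 10.3, tolerance = 0.1)
  expect_true(all(met$rn < (1 - site$albedo) * met$rs))
  expect_true(all(met$rn >= 0))
  expect_equal(net_radiation(20, 10, 0, 30, 1.2, 0), 0)
})

test_that("Doorenbos-Pruitt daytime percentage", {
  expect_equal(daytime_percentage(11.41, 1), 0.26, tolerance = 0.005)
  expect_equal(daytime_percentage(0, 7), 0.27)
  expect_error(daytime_percentage(65, 1), "range")
  # p is a percentage of annual daytime hours: weighted by days it sums
  # to about 100% over the year
  days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  for (lat in c(0, 11.41, -23, 40, 60)) {
    p <- daytime_percentage(lat, 1:12)
    expect_equal(sum(p * days), 100, tolerance = 3)
  }
  # southern-hemisphere seasons are shifted by six months
  expect_equal(daytime_percentage(-40, 1), daytime_percentage(40, 7))
})

test_that("solar radiation unit dialects", {
  expect_equal(unit_convert_rs(19.29, "cal_cm2"), 460.72, tolerance = 0.01)
  expect_equal(unit_convert_rs(1, "kJ_m2"), 1000)
  expect_equal(unit_convert_rs(0, "cal_cm2"), 0)
  expect_equal(unit_convert_rs(5, "MJ"), 5)
})

test_that("primitives agree with a naive oracle on random inputs", {
  set.seed(101)
  for (i in 1:1000) {
    t <- runif(1, -40, 60)
    expect_equal(saturation_vapour_pressure(t), oracle_es(t),
                 tolerance = 1e-9)
    lat <- runif(1, -89, 89)
    doy <- sample(1:365, 1)
    expect_equal(extraterrestrial_radiation(lat, doy), oracle_ra(lat, doy),
                 tolerance = 1e-9)
  }
})

test_that("derive_met covers every field with consistent bounds", {
  met <- derive_met(clim, site)
  expect_identical(nrow(met), 12L)
  expect_true(all(met$rs >= 0 & met$rs <= met$ra))
  expect_true(all(met$rn <= met$rs))
  expect_true(all(met$delta > 0))
  expect_true(all(met$gamma > 0))
  expect_true(all(met$ea > 0 & met$ea <= met$es))
  expect_true(all(met$ema > 0))
  expect_true(all(met$td >= 0))
  expect_true(all(met$g_soil == 0))
})
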