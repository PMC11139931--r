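# Registry and evaluation of the 18 empirical ET0 models: 8 temperature-
# based (Hargreaves-Samani, Schendel, Kharrufa, Trajkovic, Berti,
# Blaney-Criddle, Papadakis, Ivanov) and 10 radiation-based (Makkink,
# Jensen-Haise, Irmak-Rs, Irmak-Rn, Caprio, Jones, Turc, Tabari,
# Priestley-Taylor, Abtew).

#' Registry of ET0 models
#'
#' One row per model: the 18 empirical models plus the two baselines.
#' `category` is `"temperature"`, `"radiation"` or `"baseline"`;
#' `rs_dialect` records the solar-radiation unit the model's coefficients
#' were fitted in (`MJ`, `cal_cm2` for Turc and Makkink, `kJ_m2` for
#' Caprio); `constant` holds the model's named multiplier where one is
#' standard (Priestley-Taylor alpha = 1.26, Jones alpha1 = 1.1).
#'
#' @return A data frame with columns `model_id`, `label`, `category`,
#'   `required_inputs` (comma-separated derived-met fields), `rs_dialect`,
#'   `constant`.
#' @export
#' @examples
#' table(model_registry()$category)
model_registry <- function() {
  df <- rbind(
    data.frame(model_id = "pan_observed", label = "Observed ETo (pan)",
               category = "baseline", required_inputs = "u2,rh_mean",
               rs_dialect = "MJ", constant = NA_real_),
    data.frame(model_id = "fao_pm", label = "FAO-PM",
               category = "baseline",
               required_inputs = "tmean,u2,rn,delta,gamma,es,ea",
               rs_dialect = "MJ", constant = NA_real_),
    data.frame(
      model_id = c("hargreaves_samani", "schendel", "kharrufa", "trajkovic",
                   "berti", "blaney_criddle", "papadakis", "ivanov"),
      label = c("Hargreaves-Samani", "Schendel", "Kharrufa", "Trajkovic",
                "Berti", "Blaney-Criddle", "Papadakis", "Ivanov"),
      category = "temperature",
      required_inputs = c("ra,tmean,td", "tmean,rh_mean", "p_daytime,tmean",
                          "ra,tmean,td", "ra,tmean,td", "p_daytime,tmean",
                          "ema,ea", "tmean,rh_mean"),
      rs_dialect = "MJ",
      constant = NA_real_),
    data.frame(
      model_id = c("makkink", "jensen_haise", "irmak_rs", "irmak_rn",
                   "caprio", "jones", "turc", "tabari", "priestley_taylor",
                   "abtew"),
      label = c("Makkink", "Jensen-Haise", "Irmak (Rs)", "Irmak (Rn)",
                "Caprio", "Jones", "Turc", "Tabari", "Priestley-Taylor",
                "Abtew"),
      category = "radiation",
      required_inputs = c("rs,delta,gamma", "rs,tmean", "rs,tmean",
                          "rn,tmean", "rs,tmean", "rs", "rs,tmean",
                          "rs", "rn,delta,gamma", "rs"),
      rs_dialect = c("cal_cm2", "MJ", "MJ", "MJ", "kJ_m2", "MJ", "cal_cm2",
                     "MJ", "MJ", "MJ"),
      constant = c(NA, NA, NA, NA, NA, 1.1, NA, NA, 1.26, NA))
  )
  rownames(df) <- NULL
  df
}

#' @keywords internal
model_rh <- function(climate, conventions) {
  switch(conventions$rh_mode,
         mean = mean_relative_humidity(climate$rhmax_pct, climate$rhmin_pct),
         min = climate$rhmin_pct)
}

# Each evaluator takes (climate, met, site, conv) and returns a 12-vector
# (mm/day, not yet floored).
eto_formulas <- list(
  hargreaves_samani = function(climate, met, site, conv)
    0.0023 * met$ra * (met$tmean + 17.8) *
      met$td^conv$hargreaves_exponent / site$latent_heat,
  schendel = function(climate, met, site, conv)
    16 * met$tmean / model_rh(climate, conv),
  kharrufa = function(climate, met, site, conv)
    0.34 * met$p_daytime * met$tmean^1.3,
  # fitted with Ra in MJ and no latent-heat division; the literal form is
  # what yields this model's characteristic overestimation in the tropics
  trajkovic = function(climate, met, site, conv)
    0.0023 * met$ra * met$td^0.424 * (met$tmean + 17.8),
  berti = function(climate, met, site, conv)
    0.00193 * met$ra * (met$tmean + 17.8) * met$td^0.5 / site$latent_heat,
  blaney_criddle = function(climate, met, site, conv)
    met$p_daytime * (0.46 * met$tmean + 8.13),
  papadakis = function(climate, met, site, conv) {
    ea <- switch(conv$papadakis_ea,
                 dual_rh = met$ea,
                 svp_tmin = saturation_vapour_pressure(climate$tmin_c))
    2.5 * (met$ema - ea)
  },
  ivanov = function(climate, met, site, conv)
    0.00006 * (25 + met$tmean)^2 * (100 - model_rh(climate, conv)),
  makkink = function(climate, met, site, conv)
    0.61 * (met$delta / (met$delta + met$gamma)) *
      unit_convert_rs(met$rs, "cal_cm2") / 58.5 - 0.12,
  jensen_haise = function(climate, met, site, conv)
    (met$rs / site$latent_heat) * (0.025 * met$tmean + 0.08),
  irmak_rs = function(climate, met, site, conv)
    -0.611 + 0.149 * met$rs + 0.079 * met$tmean,
  irmak_rn = function(climate, met, site, conv)
    0.489 + 0.289 * met$rn + 0.023 * met$tmean,
  caprio = function(climate, met, site, conv)
    (6.1 / 1e6) * unit_convert_rs(met$rs, "kJ_m2") * (1.8 * met$tmean + 1.0),
  jones = function(climate, met, site, conv)
    1.1 * 3.87e-3 * met$rs *
      (0.6 * climate$tmax_c + 0.4 * climate$tmin_c + 29),
  turc = function(climate, met, site, conv)
    0.013 * (met$tmean / (met$tmean + 15)) *
      (unit_convert_rs(met$rs, "cal_cm2") + 50),
  tabari = function(climate, met, site, conv)
    0.156 * met$rs - 0.0112 * climate$tmax_c + 0.0733 * climate$tmin_c - 0.478,
  priestley_taylor = function(climate, met, site, conv)
    1.26 * (met$delta / (met$delta + met$gamma)) * met$rn / site$latent_heat,
  abtew = function(climate, met, site, conv)
    0.53 * met$rs / site$latent_heat
)

#' Evaluate one empirical ET0 model
#'
#' Evaluates the named model's formula on a climate table and its derived
#' meteorology. Raw negative values (possible for the linear Irmak and
#' Tabari fits at cold extremes) are floored at zero with a warning.
#'
#' @param model_id One of the empirical `model_id`s in [model_registry()].
#' @inheritParams derive_met
#' @param met Optional pre-computed [derive_met()] table.
#' @return A numeric vector of 12 monthly ET0 values (mm/day).
#' @export
#' @examples
#' clim <- table1_fixture()
#' eto_empirical("blaney_criddle", clim)[1]
eto_empirical <- function(model_id, climate, site = udhagamandalam_site(),
                          conventions = eto_conventions(), met = NULL) {
  stopifnot(length(model_id) == 1L)
  f <- eto_formulas[[model_id]]
  if (is.null(f)) stop("unknown empirical model: ", model_id)
  climate <- validate_climate(climate)
  if (is.null(met)) met <- derive_met(climate, site, conventions)
  reg <- model_registry()
  need <- strsplit(reg$required_inputs[reg$model_id == model_id], ",")[[1]]
  missing <- setdiff(need, names(met))
  if (length(missing))
    stop("met lacks required inputs: ", paste(missing, collapse = ", "))
  v <- f(climate, met, site, conventions)
  if (any(v < 0)) {
    warning(sprintf("%s: %d negative monthly value(s) floored at 0",
                    model_id, sum(v < 0)))
    v <- pmax(v, 0)
  }
  v
}

#' @rdname eto_empirical
#' @details `eto_temperature()` and `eto_radiation()` are guards that
#'   additionally check the model belongs to the expected category.
#' @export
eto_temperature <- function(model_id, climate, site = udhagamandalam_site(),
                            conventions = eto_conventions(), met = NULL) {
  reg <- model_registry()
  if (!model_id %in% reg$model_id[reg$category == "temperature"])
    stop(model_id, " is not a registered temperature-based model")
  eto_empirical(model_id, climate, site, conventions, met)
}

#' @rdname eto_empirical
#' @export
eto_radiation <- function(model_id, climate, site = udhagamandalam_site(),
                          conventions = eto_conventions(), met = NULL) {
  reg <- model_registry()
  if (!model_id %in% reg$model_id[reg$category == "radiation"])
    stop(model_id, " is not a registered radiation-based model")
  eto_empirical(model_id, climate, site, conventions, met)
}

#' Compute the full monthly ET0 table
#'
#' Runs both baselines and the requested empirical models on a climate
#' table, producing one row per model with the 12 monthly ET0 values
#' (the shape of a published model-comparison table).
#'
#' @inheritParams derive_met
#' @param models `"all"`, `"temperature"`, `"radiation"`, or a character
#'   vector of model ids. Baselines are always included.
#' @return A data frame with columns `model_id`, `category`,
#'   `jan` ... `dec`.
#' @export
#' @examples
#' tab <- compute_eto_table(table1_fixture())
#' subset(tab, model_id == "blaney_criddle")
compute_eto_table <- function(climate, site = udhagamandalam_site(),
                              conventions = eto_conventions(),
                              models = "all") {
  climate <- validate_climate(climate)
  met <- derive_met(climate, site, conventions)
  reg <- model_registry()
  emp <- reg[reg$category != "baseline", ]
  ids <- if (identical(models, "all")) emp$model_id
  else if (identical(models, "temperature")) emp$model_id[emp$category == "temperature"]
  else if (identical(models, "radiation")) emp$model_id[emp$category == "radiation"]
  else {
    bad <- setdiff(models, emp$model_id)
    if (length(bad)) stop("unknown model id(s): ", paste(bad, collapse = ", "))
    models
  }
  rows <- rbind(
    data.frame(model_id = "pan_observed",
               t(pan_observed_eto(climate, site, conventions, met))),
    data.frame(model_id = "fao_pm", t(fao_penman_monteith(met)))
  )
  for (id in ids)
    rows <- rbind(rows, data.frame(
      model_id = id, t(eto_empirical(id, climate, site, conventions, met))))
  names(rows)[-1] <- month_cols
  rows$category <- reg$category[match(rows$model_id, reg$model_id)]
  rows <- rows[c("model_id", "category", month_cols)]
  rownames(rows) <- NULL
  rows
}

#' @keywords internal
month_cols <- c("jan", "feb", "mar", "apr", "may", "jun",
                "jul", "aug", "sep", "oct", "nov", "dec")

#' Extract one model's 12-month series from an ET0 table
#'
#' @param eto_table A table from [compute_eto_table()] or [table3_fixture()].
#' @param model_id Row to extract.
#' @return Numeric vector of 12 monthly values.
#' @export
eto_series <- function(eto_table, model_id) {
  i <- match(model_id, eto_table$model_id)
  if (is.na(i)) stop("no series for model: ", model_id)
  v <- as.numeric(eto_table[i, month_cols])
  if (length(v) != 12L || any(!is.finite(v)) || any(v < 0))
    stop("invalid series for model: ", model_id)
  v
}
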