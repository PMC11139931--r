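#' Site metadata for ET0 computation
#'
#' Bundles the static, location-specific quantities the ET0 equations need:
#' latitude and elevation (for extraterrestrial radiation and atmospheric
#' pressure), surface albedo, Angstrom-Prescott sunshine coefficients, the
#' upwind green-crop fetch of the class-A pan, anemometer height, and the
#' latent heat of vaporisation.
#'
#' @param latitude Decimal degrees north (negative south); strictly between
#'   -90 and 90.
#' @param elevation Metres above sea level; non-negative.
#' @param albedo Shortwave reflectance of the reference surface; the FAO-56
#'   grass reference uses 0.23.
#' @param angstrom_a,angstrom_b Angstrom-Prescott regression coefficients
#'   relating relative sunshine duration to the clear-sky transmissivity.
#'   FAO-56 recommends a = 0.25, b = 0.50 where no local calibration exists.
#' @param pan_fetch Upwind fetch F (m) of green crop around the class-A pan;
#'   must exceed 1 m so log(F) is positive.
#' @param anemometer_height Height (m) of the wind measurement; wind speeds
#'   are reduced to 2 m with the FAO-56 logarithmic profile when it differs
#'   from 2 m.
#' @param gamma_override Optional fixed psychrometric constant (kPa / degC).
#'   When `NULL` (default) gamma is computed from elevation via atmospheric
#'   pressure.
#' @param latent_heat Latent heat of vaporisation lambda (MJ/kg); the FAO-56
#'   convention fixes it at 2.45.
#'
#' @return An object of class `eto_site` (a named list).
#' @seealso [udhagamandalam_site()] for the packaged tropical-highland site.
#' @export
#' @examples
#' site <- site_metadata(latitude = 11.41, elevation = 2218)
#' psychrometric_constant(site)
site_metadata <- function(latitude, elevation, albedo = 0.23,
                          angstrom_a = 0.25, angstrom_b = 0.50,
                          pan_fetch = 100, anemometer_height = 2,
                          gamma_override = NULL, latent_heat = 2.45) {
  stopifnot(
    is.numeric(latitude), length(latitude) == 1L,
    latitude > -90, latitude < 90,
    is.numeric(elevation), length(elevation) == 1L, elevation >= 0,
    is.numeric(albedo), albedo >= 0, albedo <= 1,
    is.numeric(angstrom_a), angstrom_a >= 0,
    is.numeric(angstrom_b), angstrom_b > 0,
    angstrom_a + angstrom_b <= 1,
    is.numeric(pan_fetch), pan_fetch > 1,
    is.numeric(anemometer_height), anemometer_height >= 0.1,
    is.numeric(latent_heat), latent_heat > 0
  )
  if (!is.null(gamma_override)) {
    stopifnot(is.numeric(gamma_override), length(gamma_override) == 1L,
              gamma_override > 0)
  }
  structure(
    list(latitude = latitude, elevation = elevation, albedo = albedo,
         angstrom_a = angstrom_a, angstrom_b = angstrom_b,
         pan_fetch = pan_fetch, anemometer_height = anemometer_height,
         gamma_override = gamma_override, latent_heat = latent_heat),
    class = "eto_site")
}

#' @export
print.eto_site <- function(x, ...) {
  cat("<eto_site>\n")
  cat(sprintf("  latitude: %.4f degN   elevation: %.0f m\n",
              x$latitude, x$elevation))
  cat(sprintf("  albedo: %.2f   Angstrom a/b: %.2f/%.2f   pan fetch: %.0f m\n",
              x$albedo, x$angstrom_a, x$angstrom_b, x$pan_fetch))
  cat(sprintf("  gamma: %s   lambda: %.2f MJ/kg\n",
              if (is.null(x$gamma_override)) "from elevation"
              else sprintf("fixed %.4f kPa/degC", x$gamma_override),
              x$latent_heat))
  invisible(x)
}

#' Packaged site: Udhagamandalam (Nilgiris, Tamil Nadu, India)
#'
#' The tropical highland station the packaged climate normals come from:
#' 11 deg 24' 36" N, 2218 m above sea level. Pan fetch defaults to 100 m,
#' consistent with the pan coefficients implied by the packaged observed-ET0
#' series.
#'
#' @param ... Overrides passed on to [site_metadata()].
#' @return An `eto_site` object.
#' @export
#' @examples
#' udhagamandalam_site()
udhagamandalam_site <- function(...) {
  args <- list(...)
  defaults <- list(latitude = 11 + 24 / 60 + 36 / 3600, elevation = 2218)
  do.call(site_metadata, utils::modifyList(defaults, args))
}

#' Read site metadata from a YAML file
#'
#' The file holds keys mirroring the arguments of [site_metadata()]
#' (`latitude`, `elevation`, `albedo`, `angstrom_a`, `angstrom_b`,
#' `pan_fetch`, `anemometer_height`, `gamma_override`, `latent_heat`);
#' missing keys fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return An `eto_site` object.
#' @export
read_site_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(site_metadata))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown site keys: ", paste(bad, collapse = ", "))
  do.call(site_metadata, cfg)
}

#' Computational conventions for the ET0 equations
#'
#' Several inputs of the empirical models are under-determined by standard
#' practice (which relative humidity a single-RH model consumes, the
#' exponent of the Hargreaves temperature-range term, which actual-vapour-
#' pressure form feeds the aerodynamic term, which pan-coefficient variant
#' is used). This object pins those choices; every computation accepts it.
#'
#' @param ea_method Actual vapour pressure convention: `"dual_rh"` (FAO-56
#'   form from RHmax over es(Tmin) and RHmin over es(Tmax)) or `"mean_rh"`
#'   (mean RH times es at mean temperature).
#' @param rh_mode Which RH single-humidity models (Schendel, Ivanov) use:
#'   `"mean"` of the monthly max/min, or `"min"`.
#' @param hargreaves_exponent Exponent on the diurnal temperature range in
#'   the Hargreaves-Samani model; the classic value 0.5 is the default (a
#'   0.517 variant circulates).
#' @param kpan_variant `"allen_pruitt"` for the standard Allen-Pruitt pan
#'   coefficient regression, or `"legacy_print"` for a circulated variant
#'   with a 3.31e-4 wind coefficient and an inverse-fourth-power log-fetch
#'   interaction (kept for audit; dimensionally inconsistent with the
#'   published regression).
#' @param papadakis_ea Vapour-pressure deficit convention for the Papadakis
#'   model: `"dual_rh"` (same ea as the aerodynamic term) or `"svp_tmin"`
#'   (saturation vapour pressure at Tmin).
#' @param g_soil Soil heat flux density G (MJ m-2 day-1); zero for monthly
#'   normals, following the daily convention.
#'
#' @return An object of class `eto_conventions`.
#' @export
eto_conventions <- function(ea_method = c("dual_rh", "mean_rh"),
                            rh_mode = c("mean", "min"),
                            hargreaves_exponent = 0.5,
                            kpan_variant = c("allen_pruitt", "legacy_print"),
                            papadakis_ea = c("dual_rh", "svp_tmin"),
                            g_soil = 0) {
  stopifnot(is.numeric(hargreaves_exponent), hargreaves_exponent > 0,
            is.numeric(g_soil), length(g_soil) == 1L)
  structure(
    list(ea_method = match.arg(ea_method),
         rh_mode = match.arg(rh_mode),
         hargreaves_exponent = hargreaves_exponent,
         kpan_variant = match.arg(kpan_variant),
         papadakis_ea = match.arg(papadakis_ea),
         g_soil = g_soil),
    class = "eto_conventions")
}
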