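#' Atmospheric correction parameters
#'
#' Parameter bundle for single-channel atmospheric correction of a thermal
#' band: atmospheric transmittance and the up- and downwelling path
#' radiances. Defaults are the mid-latitude profile used for the Luoping
#' County Landsat 8 TIRS scene (NASA atmospheric-correction tool output for
#' the acquisition time and scene centre).
#'
#' @param tau atmospheric transmittance in the thermal band, unitless,
#'   in (0, 1].
#' @param L_up upwelling path radiance, W/m2/sr/um, >= 0.
#' @param L_down downwelling atmospheric radiance, W/m2/sr/um, >= 0.
#' @return A list of class `atmospheric_profile`.
#' @export
atmospheric_profile <- function(tau = 0.91, L_up = 0.75, L_down = 1.29) {
  stopifnot(tau > 0, tau <= 1, L_up >= 0, L_down >= 0)
  structure(list(tau = tau, L_up = L_up, L_down = L_down),
            class = "atmospheric_profile")
}

#' Planck calibration constants
#'
#' Thermal-band calibration constants K1 (radiance scale) and K2 (effective
#' wavelength temperature) for the Planck-law conversion between band
#' radiance and brightness temperature. Defaults are Landsat 8 TIRS band 10.
#'
#' @param K1 W/m2/sr/um, > 0.
#' @param K2 kelvin, > 0.
#' @return A list of class `planck_constants`.
#' @export
planck_constants <- function(K1 = 774.89, K2 = 1321.08) {
  stopifnot(K1 > 0, K2 > 0)
  structure(list(K1 = K1, K2 = K2), class = "planck_constants")
}

#' Emissivity model parameters
#'
#' Surface emissivity is modelled linearly in vegetation fraction,
#' `epsilon = slope * P_V + intercept`, with the vegetation fraction scaled
#' from NDVI between a bare-soil and a full-vegetation endpoint. The NDVI
#' endpoints are not scene constants of the retrieval literature so much as
#' analyst choices; the defaults 0.05 / 0.70 are common Landsat practice and
#' both are exposed here.
#'
#' @param slope,intercept coefficients of the linear emissivity model.
#' @param ndvi_soil NDVI of bare soil (vegetation fraction 0).
#' @param ndvi_veg NDVI of full vegetation cover (vegetation fraction 1).
#' @return A list of class `emissivity_params`.
#' @export
emissivity_params <- function(slope = 0.004, intercept = 0.986,
                              ndvi_soil = 0.05, ndvi_veg = 0.70) {
  stopifnot(ndvi_soil < ndvi_veg)
  eps_range <- intercept + slope * c(0, 1)
  if (any(eps_range <= 0) || any(eps_range > 1))
    stop("emissivity model must map P_V in [0,1] into (0, 1]")
  structure(list(slope = slope, intercept = intercept,
                 ndvi_soil = ndvi_soil, ndvi_veg = ndvi_veg),
            class = "emissivity_params")
}

kelvin_offset <- 273.15

#' Normalized difference vegetation index
#'
#' `(nir - red) / (nir + red)` per cell. Cells where the band sum is zero
#' become nodata (with a message reporting the count); nodata in either band
#' propagates.
#'
#' @param red,nir congruent reflectance `raster_grid`s.
#' @return `raster_grid` of NDVI in \[-1, 1\].
#' @export
ndvi <- function(red, nir) {
  check_congruent(red, nir)
  s <- nir + red
  zero <- !is.na(s) & s == 0
  if (any(zero)) {
    message(sum(zero), " cell(s) with nir + red = 0 set to nodata")
    s[zero] <- NA_real_
  }
  raster_grid((nir - red) / s, cell_size(red))
}

#' Vegetation fraction from NDVI
#'
#' Linear scaling of NDVI between the bare-soil and full-vegetation
#' endpoints, clipped to \[0, 1\].
#'
#' @param ndvi `raster_grid` of NDVI values.
#' @param params [emissivity_params()].
#' @return `raster_grid` of vegetation fraction P_V in \[0, 1\].
#' @export
vegetation_fraction <- function(ndvi, params = emissivity_params()) {
  pv <- (ndvi - params$ndvi_soil) / (params$ndvi_veg - params$ndvi_soil)
  raster_grid(pmin(pmax(unclass(pv), 0), 1), cell_size(ndvi))
}

#' Surface emissivity from vegetation fraction
#'
#' @param pv `raster_grid` of vegetation fraction in \[0, 1\].
#' @param params [emissivity_params()].
#' @return `raster_grid` of emissivity; with the default coefficients the
#'   range is \[0.986, 0.990\].
#' @export
emissivity <- function(pv, params = emissivity_params()) {
  raster_grid(params$slope * unclass(pv) + params$intercept, cell_size(pv))
}

#' Surface-leaving blackbody radiance
#'
#' Removes the atmospheric path terms and the reflected downwelling
#' component from at-sensor thermal radiance:
#' `B = (L - L_up - tau * (1 - eps) * L_down) / (tau * eps)`.
#' Cells where the corrected radiance is non-positive (at-sensor radiance at
#' or below the path radiance, non-physical for a warm surface) become
#' nodata; the count is reported.
#'
#' @param radiance at-sensor thermal radiance `raster_grid`, W/m2/sr/um.
#' @param epsilon emissivity `raster_grid` (or scalar), values in (0, 1].
#' @param atmos [atmospheric_profile()].
#' @return `raster_grid` of blackbody radiance B(T_S).
#' @export
blackbody_radiance <- function(radiance, epsilon, atmos = atmospheric_profile()) {
  if (inherits(epsilon, "raster_grid")) check_congruent(radiance, epsilon)
  eps <- unclass(epsilon)
  if (any(!is.na(eps) & eps <= 0)) stop("emissivity must be positive")
  b <- (unclass(radiance) - atmos$L_up - atmos$tau * (1 - eps) * atmos$L_down) /
    (atmos$tau * eps)
  bad <- !is.na(b) & b <= 0
  if (any(bad)) {
    message(sum(bad), " cell(s) with non-positive corrected radiance set to nodata")
    b[bad] <- NA_real_
  }
  raster_grid(b, cell_size(radiance))
}

#' Invert Planck's law
#'
#' Converts blackbody radiance to surface temperature,
#' `T_S = K2 / ln(K1 / B + 1)` (kelvin). Strictly increasing in B.
#'
#' @param b blackbody radiance `raster_grid`, > 0 (non-positive cells become
#'   nodata).
#' @param planck [planck_constants()].
#' @return `raster_grid` of temperature in kelvin.
#' @export
planck_invert <- function(b, planck = planck_constants()) {
  v <- unclass(b)
  v[!is.na(v) & v <= 0] <- NA_real_
  raster_grid(planck$K2 / log(planck$K1 / v + 1), cell_size(b))
}

#' Retrieve land surface temperature from thermal radiance
#'
#' The full single-channel atmospheric-correction chain:
#' NDVI -> vegetation fraction -> emissivity -> atmospheric correction ->
#' Planck inversion -> Celsius. Nodata propagates through every stage.
#'
#' @param radiance at-sensor thermal radiance `raster_grid`.
#' @param red,nir reflectance `raster_grid`s congruent with `radiance`.
#' @param atmos [atmospheric_profile()].
#' @param planck [planck_constants()].
#' @param emis_params [emissivity_params()].
#' @return `raster_grid` of LST in degrees Celsius.
#' @examples
#' sc <- generate_scene(default_scene_spec(n_rows = 60, n_cols = 60))
#' lst <- retrieve_lst(sc$radiance, sc$red, sc$nir)
#' max(abs(lst - sc$lst_true), na.rm = TRUE) # < 0.01 degC
#' @export
retrieve_lst <- function(radiance, red, nir,
                         atmos = atmospheric_profile(),
                         planck = planck_constants(),
                         emis_params = emissivity_params()) {
  check_congruent(radiance, red, nir)
  nd <- ndvi(red, nir)
  pv <- vegetation_fraction(nd, emis_params)
  eps <- emissivity(pv, emis_params)
  b <- blackbody_radiance(radiance, eps, atmos)
  tk <- planck_invert(b, planck)
  raster_grid(unclass(tk) - kelvin_offset, cell_size(radiance))
}
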