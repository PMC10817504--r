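#' Species legend used throughout the package
#'
#' Five dominant-cover classes: four tree species common in Pannonian
#' lowland forests plus clearcut. Codes are stable integers; zonal-majority
#' ties are broken toward the lowest code.
#'
#' @return Named integer vector mapping class name to code.
#' @export
species_legend <- function() {
  c(black_locust = 1L, scots_pine = 2L, pedunculate_oak = 3L,
    red_oak = 4L, clearcut = 5L)
}

#' Seasonal reflectance model for one cover class
#'
#' A double-logistic NDVI phenology curve (green-up ramp, summer plateau,
#' senescence ramp) plus a fixed visible-band signature. NDVI at day-of-year
#' `t` is
#' `base + (peak - base) * (plogis((t - greenup)/width_up) - plogis((t - senescence)/width_down))`.
#' The red band is held at the class signature and the NIR band is derived
#' from the target NDVI, so the noiseless simulated NDVI equals the curve
#' exactly.
#'
#' @param peak_ndvi Midsummer plateau NDVI, in (0, 1].
#' @param greenup_doy,senescence_doy Days of year of the two ramp midpoints;
#'   green-up must precede senescence.
#' @param width_up,width_down Logistic ramp widths in days.
#' @param base_ndvi Off-season NDVI floor.
#' @param blue,green,red Reflectance signature of the class in B2/B3/B4
#'   (unitless surface reflectance in \[0, 1\]).
#' @param noise_sd Gaussian reflectance noise standard deviation added
#'   independently per pixel, band and acquisition (unitless); >= 0.
#' @return An object of class `fm_phenology`.
#' @export
phenology_model <- function(peak_ndvi, greenup_doy, senescence_doy,
                            width_up = 10, width_down = 15,
                            base_ndvi = 0.25,
                            blue = 0.03, green = 0.06, red = 0.05,
                            noise_sd = 0.02) {
  if (peak_ndvi <= 0 || peak_ndvi > 1) stop("peak_ndvi must lie in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (greenup_doy >= senescence_doy) stop("green-up must precede senescence")
  structure(
    list(peak_ndvi = peak_ndvi, greenup_doy = greenup_doy,
         senescence_doy = senescence_doy, width_up = width_up,
         width_down = width_down, base_ndvi = base_ndvi,
         blue = blue, green = green, red = red, noise_sd = noise_sd),
    class = "fm_phenology"
  )
}

#' Default phenology set for the five cover classes
#'
#' Per-class reflectance signatures are free parameters of the simulator
#' (no published per-species values exist); they are chosen to be mutually
#' separable in B2/B3/B4/B8 and to give an oak plateau NDVI near 0.9, the
#' ideal midsummer value for a healthy closed-canopy stand.
#'
#' @param noise_sd Reflectance noise sd applied to every class.
#' @return Named list of [phenology_model()]s, one per legend class.
#' @export
default_phenology <- function(noise_sd = 0.02) {
  list(
    black_locust = phenology_model(0.85, 110, 275, base_ndvi = 0.25,
                                   blue = 0.030, green = 0.055, red = 0.045,
                                   noise_sd = noise_sd),
    scots_pine = phenology_model(0.75, 95, 300, base_ndvi = 0.45,
                                 blue = 0.020, green = 0.040, red = 0.030,
                                 noise_sd = noise_sd),
    pedunculate_oak = phenology_model(0.90, 115, 285, base_ndvi = 0.25,
                                      blue = 0.030, green = 0.080, red = 0.040,
                                      noise_sd = noise_sd),
    red_oak = phenology_model(0.87, 112, 290, base_ndvi = 0.25,
                              blue = 0.045, green = 0.100, red = 0.065,
                              noise_sd = noise_sd),
    clearcut = phenology_model(0.30, 100, 290, base_ndvi = 0.12,
                               width_up = 25, width_down = 30,
                               blue = 0.080, green = 0.105, red = 0.120,
                               noise_sd = noise_sd)
  )
}

#' Noiseless NDVI of a phenology curve at given days of year
#'
#' @param model An [phenology_model()].
#' @param doy Numeric vector of days of year.
#' @return NDVI values in (-1, 1).
#' @export
phenology_ndvi <- function(model, doy) {
  up <- stats::plogis((doy - model$greenup_doy) / model$width_up)
  down <- stats::plogis((doy - model$senescence_doy) / model$width_down)
  model$base_ndvi + (model$peak_ndvi - model$base_ndvi) * (up - down)
}

# Noiseless band reflectances for one class at one date. NIR is solved from
# the target NDVI v with the red signature r: nir = r (1 + v) / (1 - v).
phenology_reflectance <- function(model, doy) {
  v <- phenology_ndvi(model, doy)
  v <- pmin(v, 0.995)
  nir <- model$red * (1 + v) / (1 - v)
  c(B2 = model$blue, B3 = model$green, B4 = model$red, B8 = nir)
}
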