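# Carbon-side fluxes: isotope-mass-balance organic burial, O2-dependent
# carbon fractionation, climate-fed silicate/carbonate weathering,
# oxidative organic weathering, and degassing.

#' Carbonate-organic carbon isotope fractionation
#'
#' Linear oxygen dependence around the present:
#' `Delta = delta0 + J * (O2mr - 1)`. Higher atmospheric O2 widens the
#' fractionation, so less organic burial is needed to satisfy a given
#' isotopic demand — a stabilizing feedback whose strength is set by `J`.
#'
#' @param o2mr Normalized ocean-atmosphere O2 (present = 1); must be > 0.
#' @param J Feedback strength (default 4).
#' @param delta0 Present-day fractionation, permil (default 25).
#' @return Fractionation in permil. A non-positive result signals model
#'   failure and raises an error.
#' @export
#' @examples
#' carbon_fractionation(1.5, J = 4, delta0 = 25)  # 27
carbon_fractionation <- function(o2mr, J = 4, delta0 = 25) {
  if (any(o2mr <= 0)) stop("o2mr must be positive")
  frac <- delta0 + J * (o2mr - 1)
  if (any(frac <= 0))
    stop("carbon isotope fractionation fell to ", min(frac),
         " permil (<= 0): model-failure condition")
  frac
}

#' Organic carbon burial from isotope mass balance
#'
#' Inverts the delta13C budget of the ocean-atmosphere carbon reservoir for
#' the organic burial flux: with input fluxes `flux_in` at compositions
#' `delta_in`, a driving record value `rec_value` and forward-time slope
#' `rec_slope`, and carbonate buried at the seawater composition,
#'
#' `F_bg = (M * rec_slope - sum(flux_in * (delta_in - rec_value))) / frac`.
#'
#' A demand for negative burial (possible under strongly negative record
#' values) is unphysical and is clipped to zero with a warning; clipping is
#' surfaced in the run's health flags.
#'
#' @param oa_c Ocean-atmosphere carbon mass (reservoir-size term `M`).
#' @param rec_value Record delta13C at t, permil.
#' @param rec_slope d(delta13C)/dt in permil/Myr (forward time).
#' @param flux_in Vector of carbon input fluxes (weathering + degassing).
#' @param delta_in Vector of their delta13C compositions, permil.
#' @param frac Fractionation from [carbon_fractionation()], permil; > 0.
#' @param warn Emit a warning when clipping (default TRUE).
#' @return List with `F_bg` (mol/Myr, >= 0) and `clipped` (logical).
#' @export
organic_burial_imb <- function(oa_c, rec_value, rec_slope, flux_in, delta_in,
                               frac, warn = TRUE) {
  if (frac <= 0) stop("fractionation must be positive")
  if (length(flux_in) != length(delta_in))
    stop("flux_in and delta_in must have equal length")
  if (sum(flux_in) <= 0) stop("total carbon input flux must be positive")
  fbg <- (oa_c * rec_slope - sum(flux_in * (delta_in - rec_value))) / frac
  clipped <- fbg < 0
  if (clipped) {
    if (warn) warning("isotope mass balance demanded negative organic burial (",
                      signif(fbg, 4), "); clipped to 0", call. = FALSE)
    fbg <- 0
  }
  list(F_bg = fbg, clipped = clipped)
}

# Climate-driven weathering multipliers (GEOCARB-family forms).
# Temperature offset from present: dT = gcm * ln(RCO2) + GEOG.
# silicate:  exp(act*dT) * (1 + runoff_T*dT)^0.65 * (2 RCO2/(1+RCO2))^fert
# carbonate: 1 + act_carb*dT
# Both equal 1 at present (RCO2 = 1, GEOG = 0), are smooth, and increase
# with RCO2.

#' Climate-weathering feedback multiplier
#'
#' @param rco2 Atmospheric CO2 normalized to present (> 0).
#' @param geog Additive paleogeographic temperature offset, K.
#' @param cfg A [model_config()].
#' @param type "silicate" or "carbonate".
#' @return Dimensionless multiplier, 1 at present.
#' @export
climate_weathering_multiplier <- function(rco2, geog = 0, cfg = model_config(),
                                          type = c("silicate", "carbonate")) {
  type <- match.arg(type)
  if (any(rco2 <= 0)) stop("rco2 must be positive")
  dT <- cfg$gcm * log(rco2) + geog
  if (type == "silicate") {
    run <- pmax(1 + cfg$runoff_T * dT, 0)
    exp(cfg$act * dT) * run^0.65 * (2 * rco2 / (1 + rco2))^cfg$fert
  } else {
    pmax(1 + cfg$act_carb * dT, 0)
  }
}

#' Silicate weathering flux
#'
#' `F_ws = F_ws_0 * fAW * fA^0.5 * fD^0.65 * plant * climate(RCO2, GEOG)`,
#' normalized so that all-present inputs return exactly `F_ws_0`.
#'
#' @param rco2 Normalized CO2 (> 0).
#' @param f Named list of forcings at t (from [forcing_at()]).
#' @param cfg A [model_config()].
#' @return Flux in 1e18 mol/Myr.
#' @export
silicate_weathering_flux <- function(rco2, f, cfg = model_config()) {
  if (any(unlist(f[c("fA", "fD", "fAW", "plant")]) <= 0))
    stop("forcings must be positive")
  cfg$F_ws_0 * f$fAW * f$fA^0.5 * f$fD^0.65 * f$plant *
    climate_weathering_multiplier(rco2, f$GEOG, cfg, "silicate")
}

#' Carbonate weathering fluxes (young and ancient)
#'
#' Young: `F_wc_y_0 * fL * fA * fD * climate_carb * Ccarb_y/Ccarb_y_0`.
#' Ancient: rate constant times the ancient reservoir mass times the
#' erosion forcing `fA * fD` (no climate term), i.e.
#' `(F_wc_a_0 / Ccarb_a_0) * Ccarb_a * fA * fD`.
#'
#' @param ccarb_y,ccarb_a Young/ancient crustal carbonate masses.
#' @param rco2 Normalized CO2.
#' @param f Forcings at t.
#' @param cfg A [model_config()].
#' @return List `F_wc_y`, `F_wc_a`.
#' @export
carbonate_weathering_flux <- function(ccarb_y, ccarb_a, rco2, f,
                                      cfg = model_config()) {
  if (ccarb_y < 0 || ccarb_a < 0) stop("reservoirs must be non-negative")
  list(
    F_wc_y = cfg$F_wc_y_0 * f$fL * f$fA * f$fD *
      climate_weathering_multiplier(rco2, f$GEOG, cfg, "carbonate") *
      ccarb_y / cfg$Ccarb_y_0,
    F_wc_a = (cfg$F_wc_a_0 / cfg$Ccarb_a_0) * ccarb_a * f$fA * f$fD
  )
}

#' Organic carbon weathering fluxes with oxidative feedback
#'
#' Each flux is rate constant x normalized reservoir mass x erosion forcing
#' `fA * fD` x `O2mr^beta_ox`; the power-law O2 dependence mirrors the
#' young-pyrite weathering law.
#'
#' @param corg_y,corg_a Young/ancient crustal organic carbon masses.
#' @param o2mr Normalized O2 (>= 0).
#' @param f Forcings at t.
#' @param cfg A [model_config()].
#' @return List `F_wg_y`, `F_wg_a`.
#' @export
organic_weathering_flux <- function(corg_y, corg_a, o2mr, f,
                                    cfg = model_config()) {
  if (o2mr < 0) stop("o2mr must be non-negative")
  ox <- o2mr^cfg$beta_ox
  ero <- f$fA * f$fD
  list(
    F_wg_y = cfg$F_wg_y_0 * (corg_y / cfg$Corg_y_0) * ero * ox,
    F_wg_a = (cfg$F_wg_a_0 / cfg$Corg_a_0) * corg_a * ero * ox
  )
}

#' Degassing flux of a crustal reservoir
#'
#' Linear in reservoir mass and spreading rate:
#' `k_degas * mass * fSR * platform_mult`, where the platform multiplier
#' applies only to carbonate reservoirs (deep-ocean carbonate is the
#' readily recycled fraction): `(1 - cpf) / (1 - cpf0)`.
#'
#' @param mass Reservoir mass (>= 0).
#' @param k_degas Rate constant, 1/Myr.
#' @param fsr Normalized seafloor spreading rate (>= 0).
#' @param carb_platform Current platform fraction, or NULL for
#'   non-carbonate reservoirs.
#' @param carb_platform_0 Present-day platform fraction (default 0.5).
#' @return Flux (same units as `mass` per Myr).
#' @export
degassing_flux <- function(mass, k_degas, fsr, carb_platform = NULL,
                           carb_platform_0 = 0.5) {
  if (mass < 0 || k_degas < 0 || fsr < 0) stop("inputs must be non-negative")
  w <- if (is.null(carb_platform)) 1
       else (1 - carb_platform) / (1 - carb_platform_0)
  k_degas * mass * fsr * w
}
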