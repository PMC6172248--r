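# Forward (process-based) sulphur cycle: pyrite and gypsum weathering and
# burial computed from model state rather than by inverting the delta34S
# record, plus the legacy isotope-inverted scheme as a diagnostic.
#
# Young weathering follows the silicate/carbonate weathering channels
# (most pyrite weathers with silicates, most gypsum with carbonates);
# pyrite burial scales with ocean sulphate, organic-matter supply and
# inverse normalized O2; gypsum burial with sulphate and the normalized
# calcium reservoir.

#' Young pyrite weathering
#'
#' `F_wp_y = (F_ws/F_ws_0) * new_kwp * (Pyr_y/Pyr_0) * O2mr^0.5`
#'
#' @param fws_ratio Silicate weathering flux relative to present.
#' @param pyr_y_ratio Young pyrite mass relative to its present value.
#' @param o2mr Normalized O2.
#' @param new_kwp Present-day young pyrite weathering flux
#'   (1e18 mol/Myr; the rate constant of the law).
#' @return Flux in 1e18 mol/Myr.
#' @export
#' @examples
#' young_pyrite_weathering(1, 1, 0.25, new_kwp = 0.6)  # half the anchor
young_pyrite_weathering <- function(fws_ratio, pyr_y_ratio, o2mr,
                                    new_kwp = 0.6) {
  if (any(c(fws_ratio, pyr_y_ratio, o2mr) < 0))
    stop("inputs must be non-negative")
  fws_ratio * new_kwp * pyr_y_ratio * sqrt(o2mr)
}

#' Young gypsum weathering
#'
#' `F_wgyp_y = (F_wc_y/F_wc_y_0) * new_kwgyp * (Gyp_y/Gyp_0)`
#'
#' @param fwc_y_ratio Young carbonate weathering flux relative to present.
#' @param gyp_y_ratio Young gypsum mass relative to its present value.
#' @param new_kwgyp Present-day young gypsum weathering flux.
#' @return Flux in 1e18 mol/Myr.
#' @export
young_gypsum_weathering <- function(fwc_y_ratio, gyp_y_ratio,
                                    new_kwgyp = 0.6) {
  if (any(c(fwc_y_ratio, gyp_y_ratio) < 0))
    stop("inputs must be non-negative")
  fwc_y_ratio * new_kwgyp * gyp_y_ratio
}

#' Forward pyrite burial
#'
#' `F_bp = k_bp * (OA_S/OA_S_0) * (F_bg/F_bg_0) * (1/O2mr)`
#'
#' Burial increases with ocean sulphate and the supply of organic matter to
#' sediments, and decreases with dissolved oxygen — an oxygen-dependent
#' feedback that needs no isotope fractionation term. The `1/O2mr`
#' singularity is guarded by a configurable floor.
#'
#' @param oas_ratio Ocean sulphate relative to present.
#' @param fbg_ratio Organic burial flux relative to present.
#' @param o2mr Normalized O2 (> 0 after flooring).
#' @param k_bp Present-day pyrite burial flux (1e18 mol/Myr).
#' @param o2mr_floor Floor applied to `o2mr` (default 1e-3).
#' @return Flux in 1e18 mol/Myr.
#' @export
#' @examples
#' pyrite_burial(1, 1, 0.5, k_bp = 1)  # 2: halving O2 doubles burial
pyrite_burial <- function(oas_ratio, fbg_ratio, o2mr, k_bp = 1,
                          o2mr_floor = 1e-3) {
  if (any(c(oas_ratio, fbg_ratio) < 0)) stop("inputs must be non-negative")
  if (o2mr <= 0) stop("o2mr must be positive (floor is ", o2mr_floor, ")")
  k_bp * oas_ratio * fbg_ratio / max(o2mr, o2mr_floor)
}

#' Gypsum burial
#'
#' `F_bgyp = k_bgyp * (OA_S/OA_S_0) * Calc`, with `Calc` the normalized
#' (dimensionless) seawater calcium reservoir.
#'
#' @param oas_ratio Ocean sulphate relative to present.
#' @param calc Normalized calcium reservoir.
#' @param k_bgyp Present-day gypsum burial flux (1e18 mol/Myr).
#' @return Flux in 1e18 mol/Myr.
#' @export
gypsum_burial <- function(oas_ratio, calc, k_bgyp = 1) {
  if (any(c(oas_ratio, calc) < 0)) stop("inputs must be non-negative")
  k_bgyp * oas_ratio * calc
}

#' Ancient sulphur weathering
#'
#' Ancient fluxes are rate constant x normalized reservoir mass x erosion
#' forcing, with an oxidative `O2mr^0.5` feedback on ancient pyrite only
#' (gypsum is already oxidized):
#' `F_wp_a = F_wp_a_0 * (Pyr_a/Pyr_a_0) * erosion * O2mr^0.5`;
#' `F_wgyp_a = F_wgyp_a_0 * (Gyp_a/Gyp_a_0) * erosion`.
#'
#' @param pyr_a,gyp_a Ancient pyrite/gypsum masses (1e18 mol).
#' @param erosion Erosion forcing (`fA * fD` at t).
#' @param o2mr Normalized O2 (>= 0).
#' @param cfg A [model_config()].
#' @return List `F_wp_a`, `F_wgyp_a`.
#' @export
ancient_sulphur_weathering <- function(pyr_a, gyp_a, erosion, o2mr,
                                       cfg = model_config()) {
  if (any(c(pyr_a, gyp_a, erosion, o2mr) < 0))
    stop("inputs must be non-negative")
  list(
    F_wp_a = cfg$F_wp_a_0 * (pyr_a / cfg$Pyr_a_0) * erosion * sqrt(o2mr),
    F_wgyp_a = cfg$F_wgyp_a_0 * (gyp_a / cfg$Gyp_a_0) * erosion
  )
}

#' Sulphur degassing and young-to-ancient transfer
#'
#' Degassing of each crustal sulphur reservoir is linear in its mass and
#' the spreading rate; degassed sulphur returns to the ocean sulphate pool
#' (oxidized on emission, with the matching O2 cost charged in the oxygen
#' budget for pyrite sulphur). The young-to-ancient transfer of each pool
#' is linear in the young mass and independent of forcings.
#'
#' @param pyr_y,pyr_a,gyp_y,gyp_a Sulphur reservoir masses (1e18 mol).
#' @param fsr Normalized spreading rate (>= 0).
#' @param cfg A [model_config()].
#' @return List `F_deg_p`, `F_deg_gyp` (ancient degassing), `F_deg_p_y`,
#'   `F_deg_gyp_y` (young degassing, 0 under defaults), `F_ya_p`,
#'   `F_ya_gyp` (transfers).
#' @export
sulphur_degassing_and_transfer <- function(pyr_y, pyr_a, gyp_y, gyp_a, fsr,
                                           cfg = model_config()) {
  if (any(c(pyr_y, pyr_a, gyp_y, gyp_a, fsr) < 0))
    stop("inputs must be non-negative")
  list(
    F_deg_p = (cfg$F_deg_p_0 / cfg$Pyr_a_0) * pyr_a * fsr,
    F_deg_gyp = (cfg$F_deg_gyp_0 / cfg$Gyp_a_0) * gyp_a * fsr,
    F_deg_p_y = cfg$k_deg_p_y * pyr_y * fsr,
    F_deg_gyp_y = cfg$k_deg_gyp_y * gyp_y * fsr,
    F_ya_p = (cfg$F_ya_p_0 / cfg$Pyr_y_0) * pyr_y,
    F_ya_gyp = (cfg$F_ya_gyp_0 / cfg$Gyp_y_0) * gyp_y
  )
}

#' Sulphur isotope rates of change
#'
#' The delta34S budget used to produce the synthetic sulphate record:
#' pyrite is buried at `delta_sulphate - alpha_s_forward`, gypsum at the
#' sulphate composition; weathering and degassing return each crustal
#' reservoir's own composition; crustal compositions evolve by
#' mass-weighted mixing of their burial/transfer inputs. The fractionation
#' is a constant — it is never inverted to compute fluxes.
#'
#' @param state Named state vector (see [initialize_state()]).
#' @param fluxes Named list of sulphur fluxes (as assembled by
#'   [model_derivatives()]).
#' @param alpha_s Burial fractionation, permil (default 35).
#' @return Named list of d(delta)/dt (permil/Myr) for `d_OA_S`, `d_Pyr_y`,
#'   `d_Pyr_a`, `d_Gyp_y`, `d_Gyp_a`.
#' @export
delta34s_rates <- function(state, fluxes, alpha_s = 35) {
  s <- as.list(state); fx <- fluxes
  if (s$OA_S <= 0) stop("ocean sulphate exhausted: isotope budget undefined")
  d <- s$d_OA_S
  dd_oas <- (fx$F_wp_y * (s$d_Pyr_y - d) +
             fx$F_wp_a * (s$d_Pyr_a - d) +
             fx$F_wgyp_y * (s$d_Gyp_y - d) +
             fx$F_wgyp_a * (s$d_Gyp_a - d) +
             fx$F_deg_p * (s$d_Pyr_a - d) +
             fx$F_deg_gyp * (s$d_Gyp_a - d) +
             (fx$F_deg_p_y %||% 0) * (s$d_Pyr_y - d) +
             (fx$F_deg_gyp_y %||% 0) * (s$d_Gyp_y - d) +
             fx$F_bp * alpha_s) / s$OA_S
  list(
    d_OA_S = dd_oas,
    d_Pyr_y = if (s$Pyr_y > 0)
      fx$F_bp * ((d - alpha_s) - s$d_Pyr_y) / s$Pyr_y else 0,
    d_Pyr_a = if (s$Pyr_a > 0)
      fx$F_ya_p * (s$d_Pyr_y - s$d_Pyr_a) / s$Pyr_a else 0,
    d_Gyp_y = if (s$Gyp_y > 0)
      fx$F_bgyp * (d - s$d_Gyp_y) / s$Gyp_y else 0,
    d_Gyp_a = if (s$Gyp_a > 0)
      fx$F_ya_gyp * (s$d_Gyp_y - s$d_Gyp_a) / s$Gyp_a else 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Legacy oxygen-dependent sulphur fractionation (diagnostic)
#'
#' The isotope-inverted scheme's power law,
#' `alpha_s = delta_s0 * O2mr^n`, which shrinks the fractionation as O2
#' falls — the pathology the forward scheme removes.
#'
#' @param o2mr Normalized O2 (>= 0).
#' @param delta_s0 Present-day fractionation, permil (default 35).
#' @param n Power-law exponent (default 1.5).
#' @return Fractionation in permil.
#' @export
#' @examples
#' legacy_alpha_s(0.25, 35, 1.5)  # 4.375
legacy_alpha_s <- function(o2mr, delta_s0 = 35, n = 1.5) {
  if (any(o2mr < 0)) stop("o2mr must be non-negative")
  delta_s0 * o2mr^n
}

#' Legacy isotope-mass-balance pyrite burial (diagnostic)
#'
#' Inverts the delta34S budget of ocean sulphate for pyrite burial, the
#' structural mirror of [organic_burial_imb()] with the legacy
#' fractionation in the denominator:
#' `F_bp = (OA_S * rec_slope - sum(flux_in * (delta_in - rec_value))) / alpha_s`.
#' As `alpha_s -> 0` the demanded burial diverges — the documented failure
#' mode of inverting the record at low O2.
#'
#' @param alpha_s Fractionation, permil (> 0).
#' @param flux_in Sulphate input fluxes.
#' @param delta_in Their delta34S compositions, permil.
#' @param rec_value Record delta34S, permil.
#' @param rec_slope d(delta34S)/dt, permil/Myr.
#' @param oa_s Ocean sulphate mass.
#' @return Pyrite burial flux (clipped at 0).
#' @export
legacy_pyrite_burial_imb <- function(alpha_s, flux_in, delta_in, rec_value,
                                     rec_slope = 0, oa_s = 38) {
  if (alpha_s <= 0) stop("alpha_s must be positive")
  fbp <- (oa_s * rec_slope - sum(flux_in * (delta_in - rec_value))) / alpha_s
  max(fbp, 0)
}
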