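# Model configuration: rate constants, present-day fluxes and reservoir
# masses, initial apportionment of sulphur, fractionation parameters and
# solver controls.
#
# Internal units: reservoir masses in 1e18 mol, fluxes in 1e18 mol/Myr,
# time in Myr, isotope compositions in permil. The present-day fluxes
# below close every reservoir budget exactly, so the present-day state is
# an exact steady state of the assembled derivative field (the model's
# normalization anchor).

#' Default model configuration
#'
#' Returns the full parameter set of the coupled carbon-sulphur-oxygen box
#' model. All masses are in units of 1e18 mol and fluxes in 1e18 mol/Myr.
#' Present-day fluxes are chosen so that every reservoir budget closes at
#' the anchor state (all forcings 1, RCO2 = 1, O2mr = 1), making the anchor
#' an exact fixed point.
#'
#' Key parameters:
#' \describe{
#'   \item{J}{Strength of the oxygen dependence of carbon isotope
#'     fractionation (dimensionless; default 4; sensitivity range 2.5-7.5).}
#'   \item{delta0_frac}{Present-day carbonate-organic carbon fractionation,
#'     permil (default 25).}
#'   \item{beta_ox}{Exponent of the O2mr oxidative-weathering feedback on
#'     organic carbon and ancient pyrite (default 0.5, matching the young
#'     pyrite weathering law).}
#'   \item{alpha_s_forward}{Constant sulphate-pyrite burial fractionation,
#'     permil (default 35), used only for the synthetic delta34S output.}
#'   \item{legacy_delta_s0, legacy_n}{Legacy isotope-inverted scheme:
#'     fractionation at present (35 permil) and its O2mr power-law exponent
#'     (1.5). Diagnostic only.}
#'   \item{sulphur_init}{"revised" (total S 418e18 mol; pyrite 280, gypsum
#'     100, ocean 38) or "legacy" (total 638e18; pyrite = gypsum = 300).}
#' }
#'
#' @param ... Named overrides of any default element.
#' @return An object of class `phanox_config` (a named list).
#' @export
#' @examples
#' cfg <- model_config(J = 5)
#' steady_delta13c(cfg)
model_config <- function(...) {
  cfg <- list(
    ## carbon reservoirs (1e18 mol) and their present delta13C (permil)
    OA_C_0   = 3.8,   d_OA_C_0   = NA,   # set to steady value below
    Corg_y_0 = 250,   d_Corg_y_0 = -24,
    Corg_a_0 = 1000,  d_Corg_a_0 = -24,
    Ccarb_y_0 = 1000, d_Ccarb_y_0 = 1,
    Ccarb_a_0 = 4000, d_Ccarb_a_0 = 1,
    ## present carbon fluxes (1e18 mol/Myr); each budget closes exactly
    F_bg_0   = 5,     # organic burial
    F_bc_0   = 20,    # carbonate burial
    F_ws_0   = 6,     # silicate weathering (CO2 sink channel)
    F_wg_y_0 = 3,   F_wg_a_0 = 1.5,   # organic weathering young/ancient
    F_wc_y_0 = 12,  F_wc_a_0 = 6,     # carbonate weathering young/ancient
    F_deg_g_0 = 0.5, F_deg_c_0 = 2,   # ancient degassing (org C, carbonate)
    F_ya_g_0 = 2,   F_ya_c_0 = 8,     # young -> ancient transfer
    k_deg_g_y = 0,  k_deg_c_y = 0,    # young degassing off by default
    ## oxygen
    O2_0 = 38,
    o2mr_floor = 1e-3,
    ## carbon fractionation
    delta0_frac = 25, J = 4, beta_ox = 0.5,
    ## climate-weathering feedback
    gcm = 4.33,        # K per ln(RCO2)
    act = 0.09,        # silicate activation response, 1/K
    runoff_T = 0.045,  # runoff response, 1/K
    fert = 0.4,        # CO2 fertilization exponent
    act_carb = 0.087,  # carbonate dissolution response, 1/K
    carb_platform_0 = 0.5,
    carbonate_closure = "restoring",  # or "exact"
    ## sulphur reservoirs: initial apportionment
    sulphur_init = "revised",
    total_S = 418, OA_S_init = 38,
    Pyr_total_init = 280, Gyp_total_init = 100,
    young_fraction_pyr = 0.5, young_fraction_gyp = 0.5,
    ## present-day sulphur reference masses (1e18 mol) for normalization
    OA_S_0 = 38, Pyr_y_0 = 140, Pyr_a_0 = 140, Gyp_y_0 = 50, Gyp_a_0 = 50,
    d_OA_S_0 = 21, d_Pyr_0 = -14, d_Gyp_0 = 21,
    ## present sulphur fluxes (1e18 mol/Myr)
    F_bp_0 = 1, F_bgyp_0 = 1,
    new_kwp = 0.6, new_kwgyp = 0.6,         # young weathering at anchor
    F_wp_a_0 = 0.3, F_wgyp_a_0 = 0.3,       # ancient weathering at anchor
    F_deg_p_0 = 0.1, F_deg_gyp_0 = 0.1,     # ancient degassing at anchor
    F_ya_p_0 = 0.4, F_ya_gyp_0 = 0.4,       # young -> ancient transfer
    k_deg_p_y = 0, k_deg_gyp_y = 0,
    alpha_s_forward = 35,
    legacy_delta_s0 = 35, legacy_n = 1.5,
    ## integration
    start_age = 570, report_step = 1,
    rtol = 1e-8, atol = 1e-8, method = "lsodar",
    smooth_spline = FALSE  # optional second-pass record smoothing
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  if (identical(cfg$sulphur_init, "legacy") &&
      !("total_S" %in% names(over))) {
    cfg$total_S <- 638; cfg$Pyr_total_init <- 300; cfg$Gyp_total_init <- 300
  }
  if (is.na(cfg$d_OA_C_0)) cfg$d_OA_C_0 <- steady_delta13c_raw(cfg)
  class(cfg) <- "phanox_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  pos <- c("OA_C_0", "Corg_y_0", "Corg_a_0", "Ccarb_y_0", "Ccarb_a_0",
           "F_bg_0", "F_bc_0", "F_ws_0", "F_wg_y_0", "F_wg_a_0",
           "F_wc_y_0", "F_wc_a_0", "O2_0", "delta0_frac",
           "total_S", "OA_S_init", "Pyr_total_init", "Gyp_total_init",
           "OA_S_0", "Pyr_y_0", "Pyr_a_0", "Gyp_y_0", "Gyp_a_0",
           "F_bp_0", "F_bgyp_0", "new_kwp", "new_kwgyp",
           "alpha_s_forward", "legacy_delta_s0", "legacy_n",
           "start_age", "rtol", "atol")
  for (nm in pos)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("config entry ", nm, " must be a positive number")
  if (abs(cfg$OA_S_init + cfg$Pyr_total_init + cfg$Gyp_total_init -
          cfg$total_S) > 1e-9 * cfg$total_S)
    stop("sulphur apportionment does not sum to total_S (",
         cfg$OA_S_init, " + ", cfg$Pyr_total_init, " + ",
         cfg$Gyp_total_init, " != ", cfg$total_S, ")")
  for (nm in c("young_fraction_pyr", "young_fraction_gyp"))
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop(nm, " must lie in [0, 1]")
  if (!cfg$carbonate_closure %in% c("restoring", "exact"))
    stop("carbonate_closure must be 'restoring' or 'exact'")
  invisible(cfg)
}

# Steady-state seawater delta13C implied by the configured present fluxes:
# the value at which isotope mass balance returns exactly F_bg_0 with zero
# record slope. delta_ss = (sum Fi * di + F_bg_0 * delta0) / sum Fi.
steady_delta13c_raw <- function(cfg) {
  fl <- c(cfg$F_wg_y_0, cfg$F_wg_a_0, cfg$F_wc_y_0, cfg$F_wc_a_0,
          cfg$F_deg_g_0, cfg$F_deg_c_0)
  dl <- c(cfg$d_Corg_y_0, cfg$d_Corg_a_0, cfg$d_Ccarb_y_0, cfg$d_Ccarb_a_0,
          cfg$d_Corg_a_0, cfg$d_Ccarb_a_0)
  (sum(fl * dl) + cfg$F_bg_0 * cfg$delta0_frac) / sum(fl)
}

#' Steady-state delta13C of the ocean-atmosphere carbon reservoir
#'
#' The record value at which isotope mass balance, with the configured
#' present input fluxes and compositions and zero record slope, returns
#' exactly the configured present organic burial flux. The steady synthetic
#' fixture pins its record to this value so the model holds the anchor.
#'
#' @param cfg A [model_config()].
#' @return Per-mil value.
#' @export
steady_delta13c <- function(cfg = model_config()) {
  stopifnot(inherits(cfg, "phanox_config"))
  steady_delta13c_raw(cfg)
}

# state vector layout (names are load-bearing: used by the ODE rhs)
.state_names <- c("OA_C", "Corg_y", "Corg_a", "Ccarb_y", "Ccarb_a",
                  "d_OA_C", "d_Corg_y", "d_Corg_a", "d_Ccarb_y", "d_Ccarb_a",
                  "OA_S", "Pyr_y", "Pyr_a", "Gyp_y", "Gyp_a",
                  "d_OA_S", "d_Pyr_y", "d_Pyr_a", "d_Gyp_y", "d_Gyp_a",
                  "O2")

#' Initial reservoir state at the start age
#'
#' Carbon reservoirs and their isotope compositions start at the configured
#' present-day (near-steady) values; the delta13C of the ocean-atmosphere
#' reservoir starts at the record value at the start age. Sulphur is
#' apportioned per the configured initialization: under the revised scheme
#' total S is 418e18 mol (ocean 38, pyrite 280, gypsum 100; pyrite:gypsum
#' 2.8), under the legacy scheme 638e18 mol with pyrite = gypsum = 300e18.
#' The young/ancient split of each crustal sulphur pool is set by
#' `young_fraction_pyr` / `young_fraction_gyp`.
#'
#' @param cfg A [model_config()].
#' @param record Optional [isotope_record()]; if supplied, the starting
#'   delta13C of the ocean-atmosphere pool is the record value at
#'   `cfg$start_age`.
#' @return Named numeric state vector (masses in 1e18 mol, deltas permil).
#' @export
initialize_state <- function(cfg, record = NULL) {
  stopifnot(inherits(cfg, "phanox_config"))
  d13 <- if (!is.null(record)) record_at(record, cfg$start_age) else cfg$d_OA_C_0
  st <- c(
    OA_C = cfg$OA_C_0,
    Corg_y = cfg$Corg_y_0, Corg_a = cfg$Corg_a_0,
    Ccarb_y = cfg$Ccarb_y_0, Ccarb_a = cfg$Ccarb_a_0,
    d_OA_C = d13,
    d_Corg_y = cfg$d_Corg_y_0, d_Corg_a = cfg$d_Corg_a_0,
    d_Ccarb_y = cfg$d_Ccarb_y_0, d_Ccarb_a = cfg$d_Ccarb_a_0,
    OA_S = cfg$OA_S_init,
    Pyr_y = cfg$Pyr_total_init * cfg$young_fraction_pyr,
    Pyr_a = cfg$Pyr_total_init * (1 - cfg$young_fraction_pyr),
    Gyp_y = cfg$Gyp_total_init * cfg$young_fraction_gyp,
    Gyp_a = cfg$Gyp_total_init * (1 - cfg$young_fraction_gyp),
    d_OA_S = cfg$d_OA_S_0,
    d_Pyr_y = cfg$d_Pyr_0, d_Pyr_a = cfg$d_Pyr_0,
    d_Gyp_y = cfg$d_Gyp_0, d_Gyp_a = cfg$d_Gyp_0,
    O2 = cfg$O2_0
  )
  st[.state_names]
}

#' @export
print.phanox_config <- function(x, ...) {
  cat("<phanox_config>\n")
  cat("  sulphur_init:", x$sulphur_init,
      sprintf("(total S %g, pyrite %g, gypsum %g, ocean %g; x1e18 mol)\n",
              x$total_S, x$Pyr_total_init, x$Gyp_total_init, x$OA_S_init))
  cat(sprintf("  J = %g, delta0 = %g permil, beta_ox = %g, alpha_s(fwd) = %g permil\n",
              x$J, x$delta0_frac, x$beta_ox, x$alpha_s_forward))
  cat(sprintf("  start %g Ma, solver %s (rtol %g, atol %g)\n",
              x$start_age, x$method, x$rtol, x$atol))
  invisible(x)
}

#' Write / read a configuration as YAML
#'
#' @param cfg A [model_config()].
#' @param path File path.
#' @return `config_to_yaml` returns `path` invisibly; `config_from_yaml`
#'   returns a [model_config()].
#' @export
config_to_yaml <- function(cfg, path) {
  stopifnot(inherits(cfg, "phanox_config"))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for YAML config I/O")
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname config_to_yaml
#' @export
config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for YAML config I/O")
  vals <- yaml::read_yaml(path)
  do.call(model_config, vals)
}
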