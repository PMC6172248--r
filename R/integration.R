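# Assembly of the full derivative field and stiff integration from the
# start age to the present.
#
# Internal time variable: Myr forward from the start age (t = 0 at
# start_age Ma, t = start_age at 0 Ma). All user-facing I/O is in Ma.

#' Atmospheric O2 as percent of the atmosphere
#'
#' Converts the normalized ocean-atmosphere O2 inventory to an atmospheric
#' mixing ratio assuming a fixed non-O2 inventory:
#' `%atm = 100 * O2mr / (O2mr + 79/21)`. The present (O2mr = 1) maps to
#' 21%.
#'
#' @param o2mr Normalized O2 (> 0).
#' @return Percent of atmosphere.
#' @export
#' @examples
#' o2_percent_atm(1)    # 21
#' o2_percent_atm(0.5)  # about 11.7
o2_percent_atm <- function(o2mr) {
  if (any(o2mr <= 0)) stop("o2mr must be positive")
  100 * o2mr / (o2mr + 79 / 21)
}

#' @rdname o2_percent_atm
#' @param pct Percent of atmosphere (0 < pct < 100).
#' @export
o2mr_from_percent <- function(pct) {
  if (any(pct <= 0 | pct >= 100)) stop("pct must lie in (0, 100)")
  (pct / 100) * (79 / 21) / (1 - pct / 100)
}

# Assemble every flux and derivative at one instant. `ffuns`/`recfun` are
# prebuilt interpolators; `health` is an optional environment collecting
# clip/floor counts during integration.
assemble_rates <- function(age, state, cfg, ffuns, recfun, recspan,
                           health = NULL, warn = FALSE) {
  s <- as.list(state)
  f <- lapply(ffuns, function(fn) fn(age))

  o2mr_raw <- s$O2 / cfg$O2_0
  o2mr <- max(o2mr_raw, cfg$o2mr_floor)
  if (!is.null(health) && o2mr_raw < cfg$o2mr_floor)
    health$n_floor <- health$n_floor + 1L
  rco2 <- max(s$OA_C / cfg$OA_C_0, 1e-6)

  ## carbon fluxes
  F_ws <- silicate_weathering_flux(rco2, f, cfg)
  wc <- carbonate_weathering_flux(s$Ccarb_y, s$Ccarb_a, rco2, f, cfg)
  wg <- organic_weathering_flux(s$Corg_y, s$Corg_a, o2mr, f, cfg)
  F_deg_g <- degassing_flux(s$Corg_a, cfg$F_deg_g_0 / cfg$Corg_a_0, f$fSR)
  F_deg_c <- degassing_flux(s$Ccarb_a, cfg$F_deg_c_0 / cfg$Ccarb_a_0, f$fSR,
                            carb_platform = f$carb_platform,
                            carb_platform_0 = cfg$carb_platform_0)
  F_ya_g <- (cfg$F_ya_g_0 / cfg$Corg_y_0) * s$Corg_y
  F_ya_c <- (cfg$F_ya_c_0 / cfg$Ccarb_y_0) * s$Ccarb_y

  flux_in <- c(wg$F_wg_y, wg$F_wg_a, wc$F_wc_y, wc$F_wc_a, F_deg_g, F_deg_c)
  delta_in <- c(s$d_Corg_y, s$d_Corg_a, s$d_Ccarb_y, s$d_Ccarb_a,
                s$d_Corg_a, s$d_Ccarb_a)

  rec_value <- recfun(min(max(age, recspan[1]), recspan[2]))
  rec_slope <- record_slope_at(recfun, age, recspan)
  frac <- carbon_fractionation(o2mr, cfg$J, cfg$delta0_frac)
  imb <- organic_burial_imb(s$OA_C, rec_value, rec_slope, flux_in, delta_in,
                            frac, warn = warn)
  F_bg <- imb$F_bg
  if (!is.null(health) && imb$clipped)
    health$n_clip_fbg <- health$n_clip_fbg + 1L
  F_bc <- if (cfg$carbonate_closure == "exact")
    max(sum(flux_in) - F_bg, 0)
  else cfg$F_bc_0 * (s$OA_C / cfg$OA_C_0)

  ## sulphur fluxes (forward scheme)
  F_wp_y <- young_pyrite_weathering(F_ws / cfg$F_ws_0, s$Pyr_y / cfg$Pyr_y_0,
                                    o2mr, cfg$new_kwp)
  F_wgyp_y <- young_gypsum_weathering(wc$F_wc_y / cfg$F_wc_y_0,
                                      s$Gyp_y / cfg$Gyp_y_0, cfg$new_kwgyp)
  anc <- ancient_sulphur_weathering(s$Pyr_a, s$Gyp_a, f$fA * f$fD, o2mr, cfg)
  F_bp <- pyrite_burial(s$OA_S / cfg$OA_S_0, F_bg / cfg$F_bg_0, o2mr,
                        cfg$F_bp_0, cfg$o2mr_floor)
  F_bgyp <- gypsum_burial(s$OA_S / cfg$OA_S_0, f$calc, cfg$F_bgyp_0)
  dt <- sulphur_degassing_and_transfer(s$Pyr_y, s$Pyr_a, s$Gyp_y, s$Gyp_a,
                                       f$fSR, cfg)

  fx <- list(F_bg = F_bg, F_bc = F_bc, F_ws = F_ws,
             F_wc_y = wc$F_wc_y, F_wc_a = wc$F_wc_a,
             F_wg_y = wg$F_wg_y, F_wg_a = wg$F_wg_a,
             F_deg_g = F_deg_g, F_deg_c = F_deg_c,
             F_ya_g = F_ya_g, F_ya_c = F_ya_c,
             F_wp_y = F_wp_y, F_wp_a = anc$F_wp_a,
             F_wgyp_y = F_wgyp_y, F_wgyp_a = anc$F_wgyp_a,
             F_bp = F_bp, F_bgyp = F_bgyp,
             F_deg_p = dt$F_deg_p, F_deg_gyp = dt$F_deg_gyp,
             F_deg_p_y = dt$F_deg_p_y, F_deg_gyp_y = dt$F_deg_gyp_y,
             F_ya_p = dt$F_ya_p, F_ya_gyp = dt$F_ya_gyp)
  bad <- vapply(fx, function(v) !is.finite(v) || v < 0, logical(1))
  if (any(bad))
    stop("non-finite or negative flux assembled: ",
         paste(names(fx)[bad], collapse = ", "), " at ", age, " Ma")

  ## mass derivatives (1e18 mol / Myr); every flux moves mass between
  ## modelled reservoirs, so total C and total S are conserved exactly
  dOA_C  <- sum(flux_in) - F_bg - F_bc
  dCorg_y <- F_bg - wg$F_wg_y - F_ya_g
  dCorg_a <- F_ya_g - wg$F_wg_a - F_deg_g
  dCcarb_y <- F_bc - wc$F_wc_y - F_ya_c
  dCcarb_a <- F_ya_c - wc$F_wc_a - F_deg_c
  dOA_S <- F_wp_y + anc$F_wp_a + F_wgyp_y + anc$F_wgyp_a +
    dt$F_deg_p + dt$F_deg_gyp + dt$F_deg_p_y + dt$F_deg_gyp_y -
    F_bp - F_bgyp
  dPyr_y <- F_bp - F_wp_y - dt$F_ya_p - dt$F_deg_p_y
  dPyr_a <- dt$F_ya_p - anc$F_wp_a - dt$F_deg_p
  dGyp_y <- F_bgyp - F_wgyp_y - dt$F_ya_gyp - dt$F_deg_gyp_y
  dGyp_a <- dt$F_ya_gyp - anc$F_wgyp_a - dt$F_deg_gyp

  ## oxygen: 1 mol O2 per mol organic C, 15/8 mol O2 per mol pyrite S
  pyr_s_ox <- F_wp_y + anc$F_wp_a + dt$F_deg_p + dt$F_deg_p_y
  dO2 <- F_bg + (15 / 8) * F_bp -
    wg$F_wg_y - wg$F_wg_a - F_deg_g - (15 / 8) * pyr_s_ox

  ## isotope derivatives: inflow mixing; outflow at own composition
  dd_OA_C <- (sum(flux_in * (delta_in - s$d_OA_C)) + F_bg * frac) / s$OA_C
  dd_Corg_y <- if (s$Corg_y > 0)
    F_bg * ((s$d_OA_C - frac) - s$d_Corg_y) / s$Corg_y else 0
  dd_Corg_a <- if (s$Corg_a > 0)
    F_ya_g * (s$d_Corg_y - s$d_Corg_a) / s$Corg_a else 0
  dd_Ccarb_y <- if (s$Ccarb_y > 0)
    F_bc * (s$d_OA_C - s$d_Ccarb_y) / s$Ccarb_y else 0
  dd_Ccarb_a <- if (s$Ccarb_a > 0)
    F_ya_c * (s$d_Ccarb_y - s$d_Ccarb_a) / s$Ccarb_a else 0
  dds <- delta34s_rates(state, fx, cfg$alpha_s_forward)

  deriv <- c(OA_C = dOA_C, Corg_y = dCorg_y, Corg_a = dCorg_a,
             Ccarb_y = dCcarb_y, Ccarb_a = dCcarb_a,
             d_OA_C = dd_OA_C, d_Corg_y = dd_Corg_y, d_Corg_a = dd_Corg_a,
             d_Ccarb_y = dd_Ccarb_y, d_Ccarb_a = dd_Ccarb_a,
             OA_S = dOA_S, Pyr_y = dPyr_y, Pyr_a = dPyr_a,
             Gyp_y = dGyp_y, Gyp_a = dGyp_a,
             d_OA_S = dds$d_OA_S, d_Pyr_y = dds$d_Pyr_y,
             d_Pyr_a = dds$d_Pyr_a, d_Gyp_y = dds$d_Gyp_y,
             d_Gyp_a = dds$d_Gyp_a,
             O2 = dO2)
  list(deriv = deriv[.state_names], fluxes = fx,
       o2mr = o2mr_raw, rco2 = rco2, frac = frac,
       rec_value = rec_value, rec_slope = rec_slope)
}

#' Evaluate the assembled derivative field at one instant
#'
#' Computes every flux and the time derivative of every reservoir mass and
#' isotope composition at a given age. The derivative is with respect to
#' forward time (Myr); carbon and sulphur are each conserved by
#' construction because every flux moves mass between modelled reservoirs.
#'
#' @param state Named state vector (see [initialize_state()]).
#' @param age_ma Age in Ma.
#' @param cfg A [model_config()].
#' @param forcings A [forcing_set()] spanning `age_ma`.
#' @param record An [isotope_record()] (delta13C driver) spanning `age_ma`.
#' @return List with `deriv` (named derivative vector, per Myr of forward
#'   time), `fluxes` (named list, 1e18 mol/Myr), and diagnostics `o2mr`,
#'   `rco2`, `frac` (permil), `rec_value`, `rec_slope`.
#' @export
#' @examples
#' cfg <- model_config()
#' fx <- make_fixture("steady")
#' st <- initialize_state(cfg, fx$record)
#' rates <- model_derivatives(st, 570, cfg, fx$forcings, fx$record)
#' max(abs(rates$deriv))  # ~0 at the steady anchor
model_derivatives <- function(state, age_ma, cfg, forcings, record) {
  stopifnot(inherits(cfg, "phanox_config"), inherits(forcings, "forcing_set"),
            inherits(record, "isotope_record"))
  ffuns <- forcing_functions(forcings)
  recfun <- stats::approxfun(record$age_ma, record$delta, rule = 2)
  recspan <- range(record$age_ma)
  assemble_rates(age_ma, state[.state_names], cfg, ffuns, recfun, recspan,
                 warn = TRUE)
}

#' Integrate the model from the start age to the present
#'
#' Integrates all reservoir masses and isotope compositions with an
#' adaptive stiff-capable solver (default `lsodar`, a variable-step,
#' variable-order method with root finding; `radau`, an implicit
#' Runge-Kutta method, is also supported). Integration terminates with a
#' structured failure — never silent continuation — when normalized O2
#' reaches the configured floor or any reservoir mass reaches zero.
#'
#' @param cfg A [model_config()].
#' @param forcings A [forcing_set()] spanning `[0, start_age]`.
#' @param record An [isotope_record()] (delta13C driver) spanning the run.
#' @param report_step Output grid step in Myr (default from config, 1).
#' @param rtol,atol Solver tolerances (default from config).
#' @param method Solver method (default from config).
#' @param state0 Optional named state vector overriding
#'   [initialize_state()] (e.g. for perturbation experiments).
#' @return An object of class `phanox_run`: a list with `trajectory` (data
#'   frame with `age_ma`, `o2_pct`, `o2mr`, `rco2`, `d34s_sulphate`,
#'   `d13c_input`, all reservoirs and fluxes), `failed`, `failure`
#'   (list with `age_ma` and `reason`, or NULL), `health` (clip/floor
#'   counts), and `config`.
#' @export
run_model <- function(cfg = model_config(), forcings, record,
                      report_step = cfg$report_step,
                      rtol = cfg$rtol, atol = cfg$atol,
                      method = cfg$method, state0 = NULL) {
  stopifnot(inherits(cfg, "phanox_config"), inherits(forcings, "forcing_set"),
            inherits(record, "isotope_record"))
  span_f <- range(forcings$age_ma); span_r <- range(record$age_ma)
  if (span_f[1] > 1e-9 || span_f[2] < cfg$start_age - 1e-9)
    stop("forcings must span [0, ", cfg$start_age, "] Ma")
  if (span_r[1] > 1e-9 || span_r[2] < cfg$start_age - 1e-9)
    stop("record must span [0, ", cfg$start_age, "] Ma")

  ffuns <- forcing_functions(forcings)
  rec <- if (cfg$smooth_spline && nrow(record) > 10) {
    ss <- stats::smooth.spline(record$age_ma, record$delta)
    function(a) stats::predict(ss, a)$y
  } else stats::approxfun(record$age_ma, record$delta, rule = 2)
  recspan <- range(record$age_ma)

  health <- new.env()
  health$n_clip_fbg <- 0L; health$n_floor <- 0L

  y0 <- if (is.null(state0)) initialize_state(cfg, record)
        else state0[.state_names]
  masses <- c("OA_C", "Corg_y", "Corg_a", "Ccarb_y", "Ccarb_a",
              "OA_S", "Pyr_y", "Pyr_a", "Gyp_y", "Gyp_a")
  rhs <- function(t, y, parms) {
    age <- cfg$start_age - t
    out <- assemble_rates(age, y, cfg, ffuns, rec, recspan, health = health)
    list(out$deriv)
  }
  rootfun <- function(t, y, parms) {
    c(y[["O2"]] / cfg$O2_0 - cfg$o2mr_floor, unname(y[masses]))
  }
  times <- seq(0, cfg$start_age, by = report_step)
  if (times[length(times)] != cfg$start_age) times <- c(times, cfg$start_age)

  sol <- try(deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                          method = method, rtol = rtol, atol = atol,
                          rootfunc = rootfun, maxsteps = 100000),
             silent = TRUE)
  if (inherits(sol, "try-error"))
    return(structure(list(trajectory = NULL, failed = TRUE,
                          failure = list(age_ma = NA_real_,
                                         reason = paste("solver error:",
                                                        attr(sol, "condition")$message)),
                          health = as.list(health), config = cfg),
                     class = "phanox_run"))

  sol <- as.data.frame(sol)
  t_end <- sol$time[nrow(sol)]
  failed <- t_end < cfg$start_age - 1e-6
  failure <- NULL
  if (failed) {
    fin <- sol[nrow(sol), ]
    reason <- if (fin$O2 / cfg$O2_0 <= cfg$o2mr_floor * (1 + 1e-6))
      sprintf("O2 floor reached (pO2 ~ %.2g%% atm)",
              o2_percent_atm(max(fin$O2 / cfg$O2_0, 1e-12)))
    else {
      empty <- masses[unlist(fin[masses]) <= 1e-9]
      if (length(empty)) paste("reservoir exhausted:",
                               paste(empty, collapse = ", "))
      else "integration terminated early"
    }
    failure <- list(age_ma = cfg$start_age - t_end, reason = reason)
  }

  ## recompute fluxes and diagnostics on the output grid
  ages <- cfg$start_age - sol$time
  diag_rows <- lapply(seq_len(nrow(sol)), function(i) {
    st <- unlist(sol[i, .state_names])
    out <- assemble_rates(ages[i], st, cfg, ffuns, rec, recspan)
    c(o2mr = out$o2mr, o2_pct = o2_percent_atm(max(out$o2mr, 1e-12)),
      rco2 = out$rco2, frac13 = out$frac, d13c_input = out$rec_value,
      unlist(out$fluxes))
  })
  diag_df <- as.data.frame(do.call(rbind, diag_rows))
  traj <- cbind(data.frame(age_ma = ages), diag_df,
                sol[, .state_names, drop = FALSE])
  names(traj)[names(traj) == "d_OA_S"] <- "d34s_sulphate"
  traj <- traj[order(traj$age_ma, decreasing = TRUE), , drop = FALSE]
  rownames(traj) <- NULL

  structure(list(trajectory = traj, failed = failed, failure = failure,
                 health = list(n_clip_fbg = health$n_clip_fbg,
                               n_floor = health$n_floor),
                 config = cfg),
            class = "phanox_run")
}

#' Write a trajectory to CSV
#'
#' @param run A `phanox_run`.
#' @param path Output CSV path.
#' @export
write_trajectory <- function(run, path) {
  stopifnot(inherits(run, "phanox_run"))
  if (is.null(run$trajectory)) stop("run has no trajectory (solver error)")
  utils::write.csv(run$trajectory, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.phanox_run <- function(x, ...) {
  cat("<phanox_run>")
  if (x$failed) {
    cat(" FAILED at ", signif(x$failure$age_ma, 5), " Ma: ",
        x$failure$reason, "\n", sep = "")
  } else cat(" completed ", x$config$start_age, " -> 0 Ma\n", sep = "")
  if (!is.null(x$trajectory)) {
    o2 <- x$trajectory$o2_pct
    cat(sprintf("  pO2: %.2f%% atm at end; range [%.2f, %.2f]%%\n",
                o2[nrow(x$trajectory)], min(o2), max(o2)))
  }
  if (x$health$n_clip_fbg > 0 || x$health$n_floor > 0)
    cat("  health: ", x$health$n_clip_fbg, " burial clips, ",
        x$health$n_floor, " O2-floor evaluations\n", sep = "")
  invisible(x)
}

#' @export
summary.phanox_run <- function(object, ...) {
  tr <- object$trajectory
  cat("Coupled C-S-O2 box model run (",
      object$config$start_age, " -> 0 Ma)\n", sep = "")
  if (object$failed)
    cat("Structured failure at ", signif(object$failure$age_ma, 5), " Ma: ",
        object$failure$reason, "\n", sep = "")
  if (!is.null(tr)) {
    show <- c("o2_pct", "o2mr", "rco2", "OA_S", "d34s_sulphate")
    print(summary(tr[, show]))
    totC <- rowSums(tr[, c("OA_C", "Corg_y", "Corg_a", "Ccarb_y", "Ccarb_a")])
    totS <- rowSums(tr[, c("OA_S", "Pyr_y", "Pyr_a", "Gyp_y", "Gyp_a")])
    cat(sprintf("relative drift: total C %.2e, total S %.2e\n",
                diff(range(totC)) / totC[1], diff(range(totS)) / totS[1]))
  }
  invisible(object)
}

#' Plot a model run
#'
#' Panels for atmospheric O2 (percent atm), the driving delta13C record and
#' the synthetic delta34S of seawater sulphate.
#'
#' @param x A `phanox_run`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.phanox_run <- function(x, ...) {
  tr <- x$trajectory
  if (is.null(tr)) stop("run has no trajectory to plot")
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$age_ma, tr$o2_pct, type = "l", xlim = rev(range(tr$age_ma)),
                 xlab = "Age (Ma)", ylab = "O2 (% atm)", ...)
  graphics::abline(h = 21, lty = 3)
  graphics::plot(tr$age_ma, tr$d13c_input, type = "l",
                 xlim = rev(range(tr$age_ma)),
                 xlab = "Age (Ma)", ylab = expression(delta^13 * C))
  graphics::plot(tr$age_ma, tr$d34s_sulphate, type = "l",
                 xlim = rev(range(tr$age_ma)),
                 xlab = "Age (Ma)", ylab = expression(delta^34 * S[sulphate]))
  invisible(x)
}
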