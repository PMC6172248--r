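# Experiment drivers: baseline run, J sweep, delta13C envelope runs, the
# legacy-vs-forward sulphur diagnostic, delta34S validation, and landmark
# checks for user-supplied (non-distributed) data compilations.

#' Baseline model run
#'
#' Thin wrapper over [run_model()] that also reports intervention counts.
#'
#' @param cfg A [model_config()].
#' @param forcings A [forcing_set()].
#' @param record A delta13C [isotope_record()].
#' @param quiet Suppress the health message (default FALSE).
#' @return A `phanox_run`.
#' @export
run_baseline <- function(cfg = model_config(), forcings, record,
                         quiet = FALSE) {
  run <- run_model(cfg, forcings, record)
  if (!quiet && (run$health$n_clip_fbg > 0 || run$health$n_floor > 0))
    message("model health: ", run$health$n_clip_fbg,
            " negative-burial clips, ", run$health$n_floor,
            " O2-floor evaluations")
  run
}

#' Sensitivity sweep over the oxygen-fractionation parameter J
#'
#' Runs the model once per value of `J`. Failed runs are recorded as
#' results (cause and age), not raised: a failed run is itself a finding.
#'
#' @param cfg A [model_config()].
#' @param forcings,record Model inputs.
#' @param j_values J values (default `c(2.5, 4, 5, 7.5)`, the baseline and
#'   the published sensitivity range).
#' @return An object of class `phanox_sweep`: list with `parameter`,
#'   `values`, `runs` (one `phanox_run` per value), and `o2_table`
#'   (data frame `age_ma` x one pO2 column per value, NA where failed).
#' @export
j_sweep <- function(cfg = model_config(), forcings, record,
                    j_values = c(2.5, 4, 5, 7.5)) {
  if (length(j_values) == 0L) stop("j_values must be non-empty")
  if (any(j_values <= 0)) stop("J values must be positive")
  runs <- lapply(j_values, function(j)
    run_model(model_config_update(cfg, J = j), forcings, record))
  names(runs) <- paste0("J=", j_values)
  structure(list(parameter = "J", values = j_values, runs = runs,
                 o2_table = sweep_o2_table(runs, cfg)),
            class = "phanox_sweep")
}

#' Record-uncertainty envelope runs
#'
#' Shifts the delta13C record by `k` standard deviations per
#' [perturb_record()] and reruns the model for each `k`. On realistic
#' records a strongly negative shift is expected to produce a structured
#' failure (oxygen collapse), which is reported as a result.
#'
#' @param cfg A [model_config()].
#' @param forcings,record Model inputs; `record` must carry `sd`.
#' @param k_values SD multiples (default `c(-0.5, 0.5, 1)`).
#' @return A `phanox_sweep` with an added `envelope` data frame
#'   (`age_ma`, `o2_min`, `o2_max` over the non-failed runs).
#' @export
delta13c_envelope <- function(cfg = model_config(), forcings, record,
                              k_values = c(-0.5, 0.5, 1)) {
  if (length(k_values) == 0L) stop("k_values must be non-empty")
  if (is.null(record$sd)) stop("record has no sd column; envelope undefined")
  runs <- lapply(k_values, function(k)
    run_model(cfg, forcings, perturb_record(record, k)))
  names(runs) <- paste0("k=", k_values)
  tab <- sweep_o2_table(runs, cfg)
  env <- data.frame(age_ma = tab$age_ma,
                    o2_min = suppressWarnings(
                      apply(tab[-1], 1, min, na.rm = TRUE)),
                    o2_max = suppressWarnings(
                      apply(tab[-1], 1, max, na.rm = TRUE)))
  env$o2_min[!is.finite(env$o2_min)] <- NA_real_
  env$o2_max[!is.finite(env$o2_max)] <- NA_real_
  structure(list(parameter = "delta13c_sd", values = k_values, runs = runs,
                 o2_table = tab, envelope = env),
            class = "phanox_sweep")
}

# rebuild a config with overrides, preserving everything else
model_config_update <- function(cfg, ...) {
  vals <- unclass(cfg)
  over <- list(...)
  vals[names(over)] <- over
  do.call(model_config, vals)
}

sweep_o2_table <- function(runs, cfg) {
  ages <- seq(cfg$start_age, 0, by = -cfg$report_step)
  tab <- data.frame(age_ma = ages)
  for (nm in names(runs)) {
    r <- runs[[nm]]
    col <- rep(NA_real_, length(ages))
    if (!is.null(r$trajectory)) {
      m <- match(round(ages, 9), round(r$trajectory$age_ma, 9))
      col[!is.na(m)] <- r$trajectory$o2_pct[m[!is.na(m)]]
    }
    tab[[nm]] <- col
  }
  tab
}

#' @export
print.phanox_sweep <- function(x, ...) {
  cat("<phanox_sweep> over ", x$parameter, ": ",
      paste(x$values, collapse = ", "), "\n", sep = "")
  for (nm in names(x$runs)) {
    r <- x$runs[[nm]]
    cat("  ", nm, ": ",
        if (r$failed) paste0("FAILED at ", signif(r$failure$age_ma, 5),
                             " Ma (", r$failure$reason, ")")
        else sprintf("pO2 end %.2f%%", r$trajectory$o2_pct[nrow(r$trajectory)]),
        "\n", sep = "")
  }
  invisible(x)
}

#' Plot a sweep
#' @param x A `phanox_sweep`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.phanox_sweep <- function(x, ...) {
  tab <- x$o2_table
  graphics::matplot(tab$age_ma, as.matrix(tab[-1]), type = "l",
                    xlim = rev(range(tab$age_ma)), xlab = "Age (Ma)",
                    ylab = "O2 (% atm)", ...)
  graphics::legend("topleft", legend = names(tab)[-1], lty = seq_len(ncol(tab) - 1),
                   col = seq_len(ncol(tab) - 1), bty = "n", cex = 0.8)
  invisible(x)
}

#' Legacy versus forward pyrite-burial diagnostic
#'
#' Evaluates, on a grid of atmospheric O2 values and against a fixed
#' present-day carbon/sulphur background, the legacy oxygen-dependent
#' fractionation [legacy_alpha_s()], the pyrite burial demanded by
#' inverting the delta34S record with that fractionation
#' ([legacy_pyrite_burial_imb()]), and the forward burial law
#' ([pyrite_burial()]). The background is held fixed (no co-integration)
#' because the diagnostic illustrates the flux relationship itself: as O2
#' falls the legacy fractionation collapses and the demanded burial
#' diverges, while the forward law stays bounded by `1/O2mr`.
#'
#' @param o2_pct_grid Grid of atmospheric O2 values, percent atm, each in
#'   (0, 100).
#' @param cfg A [model_config()].
#' @return Data frame with `o2_pct`, `o2mr`, `alpha_s` (permil),
#'   `legacy_burial_rel` and `forward_burial_rel` (relative to the present
#'   flux).
#' @export
legacy_sulphur_diagnostic <- function(o2_pct_grid, cfg = model_config()) {
  if (any(o2_pct_grid <= 0 | o2_pct_grid >= 100))
    stop("o2_pct_grid values must lie in (0, 100)")
  o2mr <- o2mr_from_percent(o2_pct_grid)
  alpha <- legacy_alpha_s(o2mr, cfg$legacy_delta_s0, cfg$legacy_n)
  ## fixed present-day sulphate background: inputs at the configured
  ## anchor fluxes and compositions, record at the present sulphate value
  flux_in <- c(cfg$new_kwp, cfg$F_wp_a_0, cfg$F_deg_p_0,
               cfg$new_kwgyp, cfg$F_wgyp_a_0, cfg$F_deg_gyp_0)
  delta_in <- c(cfg$d_Pyr_0, cfg$d_Pyr_0, cfg$d_Pyr_0,
                cfg$d_Gyp_0, cfg$d_Gyp_0, cfg$d_Gyp_0)
  legacy <- vapply(alpha, function(a)
    legacy_pyrite_burial_imb(a, flux_in, delta_in, cfg$d_OA_S_0,
                             rec_slope = 0, oa_s = cfg$OA_S_0),
    numeric(1)) / cfg$F_bp_0
  forward <- vapply(o2mr, function(r)
    pyrite_burial(1, 1, r, cfg$F_bp_0, cfg$o2mr_floor), numeric(1)) /
    cfg$F_bp_0
  data.frame(o2_pct = o2_pct_grid, o2mr = o2mr, alpha_s = alpha,
             legacy_burial_rel = legacy, forward_burial_rel = forward)
}

#' Validate the synthetic delta34S output against an observed record
#'
#' Flags, age by age on the run's reporting grid restricted to the overlap
#' of the two spans, whether the modelled seawater-sulphate delta34S lies
#' within `band` permil of the observed record, and summarizes the
#' fraction inside.
#'
#' @param run A `phanox_run`.
#' @param observed A delta34S [isotope_record()].
#' @param band Half-width of the acceptance band, permil.
#' @return List with `fraction_inside`, `n`, and a data frame `detail`
#'   (`age_ma`, `model`, `observed`, `inside`).
#' @export
validate_d34s <- function(run, observed, band) {
  stopifnot(inherits(run, "phanox_run"), inherits(observed, "isotope_record"))
  if (is.null(run$trajectory)) stop("run has no trajectory")
  if (band < 0) stop("band must be non-negative")
  tr <- run$trajectory
  lo <- max(min(tr$age_ma), min(observed$age_ma))
  hi <- min(max(tr$age_ma), max(observed$age_ma))
  if (lo > hi) stop("trajectory and observed record spans are disjoint")
  sel <- tr$age_ma >= lo & tr$age_ma <= hi
  obs <- record_at(observed, tr$age_ma[sel])
  inside <- abs(tr$d34s_sulphate[sel] - obs) <= band
  list(fraction_inside = mean(inside), n = sum(sel),
       detail = data.frame(age_ma = tr$age_ma[sel],
                           model = tr$d34s_sulphate[sel],
                           observed = obs, inside = inside))
}

#' Check a trajectory against expected pO2 landmarks
#'
#' Utility for comparing a run driven by user-supplied data compilations
#' against a table of expected features, each a target pO2 at an age with
#' a tolerance. The packaged synthetic records cannot reproduce
#' data-derived landmarks; this check is meaningful only with externally
#' digitized delta13C and forcing tables.
#'
#' @param run A `phanox_run`.
#' @param landmarks Data frame with columns `age_ma`, `o2_pct`, `tol_pct`.
#' @return The `landmarks` data frame with added `model_o2_pct` and `pass`.
#' @export
check_landmarks <- function(run, landmarks) {
  stopifnot(inherits(run, "phanox_run"))
  need <- c("age_ma", "o2_pct", "tol_pct")
  if (!all(need %in% names(landmarks)))
    stop("landmarks must have columns age_ma, o2_pct, tol_pct")
  tr <- run$trajectory
  if (is.null(tr)) stop("run has no trajectory")
  model <- stats::approx(tr$age_ma, tr$o2_pct, xout = landmarks$age_ma)$y
  landmarks$model_o2_pct <- model
  landmarks$pass <- abs(model - landmarks$o2_pct) <= landmarks$tol_pct
  landmarks
}
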