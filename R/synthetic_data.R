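# Synthetic model inputs: everything needed to build, test and demonstrate
# the model without any external file.

#' Build a complete synthetic fixture
#'
#' Returns matched forcings, driving delta13C record, delta34S validation
#' record and configuration for one of three scenarios:
#' \describe{
#'   \item{steady}{Exact-balance inputs: unit forcings and a flat record at
#'     the steady-state delta13C implied by the configured present fluxes
#'     (see [steady_delta13c()]), so the model holds 21% atm O2 for the
#'     whole run. The anchor for conservation and convergence checks.}
#'   \item{excursion}{Adds one positive delta13C excursion (+3 permil,
#'     ~20 Myr wide, centred at 497 Ma, after the style of the late-
#'     Cambrian Steptoean positive excursion) on the steady baseline.
#'     Higher delta13C demands more organic burial, so O2 rises during and
#'     after the event.}
#'   \item{stress}{Adds a strong negative excursion (-8 permil sustained
#'     over ~40 Myr early in the run) that drives the isotope-mass-balance
#'     burial demand negative and is expected to trigger the structured
#'     oxygen-collapse failure path.}
#' }
#'
#' The record's standard deviation is a constant 1 permil, the typical
#' per-point scatter of Phanerozoic carbonate compilations.
#'
#' @param scenario One of "steady", "excursion", "stress".
#' @param seed Integer seed (fixtures are deterministic per seed).
#' @param start_age Oldest age, Ma (default 570).
#' @param cfg Optional [model_config()] (default `model_config()`).
#' @return List with elements `forcings`, `record` (delta13C),
#'   `record_d34s`, `config`, `scenario`.
#' @export
#' @examples
#' fx <- make_fixture("steady")
#' run <- run_model(fx$config, fx$forcings, fx$record)
make_fixture <- function(scenario = c("steady", "excursion", "stress"),
                         seed = 1L, start_age = 570, cfg = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(cfg)) cfg <- model_config(start_age = start_age)
  dss <- steady_delta13c(cfg)
  age <- seq(start_age, 0, by = -1)
  delta <- rep(dss, length(age))
  if (scenario == "excursion") {
    delta <- delta + 3 * exp(-((age - 497) / 10)^2)
  } else if (scenario == "stress") {
    onset <- start_age - 30
    delta <- delta - 8 / (1 + exp((age - onset) / 5)) /
      (1 + exp((onset - 70 - age) / 5))
  }
  record <- isotope_record(age, delta, sd = 1)
  forcings <- forcing_set(c(start_age, 0))  # unit forcings
  d34s <- synthetic_delta34s(seed, start_age, baseline = cfg$d_OA_S_0)
  list(forcings = forcings, record = record, record_d34s = d34s,
       config = cfg, scenario = scenario)
}

#' Write a fixture's inputs to CSV files
#'
#' Writes `forcings.csv`, `delta13c.csv` and `delta34s.csv` (plus
#' `config.yaml` when the yaml package is available) into `dir`.
#'
#' @param fixture A list from [make_fixture()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(unclass(fixture$forcings)),
                   file.path(dir, "forcings.csv"), row.names = FALSE)
  write_isotope_record(fixture$record, file.path(dir, "delta13c.csv"))
  write_isotope_record(fixture$record_d34s, file.path(dir, "delta34s.csv"))
  if (requireNamespace("yaml", quietly = TRUE))
    config_to_yaml(fixture$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
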