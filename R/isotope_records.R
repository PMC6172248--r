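# Age-indexed stable-isotope records (delta13C of seawater carbonate drives
# the model; delta34S of seawater sulphate is used only for validation).

#' Construct an isotope record
#'
#' @param age_ma Ages in Ma, strictly monotonic.
#' @param delta Per-mil isotope values (delta13C or delta34S).
#' @param sd Optional per-mil standard deviation at each node (needed for
#'   envelope runs).
#' @return An object of class `isotope_record` (a data frame with columns
#'   `age_ma`, `delta` and optionally `sd`), ages stored descending.
#' @export
#' @examples
#' rec <- isotope_record(c(570, 285, 0), c(1, 3, 1), sd = 1)
#' record_at(rec, 400)
isotope_record <- function(age_ma, delta, sd = NULL) {
  age_ma <- as.numeric(age_ma); delta <- as.numeric(delta)
  if (length(age_ma) == 0L) stop("empty record")
  if (length(delta) == 1L) delta <- rep(delta, length(age_ma))
  if (length(delta) != length(age_ma))
    stop("delta and age_ma must have equal length")
  d <- diff(age_ma)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("ages must be strictly monotonic")
  if (any(!is.finite(delta))) stop("delta values must be finite")
  rec <- data.frame(age_ma = age_ma, delta = delta)
  if (!is.null(sd)) {
    sd <- as.numeric(sd)
    if (length(sd) == 1L) sd <- rep(sd, length(age_ma))
    if (length(sd) != length(age_ma)) stop("sd length mismatch")
    if (any(sd < 0, na.rm = TRUE)) stop("sd must be non-negative")
    rec$sd <- sd
  }
  rec <- rec[order(rec$age_ma, decreasing = TRUE), , drop = FALSE]
  rownames(rec) <- NULL
  class(rec) <- c("isotope_record", "data.frame")
  rec
}

#' Read an isotope record from CSV
#'
#' Columns `age_ma`, `delta_permil` and optionally `sd_permil`.
#'
#' @param path CSV path.
#' @return An [isotope_record()].
#' @export
read_isotope_record <- function(path) {
  if (!file.exists(path)) stop("record file not found: ", path)
  tab <- utils::read.csv(path)
  need <- c("age_ma", "delta_permil")
  if (!all(need %in% names(tab)))
    stop("record CSV must have columns age_ma, delta_permil[, sd_permil]")
  isotope_record(tab$age_ma, tab$delta_permil,
                 sd = if ("sd_permil" %in% names(tab)) tab$sd_permil)
}

#' Write an isotope record to CSV
#' @param rec An [isotope_record()].
#' @param path Output CSV path.
#' @export
write_isotope_record <- function(rec, path) {
  stopifnot(inherits(rec, "isotope_record"))
  out <- data.frame(age_ma = rec$age_ma, delta_permil = rec$delta)
  if (!is.null(rec$sd)) out$sd_permil <- rec$sd
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Moving-average smoothing of an isotope record
#'
#' Centered moving average over a window defined in age units (Myr), not
#' sample counts, so irregular grids are handled consistently: each output
#' node averages all nodes within half a window of it. The standard
#' deviation, where present, is propagated as the window mean of `sd`.
#' A window narrower than the local grid spacing leaves the record
#' unchanged.
#'
#' @param rec An [isotope_record()].
#' @param window Window width in Myr (default 10, the treatment applied to
#'   the driving carbonate delta13C compilation).
#' @return A smoothed [isotope_record()] on the same age grid.
#' @export
smooth_record <- function(rec, window = 10) {
  stopifnot(inherits(rec, "isotope_record"))
  if (window <= 0) stop("window must be positive")
  if (nrow(rec) == 0L) stop("empty record")
  half <- window / 2
  sm <- vapply(rec$age_ma, function(a) {
    i <- abs(rec$age_ma - a) <= half
    mean(rec$delta[i])
  }, numeric(1))
  sd <- if (!is.null(rec$sd))
    vapply(rec$age_ma, function(a) {
      i <- abs(rec$age_ma - a) <= half
      mean(rec$sd[i])
    }, numeric(1))
  isotope_record(rec$age_ma, sm, sd = sd)
}

#' Shift a record by a multiple of its standard deviation
#'
#' Nodewise `delta + k * sd`, used for the sensitivity envelopes driven by
#' the uncertainty of the delta13C compilation. `sd` itself is unchanged.
#'
#' @param rec An [isotope_record()] with `sd` at every node.
#' @param k Signed multiple of the standard deviation.
#' @return A perturbed [isotope_record()].
#' @export
perturb_record <- function(rec, k) {
  stopifnot(inherits(rec, "isotope_record"))
  if (is.null(rec$sd) || anyNA(rec$sd))
    stop("perturb_record requires sd at every node")
  isotope_record(rec$age_ma, rec$delta + k * rec$sd, sd = rec$sd)
}

#' Evaluate a record at an age
#'
#' Piecewise-linear interpolation, exact at nodes, no extrapolation.
#'
#' @param rec An [isotope_record()].
#' @param age_ma Age in Ma (scalar or vector).
#' @return Per-mil value(s).
#' @export
record_at <- function(rec, age_ma) {
  stopifnot(inherits(rec, "isotope_record"))
  lo <- min(rec$age_ma); hi <- max(rec$age_ma)
  if (any(age_ma < lo - 1e-9 | age_ma > hi + 1e-9))
    stop("age outside record span [", lo, ", ", hi, "] Ma")
  age_ma <- pmin(pmax(age_ma, lo), hi)
  if (nrow(rec) == 1L) return(rep(rec$delta, length(age_ma)))
  stats::approx(rec$age_ma, rec$delta, xout = age_ma)$y
}

# d(delta)/d(forward time) in permil/Myr at a given age: the negative of
# the age-derivative of the linear interpolant, central-differenced with a
# step clamped to the record span.
record_slope_at <- function(recfun, age_ma, span, h = 0.25) {
  a1 <- min(max(age_ma - h, span[1]), span[2])
  a2 <- min(max(age_ma + h, span[1]), span[2])
  if (a2 == a1) return(0)
  -(recfun(a2) - recfun(a1)) / (a2 - a1)
}

#' Generate a synthetic carbonate delta13C record
#'
#' A smooth low-frequency baseline drift plus a small number of localized
#' Gaussian excursions, with constant reported standard deviation. The
#' present-day (0 Ma) value is pinned to `present_value` — by default the
#' steady-state delta13C implied by the configured present fluxes — so a
#' run started from the present-day anchor state is initialized at isotopic
#' balance. Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param start_age Oldest age, Ma (default 570).
#' @param baseline Baseline per-mil value (default the configured
#'   steady-state value).
#' @param excursion_amp Maximum excursion magnitude in permil (default 2).
#' @param sd_level Constant per-point standard deviation in permil
#'   (default 1, the typical scatter of Phanerozoic carbonate compilations).
#' @param n_excursions Number of localized excursions (default 3).
#' @param step Grid step, Myr (default 1).
#' @param present_value Value pinned at 0 Ma (default `baseline`).
#' @return An [isotope_record()].
#' @export
synthetic_delta13c <- function(seed = 1L, start_age = 570,
                               baseline = steady_delta13c(model_config()),
                               excursion_amp = 2, sd_level = 1,
                               n_excursions = 3, step = 1,
                               present_value = baseline) {
  if (sd_level < 0) stop("sd_level must be non-negative")
  set.seed(as.integer(seed))
  age <- seq(start_age, 0, by = -step)
  if (age[length(age)] != 0) age <- c(age, 0)
  delta <- rep(baseline, length(age))
  if (excursion_amp > 0 && n_excursions > 0) {
    # drift uses at most half the budget; excursions the rest
    drift_amp <- 0.25 * excursion_amp
    drift <- drift_amp * sin(2 * pi * age / start_age + stats::runif(1, 0, 2 * pi))
    drift <- drift - drift[length(drift)]
    centers <- stats::runif(n_excursions, 0.15, 0.85) * start_age
    widths <- stats::runif(n_excursions, 8, 25)
    signs <- sample(c(-1, 1), n_excursions, replace = TRUE)
    exc <- rep(0, length(age))
    for (i in seq_len(n_excursions))
      exc <- exc + signs[i] * 0.5 * excursion_amp *
        exp(-((age - centers[i]) / widths[i])^2)
    tot <- drift + exc
    m <- max(abs(tot))
    if (m > excursion_amp) tot <- tot / m * excursion_amp
    delta <- baseline + tot
  }
  delta <- delta + (present_value - delta[length(delta)]) *
    exp(-(age / 25)^2)  # taper the present-day pin over ~25 Myr
  isotope_record(age, delta, sd = sd_level)
}

#' Generate a synthetic seawater-sulphate delta34S record
#'
#' A smooth drift around a Phanerozoic-like mean, for exercising the
#' delta34S validation path. Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param start_age Oldest age, Ma.
#' @param baseline Mean per-mil value (default 21, near modern seawater
#'   sulphate).
#' @param amplitude Drift amplitude, permil (default 6).
#' @param sd_level Reported standard deviation, permil (default 2).
#' @param step Grid step, Myr (default 5).
#' @return An [isotope_record()].
#' @export
synthetic_delta34s <- function(seed = 1L, start_age = 570, baseline = 21,
                               amplitude = 6, sd_level = 2, step = 5) {
  set.seed(as.integer(seed) + 777L)
  age <- seq(start_age, 0, by = -step)
  if (age[length(age)] != 0) age <- c(age, 0)
  ph <- stats::runif(2, 0, 2 * pi)
  drift <- amplitude * (0.7 * sin(2 * pi * age / start_age + ph[1]) +
                        0.3 * sin(4 * pi * age / start_age + ph[2]))
  drift <- drift - drift[length(drift)]
  isotope_record(age, baseline + drift, sd = sd_level)
}

#' @export
print.isotope_record <- function(x, ...) {
  cat("<isotope_record> ", nrow(x), " nodes, ",
      max(x$age_ma), " -> ", min(x$age_ma), " Ma; delta in [",
      signif(min(x$delta), 4), ", ", signif(max(x$delta), 4), "] permil",
      if (!is.null(x$sd)) " (with sd)", "\n", sep = "")
  invisible(x)
}
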