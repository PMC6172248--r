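# Time-dependent, nondimensional Earth-system forcings.
#
# All multiplicative forcings are normalized to 1 at the present day (0 Ma);
# GEOG is an additive temperature offset (K) that is 0 at present. Ages are
# stored descending (start age -> 0 Ma); interpolation is piecewise linear.

.forcing_fields <- c("fA", "fD", "fL", "fAW", "GEOG", "fSR",
                     "plant", "calc", "carb_platform")
.forcing_normalized <- c("fA", "fD", "fL", "fAW", "fSR", "plant", "calc")

#' Construct a set of Earth-system forcings
#'
#' Bundles the nondimensional drivers that scale weathering and degassing
#' fluxes through time: land area (`fA`), river runoff (`fD`), fraction of
#' land underlain by carbonates (`fL`), fraction of land experiencing
#' chemical weathering (`fAW`), the paleogeographic temperature offset
#' (`GEOG`, K, additive), seafloor spreading rate (`fSR`), land-plant
#' weathering enhancement (`plant`), the normalized seawater calcium
#' reservoir (`calc`) entering gypsum burial, and the fraction of carbonate
#' deposited on shallow platforms rather than the deep ocean
#' (`carb_platform`).
#'
#' Every multiplicative forcing must equal 1 at 0 Ma (within 1e-9) and be
#' strictly positive; `GEOG` must be 0 at 0 Ma; `carb_platform` lies in
#' (0, 1). Scalars are recycled across the age grid.
#'
#' @param age_ma Numeric vector of ages in Ma, strictly monotonic. Stored
#'   descending internally.
#' @param fA,fD,fL,fAW,fSR,plant,calc Normalized multiplicative forcings
#'   (default 1).
#' @param GEOG Additive temperature offset in K (default 0).
#' @param carb_platform Fraction of platform carbonate deposition
#'   (default 0.5).
#' @return An object of class `forcing_set`: a data frame with one row per
#'   age and one column per forcing.
#' @seealso [forcing_at()], [read_forcings()], [synthetic_forcings()]
#' @export
#' @examples
#' fs <- forcing_set(c(570, 285, 0))
#' forcing_at(fs, 100)$fA
forcing_set <- function(age_ma, fA = 1, fD = 1, fL = 1, fAW = 1, GEOG = 0,
                        fSR = 1, plant = 1, calc = 1, carb_platform = 0.5) {
  age_ma <- as.numeric(age_ma)
  if (length(age_ma) < 1L || anyNA(age_ma))
    stop("age_ma must be a non-empty numeric vector without NA")
  d <- diff(age_ma)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("age_ma must be strictly monotonic")
  vals <- list(fA = fA, fD = fD, fL = fL, fAW = fAW, GEOG = GEOG, fSR = fSR,
               plant = plant, calc = calc, carb_platform = carb_platform)
  n <- length(age_ma)
  vals <- lapply(vals, function(v) {
    v <- as.numeric(v)
    if (length(v) == 1L) v <- rep(v, n)
    if (length(v) != n) stop("forcing series length does not match age grid")
    v
  })
  fs <- data.frame(age_ma = age_ma, vals)
  fs <- fs[order(fs$age_ma, decreasing = TRUE), , drop = FALSE]
  rownames(fs) <- NULL
  class(fs) <- c("forcing_set", "data.frame")
  validate_forcing_set(fs)
  fs
}

validate_forcing_set <- function(fs) {
  if (min(fs$age_ma) > 0)
    stop("forcing set must include (or reach) age 0 Ma")
  present <- vapply(.forcing_normalized, function(nm)
    stats::approx(fs$age_ma, fs[[nm]], xout = 0)$y, numeric(1))
  bad <- names(present)[abs(present - 1) > 1e-9]
  if (length(bad))
    stop("forcings not normalized to 1 at present: ",
         paste(bad, collapse = ", "),
         " (use normalize_to_present() or read_forcings(strict = FALSE))")
  for (nm in .forcing_normalized)
    if (any(fs[[nm]] <= 0))
      stop("forcing ", nm, " must be strictly positive")
  g0 <- stats::approx(fs$age_ma, fs$GEOG, xout = 0)$y
  if (abs(g0) > 1e-9)
    stop("GEOG must be 0 K at present (it is an offset from today)")
  if (any(fs$carb_platform <= 0 | fs$carb_platform >= 1))
    stop("carb_platform must lie strictly within (0, 1)")
  invisible(fs)
}

#' Normalize an age-indexed series to its present-day value
#'
#' Divides a series by its value at 0 Ma (interpolated if 0 Ma is not a
#' grid node) so that the present-day value is exactly 1.
#'
#' @param values Numeric series.
#' @param age_ma Ages in Ma matching `values`.
#' @return Numeric series with value 1 at 0 Ma.
#' @export
normalize_to_present <- function(values, age_ma) {
  if (length(values) != length(age_ma))
    stop("values and age_ma must have equal length")
  v0 <- stats::approx(age_ma, values, xout = 0)$y
  if (is.na(v0)) stop("series does not reach age 0 Ma")
  if (v0 <= 0) stop("present-day value must be positive to normalize")
  out <- values / v0
  # guard rounding so the invariant holds exactly at an age-0 node
  out[age_ma == 0] <- 1
  out
}

#' Read a forcing table from CSV
#'
#' Expects a header row with an `age_ma` column plus one column per forcing
#' (`fA`, `fD`, `fL`, `fAW`, `GEOG`, `fSR`, `plant`, `calc`,
#' `carb_platform`). Nonstandard headers are mapped via `column_map`.
#' Forcings absent from the file default to their no-effect value with a
#' warning. Under `strict = TRUE` (default) a multiplicative forcing whose
#' present-day value is not 1 is an error; under `strict = FALSE` it is
#' renormalized via [normalize_to_present()].
#'
#' @param path Path to a CSV file.
#' @param column_map Named character vector mapping standard names to file
#'   headers, e.g. `c(fA = "land_area")`.
#' @param strict Logical; error (TRUE) or auto-normalize (FALSE) on a
#'   non-unit present-day value.
#' @return A [forcing_set()].
#' @export
read_forcings <- function(path, column_map = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("forcing table not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE)
  nm <- names(tab)
  lookup <- function(std) {
    if (!is.null(column_map) && std %in% names(column_map))
      column_map[[std]] else std
  }
  agecol <- lookup("age_ma")
  if (!agecol %in% nm) stop("no age column '", agecol, "' in ", path)
  age <- tab[[agecol]]
  if (!is.numeric(age)) stop("non-numeric age column in ", path)
  if (anyDuplicated(age)) stop("duplicate ages in ", path)
  args <- list(age_ma = age)
  for (f in .forcing_fields) {
    col <- lookup(f)
    if (col %in% nm) {
      v <- tab[[col]]
      if (!is.numeric(v)) {
        bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
        stop("non-numeric value in column '", col, "', row ", bad,
             " of ", path)
      }
      if (f %in% .forcing_normalized) {
        v0 <- stats::approx(age, v, xout = 0)$y
        if (!is.na(v0) && abs(v0 - 1) > 1e-9) {
          if (strict)
            stop("forcing '", f, "' is ", signif(v0, 6), " at 0 Ma, not 1; ",
                 "re-run with strict = FALSE to auto-normalize")
          v <- normalize_to_present(v, age)
          message("renormalized forcing '", f, "' to 1 at present")
        }
      }
      args[[f]] <- v
    } else {
      default <- if (f == "GEOG") 0 else if (f == "carb_platform") 0.5 else 1
      warning("forcing '", f, "' absent from ", basename(path),
              "; defaulting to ", default, call. = FALSE)
      args[[f]] <- default
    }
  }
  do.call(forcing_set, args)
}

#' Evaluate all forcings at an age
#'
#' Piecewise-linear interpolation on the stored grid; exact at grid nodes.
#' Ages outside the grid span are an error (no extrapolation).
#'
#' @param fs A [forcing_set()].
#' @param age_ma Age in Ma (scalar).
#' @return Named list with one scalar per forcing field.
#' @export
forcing_at <- function(fs, age_ma) {
  stopifnot(inherits(fs, "forcing_set"), length(age_ma) == 1L)
  lo <- min(fs$age_ma); hi <- max(fs$age_ma)
  if (age_ma < lo - 1e-9 || age_ma > hi + 1e-9)
    stop("age ", age_ma, " Ma outside forcing grid span [", lo, ", ", hi, "]")
  age_ma <- min(max(age_ma, lo), hi)
  out <- lapply(.forcing_fields, function(f)
    stats::approx(fs$age_ma, fs[[f]], xout = age_ma)$y)
  names(out) <- .forcing_fields
  out
}

# Fast interpolators for use inside the ODE right-hand side: one approxfun
# per field, built once per run.
forcing_functions <- function(fs) {
  funs <- lapply(.forcing_fields, function(f)
    stats::approxfun(fs$age_ma, fs[[f]], rule = 2))
  names(funs) <- .forcing_fields
  funs
}

#' Generate smooth synthetic forcing curves
#'
#' Builds a reproducible set of forcings as sums of low-frequency sines,
#' each pinned to its no-effect value at 0 Ma and bounded within
#' `amplitude` of it. Used as a stand-in for the tabulated GEOCARB-family
#' forcing histories, which are not redistributed here.
#'
#' @param seed Integer seed; output is deterministic per seed.
#' @param start_age Oldest age in Ma (default 570).
#' @param amplitude Maximum deviation from 1 (0 to 0.5; default 0.2). GEOG
#'   deviates by up to `10 * amplitude` K from 0.
#' @param step Grid step in Myr (default 10).
#' @return A [forcing_set()].
#' @export
synthetic_forcings <- function(seed = 1L, start_age = 570, amplitude = 0.2,
                               step = 10) {
  if (amplitude < 0 || amplitude > 0.5)
    stop("amplitude must lie in [0, 0.5]")
  age <- seq(start_age, 0, by = -step)
  if (age[length(age)] != 0) age <- c(age, 0)
  smooth_curve <- function(rng, amp) {
    if (amp == 0) return(rep(0, length(age)))
    k <- 1:3
    a <- stats::runif(3, -1, 1)
    ph <- stats::runif(3, 0, 2 * pi)
    # each mode vanishes at age 0 so the present-day pin is exact
    w <- sapply(k, function(kk) sin(pi * kk * age / start_age + 0) )
    raw <- drop(w %*% a)
    raw <- raw - raw[length(raw)]       # exact 0 at 0 Ma
    m <- max(abs(raw))
    if (m == 0) rep(0, length(age)) else raw / m * amp
  }
  set.seed(as.integer(seed))
  mk <- function(amp) 1 + smooth_curve(NULL, amp)
  forcing_set(age_ma = age,
              fA = mk(amplitude), fD = mk(amplitude), fL = mk(amplitude),
              fAW = mk(amplitude), GEOG = smooth_curve(NULL, 10 * amplitude),
              fSR = mk(amplitude), plant = mk(amplitude),
              calc = mk(amplitude),
              carb_platform = 0.5 + smooth_curve(NULL, amplitude * 0.4))
}

#' @export
print.forcing_set <- function(x, ...) {
  cat("<forcing_set> ", nrow(x), " ages, ",
      max(x$age_ma), " -> ", min(x$age_ma), " Ma\n", sep = "")
  cat("fields:", paste(.forcing_fields, collapse = ", "), "\n")
  invisible(x)
}
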