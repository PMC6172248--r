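# Shared helpers: independent brute-force integrators and budget oracles
# used to cross-check the solver and the isotope-mass-balance inversion.

# Fixed-step explicit Euler over the same derivative field, forward in time
# from `start_age_ma` for `span_myr` at step `dt` (Myr).
euler_integrate <- function(state, start_age_ma, span_myr, dt, cfg,
                            forcings, record) {
  n <- round(span_myr / dt)
  for (i in seq_len(n)) {
    age <- start_age_ma - (i - 1) * dt
    d <- model_derivatives(state, age, cfg, forcings, record)$deriv
    state <- state + dt * d
  }
  state
}

# Two-box finite-difference isotope budget: given a candidate organic
# burial flux, step the ocean-atmosphere delta13C forward and return the
# achieved slope. Used to verify the closed-form inversion independently.
achieved_slope <- function(fbg, oa_c, delta, flux_in, delta_in, frac, dt = 1e-4) {
  d_new <- delta + dt * (sum(flux_in * (delta_in - delta)) + fbg * frac) / oa_c
  (d_new - delta) / dt
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-12)), tol)
}
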