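cfg <- model_config()
fx <- make_fixture("steady")

test_that("O2 mass-to-atmosphere conversion matches its closed form", {
  expect_equal(o2_percent_atm(1), 21)
  expect_equal(o2_percent_atm(0.5), 100 * 0.5 / (0.5 + 79 / 21))  # ~11.73
  expect_equal(o2_percent_atm(0.5), 11.7318, tolerance = 1e-4)
  expect_equal(o2_percent_atm(2), 34.7107, tolerance = 1e-4)
  expect_true(all(diff(o2_percent_atm(seq(0.1, 3, 0.1))) > 0))
  # inverse round-trip
  p <- c(2, 10, 21, 35)
  expect_equal(o2_percent_atm(o2mr_from_percent(p)), p)
})

test_that("initialization apportions sulphur per configuration", {
  st <- initialize_state(cfg)
  s_tot <- sum(st[c("OA_S", "Pyr_y", "Pyr_a", "Gyp_y", "Gyp_a")])
  expect_equal(s_tot, 418)
  expect_equal(sum(st[c("Pyr_y", "Pyr_a")]) / sum(st[c("Gyp_y", "Gyp_a")]),
               2.8)
  leg <- initialize_state(model_config(sulphur_init = "legacy"))
  expect_equal(sum(leg[c("OA_S", "Pyr_y", "Pyr_a", "Gyp_y", "Gyp_a")]), 638)
  expect_equal(sum(leg[c("Pyr_y", "Pyr_a")]), 300)
  expect_equal(sum(leg[c("Gyp_y", "Gyp_a")]), 300)
  # inconsistent apportionment is a config error
  expect_error(model_config(total_S = 500), "sum")
})

test_that("the derivative field vanishes at the anchor and conserves mass", {
  st <- initialize_state(cfg, fx$record)
  out <- model_derivatives(st, 570, cfg, fx$forcings, fx$record)
  expect_lt(max(abs(out$deriv)), 1e-12)
  # conservation by construction, checked at a perturbed state
  st2 <- st
  st2["O2"] <- 1.3 * cfg$O2_0; st2["OA_C"] <- 1.2 * cfg$OA_C_0
  st2["Pyr_y"] <- 0.7 * cfg$Pyr_y_0
  out2 <- model_derivatives(st2, 300, cfg, fx$forcings, fx$record)
  dC <- sum(out2$deriv[c("OA_C", "Corg_y", "Corg_a", "Ccarb_y", "Ccarb_a")])
  dS <- sum(out2$deriv[c("OA_S", "Pyr_y", "Pyr_a", "Gyp_y", "Gyp_a")])
  expect_lt(abs(dC), 1e-12)
  expect_lt(abs(dS), 1e-12)
})

test_that("excess oxygen decays through the assembled feedbacks", {
  st <- initialize_state(cfg, fx$record)
  st["O2"] <- 1.1 * cfg$O2_0
  out <- model_derivatives(st, 300, cfg, fx$forcings, fx$record)
  expect_lt(out$deriv[["O2"]], 0)
})

test_that("the oxygen budget carries the 15:8 pyrite stoichiometry", {
  st <- initialize_state(cfg, fx$record)
  out <- model_derivatives(st, 300, cfg, fx$forcings, fx$record)
  fl <- out$fluxes
  # reassemble the O2 budget from the reported fluxes
  expected <- fl$F_bg + (15 / 8) * fl$F_bp -
    fl$F_wg_y - fl$F_wg_a - fl$F_deg_g -
    (15 / 8) * (fl$F_wp_y + fl$F_wp_a + fl$F_deg_p + fl$F_deg_p_y)
  expect_equal(out$deriv[["O2"]], expected)
  # a unit of pyrite burial alone is worth 15/8 units of O2
  expect_equal((15 / 8) * 1, 1.875)
})

test_that("isotope-weighted sulphur mass is conserved by the rate field", {
  st <- initialize_state(cfg, fx$record)
  st["O2"] <- 0.8 * cfg$O2_0           # off-balance state
  st["d_OA_S"] <- 25; st["d_Pyr_y"] <- -20
  out <- model_derivatives(st, 300, cfg, fx$forcings, fx$record)
  pools <- list(c("OA_S", "d_OA_S"), c("Pyr_y", "d_Pyr_y"),
                c("Pyr_a", "d_Pyr_a"), c("Gyp_y", "d_Gyp_y"),
                c("Gyp_a", "d_Gyp_a"))
  d_tot <- sum(vapply(pools, function(p)
    st[[p[1]]] * out$deriv[[p[2]]] + st[[p[2]]] * out$deriv[[p[1]]],
    numeric(1)))
  expect_lt(abs(d_tot), 1e-9)
})

test_that("a steady run holds the anchor and conserves totals", {
  run <- run_model(cfg, fx$forcings, fx$record)
  expect_false(run$failed)
  tr <- run$trajectory
  expect_true(all(abs(tr$o2_pct - 21) < 0.1))
  totC <- rowSums(tr[, c("OA_C", "Corg_y", "Corg_a", "Ccarb_y", "Ccarb_a")])
  totS <- rowSums(tr[, c("OA_S", "Pyr_y", "Pyr_a", "Gyp_y", "Gyp_a")])
  expect_lt(diff(range(totC)) / totC[1], 1e-6)
  expect_lt(diff(range(totS)) / totS[1], 1e-6)
  # ages reported descending to 0
  expect_equal(tr$age_ma[1], 570)
  expect_equal(tr$age_ma[nrow(tr)], 0)
})

test_that("a perturbed run relaxes monotonically back to the anchor", {
  cfg2 <- model_config(start_age = 300)
  fx2 <- make_fixture("steady", cfg = cfg2)
  st <- initialize_state(cfg2, fx2$record)
  st["O2"] <- 1.1 * cfg2$O2_0
  run <- run_model(cfg2, fx2$forcings, fx2$record, state0 = st)
  tr <- run$trajectory
  seg <- tr[tr$age_ma >= 250, ]
  dev <- abs(seg$O2 - cfg2$O2_0)
  expect_true(all(diff(dev) <= 1e-9))               # monotone decay
  expect_lt(dev[length(dev)] / dev[1], 0.5)         # over half gone in 50 Myr
})

test_that("halving solver tolerances leaves the trajectory unchanged to 0.1%", {
  fe <- make_fixture("excursion")
  r1 <- run_model(cfg, fe$forcings, fe$record)
  r2 <- run_model(cfg, fe$forcings, fe$record,
                  rtol = cfg$rtol / 2, atol = cfg$atol / 2)
  expect_rel_equal(r1$trajectory$o2_pct, r2$trajectory$o2_pct, 1e-3)
})

test_that("the stiff solver matches brute-force Euler on a sub-interval", {
  cfg3 <- model_config(start_age = 502)
  fe <- make_fixture("excursion", cfg = cfg3)  # excursion centred at 497 Ma
  run <- run_model(cfg3, fe$forcings, fe$record)
  st0 <- initialize_state(cfg3, fe$record)
  st_euler <- euler_integrate(st0, 502, 10, 0.001, cfg3, fe$forcings,
                              fe$record)
  row <- run$trajectory[run$trajectory$age_ma == 492, ]
  row$d_OA_S <- row$d34s_sulphate  # trajectory's user-facing column name
  for (nm in names(st_euler))
    expect_lt(abs(row[[nm]] - st_euler[[nm]]) /
                max(abs(st_euler[[nm]]), 1e-8), 5e-3)
})

test_that("the implicit Runge-Kutta method agrees with the default solver", {
  cfg4 <- model_config(start_age = 100)
  f4 <- make_fixture("excursion", cfg = cfg4)
  r_lsodar <- run_model(cfg4, f4$forcings, f4$record)
  r_radau <- run_model(cfg4, f4$forcings, f4$record, method = "radau")
  expect_rel_equal(r_lsodar$trajectory$o2_pct, r_radau$trajectory$o2_pct,
                   1e-3)
})

test_that("oxygen collapse is reported as a structured failure, not NaN", {
  fs <- make_fixture("stress")
  run <- run_model(cfg, fs$forcings, fs$record)
  expect_true(run$failed)
  expect_match(run$failure$reason, "O2 floor")
  expect_true(is.finite(run$failure$age_ma))
  expect_false(anyNA(run$trajectory$o2_pct))
})

test_that("trajectories write to CSV with the documented columns", {
  run <- run_model(cfg, fx$forcings, fx$record)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(run, path)
  back <- read.csv(path)
  expect_true(all(c("age_ma", "o2_pct", "o2mr", "rco2", "d34s_sulphate",
                    "d13c_input", "F_bg", "F_bp") %in% names(back)))
  expect_equal(back$o2_pct, run$trajectory$o2_pct)
})
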