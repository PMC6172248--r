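cfg <- model_config()
unit_f <- forcing_at(forcing_set(c(570, 0)), 100)  # all forcings at 1

test_that("carbon fractionation follows the linear oxygen dependence", {
  expect_equal(carbon_fractionation(1, J = 4, delta0 = 25), 25)
  expect_equal(carbon_fractionation(1.5, J = 4, delta0 = 25), 27)
  expect_equal(carbon_fractionation(0.3, J = 0, delta0 = 25), 25)
  # strictly increasing in O2 for positive J
  o2 <- seq(0.2, 2, by = 0.2)
  expect_true(all(diff(carbon_fractionation(o2, 4, 25)) > 0))
  expect_error(carbon_fractionation(1e-3, J = 30, delta0 = 25),
               "model-failure")
})

test_that("isotope-mass-balance burial matches its closed forms", {
  # steady state, single input 5 permil below the record, 25 permil
  # fractionation: organic fraction is 0.2
  r <- organic_burial_imb(3.8, 0, 0, flux_in = 10, delta_in = -5, frac = 25)
  expect_equal(r$F_bg, 0.2 * 10)
  # no isotopic contrast and no slope: no burial demanded
  r0 <- organic_burial_imb(3.8, 2, 0, flux_in = 10, delta_in = 2, frac = 25)
  expect_equal(r0$F_bg, 0)
  # negative demand is clipped with a warning
  expect_warning(
    rc <- organic_burial_imb(3.8, -6, 0, flux_in = 10, delta_in = 0, frac = 25),
    "clipped")
  expect_equal(rc$F_bg, 0)
  expect_true(rc$clipped)
  expect_error(organic_burial_imb(3.8, 0, 0, 10, -5, frac = -1), "positive")
})

test_that("inverted burial reproduces the record slope in a finite-difference budget", {
  # oracle: stepping the ocean-atmosphere delta13C with the returned flux
  # must achieve the demanded slope to <0.1%
  cases <- list(
    list(oa = 3.8, delta = 1, slope = 0.05, fl = c(3, 12), dl = c(-24, 1), fr = 25),
    list(oa = 3.8, delta = 2.5, slope = -0.1, fl = c(5, 20, 2), dl = c(-22, 1, 0.5), fr = 27),
    list(oa = 10, delta = 0, slope = 0.2, fl = c(4, 15), dl = c(-25, 2), fr = 23)
  )
  for (cs in cases) {
    fbg <- organic_burial_imb(cs$oa, cs$delta, cs$slope, cs$fl, cs$dl, cs$fr)$F_bg
    got <- achieved_slope(fbg, cs$oa, cs$delta, cs$fl, cs$dl, cs$fr)
    expect_rel_equal(got, cs$slope, 1e-3)
  }
})

test_that("burial demand falls as fractionation widens", {
  f1 <- organic_burial_imb(3.8, 1, 0.05, c(3, 12), c(-24, 1), frac = 25)$F_bg
  f2 <- organic_burial_imb(3.8, 1, 0.05, c(3, 12), c(-24, 1), frac = 29)$F_bg
  expect_lt(f2, f1)
})

test_that("silicate weathering honours its anchors and monotonicity", {
  expect_equal(silicate_weathering_flux(1, unit_f, cfg), cfg$F_ws_0)
  expect_gt(silicate_weathering_flux(2, unit_f, cfg),
            silicate_weathering_flux(1, unit_f, cfg))
  f_half <- unit_f; f_half$fAW <- 0.5
  expect_equal(silicate_weathering_flux(1, f_half, cfg), 0.5 * cfg$F_ws_0)
  f_bad <- unit_f; f_bad$fD <- -1
  expect_error(silicate_weathering_flux(1, f_bad, cfg), "positive")
})

test_that("carbonate weathering scales with reservoirs and carbonate land", {
  w <- carbonate_weathering_flux(cfg$Ccarb_y_0, cfg$Ccarb_a_0, 1, unit_f, cfg)
  expect_equal(w$F_wc_y, cfg$F_wc_y_0)
  expect_equal(w$F_wc_a, cfg$F_wc_a_0)
  w2 <- carbonate_weathering_flux(cfg$Ccarb_y_0, 2 * cfg$Ccarb_a_0, 1, unit_f, cfg)
  expect_equal(w2$F_wc_a, 2 * cfg$F_wc_a_0)
  f0 <- unit_f; f0$fL <- 1e-12  # no carbonate land
  expect_lt(carbonate_weathering_flux(cfg$Ccarb_y_0, cfg$Ccarb_a_0, 1,
                                      f0, cfg)$F_wc_y, 1e-9)
})

test_that("organic weathering carries the oxidative power law", {
  w <- organic_weathering_flux(cfg$Corg_y_0, cfg$Corg_a_0, 1, unit_f, cfg)
  expect_equal(w$F_wg_y, cfg$F_wg_y_0)
  expect_equal(w$F_wg_a, cfg$F_wg_a_0)
  wq <- organic_weathering_flux(cfg$Corg_y_0, cfg$Corg_a_0, 0.25, unit_f, cfg)
  expect_equal(wq$F_wg_y, 0.5 * cfg$F_wg_y_0)  # 0.25^0.5
  w0 <- organic_weathering_flux(cfg$Corg_y_0, cfg$Corg_a_0, 0, unit_f, cfg)
  expect_equal(w0$F_wg_y, 0)
  expect_equal(w0$F_wg_a, 0)
})

test_that("degassing is linear in mass and spreading rate", {
  expect_equal(degassing_flux(1000, 0.5 / 1000, 1), 0.5)
  expect_equal(degassing_flux(1000, 0.5 / 1000, 2), 1)
  expect_equal(degassing_flux(0, 0.5 / 1000, 1), 0)
  # platform weighting: all-platform carbonate does not degas
  expect_equal(degassing_flux(1000, 2 / 1000, 1, carb_platform = 0.5,
                              carb_platform_0 = 0.5), 2)
  expect_lt(degassing_flux(1000, 2 / 1000, 1, carb_platform = 0.9,
                           carb_platform_0 = 0.5), 2)
})

test_that("every carbon flux hits its configured present value at the anchor", {
  fx <- make_fixture("steady")
  st <- initialize_state(cfg, fx$record)
  out <- model_derivatives(st, 300, cfg, fx$forcings, fx$record)
  fl <- out$fluxes
  expect_equal(fl$F_bg, cfg$F_bg_0, tolerance = 1e-10)
  expect_equal(fl$F_bc, cfg$F_bc_0, tolerance = 1e-10)
  expect_equal(fl$F_ws, cfg$F_ws_0, tolerance = 1e-10)
  expect_equal(fl$F_wc_y, cfg$F_wc_y_0, tolerance = 1e-10)
  expect_equal(fl$F_wc_a, cfg$F_wc_a_0, tolerance = 1e-10)
  expect_equal(fl$F_wg_y, cfg$F_wg_y_0, tolerance = 1e-10)
  expect_equal(fl$F_wg_a, cfg$F_wg_a_0, tolerance = 1e-10)
  expect_equal(fl$F_deg_g, cfg$F_deg_g_0, tolerance = 1e-10)
  expect_equal(fl$F_deg_c, cfg$F_deg_c_0, tolerance = 1e-10)
})
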