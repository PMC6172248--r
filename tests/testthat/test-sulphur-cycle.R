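cfg <- model_config()

test_that("young weathering laws reproduce their anchors and scalings", {
  # pyrite: silicate channel with sqrt-O2 feedback
  expect_equal(young_pyrite_weathering(1, 1, 1, cfg$new_kwp), cfg$new_kwp)
  expect_equal(young_pyrite_weathering(1, 1, 0.25, cfg$new_kwp),
               0.5 * cfg$new_kwp)
  expect_equal(young_pyrite_weathering(2, 0.5, 1, cfg$new_kwp), cfg$new_kwp)
  expect_error(young_pyrite_weathering(-1, 1, 1), "non-negative")
  # gypsum: carbonate channel, no O2 term
  expect_equal(young_gypsum_weathering(1, 1, cfg$new_kwgyp), cfg$new_kwgyp)
  expect_equal(young_gypsum_weathering(2, 0.5, cfg$new_kwgyp), cfg$new_kwgyp)
  expect_equal(young_gypsum_weathering(5, 0, cfg$new_kwgyp), 0)
})

test_that("burial laws reproduce their anchors and scalings", {
  expect_equal(pyrite_burial(1, 1, 1, k_bp = 1), 1)
  expect_equal(pyrite_burial(1, 1, 0.5, k_bp = 1), 2)   # reciprocal O2
  expect_equal(pyrite_burial(0.5, 2, 1, k_bp = 1), 1)   # cancellation
  # strictly decreasing in O2
  o2 <- seq(0.1, 2, by = 0.1)
  fb <- vapply(o2, function(r) pyrite_burial(1, 1, r), numeric(1))
  expect_true(all(diff(fb) < 0))
  # the floor guards the singularity
  expect_equal(pyrite_burial(1, 1, 1e-9, k_bp = 1, o2mr_floor = 1e-3), 1e3)
  expect_equal(gypsum_burial(1, 1, k_bgyp = 1), 1)
  expect_equal(gypsum_burial(1, 0.5, k_bgyp = 1), 0.5)
  expect_equal(gypsum_burial(0, 1, k_bgyp = 1), 0)
})

test_that("ancient weathering keeps the oxidative feedback on pyrite only", {
  a <- ancient_sulphur_weathering(cfg$Pyr_a_0, cfg$Gyp_a_0, 1, 1, cfg)
  expect_equal(a$F_wp_a, cfg$F_wp_a_0)
  expect_equal(a$F_wgyp_a, cfg$F_wgyp_a_0)
  a2 <- ancient_sulphur_weathering(cfg$Pyr_a_0, cfg$Gyp_a_0, 1, 0.25, cfg)
  expect_equal(a2$F_wp_a, 0.5 * cfg$F_wp_a_0)
  expect_equal(a2$F_wgyp_a, cfg$F_wgyp_a_0)   # gypsum unchanged
  a3 <- ancient_sulphur_weathering(0, cfg$Gyp_a_0, 1, 1, cfg)
  expect_equal(a3$F_wp_a, 0)
})

test_that("degassing and transfer are linear with the right anchors", {
  d <- sulphur_degassing_and_transfer(cfg$Pyr_y_0, cfg$Pyr_a_0,
                                      cfg$Gyp_y_0, cfg$Gyp_a_0, 1, cfg)
  expect_equal(d$F_deg_p, cfg$F_deg_p_0)
  expect_equal(d$F_deg_gyp, cfg$F_deg_gyp_0)
  expect_equal(d$F_ya_p, cfg$F_ya_p_0)
  expect_equal(d$F_ya_gyp, cfg$F_ya_gyp_0)
  d0 <- sulphur_degassing_and_transfer(cfg$Pyr_y_0, cfg$Pyr_a_0,
                                       cfg$Gyp_y_0, cfg$Gyp_a_0, 0, cfg)
  expect_equal(d0$F_deg_p, 0)                   # no spreading, no degassing
  expect_equal(d0$F_ya_p, cfg$F_ya_p_0)         # transfer forcing-independent
  d2 <- sulphur_degassing_and_transfer(2 * cfg$Pyr_y_0, cfg$Pyr_a_0,
                                       cfg$Gyp_y_0, cfg$Gyp_a_0, 1, cfg)
  expect_equal(d2$F_ya_p, 2 * cfg$F_ya_p_0)
})

test_that("the sulphate isotope budget has the expected structure", {
  fx <- make_fixture("steady")
  st <- initialize_state(cfg, fx$record)
  out <- model_derivatives(st, 300, cfg, fx$forcings, fx$record)
  # at the configured steady state all compositions are stationary
  dd <- delta34s_rates(st, out$fluxes, cfg$alpha_s_forward)
  expect_lt(max(abs(unlist(dd))), 1e-12)
  # uniform compositions with zero fractionation: exact fixed point
  st2 <- st
  st2[c("d_OA_S", "d_Pyr_y", "d_Pyr_a", "d_Gyp_y", "d_Gyp_a")] <- 10
  dd2 <- delta34s_rates(st2, out$fluxes, alpha_s = 0)
  expect_lt(max(abs(unlist(dd2))), 1e-12)
  # pyrite burial alone drives sulphate positive
  fzero <- lapply(out$fluxes, function(x) 0)
  fzero$F_bp <- 1
  dd3 <- delta34s_rates(st, fzero, alpha_s = 35)
  expect_gt(dd3$d_OA_S, 0)
  # linearity: doubling all fluxes doubles every rate
  fdouble <- lapply(out$fluxes, function(x) 2 * x)
  st4 <- st2  # non-trivial compositions
  st4["d_Pyr_y"] <- -20
  dd_single <- delta34s_rates(st4, out$fluxes, 35)
  dd_double <- delta34s_rates(st4, fdouble, 35)
  expect_equal(unlist(dd_double), 2 * unlist(dd_single))
})

test_that("the legacy fractionation law and its inversion behave as documented", {
  expect_equal(legacy_alpha_s(1, 35, 1.5), 35)
  expect_equal(legacy_alpha_s(0.25, 35, 1.5), 4.375)
  expect_equal(legacy_alpha_s(0, 35, 1.5), 0)
  o2 <- seq(0.05, 2, by = 0.05)
  expect_true(all(diff(legacy_alpha_s(o2)) > 0))
  # steady state, one input 15 permil below the record, 30 permil
  # fractionation: burial takes half the input flux
  expect_equal(legacy_pyrite_burial_imb(30, 4, -15 + 21, 21), 2)
  # halving the fractionation doubles the demanded burial
  expect_equal(legacy_pyrite_burial_imb(15, 4, 6, 21),
               2 * legacy_pyrite_burial_imb(30, 4, 6, 21))
  expect_equal(legacy_pyrite_burial_imb(30, 4, 21, 21), 0)
  expect_error(legacy_pyrite_burial_imb(0, 4, 6, 21), "positive")
})

test_that("raising O2 pushes both sulphur feedbacks toward lower O2", {
  fx <- make_fixture("steady")
  st <- initialize_state(cfg, fx$record)
  hi <- st; hi["O2"] <- 1.5 * cfg$O2_0
  lo <- st
  out_hi <- model_derivatives(hi, 300, cfg, fx$forcings, fx$record)$fluxes
  out_lo <- model_derivatives(lo, 300, cfg, fx$forcings, fx$record)$fluxes
  expect_lt(out_hi$F_bp, out_lo$F_bp)  # less O2 production via pyrite
  expect_gt(out_hi$F_wp_y + out_hi$F_wp_a,
            out_lo$F_wp_y + out_lo$F_wp_a)  # more O2 consumption
})
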