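test_that("perturbations recover the target rate and move weights with the input", {
  p <- wp_params()
  pl <- wp_plasticity()
  up <- perturbation_experiment(p, pl, rho_base = 2, rho_disr = 2.5)
  expect_equal(up$after$rates$nu_E, 1, tolerance = 1e-3)
  expect_equal(up$delta$sign_w_EE, 1)
  expect_equal(up$delta$sign_w_EI, 1)
  # upward input perturbation raises the presynaptic LTD/LTP threshold
  expect_gt(up$after$c_pre_E, up$before$c_pre_E)
  # the attractor steepens with the input rate
  expect_gt(up$after$attractor$slope, up$before$attractor$slope)

  down <- perturbation_experiment(p, pl, rho_base = 2, rho_disr = 1.5)
  expect_equal(down$after$rates$nu_E, 1, tolerance = 1e-3)
  expect_equal(down$delta$sign_w_EE, -1)
  expect_equal(down$delta$sign_w_EI, -1)
  expect_lt(down$after$c_pre_E, down$before$c_pre_E)

  null <- perturbation_experiment(p, pl, rho_base = 2, rho_disr = 2)
  expect_equal(null$delta$w_EE, 0, tolerance = 1e-8)
  expect_equal(null$delta$w_EI, 0, tolerance = 1e-8)
  expect_equal(null$after$c_pre_E, null$before$c_pre_E, tolerance = 1e-6)
})

test_that("induction from random weights compresses the E/I ratio towards R_inf", {
  p <- wp_params()
  pl <- wp_plasticity()
  ei <- ei_induction_experiment(p, pl, n_draws = 300, seed = 21)
  expect_true(all(ei$w_EE_0 >= 0 & ei$w_EE_0 <= 3))
  expect_true(all(ei$R_before <= 12))
  r_inf <- attr(ei, "R_inf")
  expect_equal(r_inf, 0.75)
  # inhibitory weights change more than excitatory ones on average
  expect_gt(mean(abs(ei$dw_EI_pct)), mean(abs(ei$dw_EE_pct)))
  # excitation-dominated draws that fire above threshold move towards R_inf
  nu0 <- rectify(2 * ei$w_EE_0 - 1.5 * ei$w_EI_0)
  big <- ei$R_before > 2 & nu0 > 1
  expect_gt(sum(big), 10)
  expect_true(all(ei$R_after[big] < ei$R_before[big]))

  # a draw exactly on the line attractor is a fixed point of the induction
  att <- line_attractor(p, 1)
  w0 <- c(1.8, phase_line_at(att, 1.8))
  nu <- steady_state_rates(p, weight_state(w0[1], w0[2]))
  expect_equal(nu$nu_E, 1)  # no plasticity at the target rate
})

test_that("long induction drives retained draws onto the attractor ratio", {
  p <- wp_params()
  pl <- wp_plasticity()
  ei <- ei_induction_experiment(p, pl, n_draws = 40, induction_time = 60,
                                dt = 0.01, seed = 4)
  att <- line_attractor(p, 1)
  # draws that kept a positive rate converge to the attractor ratio
  ok <- is.finite(ei$R_after) & ei$R_after > 0 & ei$dw_EI_pct != 0
  expect_gt(mean(ok), 0.5)
  final_wEI <- ei$w_EI_0 * (1 + ei$dw_EI_pct / 100)
  pred <- sapply(final_wEI[ok], function(w) ei_ratios(p, 1, w)$R)
  expect_equal(ei$R_after[ok], pred, tolerance = 1e-3)
})

test_that("postsynaptic variability leaves weights in a bounded band", {
  p <- wp_params(tau_FR_E = 0.1, tau_FR_I = 0.1, dt = 0.1)
  pl <- wp_plasticity()
  set.seed(31)
  dn <- varying_drive_experiment(p, pl,
                                 drive_spec("rho_add", "gaussian_noise",
                                            sd = 0.01),
                                 init = weight_state(1.845, 1.793), T = 2000)
  expect_false(dn$trajectory$diverged)
  expect_equal(dn$drift$slope_w_EE, 0, tolerance = 1e-4)
  expect_equal(dn$drift$slope_w_EI, 0, tolerance = 1e-4)
  expect_equal(dn$drift$nu_E_mean, 1, tolerance = 0.05)
  d <- dn$trajectory$trajectory
  expect_lt(max(d$w_EE) - min(d$w_EE), 0.2)
})

test_that("presynaptic sinusoid produces slow upward drift at a stable mean rate", {
  p <- wp_params()
  pl <- wp_plasticity()
  ds <- varying_drive_experiment(p, pl,
                                 drive_spec("rho_E", "sinusoid", offset = 2,
                                            amplitude = 0.5, omega = 0.01),
                                 init = weight_state(1.845, 1.793), T = 3000)
  expect_gt(ds$drift$slope_w_EE, 0)
  expect_gt(ds$drift$slope_w_EI, 0)
  expect_equal(ds$drift$nu_E_mean, 1, tolerance = 0.05)
})

test_that("postsynaptic sinusoid trajectories hug the phase-shifted attractors", {
  # the additive drive moves the attractor's intercept but not its slope, so
  # at each drive extremum the weights lie on the correspondingly shifted
  # line (the quasi-static lag is tiny at this drive frequency)
  p <- wp_params()
  pl <- wp_plasticity()
  drv <- drive_spec("rho_add", "sinusoid", amplitude = 0.25, omega = 0.01)
  ds <- varying_drive_experiment(p, pl, drv,
                                 init = weight_state(1.845, 1.793), T = 3000,
                                 record_every = 1L)
  d <- ds$trajectory$trajectory
  d <- d[d$t > max(d$t) / 2, ]
  for (s in c(1, -1)) {
    extrema <- d[abs(sin(0.01 * d$t) - s) < 1e-4, ]
    expect_gt(nrow(extrema), 10)
    att <- line_attractor(p, c_post = 1, rho_add = s * 0.25)
    expect_equal(att$slope, line_attractor(p, 1)$slope)  # slope unchanged
    resid <- extrema$w_EI - phase_line_at(att, extrema$w_EE)
    expect_lt(max(abs(resid)), 0.01)
  }
})

test_that("zero-amplitude drive reproduces the constant-input run", {
  p <- wp_params()
  pl <- wp_plasticity()
  base <- run_feedforward(p, pl, weight_state(1.5, 0.5), T = 30)
  flat <- varying_drive_experiment(p, pl,
                                   drive_spec("rho_add", "sinusoid",
                                              amplitude = 0, omega = 0.01),
                                   init = weight_state(1.5, 0.5), T = 30)
  expect_equal(flat$trajectory$final$w_EE, base$final$w_EE)
  expect_equal(flat$trajectory$final$w_EI, base$final$w_EI)
})

test_that("predicted and simulated stability agree away from the boundary", {
  sw <- stability_sweep(n_draws = 25, seed = 13)
  expect_equal(nrow(sw), 25)
  expect_true(all(sw$agree))
  expect_true(any(sw$predicted_stable) && any(!sw$predicted_stable))
})

test_that("feedback-motif stability map is consistent and monotone", {
  p <- wp_params()
  pl <- wp_plasticity()
  m <- feedback_motif_stability_map(p, pl, w_ff_grid = seq(0, 1, by = 0.25),
                                    w_fb_grid = seq(0, 0.8, by = 0.4))
  # no inhibition at all: unstable
  expect_false(m[1, 1])
  # the feedforward-only column matches the closed-form classifier
  for (i in seq_len(nrow(m))) {
    p_i <- p; p_i$w_IE <- as.numeric(rownames(m))[i]
    expect_equal(unname(m[i, 1]), stability_condition(p_i, pl)$stable)
  }
  # increasing either weight never destabilizes
  expect_true(all(apply(m, 2, function(col) all(diff(col) >= 0))))
  expect_true(all(apply(m, 1, function(row) all(diff(row) >= 0))))
})
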