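test_that("presynaptic LTD/LTP threshold matches the closed form", {
  # (1 + 1 * 1.5 * 0.75) / (1 * 1.5)
  expect_equal(presynaptic_threshold(1.5, 0.75, 1.5, 1)$c_pre_E, 2.125 / 1.5)
  expect_equal(presynaptic_threshold(1.5, 0, 1.5, 1)$c_pre_E, 1 / 1.5)
  expect_error(presynaptic_threshold(0, 0.5, 1.5, 1), "w_EE")
  # stronger inhibitory weights require more presynaptic drive for LTP
  cpre <- sapply(seq(0, 1.5, by = 0.25),
                 function(w) presynaptic_threshold(1.5, w, 1.5, 1)$c_pre_E)
  expect_true(all(diff(cpre) > 0))
})

test_that("self-consistent presynaptic threshold solves nu_E(rho) = c_post", {
  p <- wp_params()
  w <- weight_state(1.5, 0.75)
  cpre <- presynaptic_threshold_selfconsistent(p, w)$c_pre_E
  r <- steady_state_rates(p, w, rho_E = cpre)
  expect_equal(r$nu_E, w$c_post_E, tolerance = 1e-12)
  expect_error(presynaptic_threshold_selfconsistent(
    p, weight_state(0.5, 10)), "crossing")
})

test_that("line attractor has the derived slope and intercepts", {
  p <- wp_params()
  att <- line_attractor(p, c_post = 1)
  expect_equal(att$slope, 4 / 3)            # 1*2 / (1*1.5)
  expect_equal(att$abscissa_intercept, 0.5) # 1 / (1*2)
  expect_equal(att$intercept, -1 / 1.5)

  # c_post = 0 gives a line through the origin
  expect_equal(line_attractor(p, c_post = 0)$intercept, 0)

  # additive postsynaptic input shifts the intercept only
  att2 <- line_attractor(p, c_post = 1, rho_add = 0.25)
  expect_equal(att2$slope, att$slope)
  expect_equal(att2$intercept, -(1 - 0.25) / 1.5)

  expect_error(line_attractor(wp_params(rho_E = 0, rho_I = 0)), "degenerate")
})

test_that("zero-rate boundary passes through the origin with the shared slope", {
  p <- wp_params()
  zb <- zero_rate_boundary(p)
  expect_equal(zb$intercept, 0)
  expect_equal(phase_line_at(zb, 1.5), 2)
  expect_equal(zb$slope, line_attractor(p, 1)$slope)
  # a point above the boundary has zero postsynaptic rate
  expect_equal(steady_state_rates(p, weight_state(1.5, 2.5))$nu_E, 0)
  expect_gt(steady_state_rates(p, weight_state(1.5, 1.5))$nu_E, 0)
})

test_that("separatrix of the linear rule classifies the printed initializations", {
  p <- wp_params()
  pl <- plasticity_params(rule = "linear")
  sep <- separatrix_linear_rule(p, pl)
  expect_equal(-sep$intercept, 1.875)  # nu_I tau_w_E / (N_E rho_E^2 tau_w_I)
  expect_equal(sep$slope, 4 / 3)
  # above the separatrix: stable; below: unstable
  expect_gt(0.5, phase_line_at(sep, 1.5) - 1e-12)  # [1.5, 0.5] above
  expect_lt(1.0, phase_line_at(sep, 2.5))          # [2.5, 1.0] below
})

test_that("stability condition reproduces the dominance inequality and spectrum", {
  p <- wp_params()
  pl <- wp_plasticity()
  s <- stability_condition(p, pl)
  expect_equal(s$lhs, 11.25)   # 1 * 1.5^2 / 0.2
  expect_equal(s$rhs, 4)       # 1 * 2^2 / 1
  expect_true(s$stable)
  expect_equal(s$trace, -7.25)
  expect_equal(s$det, 0)
  expect_equal(sort(s$eigenvalues), c(-7.25, 0))

  # frozen inhibitory plasticity destroys stability
  s2 <- stability_condition(p, plasticity_params(tau_w_I = 1e9))
  expect_false(s2$stable)
})

test_that("numeric Jacobian agrees with the closed form on the attractor", {
  p <- wp_params()
  pl <- wp_plasticity()
  att <- line_attractor(p, 1)
  J <- jacobian_numeric(p, pl, weight_state(1.5, phase_line_at(att, 1.5)))
  expect_true(attr(J, "on_attractor"))
  expect_lt(abs(det(J)), 1e-6)
  ev <- sort(Re(eigen(J)$values))
  expect_equal(ev[1], -7.25, tolerance = 1e-6)
  expect_equal(ev[2], 0, tolerance = 1e-6)
  expect_warning(jacobian_numeric(p, pl, weight_state(1.5, 1)), "off the line")
})

test_that("numeric and closed-form eigenvalues agree over a random sweep", {
  set.seed(11)
  for (i in 1:20) {
    p <- wp_params(rho_E = runif(1, 0.5, 3), rho_I = runif(1, 0, 1),
                   w_IE = runif(1, 0.2, 1))
    pl <- plasticity_params(tau_w_E = runif(1, 0.5, 2),
                            tau_w_I = runif(1, 0.05, 0.5))
    att <- line_attractor(p, 1)
    x <- att$abscissa_intercept + runif(1, 0.5, 2)
    J <- jacobian_numeric(p, pl, weight_state(x, phase_line_at(att, x)))
    s <- stability_condition(p, pl)
    expect_lt(abs(det(J)), 1e-6)
    expect_equal(sort(Re(eigen(J)$values))[1], min(s$eigenvalues),
                 tolerance = 1e-6)
  }
})

test_that("Jacobian trace scales inversely with a common timescale factor", {
  p <- wp_params()
  att <- line_attractor(p, 1)
  w <- weight_state(1.5, phase_line_at(att, 1.5))
  J1 <- jacobian_numeric(p, plasticity_params(tau_w_E = 1, tau_w_I = 0.2), w)
  J2 <- jacobian_numeric(p, plasticity_params(tau_w_E = 2, tau_w_I = 0.4), w)
  expect_equal(sum(diag(J2)), sum(diag(J1)) / 2, tolerance = 1e-5)
})

test_that("E/I ratios match the closed forms and their limits", {
  p <- wp_params()
  r <- ei_ratios(p, c_post = 1, w_EI = 2)
  expect_equal(r$R_inf, 0.75)                      # 1.5 / 2
  expect_equal(r$R, (1.5 * 2 + 1) / (2 * 2))
  expect_equal(r$R_tot, (1.5 * 2 + 1) / (1.5 * 2))
  expect_error(ei_ratios(p, 1, w_EI = 0), "w_EI")

  # offset vanishes with c_post = 0
  expect_equal(ei_ratios(p, c_post = 0, w_EI = 0.7)$R,
               ei_ratios(p, c_post = 0, w_EI = 0.7)$R_inf)

  # large-rho_E limit approaches w_IE for N_E = N_I
  p_big <- wp_params(rho_E = 1e6)
  expect_equal(ei_ratios(p_big, 1, 1)$R_large_rhoE, 0.5, tolerance = 1e-3)
})

test_that("R_inf matches the attractor geometry and is monotone in rho_E and w_IE", {
  # the attractor line is w_EI(w_EE) with slope N_E rho_E / (N_I nu_I), so
  # the limiting weight ratio w_EE/w_EI is its reciprocal
  set.seed(5)
  for (i in 1:10) {
    p <- wp_params(rho_E = runif(1, 0.5, 4), rho_I = runif(1, 0, 1),
                   w_IE = runif(1, 0.2, 1))
    expect_equal(ei_ratios(p, 1, 1)$R_inf, 1 / line_attractor(p, 1)$slope)
  }
  rinf_rho <- sapply(c(0.5, 1, 2, 4, 8),
                     function(r) ei_ratios(wp_params(rho_E = r), 1, 1)$R_inf)
  expect_true(all(diff(rinf_rho) < 0))
  rinf_wie <- sapply(c(0.2, 0.5, 1, 2),
                     function(w) ei_ratios(wp_params(w_IE = w), 1, 1)$R_inf)
  expect_true(all(diff(rinf_wie) > 0))
})

test_that("long simulations terminate on the attractor at the predicted ratio", {
  p <- wp_params()
  pl <- wp_plasticity()
  att <- line_attractor(p, 1)
  for (w0 in list(c(1.5, 0.5), c(1.5, 1.8), c(2.5, 1.0))) {
    tr <- run_to_convergence(p, pl, weight_state(w0[1], w0[2]))
    expect_true(tr$converged)
    expect_equal(tr$final$w_EI, phase_line_at(att, tr$final$w_EE),
                 tolerance = 1e-3)
    expect_equal(tr$final$w_EE / tr$final$w_EI,
                 ei_ratios(p, 1, tr$final$w_EI)$R, tolerance = 1e-3)
  }
})
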