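test_that("excitatory rule matches hand-evaluated values and its zeros", {
  expect_equal(dw_ee(2, 2, 1, 1), 4)
  expect_equal(dw_ee(2, 1, 1, 1), 0)    # at the threshold
  expect_equal(dw_ee(2, 0, 1, 1), 0)    # silent postsynaptic neuron
})

test_that("linear inhibitory rule depresses at zero postsynaptic rate", {
  expect_equal(dw_ei_linear(1.5, 0, 1, 0.2), -7.5)
  expect_equal(dw_ei_linear(1.5, 1, 1, 0.2), 0)
  expect_equal(dw_ei_linear(0, 3, 1, 0.2), 0)  # presynaptic gating
})

test_that("nonlinear inhibitory rule is silent without postsynaptic activity", {
  expect_equal(dw_ei_nonlinear(1.5, 0, 1, 0.2), 0)
  expect_equal(dw_ei_nonlinear(7.3, 0, 1, 0.2), 0)
  expect_equal(dw_ei_nonlinear(1.5, 2, 1, 0.2), 15)
  expect_equal(dw_ei_nonlinear(1.5, 1, 1, 0.2), 0)
})

test_that("nonlinear rule equals nu_E times the linear rule everywhere", {
  set.seed(7)
  nu_I <- runif(50, 0, 5); nu_E <- runif(50, 0, 5)
  cc <- runif(50, 0.2, 3); tau <- runif(50, 0.05, 2)
  expect_equal(dw_ei_nonlinear(nu_I, nu_E, cc, tau),
               nu_E * dw_ei_linear(nu_I, nu_E, cc, tau))
})

test_that("same-sign structure holds for equal thresholds", {
  cc <- 1
  for (nu_E in c(1.2, 2, 4)) {       # above threshold: both potentiate
    expect_gt(dw_ee(2, nu_E, cc, 1), 0)
    expect_gt(dw_ei_nonlinear(1.5, nu_E, cc, 0.2), 0)
  }
  for (nu_E in c(0.1, 0.5, 0.9)) {   # below threshold: both depress
    expect_lt(dw_ee(2, nu_E, cc, 1), 0)
    expect_lt(dw_ei_nonlinear(1.5, nu_E, cc, 0.2), 0)
  }
})

test_that("weight step applies Euler update and floor", {
  w <- weight_state(1.5, 0.5)
  w1 <- step_weights(w, 4, 0, dt = 0.1)
  expect_equal(w1$w_EE, 1.9)
  expect_equal(w1$w_EI, 0.5)
  expect_equal(w1$t, 0.1)
  w2 <- step_weights(weight_state(0.05, 0.5), -1, 0, dt = 0.1,
                     weight_floor = 0)
  expect_equal(w2$w_EE, 0)
  w3 <- step_weights(w, 0, 0, dt = 0.1)
  expect_equal(w3$w_EE, w$w_EE)
  expect_equal(w3$w_EI, w$w_EI)
})

test_that("threshold step slides thresholds in opposite directions", {
  w <- weight_state(1.5, 0.5, 1, 1)
  w0 <- step_thresholds(w, 0, 0, tau_c = 2, dt = 0.01)
  expect_equal(w0$c_post_E, 1)
  expect_equal(w0$c_post_I, 1)
  w1 <- step_thresholds(w, 4, 15, tau_c = 2, dt = 0.01)
  expect_gt(w1$c_post_E, 1)   # excitatory LTP raises the excitatory threshold
  expect_lt(w1$c_post_I, 1)   # inhibitory LTP lowers the inhibitory threshold
  # clamp keeps thresholds strictly positive
  w2 <- step_thresholds(w, -1e6, 1e6, tau_c = 2, dt = 0.01)
  expect_gt(w2$c_post_E, 0)
  expect_gt(w2$c_post_I, 0)
})

test_that("dynamic thresholds match from either ordering with live weights", {
  p <- wp_params(tau_FR_E = 1e-3, tau_FR_I = 1e-3, dt = 1e-3)
  for (cc in list(c(0.7, 1.3), c(1.3, 0.7))) {
    pl <- plasticity_params(c_post_E = cc[1], c_post_I = cc[2],
                            dynamic_thresholds = TRUE)
    tr <- run_feedforward(p, pl, weight_state(1, 1, cc[1], cc[2]), T = 400)
    expect_false(tr$diverged)
    expect_gt(tr$final$w_EE, 0)
    expect_gt(tr$final$w_EI, 0)
    expect_lt(abs(tr$final$c_post_E - tr$final$c_post_I), 1e-3)
    # the postsynaptic rate settles at the common threshold
    expect_equal(tr$rates$nu_E, tr$final$c_post_E, tolerance = 1e-3)
  }
})
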