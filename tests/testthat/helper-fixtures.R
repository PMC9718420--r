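# Standard working point: single pre/post pair, rho_E = 2 Hz, rho_I = 0.5 Hz,
# w_IE = 0.5 (so nu_I = 1.5 Hz at steady state), thresholds at 1 Hz,
# tau_w_E = 1, tau_w_I = 0.2. Instantaneous-rate mode, dt = 0.01.
wp_params <- function(...) ff_params(...)
wp_plasticity <- function(...) plasticity_params(...)

# brute-force reference integrator: plain R loop over the exported step
# functions, independent of the compiled path
r_reference_sim <- function(params, plasticity, init, n_steps, drive = NULL) {
  w <- init
  rates <- steady_state_rates(params, w)
  for (i in seq_len(n_steps)) {
    t <- init$t + i * params$dt
    rates <- step_rates(rates, w, params, drive, t)
    dwee <- dw_ee(params$rho_E, rates$nu_E, w$c_post_E, plasticity$tau_w_E)
    dwei <- if (plasticity$rule == "nonlinear") {
      dw_ei_nonlinear(rates$nu_I, rates$nu_E, w$c_post_I, plasticity$tau_w_I)
    } else {
      dw_ei_linear(rates$nu_I, rates$nu_E, w$c_post_I, plasticity$tau_w_I)
    }
    if (plasticity$dynamic_thresholds) {
      w <- step_thresholds(w, dwee, dwei, plasticity$tau_c, params$dt)
    }
    w <- step_weights(w, dwee, dwei, params$dt, plasticity$weight_floor)
  }
  list(weights = w, rates = rates)
}
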