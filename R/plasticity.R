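#' Excitatory weight-change rate
#'
#' Nonlinear Hebbian rule for excitatory-to-excitatory weights:
#' \deqn{\dot w^{EE} = \rho^E \nu^E (\nu^E - c_{post}^E) / \tau_w^E.}
#' Depression below the postsynaptic LTD/LTP threshold, potentiation above it,
#' and no change without postsynaptic activity.
#'
#' @param rho_E presynaptic excitatory rate (Hz).
#' @param nu_E postsynaptic excitatory rate (Hz).
#' @param c_post_E postsynaptic LTD/LTP threshold (Hz).
#' @param tau_w_E plasticity timescale (Hz^2).
#' @return weight-change rate (per unit time). Vectorized in all arguments.
#' @examples
#' dw_ee(2, 2, 1, 1)   # 4: LTP above threshold
#' dw_ee(2, 0, 1, 1)   # 0: silent postsynaptic neuron
#' @export
dw_ee <- function(rho_E, nu_E, c_post_E, tau_w_E) {
  rho_E * nu_E * (nu_E - c_post_E) / tau_w_E
}

#' Linear inhibitory weight-change rate
#'
#' The classical homeostatic rule,
#' \eqn{\dot w^{EI} = \nu^I (\nu^E - c_{post}^I) / \tau_w^I}: linear in the
#' postsynaptic rate, so a silent postsynaptic neuron still produces
#' inhibitory LTD (the key contrast with \code{\link{dw_ei_nonlinear}}).
#'
#' @param nu_I presynaptic inhibitory rate (Hz).
#' @param nu_E postsynaptic excitatory rate (Hz).
#' @param c_post_I inhibitory postsynaptic LTD/LTP threshold, i.e. the target
#'   rate (Hz).
#' @param tau_w_I plasticity timescale (Hz for this rule).
#' @return weight-change rate. Vectorized.
#' @examples
#' dw_ei_linear(1.5, 0, 1, 0.2)   # -7.5: LTD although nu_E = 0
#' @export
dw_ei_linear <- function(nu_I, nu_E, c_post_I, tau_w_I) {
  nu_I * (nu_E - c_post_I) / tau_w_I
}

#' Nonlinear inhibitory weight-change rate
#'
#' The same-sign inhibitory rule,
#' \eqn{\dot w^{EI} = \nu^I \nu^E (\nu^E - c_{post}^I) / \tau_w^I}: inhibitory
#' synapses potentiate and depress with the same sign as excitatory ones and
#' do not change when the postsynaptic neuron is silent. Algebraically
#' \code{dw_ei_nonlinear(...) == nu_E * dw_ei_linear(...)}.
#'
#' @inheritParams dw_ei_linear
#' @param tau_w_I plasticity timescale (Hz^2 for this rule).
#' @return weight-change rate. Vectorized.
#' @examples
#' dw_ei_nonlinear(1.5, 2, 1, 0.2)  # 15
#' dw_ei_nonlinear(1.5, 0, 1, 0.2)  # 0: no plasticity without postsynaptic activity
#' @export
dw_ei_nonlinear <- function(nu_I, nu_E, c_post_I, tau_w_I) {
  nu_I * nu_E * (nu_E - c_post_I) / tau_w_I
}

# dispatch on the rule chosen in plasticity_params
dw_ei <- function(plasticity, nu_I, nu_E, c_post_I) {
  if (plasticity$rule == "nonlinear") {
    dw_ei_nonlinear(nu_I, nu_E, c_post_I, plasticity$tau_w_I)
  } else {
    dw_ei_linear(nu_I, nu_E, c_post_I, plasticity$tau_w_I)
  }
}

#' One Euler step of the weights
#'
#' \code{w <- max(w + dw * dt, weight_floor)} for both weights. The floor is
#' applied after the step (no reflecting dynamics).
#'
#' @param state a \code{\link{weight_state}}.
#' @param dwee,dwei weight-change rates (from the \code{dw_*} functions).
#' @param dt Euler step.
#' @param weight_floor lower weight bound (default 0).
#' @return the updated \code{weight_state} with \code{t} advanced by \code{dt}.
#' @export
step_weights <- function(state, dwee, dwei, dt, weight_floor = 0) {
  state$w_EE <- max(state$w_EE + dwee * dt, weight_floor)
  state$w_EI <- max(state$w_EI + dwei * dt, weight_floor)
  state$t <- state$t + dt
  state
}

# thresholds are clamped at a small positive rate so the target stays a
# meaningful firing rate
.threshold_eps <- 1e-6

#' One Euler step of the sliding LTD/LTP thresholds
#'
#' Metaplastic threshold dynamics driven by the realized plasticity rates:
#' \deqn{\tau_c \dot c_{post}^E = \dot w^{EE}, \qquad
#'       \tau_c \dot c_{post}^I = -\dot w^{EI}.}
#' The excitatory threshold therefore rises during excitatory LTP (making
#' further LTP harder) while the inhibitory threshold falls during inhibitory
#' LTP; the two thresholds slide towards each other and eventually match.
#' Thresholds are clamped strictly positive.
#'
#' @param state a \code{\link{weight_state}}.
#' @param dwee,dwei weight-change rates.
#' @param tau_c threshold-adaptation timescale.
#' @param dt Euler step.
#' @return the updated \code{weight_state} (time is not advanced here; pair
#'   with \code{\link{step_weights}}).
#' @export
step_thresholds <- function(state, dwee, dwei, tau_c, dt) {
  state$c_post_E <- max(state$c_post_E + dwee * dt / tau_c, .threshold_eps)
  state$c_post_I <- max(state$c_post_I - dwei * dt / tau_c, .threshold_eps)
  state
}
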