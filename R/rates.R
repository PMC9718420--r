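#' Linear rectification
#'
#' Threshold-linear transfer: negative values are set to zero. Vectorized.
#'
#' @param x numeric.
#' @return \code{pmax(x, 0)}.
#' @examples
#' rectify(c(-3, 0, 2.25))
#' @export
rectify <- function(x) pmax(x, 0)

#' Steady-state population rates
#'
#' Fixed point of the threshold-linear rate equations for given weights and
#' inputs:
#' \deqn{\nu^I = [N^E \rho^E w^{IE} + \rho^I]_+}
#' \deqn{\nu^E = [N^E \rho^E w^{EE} - N^I \nu^I w^{EI} + \rho_{add}]_+}
#' With a feedback connection (\code{w_FB_IE > 0}) the coupled pair is solved
#' jointly, handling the rectifier cases.
#'
#' @param params an \code{\link{ff_params}} object.
#' @param weights a \code{\link{weight_state}}.
#' @param rho_add additive input to the postsynaptic neuron (default 0).
#' @param rho_E,rho_I optional overrides of the corresponding parameter values
#'   (used by time-varying drives).
#' @return A list of class \code{"rate_state"} with fields \code{nu_E},
#'   \code{nu_I} (both >= 0).
#' @examples
#' steady_state_rates(ff_params(), weight_state(1.5, 0.5))  # nu_I = 1.5, nu_E = 2.25
#' @export
steady_state_rates <- function(params, weights, rho_add = 0,
                               rho_E = params$rho_E, rho_I = params$rho_I) {
  exc_I <- params$N_E * rho_E * params$w_IE + rho_I
  exc_E <- params$N_E * rho_E * weights$w_EE + rho_add
  if (params$w_FB_IE == 0) {
    nu_I <- rectify(exc_I)
    nu_E <- rectify(exc_E - params$N_I * nu_I * weights$w_EI)
  } else {
    # joint interior solution, then fall back through the rectifier cases
    denom <- 1 + params$N_I * params$w_FB_IE * weights$w_EI
    nu_E <- (exc_E - params$N_I * exc_I * weights$w_EI) / denom
    nu_I <- exc_I + params$w_FB_IE * nu_E
    if (nu_E < 0) {
      nu_E <- 0
      nu_I <- rectify(exc_I)
    } else if (nu_I < 0) {
      nu_I <- 0
      nu_E <- rectify(exc_E)
    }
  }
  structure(list(nu_E = nu_E, nu_I = nu_I), class = "rate_state")
}

#' @export
print.rate_state <- function(x, ...) {
  cat(sprintf("rates: nu_E = %g Hz, nu_I = %g Hz\n", x$nu_E, x$nu_I))
  invisible(x)
}

#' One explicit Euler step of the rate dynamics
#'
#' Advances both population rates by one step \code{dt} of
#' \deqn{\tau_{FR}^E \dot\nu^E = -\nu^E + [N^E \rho^E w^{EE} -
#'   N^I \nu^I w^{EI} + \rho_{add}]_+}
#' and the analogous inhibitory equation, with the drive evaluated at time
#' \code{t}. Requires \code{dt <= tau_FR} (explicit-Euler stability); when
#' \code{tau_FR = dt} the update reduces exactly to the instantaneous steady
#' state.
#'
#' @param rates a \code{"rate_state"} (list with \code{nu_E}, \code{nu_I}).
#' @param weights a \code{\link{weight_state}}.
#' @param params an \code{\link{ff_params}}; \code{params$dt} is the step.
#' @param drive optional \code{\link{drive_spec}} modulating one input channel.
#' @param t current time (drive evaluation point).
#' @return The updated \code{"rate_state"}; rates remain nonnegative.
#' @export
step_rates <- function(rates, weights, params, drive = NULL, t = 0) {
  if (params$dt > params$tau_FR_E || params$dt > params$tau_FR_I) {
    stop("dt exceeds a rate time constant (explicit Euler unstable); ",
         "use dt <= min(tau_FR_E, tau_FR_I)", call. = FALSE)
  }
  d <- resolve_drives(params, drive, t)
  # upstream-first (Gauss-Seidel) order: the inhibitory population is updated
  # first and its new rate feeds the postsynaptic update, so that with
  # tau_FR = dt a single step lands exactly on the instantaneous steady state
  exc_I <- params$N_E * d[["rho_E"]] * params$w_IE +
    params$w_FB_IE * rates$nu_E + d[["rho_I"]]
  nu_I <- rates$nu_I +
    (-rates$nu_I + rectify(exc_I)) * params$dt / params$tau_FR_I
  inp_E <- params$N_E * d[["rho_E"]] * weights$w_EE -
    params$N_I * nu_I * weights$w_EI + d[["rho_add"]]
  nu_E <- rates$nu_E +
    (-rates$nu_E + rectify(inp_E)) * params$dt / params$tau_FR_E
  structure(list(nu_E = rectify(nu_E), nu_I = rectify(nu_I)),
            class = "rate_state")
}
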