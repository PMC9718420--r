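#' Feedforward circuit parameters
#'
#' Constants of the feedforward inhibitory motif: a single postsynaptic
#' excitatory neuron receives input from \code{N_E} presynaptic excitatory
#' neurons (rate \code{rho_E}) and from \code{N_I} inhibitory neurons, which are
#' themselves driven by the same presynaptic pool (fixed weight \code{w_IE}) and
#' by an external drive \code{rho_I}. All times (\code{tau_FR_E},
#' \code{tau_FR_I}, \code{dt}) are in one consistent arbitrary simulation time
#' unit; rates are in Hz. When \code{tau_FR_E = tau_FR_I = dt} the rate update
#' degenerates to the instantaneous steady state ("instantaneous integrators"),
#' which is the package default.
#'
#' @param N_E number of presynaptic excitatory neurons (>= 1).
#' @param N_I number of inhibitory neurons (>= 1).
#' @param rho_E presynaptic excitatory rate (Hz, >= 0).
#' @param rho_I external excitatory rate onto the inhibitory neurons (Hz; may
#'   be negative, modelling inhibition of the inhibitory neurons).
#' @param w_IE fixed excitatory-to-inhibitory weight (>= 0).
#' @param tau_FR_E,tau_FR_I time constants of the rate dynamics.
#' @param dt Euler time step (> 0, must not exceed the rate time constants).
#' @param w_FB_IE feedback weight from the postsynaptic excitatory neuron onto
#'   the inhibitory population (0 gives the pure feedforward motif).
#'
#' @return An object of class \code{"ff_params"} (a named list).
#' @examples
#' p <- ff_params()              # the standard working point
#' steady_state_rates(p, weight_state(1.5, 0.5))
#' @export
ff_params <- function(N_E = 1, N_I = 1, rho_E = 2, rho_I = 0.5, w_IE = 0.5,
                      tau_FR_E = 0.01, tau_FR_I = 0.01, dt = 0.01,
                      w_FB_IE = 0) {
  p <- list(N_E = N_E, N_I = N_I, rho_E = rho_E, rho_I = rho_I, w_IE = w_IE,
            tau_FR_E = tau_FR_E, tau_FR_I = tau_FR_I, dt = dt,
            w_FB_IE = w_FB_IE)
  validate_ff_params(p)
  structure(p, class = "ff_params")
}

validate_ff_params <- function(p) {
  stopifnot(p$N_E >= 1, p$N_I >= 1)
  if (p$rho_E < 0) stop("rho_E must be >= 0", call. = FALSE)
  if (p$w_IE < 0) stop("w_IE must be >= 0", call. = FALSE)
  if (p$w_FB_IE < 0) stop("w_FB_IE must be >= 0", call. = FALSE)
  if (p$tau_FR_E <= 0 || p$tau_FR_I <= 0) {
    stop("rate time constants tau_FR_E, tau_FR_I must be > 0", call. = FALSE)
  }
  if (p$dt <= 0) stop("dt must be > 0", call. = FALSE)
  invisible(p)
}

#' @export
print.ff_params <- function(x, ...) {
  cat("Feedforward E/I circuit parameters\n")
  cat(sprintf("  N_E = %g, N_I = %g, rho_E = %g Hz, rho_I = %g Hz, w_IE = %g\n",
              x$N_E, x$N_I, x$rho_E, x$rho_I, x$w_IE))
  if (x$w_FB_IE > 0) cat(sprintf("  feedback E->I weight w_FB_IE = %g\n", x$w_FB_IE))
  cat(sprintf("  tau_FR_E = %g, tau_FR_I = %g, dt = %g%s\n",
              x$tau_FR_E, x$tau_FR_I, x$dt,
              if (x$tau_FR_E == x$dt && x$tau_FR_I == x$dt)
                " (instantaneous-rate mode)" else ""))
  invisible(x)
}

#' Plasticity rule parameters
#'
#' Timescales and thresholds of the excitatory rule and of the chosen
#' inhibitory rule. The excitatory rule is always the nonlinear one,
#' \eqn{\tau_w^E \dot w^{EE} = \rho^E \nu^E (\nu^E - c_{post}^E)}. The
#' inhibitory rule is either \code{"nonlinear"},
#' \eqn{\tau_w^I \dot w^{EI} = \nu^I \nu^E (\nu^E - c_{post}^I)}, or the
#' classical \code{"linear"} one,
#' \eqn{\tau_w^I \dot w^{EI} = \nu^I (\nu^E - c_{post}^I)}.
#'
#' @param tau_w_E excitatory plasticity timescale (inverse learning rate,
#'   units Hz^2).
#' @param tau_w_I inhibitory plasticity timescale (Hz for the linear rule,
#'   Hz^2 for the nonlinear rule).
#' @param c_post_E,c_post_I initial postsynaptic LTD/LTP thresholds (Hz, > 0).
#'   \code{c_post_I} is the target rate of the postsynaptic neuron.
#' @param rule inhibitory rule, \code{"nonlinear"} or \code{"linear"}.
#' @param dynamic_thresholds if \code{TRUE} the two thresholds slide in
#'   opposite directions driven by the realized weight changes
#'   (metaplasticity), eventually matching each other.
#' @param tau_c threshold-adaptation timescale (default 2: thresholds slide
#'   on a comparable timescale to the weights; much faster sliding makes the
#'   inhibitory threshold outrun the rate during transients and drives both
#'   thresholds to the floor).
#' @param weight_floor lower bound applied to both weights after each Euler
#'   step (default 0).
#'
#' @return An object of class \code{"plasticity_params"}.
#' @export
plasticity_params <- function(tau_w_E = 1, tau_w_I = 0.2,
                              c_post_E = 1, c_post_I = 1,
                              rule = c("nonlinear", "linear"),
                              dynamic_thresholds = FALSE,
                              tau_c = 2, weight_floor = 0) {
  rule <- match.arg(rule)
  if (tau_w_E <= 0 || tau_w_I <= 0) stop("tau_w_E and tau_w_I must be > 0", call. = FALSE)
  if (tau_c <= 0) stop("tau_c must be > 0", call. = FALSE)
  if (c_post_E <= 0 || c_post_I <= 0) stop("LTD/LTP thresholds must be > 0", call. = FALSE)
  if (weight_floor < 0) stop("weight_floor must be >= 0", call. = FALSE)
  structure(list(tau_w_E = tau_w_E, tau_w_I = tau_w_I,
                 c_post_E = c_post_E, c_post_I = c_post_I,
                 rule = rule, dynamic_thresholds = isTRUE(dynamic_thresholds),
                 tau_c = tau_c, weight_floor = weight_floor),
            class = "plasticity_params")
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat(sprintf("Plasticity: %s inhibitory rule, tau_w_E = %g, tau_w_I = %g\n",
              x$rule, x$tau_w_E, x$tau_w_I))
  cat(sprintf("  thresholds c_post_E = %g Hz, c_post_I = %g Hz (%s)\n",
              x$c_post_E, x$c_post_I,
              if (x$dynamic_thresholds) sprintf("dynamic, tau_c = %g", x$tau_c)
              else "static"))
  invisible(x)
}

#' Plastic weight and threshold state
#'
#' The state variables that evolve under plasticity: the excitatory-to-
#' excitatory weight \code{w_EE}, the inhibitory-to-excitatory weight
#' \code{w_EI}, the two postsynaptic LTD/LTP thresholds, and the current time.
#'
#' @param w_EE,w_EI synaptic weights (>= 0).
#' @param c_post_E,c_post_I postsynaptic LTD/LTP thresholds (Hz, > 0).
#' @param t current time.
#' @return An object of class \code{"weight_state"}.
#' @export
weight_state <- function(w_EE, w_EI, c_post_E = 1, c_post_I = 1, t = 0) {
  if (w_EE < 0 || w_EI < 0) stop("weights must be >= 0", call. = FALSE)
  if (c_post_E <= 0 || c_post_I <= 0) stop("thresholds must be > 0", call. = FALSE)
  structure(list(w_EE = w_EE, w_EI = w_EI,
                 c_post_E = c_post_E, c_post_I = c_post_I, t = t),
            class = "weight_state")
}

#' @export
print.weight_state <- function(x, ...) {
  cat(sprintf("weights at t = %g: w_EE = %g, w_EI = %g (c_post_E = %g, c_post_I = %g)\n",
              x$t, x$w_EE, x$w_EI, x$c_post_E, x$c_post_I))
  invisible(x)
}

#' Time-varying drive specification
#'
#' Describes how one input quantity is modulated over time: the presynaptic
#' excitatory rate \code{rho_E}, an additive term \code{rho_add} on the
#' postsynaptic neuron, or the external drive \code{rho_I} onto the inhibitory
#' neurons.
#'
#' @param target one of \code{"rho_E"}, \code{"rho_add"}, \code{"rho_I"}.
#' @param kind \code{"constant"}, \code{"step"}, \code{"gaussian_noise"} or
#'   \code{"sinusoid"}.
#' @param value constant value (\code{kind = "constant"}).
#' @param rho_base,rho_disr,t_switch base value, disrupted value and switch
#'   time of a step (\code{kind = "step"}); the step is instantaneous and
#'   permanent.
#' @param mean,sd mean and standard deviation of per-step i.i.d. Gaussian
#'   noise (\code{kind = "gaussian_noise"}); no \code{sqrt(dt)} scaling is
#'   applied, matching the per-step construction of the model.
#' @param amplitude,omega,offset sinusoid \code{offset + amplitude *
#'   sin(omega * t)} (\code{kind = "sinusoid"}).
#' @return An object of class \code{"drive_spec"}.
#' @examples
#' drive_spec("rho_E", "step", rho_base = 2, rho_disr = 2.5, t_switch = 10)
#' drive_spec("rho_add", "sinusoid", amplitude = 0.25, omega = 0.01)
#' @export
drive_spec <- function(target = c("rho_E", "rho_add", "rho_I"),
                       kind = c("constant", "step", "gaussian_noise", "sinusoid"),
                       value = 0, rho_base = 0, rho_disr = 0, t_switch = 0,
                       mean = 0, sd = 0, amplitude = 0, omega = 0, offset = 0) {
  target <- match.arg(target)
  kind <- match.arg(kind)
  if (sd < 0) stop("noise sd must be >= 0", call. = FALSE)
  if (t_switch < 0) stop("step t_switch must be >= 0", call. = FALSE)
  structure(list(target = target, kind = kind, value = value,
                 rho_base = rho_base, rho_disr = rho_disr, t_switch = t_switch,
                 mean = mean, sd = sd,
                 amplitude = amplitude, omega = omega, offset = offset),
            class = "drive_spec")
}

#' Evaluate a drive at a time point
#'
#' Deterministic drives return their value at \code{t}; Gaussian-noise drives
#' draw one value per call from R's random number stream (so \code{set.seed}
#' controls reproducibility).
#'
#' @param drive a \code{\link{drive_spec}}.
#' @param t time.
#' @return scalar drive value.
#' @export
drive_value <- function(drive, t) {
  switch(drive$kind,
         constant = drive$value,
         step = if (t < drive$t_switch) drive$rho_base else drive$rho_disr,
         gaussian_noise = stats::rnorm(1, drive$mean, drive$sd),
         sinusoid = drive$offset + drive$amplitude * sin(drive$omega * t))
}

# resolve the three drive channels (rho_E, rho_add, rho_I) at time t given the
# baseline parameters and an optional drive_spec modulating one of them
resolve_drives <- function(params, drive, t) {
  out <- c(rho_E = params$rho_E, rho_add = 0, rho_I = params$rho_I)
  if (!is.null(drive)) out[[drive$target]] <- drive_value(drive, t)
  out
}
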