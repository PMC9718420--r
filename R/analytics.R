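# Closed-form theory of the coupled (w_EE, w_EI) dynamics: presynaptic
# LTD/LTP threshold, phase-plane lines, stability condition, Jacobian and
# E/I weight ratios. Throughout, the inhibitory rate at steady state is
# nu_I = [N_E rho_E w_IE + rho_I]_+ unless supplied explicitly.

steady_nu_I <- function(params, rho_E = params$rho_E, rho_I = params$rho_I) {
  rectify(params$N_E * rho_E * params$w_IE + rho_I)
}

phase_line <- function(kind, slope, intercept, abscissa_intercept = NA_real_) {
  structure(list(kind = kind, slope = slope, intercept = intercept,
                 abscissa_intercept = abscissa_intercept),
            class = "phase_line")
}

#' @export
print.phase_line <- function(x, ...) {
  cat(sprintf("%s line: w_EI = %g * w_EE %+g", x$kind, x$slope, x$intercept))
  if (is.finite(x$abscissa_intercept)) {
    cat(sprintf("  (crosses w_EI = 0 at w_EE = %g)", x$abscissa_intercept))
  }
  cat("\n")
  invisible(x)
}

#' Presynaptic LTD/LTP threshold
#'
#' The presynaptic excitatory rate at which excitatory plasticity changes sign
#' (no plasticity is induced), treating the inhibitory rate as given:
#' \deqn{c_{pre}^E = \frac{c_{post} + N^I \nu^I w^{EI}}{N^E w^{EE}}.}
#' Stronger inhibitory weights raise \eqn{c_{pre}^E}: more presynaptic drive is
#' then needed to induce LTP (a metaplastic shift).
#'
#' @param w_EE,w_EI current synaptic weights (\code{w_EE > 0}).
#' @param nu_I inhibitory rate (Hz), taken as given.
#' @param c_post postsynaptic LTD/LTP threshold (Hz).
#' @param N_E,N_I neuron counts.
#' @return A list of class \code{"analytic_report"} with \code{c_pre_E} and the
#'   echoed context parameters.
#' @seealso \code{\link{presynaptic_threshold_selfconsistent}} for the variant
#'   that solves for the input rate with \eqn{\nu^I} itself input-dependent.
#' @examples
#' presynaptic_threshold(1.5, 0.75, 1.5, 1)$c_pre_E  # ~1.4167
#' @export
presynaptic_threshold <- function(w_EE, w_EI, nu_I, c_post, N_E = 1, N_I = 1) {
  if (w_EE <= 0) {
    stop("presynaptic threshold undefined for w_EE = 0", call. = FALSE)
  }
  structure(list(c_pre_E = (c_post + N_I * nu_I * w_EI) / (N_E * w_EE),
                 w_EE = w_EE, w_EI = w_EI, nu_I = nu_I, c_post = c_post,
                 N_E = N_E, N_I = N_I),
            class = "analytic_report")
}

#' @export
print.analytic_report <- function(x, ...) {
  cat(sprintf("presynaptic LTD/LTP threshold c_pre_E = %g Hz\n", x$c_pre_E))
  invisible(x)
}

#' Self-consistent presynaptic LTD/LTP threshold
#'
#' Convenience extension of \code{\link{presynaptic_threshold}}: solves for the
#' presynaptic rate \eqn{\rho^E} at which plasticity vanishes while letting the
#' inhibitory rate follow its own steady state
#' \eqn{\nu^I = N^E \rho^E w^{IE} + \rho^I}, i.e. the rate at which
#' \eqn{\nu^E(\rho^E) = c_{post}}:
#' \deqn{c_{pre}^E = \frac{c_{post} + N^I \rho^I w^{EI}}
#'   {N^E (w^{EE} - N^I w^{IE} w^{EI})}.}
#'
#' @param params an \code{\link{ff_params}}.
#' @param weights a \code{\link{weight_state}}.
#' @param c_post postsynaptic LTD/LTP threshold (defaults to the threshold
#'   stored in \code{weights}).
#' @return An \code{"analytic_report"} as in
#'   \code{\link{presynaptic_threshold}}. Errors if the effective excitatory
#'   gain \eqn{w^{EE} - N^I w^{IE} w^{EI}} is not positive (then no finite
#'   positive crossing exists).
#' @export
presynaptic_threshold_selfconsistent <- function(params, weights,
                                                 c_post = weights$c_post_E) {
  gain <- weights$w_EE - params$N_I * params$w_IE * weights$w_EI
  if (gain <= 0) {
    stop("no positive presynaptic crossing: w_EE - N_I * w_IE * w_EI <= 0",
         call. = FALSE)
  }
  cpre <- (c_post + params$N_I * params$rho_I * weights$w_EI) /
    (params$N_E * gain)
  structure(list(c_pre_E = cpre, w_EE = weights$w_EE, w_EI = weights$w_EI,
                 nu_I = steady_nu_I(params, rho_E = cpre), c_post = c_post,
                 N_E = params$N_E, N_I = params$N_I),
            class = "analytic_report")
}

#' Line attractor of the coupled weight dynamics
#'
#' With equal LTD/LTP thresholds the nullclines of both weights coincide in a
#' line of fixed points in the \eqn{(w^{EE}, w^{EI})} plane:
#' \deqn{w^{EI} = \frac{N^E \rho^E}{N^I \nu^I} w^{EE} -
#'   \frac{c_{post} - \rho_{add}}{N^I \nu^I},}
#' with \eqn{\nu^I = N^E \rho^E w^{IE} + \rho^I}. An additive postsynaptic
#' drive \code{rho_add} shifts the intercept only, never the slope.
#'
#' @param params an \code{\link{ff_params}}.
#' @param c_post the common postsynaptic LTD/LTP threshold (Hz).
#' @param rho_add additive postsynaptic input (default 0).
#' @return A \code{"phase_line"} with \code{kind = "attractor"}, fields
#'   \code{slope}, \code{intercept} (w_EI-axis) and \code{abscissa_intercept}
#'   (w_EE where w_EI = 0).
#' @examples
#' line_attractor(ff_params(), c_post = 1)  # slope 4/3, abscissa intercept 0.5
#' @export
line_attractor <- function(params, c_post = 1, rho_add = 0) {
  nu_I <- steady_nu_I(params)
  if (nu_I <= 0) {
    stop("degenerate phase-plane geometry: steady-state nu_I = 0", call. = FALSE)
  }
  phase_line("attractor",
             slope = params$N_E * params$rho_E / (params$N_I * nu_I),
             intercept = -(c_post - rho_add) / (params$N_I * nu_I),
             abscissa_intercept = (c_post - rho_add) /
               (params$N_E * params$rho_E))
}

#' Zero-rate boundary
#'
#' The line through the origin above which total inhibition exceeds total
#' excitation, the postsynaptic rate is rectified to zero and (under the
#' nonlinear rules) all weight dynamics stop:
#' \eqn{w^{EI} = (N^E \rho^E / (N^I \nu^I)) \, w^{EE}}.
#' It shares its slope with the line attractor.
#'
#' @inheritParams line_attractor
#' @return A \code{"phase_line"} with \code{kind = "zero_rate"}.
#' @export
zero_rate_boundary <- function(params) {
  nu_I <- steady_nu_I(params)
  if (nu_I <= 0) {
    stop("degenerate phase-plane geometry: steady-state nu_I = 0", call. = FALSE)
  }
  phase_line("zero_rate",
             slope = params$N_E * params$rho_E / (params$N_I * nu_I),
             intercept = 0, abscissa_intercept = 0)
}

#' Separatrix of the linear inhibitory rule
#'
#' Under the linear inhibitory rule, initial weights below this line diverge
#' (Hebbian runaway) while initial weights above it converge to the line
#' attractor:
#' \deqn{w^{EI} = \frac{N^E \rho^E}{N^I \nu^I} w^{EE} -
#'   \frac{\nu^I \tau_w^E}{N^E (\rho^E)^2 \tau_w^I}.}
#'
#' @inheritParams line_attractor
#' @param plasticity a \code{\link{plasticity_params}} (its timescales are
#'   used; intended for \code{rule = "linear"}).
#' @return A \code{"phase_line"} with \code{kind = "separatrix"}.
#' @export
separatrix_linear_rule <- function(params, plasticity) {
  nu_I <- steady_nu_I(params)
  if (nu_I <= 0) {
    stop("degenerate phase-plane geometry: steady-state nu_I = 0", call. = FALSE)
  }
  offset <- nu_I * plasticity$tau_w_E /
    (params$N_E * params$rho_E^2 * plasticity$tau_w_I)
  slope <- params$N_E * params$rho_E / (params$N_I * nu_I)
  phase_line("separatrix", slope = slope, intercept = -offset,
             abscissa_intercept = offset / slope)
}

#' Evaluate a phase line at given w_EE values
#'
#' @param line a \code{"phase_line"}.
#' @param w_EE numeric vector of E-to-E weights.
#' @return the corresponding \code{w_EI} values.
#' @export
phase_line_at <- function(line, w_EE) line$slope * w_EE + line$intercept

#' Stability condition of the nonlinear-rule line attractor
#'
#' With the nonlinear inhibitory rule and equal thresholds, the line attractor
#' is stable iff inhibition dominates excitation:
#' \deqn{\frac{N^I (\nu^I)^2}{\tau_w^I} > \frac{N^E (\rho^E)^2}{\tau_w^E}.}
#' The Jacobian on the attractor has
#' \eqn{Tr(J^*) = (N^E (\rho^E)^2/\tau_w^E - N^I (\nu^I)^2/\tau_w^I)\,c_{post}},
#' \eqn{Det(J^*) = 0} and eigenvalues \eqn{\{Tr(J^*), 0\}} — marginal along the
#' attractor, contracting transverse to it when stable.
#'
#' @inheritParams separatrix_linear_rule
#' @param c_post common postsynaptic LTD/LTP threshold (defaults to
#'   \code{plasticity$c_post_I}).
#' @return A list of class \code{"stability_report"} with fields \code{lhs}
#'   (inhibitory side), \code{rhs} (excitatory side), \code{stable},
#'   \code{trace}, \code{det}, \code{eigenvalues}.
#' @examples
#' stability_condition(ff_params(), plasticity_params())  # lhs 11.25 > rhs 4
#' @export
stability_condition <- function(params, plasticity,
                                c_post = plasticity$c_post_I) {
  nu_I <- steady_nu_I(params)
  lhs <- params$N_I * nu_I^2 / plasticity$tau_w_I
  rhs <- params$N_E * params$rho_E^2 / plasticity$tau_w_E
  trace <- (rhs - lhs) * c_post
  structure(list(lhs = lhs, rhs = rhs, stable = lhs > rhs,
                 trace = trace, det = 0, eigenvalues = c(trace, 0),
                 nu_I = nu_I, c_post = c_post),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("inhibitory dominance: N_I nu_I^2 / tau_w_I = %g %s N_E rho_E^2 / tau_w_E = %g\n",
              x$lhs, if (x$stable) ">" else "<=", x$rhs))
  cat(sprintf("  => %s; Tr(J*) = %g, Det(J*) = 0, eigenvalues {%g, 0}\n",
              if (x$stable) "stable line attractor" else "unstable (runaway) dynamics",
              x$trace, x$trace))
  invisible(x)
}

# weight-derivative field with rates at their (feedforward) steady state,
# rectifier included; used by the numeric Jacobian and phase-portrait tooling
weight_field <- function(params, plasticity, w_EE, w_EI, c_post) {
  nu_I <- steady_nu_I(params)
  nu_E <- rectify(params$N_E * params$rho_E * w_EE -
                    params$N_I * nu_I * w_EI)
  c(dw_EE = dw_ee(params$rho_E, nu_E, c_post, plasticity$tau_w_E),
    dw_EI = dw_ei(plasticity, nu_I, nu_E, c_post))
}

#' Numerical Jacobian of the weight dynamics at a fixed point
#'
#' Central-difference Jacobian of \eqn{(\dot w^{EE}, \dot w^{EI})} (rates at
#' steady state, equal thresholds) at a point in the weight plane. Serves as
#' an independent check of \code{\link{stability_condition}}: on the line
#' attractor the determinant is zero and the eigenvalues are
#' \eqn{\{Tr(J^*), 0\}}. Points off the attractor (beyond \code{tol}) are
#' allowed — phase-portrait tooling needs them — but flagged with a warning
#' and \code{attr(, "on_attractor") = FALSE}.
#'
#' @inheritParams stability_condition
#' @param fixed_point a \code{\link{weight_state}} (or list with \code{w_EE},
#'   \code{w_EI}).
#' @param h central-difference step (default 1e-6).
#' @param tol attractor-membership tolerance, absolute in weight units.
#' @return A 2x2 matrix (rows: dw_EE, dw_EI; columns: d/dw_EE, d/dw_EI) with
#'   attribute \code{"on_attractor"}.
#' @export
jacobian_numeric <- function(params, plasticity, fixed_point,
                             c_post = plasticity$c_post_I,
                             h = 1e-6, tol = 1e-6) {
  att <- line_attractor(params, c_post = c_post)
  w0 <- c(fixed_point$w_EE, fixed_point$w_EI)
  resid <- abs(w0[2] - phase_line_at(att, w0[1]))
  on_att <- resid <= tol
  if (!on_att) {
    warning(sprintf("point is %.3g weight units off the line attractor", resid),
            call. = FALSE)
  }
  J <- matrix(NA_real_, 2, 2,
              dimnames = list(c("dw_EE", "dw_EI"), c("w_EE", "w_EI")))
  for (j in 1:2) {
    up <- w0; up[j] <- up[j] + h
    dn <- w0; dn[j] <- dn[j] - h
    J[, j] <- (weight_field(params, plasticity, up[1], up[2], c_post) -
                 weight_field(params, plasticity, dn[1], dn[2], c_post)) / (2 * h)
  }
  attr(J, "on_attractor") <- on_att
  J
}

#' Excitatory-to-inhibitory weight ratios at steady state
#'
#' On the line attractor the E/I weight ratio is
#' \deqn{R^{E/I} = \frac{w^{EE}}{w^{EI}} =
#'   \frac{N^I \nu^I w^{EI} + c_{post}}{N^E \rho^E w^{EI}},}
#' which for strong inhibitory weights approaches the lower bound
#' \eqn{R_\infty^{E/I} = N^I \nu^I / (N^E \rho^E)} — the slope of the line
#' attractor. In the large-\eqn{\rho^E} limit
#' \eqn{R_\infty^{E/I} \to (N^I/N^E)(\rho^I/\rho^E + w^{IE})}, i.e. for
#' \eqn{N^E = N^I} the ratio is bounded below by the fixed E-to-I weight
#' \eqn{w^{IE}}. The total-input ratio (excitatory over inhibitory input) is
#' \eqn{R_{tot}^{E/I} = (N^I \nu^I w^{EI} + c_{post})/(N^I \nu^I w^{EI})}.
#'
#' @inheritParams line_attractor
#' @param w_EI inhibitory-to-excitatory weight at which to evaluate the ratio
#'   (> 0).
#' @return A list of class \code{"ei_ratio_report"} with fields \code{R},
#'   \code{R_inf}, \code{R_large_rhoE}, \code{R_tot}.
#' @examples
#' ei_ratios(ff_params(), c_post = 1, w_EI = 2)$R_inf  # 0.75
#' @export
ei_ratios <- function(params, c_post = 1, w_EI) {
  if (w_EI <= 0) stop("E/I ratio undefined for w_EI <= 0", call. = FALSE)
  nu_I <- steady_nu_I(params)
  if (nu_I <= 0) stop("E/I ratio undefined for steady-state nu_I = 0", call. = FALSE)
  inh <- params$N_I * nu_I * w_EI
  structure(list(R = (inh + c_post) / (params$N_E * params$rho_E * w_EI),
                 R_inf = params$N_I * nu_I / (params$N_E * params$rho_E),
                 R_large_rhoE = (params$N_I / params$N_E) *
                   (params$rho_I / params$rho_E + params$w_IE),
                 R_tot = (inh + c_post) / inh,
                 nu_I = nu_I, w_EI = w_EI, c_post = c_post),
            class = "ei_ratio_report")
}

#' @export
print.ei_ratio_report <- function(x, ...) {
  cat(sprintf("E/I weight ratio R = %g at w_EI = %g (lower bound R_inf = %g)\n",
              x$R, x$w_EI, x$R_inf))
  cat(sprintf("  large-rho_E limit %g; total-input ratio R_tot = %g\n",
              x$R_large_rhoE, x$R_tot))
  invisible(x)
}

#' Sampled phase-plane vector field
#'
#' Evaluates the weight-derivative field on a grid, for phase-portrait
#' plotting alongside the three analytic lines.
#'
#' @inheritParams stability_condition
#' @param w_EE,w_EI numeric vectors defining the grid.
#' @return A data.frame with columns \code{w_EE}, \code{w_EI}, \code{dw_EE},
#'   \code{dw_EI}.
#' @export
phase_field <- function(params, plasticity, w_EE = seq(0, 3, by = 0.25),
                        w_EI = seq(0, 3, by = 0.25),
                        c_post = plasticity$c_post_I) {
  grid <- expand.grid(w_EE = w_EE, w_EI = w_EI)
  f <- t(mapply(function(a, b) weight_field(params, plasticity, a, b, c_post),
                grid$w_EE, grid$w_EI))
  cbind(grid, dw_EE = f[, 1], dw_EI = f[, 2])
}
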