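# Single-postsynaptic-neuron experiments: input-rate perturbation, plasticity
# induction from random weights (E/I-ratio protocol), varying drive, and the
# feedback-motif stability map.

#' Input-rate perturbation experiment
#'
#' Converges the motif at a baseline presynaptic rate, applies an
#' instantaneous and permanent step of \eqn{\rho^E}, and integrates to the new
#' steady state. The nonlinear inhibitory rule returns the postsynaptic rate
#' to the target while both weights potentiate (upward step) or depress
#' (downward step), and the presynaptic LTD/LTP threshold shifts in the
#' direction of the perturbation.
#'
#' @inheritParams run_feedforward
#' @param rho_base,rho_disr baseline and disrupted presynaptic rates (Hz).
#' @param tol run-in/run-out convergence tolerance on \code{max|dw|} per unit
#'   time.
#' @param max_T horizon for each phase.
#' @return A list of class \code{"perturbation_result"}: \code{$before} and
#'   \code{$after} (each: weights, rates, \code{c_pre_E}, line attractor),
#'   \code{$delta} (weight changes and their signs), and the two trajectories.
#' @examples
#' \donttest{
#' pe <- perturbation_experiment(ff_params(), plasticity_params(),
#'                               rho_base = 2, rho_disr = 2.5)
#' pe$after$rates$nu_E   # back at the target rate
#' }
#' @export
perturbation_experiment <- function(params, plasticity,
                                    rho_base = 2, rho_disr,
                                    init = weight_state(1.5, 0.5,
                                                        plasticity$c_post_E,
                                                        plasticity$c_post_I),
                                    tol = 1e-8, max_T = 2000, guard = 1e6) {
  p_base <- params; p_base$rho_E <- rho_base
  run_in <- run_to_convergence(p_base, plasticity, init, tol = tol,
                               max_T = max_T, guard = guard)
  if (run_in$diverged || !run_in$converged) {
    stop("run-in did not converge at the baseline rate", call. = FALSE)
  }
  snap <- function(p, traj) {
    w <- traj$final
    list(weights = w, rates = traj$rates,
         c_pre_E = presynaptic_threshold(w$w_EE, w$w_EI, traj$rates$nu_I,
                                         w$c_post_E, p$N_E, p$N_I)$c_pre_E,
         attractor = line_attractor(p, c_post = w$c_post_I))
  }
  before <- snap(p_base, run_in)

  p_disr <- params; p_disr$rho_E <- rho_disr
  run_out <- run_to_convergence(p_disr, plasticity, run_in$final, tol = tol,
                                max_T = max_T, guard = guard)
  after <- snap(p_disr, run_out)

  d_ee <- after$weights$w_EE - before$weights$w_EE
  d_ei <- after$weights$w_EI - before$weights$w_EI
  structure(list(before = before, after = after,
                 delta = list(w_EE = d_ee, w_EI = d_ei,
                              sign_w_EE = sign(round(d_ee, 10)),
                              sign_w_EI = sign(round(d_ei, 10)),
                              rho = rho_disr - rho_base),
                 run_in = run_in, run_out = run_out,
                 rho_base = rho_base, rho_disr = rho_disr),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("presynaptic rate step %g -> %g Hz\n", x$rho_base, x$rho_disr))
  cat(sprintf("  nu_E: %.4g -> %.4g Hz (target %g); nu_I: %.4g -> %.4g Hz\n",
              x$before$rates$nu_E, x$after$rates$nu_E,
              x$after$weights$c_post_I,
              x$before$rates$nu_I, x$after$rates$nu_I))
  cat(sprintf("  w_EE: %.4g -> %.4g; w_EI: %.4g -> %.4g\n",
              x$before$weights$w_EE, x$after$weights$w_EE,
              x$before$weights$w_EI, x$after$weights$w_EI))
  cat(sprintf("  presynaptic LTD/LTP threshold c_pre_E: %.4g -> %.4g Hz\n",
              x$before$c_pre_E, x$after$c_pre_E))
  invisible(x)
}

#' Plasticity-induction experiment over random initial weights
#'
#' Draws initial weight pairs uniformly from \code{weight_range}, drops draws
#' with extreme initial E/I ratio (\code{R_before > exclusion_ratio}), induces
#' excitatory and (nonlinear) inhibitory plasticity for a brief
#' \code{induction_time}, and records E/I ratios and percent weight changes.
#' All draws share the dynamics, so the induction is integrated vectorized
#' across draws.
#'
#' @inheritParams run_feedforward
#' @param n_draws number of random initial weight configurations (>= 1).
#' @param induction_time induction duration (default 0.1 time units, the
#'   100 ms protocol).
#' @param weight_range range of the uniform initial-weight distribution.
#' @param exclusion_ratio draws with \code{w_EE/w_EI} above this are dropped
#'   before induction (default 12).
#' @param dt Euler step for the induction (default 1e-3 so the 100 ms
#'   induction is resolved by 100 steps).
#' @param seed optional integer seed.
#' @return A data.frame of class \code{"ei_induction"} with columns
#'   \code{w_EE_0}, \code{w_EI_0}, \code{R_before}, \code{R_after},
#'   \code{dw_EE_pct}, \code{dw_EI_pct}, plus attributes \code{R_inf} and
#'   \code{n_excluded}.
#' @export
ei_induction_experiment <- function(params, plasticity, n_draws = 200,
                                    induction_time = 0.1,
                                    weight_range = c(0, 3),
                                    exclusion_ratio = 12,
                                    dt = 1e-3, seed = NULL) {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  w_ee <- stats::runif(n_draws, weight_range[1], weight_range[2])
  w_ei <- stats::runif(n_draws, weight_range[1], weight_range[2])
  r0 <- w_ee / w_ei
  keep <- is.finite(r0) & r0 <= exclusion_ratio & w_ei > 0 & w_ee > 0
  w_ee0 <- w_ee[keep]; w_ei0 <- w_ei[keep]
  nu_I <- steady_nu_I(params)
  cE <- plasticity$c_post_E; cI <- plasticity$c_post_I

  ee <- w_ee0; ei <- w_ei0
  n_steps <- round(induction_time / dt)
  for (i in seq_len(n_steps)) {
    nu_E <- rectify(params$N_E * params$rho_E * ee - params$N_I * nu_I * ei)
    ee <- pmax(ee + dt * dw_ee(params$rho_E, nu_E, cE, plasticity$tau_w_E),
               plasticity$weight_floor)
    ei <- pmax(ei + dt * dw_ei(plasticity, nu_I, nu_E, cI),
               plasticity$weight_floor)
  }
  out <- data.frame(w_EE_0 = w_ee0, w_EI_0 = w_ei0,
                    R_before = w_ee0 / w_ei0, R_after = ee / ei,
                    dw_EE_pct = 100 * (ee - w_ee0) / w_ee0,
                    dw_EI_pct = 100 * (ei - w_ei0) / w_ei0)
  attr(out, "R_inf") <- ei_ratios(params, c_post = cI, w_EI = 1)$R_inf
  attr(out, "n_excluded") <- sum(!keep)
  class(out) <- c("ei_induction", class(out))
  out
}

#' Varying-drive experiment
#'
#' Runs the motif under a noisy or sinusoidal drive and summarizes drift:
#' ordinary-least-squares slopes of both weights over the final half of the
#' recorded samples plus mean and variance of the postsynaptic rate. Additive
#' postsynaptic variability only shifts the line attractor's intercept, so
#' weights stay in a bounded band (near-zero drift); varying the presynaptic
#' rate changes the attractor's slope and produces a slow weight drift.
#'
#' @inheritParams run_feedforward
#' @param drive a \code{\link{drive_spec}} of kind \code{"gaussian_noise"} or
#'   \code{"sinusoid"} (a zero-amplitude/zero-sd drive reduces to the constant
#'   baseline).
#' @return A list of class \code{"drive_result"}: \code{$trajectory} (an
#'   \code{"eiplast_traj"}) and \code{$drift} with \code{slope_w_EE},
#'   \code{slope_w_EI}, \code{nu_E_mean}, \code{nu_E_var}.
#' @export
varying_drive_experiment <- function(params, plasticity, drive,
                                     init = weight_state(1.5, 0.5,
                                                         plasticity$c_post_E,
                                                         plasticity$c_post_I),
                                     T = 3000, record_every = NULL,
                                     guard = 1e6) {
  if (!drive$kind %in% c("gaussian_noise", "sinusoid", "constant")) {
    stop("drive kind must be gaussian_noise, sinusoid or constant",
         call. = FALSE)
  }
  traj <- run_feedforward(params, plasticity, init, drive = drive, T = T,
                          record_every = record_every, guard = guard)
  tr <- traj$trajectory
  half <- tr[tr$t >= (tr$t[1] + traj$final$t) / 2, , drop = FALSE]
  ols_slope <- function(y) {
    if (nrow(half) < 3) return(NA_real_)
    unname(stats::coef(stats::lm(y ~ half$t))[2])
  }
  structure(list(trajectory = traj,
                 drift = list(slope_w_EE = ols_slope(half$w_EE),
                              slope_w_EI = ols_slope(half$w_EI),
                              nu_E_mean = mean(half$nu_E),
                              nu_E_var = stats::var(half$nu_E))),
            class = "drive_result")
}

#' @export
print.drive_result <- function(x, ...) {
  d <- x$drift
  cat("varying-drive run\n")
  cat(sprintf("  drift slopes (final half): w_EE %.3g, w_EI %.3g per unit time\n",
              d$slope_w_EE, d$slope_w_EI))
  cat(sprintf("  nu_E over final half: mean %.4g Hz, var %.3g\n",
              d$nu_E_mean, d$nu_E_var))
  invisible(x)
}

#' Stability map of the feedback inhibitory motif
#'
#' Adds a feedback connection from the postsynaptic excitatory neuron onto the
#' inhibitory population (\eqn{\tau_{FR}^I \dot\nu^I = -\nu^I + [N^E \rho^E
#' w_{FF}^{IE} + w_{FB}^{IE} \nu^E + \rho^I]_+}) and classifies each point of a
#' (feedforward, feedback) weight grid as stable or divergent by simulation
#' with the divergence guard. Sufficiently strong feedforward and feedback
#' E-to-I weights guarantee stability.
#'
#' @inheritParams run_feedforward
#' @param w_ff_grid,w_fb_grid numeric vectors of feedforward and feedback
#'   E-to-I weights.
#' @return A logical matrix (\code{TRUE} = stable) with feedforward weights in
#'   rows and feedback weights in columns, class \code{"stability_map"}.
#' @export
feedback_motif_stability_map <- function(params, plasticity,
                                         w_ff_grid = seq(0, 1, by = 0.2),
                                         w_fb_grid = seq(0, 1, by = 0.2),
                                         init = weight_state(1.5, 0.5,
                                                             plasticity$c_post_E,
                                                             plasticity$c_post_I),
                                         T = 200, guard = 1e6) {
  stable <- matrix(NA, length(w_ff_grid), length(w_fb_grid),
                   dimnames = list(w_FF_IE = signif(w_ff_grid, 4),
                                   w_FB_IE = signif(w_fb_grid, 4)))
  for (i in seq_along(w_ff_grid)) {
    for (j in seq_along(w_fb_grid)) {
      p <- params
      p$w_IE <- w_ff_grid[i]
      p$w_FB_IE <- w_fb_grid[j]
      tr <- run_feedforward(p, plasticity, init, T = T, guard = guard,
                            record_every = 1000L)
      stable[i, j] <- !tr$diverged
    }
  }
  structure(stable, class = c("stability_map", "matrix"))
}

#' Seeded random-parameter stability sweep
#'
#' Draws random circuit/plasticity parameter sets, discards draws within
#' \code{margin} (relative) of the inhibitory-dominance boundary, and compares
#' the closed-form stability prediction with simulated divergence under the
#' guard.
#'
#' @inheritParams run_feedforward
#' @param n_draws number of random parameter draws.
#' @param seed integer seed.
#' @param margin relative distance from the boundary \code{lhs = rhs} below
#'   which draws are discarded (default 0.1).
#' @return A data.frame with the drawn parameters, \code{predicted_stable},
#'   \code{simulated_stable} and \code{agree}.
#' @export
stability_sweep <- function(n_draws = 50, seed = 1, margin = 0.1,
                            T = 300, guard = 1e6) {
  set.seed(seed)
  rows <- vector("list", n_draws)
  n_kept <- 0
  while (n_kept < n_draws) {
    rho_E <- stats::runif(1, 0.5, 3)
    rho_I <- stats::runif(1, 0, 1)
    w_IE <- stats::runif(1, 0.1, 1)
    tau_w_E <- stats::runif(1, 0.5, 2)
    tau_w_I <- stats::runif(1, 0.1, 0.5)
    p <- ff_params(rho_E = rho_E, rho_I = rho_I, w_IE = w_IE,
                   tau_FR_E = 1e-3, tau_FR_I = 1e-3, dt = 1e-3)
    pl <- plasticity_params(tau_w_E = tau_w_E, tau_w_I = tau_w_I)
    rep <- stability_condition(p, pl)
    if (abs(rep$lhs / rep$rhs - 1) < margin) next
    n_kept <- n_kept + 1
    # start with the postsynaptic neuron firing above threshold (nu_E = 2c),
    # the regime in which unstable draws actually run away
    cpost <- pl$c_post_I
    nu_I <- rep$nu_I
    w_EE0 <- 3 * cpost / (p$N_E * p$rho_E)
    w_EI0 <- cpost / (p$N_I * nu_I)
    tr <- run_feedforward(p, pl, weight_state(w_EE0, w_EI0), T = T,
                          guard = guard, record_every = 1000L)
    rows[[n_kept]] <- data.frame(rho_E = rho_E, rho_I = rho_I, w_IE = w_IE,
                                 tau_w_E = tau_w_E, tau_w_I = tau_w_I,
                                 lhs = rep$lhs, rhs = rep$rhs,
                                 predicted_stable = rep$stable,
                                 simulated_stable = !tr$diverged)
  }
  out <- do.call(rbind, rows)
  out$agree <- out$predicted_stable == out$simulated_stable
  out
}
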