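# Feedforward-motif simulation: thin R wrapper around the compiled Euler loop.

drive_target_code <- c(rho_E = 1L, rho_add = 2L, rho_I = 3L)
drive_kind_code <- c(constant = 0L, step = 1L, gaussian_noise = 2L,
                     sinusoid = 3L)

encode_drive <- function(drive) {
  if (is.null(drive)) {
    return(list(target = 0L, kind = 0L, par = numeric(9)))
  }
  list(target = drive_target_code[[drive$target]],
       kind = drive_kind_code[[drive$kind]],
       par = c(drive$value, drive$rho_base, drive$rho_disr, drive$t_switch,
               drive$mean, drive$sd, drive$amplitude, drive$omega,
               drive$offset))
}

make_trajectory <- function(res, params, plasticity, drive) {
  tr <- as.data.frame(res$trajectory)
  names(tr) <- c("t", "nu_E", "nu_I", "w_EE", "w_EI", "c_post_E", "c_post_I")
  structure(list(trajectory = tr,
                 final = weight_state(res$w_EE, res$w_EI,
                                      max(res$c_post_E, .threshold_eps),
                                      max(res$c_post_I, .threshold_eps),
                                      t = res$t),
                 rates = structure(list(nu_E = res$nu_E, nu_I = res$nu_I),
                                   class = "rate_state"),
                 diverged = res$diverged, converged = res$converged,
                 t_event = res$t_event,
                 params = params, plasticity = plasticity, drive = drive),
            class = "eiplast_traj")
}

#' Simulate the plastic feedforward motif
#'
#' Integrates the rate equations together with the excitatory rule and the
#' selected inhibitory plasticity rule (and, optionally, the sliding LTD/LTP
#' thresholds) by explicit Euler steps of \code{params$dt}. Weight blow-up is
#' detected by a divergence guard and reported as a flag, not an error.
#'
#' @param params an \code{\link{ff_params}}.
#' @param plasticity a \code{\link{plasticity_params}}.
#' @param init initial \code{\link{weight_state}}.
#' @param drive optional \code{\link{drive_spec}}; \code{NULL} means constant
#'   baseline inputs from \code{params}.
#' @param T simulated duration (time units).
#' @param record_every record every k-th step (default: about 2000 rows).
#' @param guard divergence guard on the weights (default 1e6).
#' @param conv_tol if > 0, stop early once both weight-change rates fall below
#'   this magnitude (per unit time).
#' @return An object of class \code{"eiplast_traj"}: list with
#'   \code{$trajectory} (data.frame t, nu_E, nu_I, w_EE, w_EI, c_post_E,
#'   c_post_I), \code{$final} (terminal \code{weight_state}), \code{$rates},
#'   logical \code{$diverged} / \code{$converged} and \code{$t_event}.
#' @examples
#' tr <- run_feedforward(ff_params(), plasticity_params(),
#'                       weight_state(1.5, 0.5), T = 50)
#' tr$final; tr$rates
#' @export
run_feedforward <- function(params, plasticity,
                            init = weight_state(1.5, 0.5,
                                                plasticity$c_post_E,
                                                plasticity$c_post_I),
                            drive = NULL, T = 100,
                            record_every = NULL, guard = 1e6, conv_tol = 0) {
  if (params$dt > params$tau_FR_E || params$dt > params$tau_FR_I) {
    stop("dt exceeds a rate time constant (explicit Euler unstable)",
         call. = FALSE)
  }
  n_steps <- round(T / params$dt)
  if (is.null(record_every)) record_every <- max(1L, ceiling(n_steps / 2000))
  d <- encode_drive(drive)
  res <- cpp_sim_feedforward(
    params$N_E, params$N_I, params$rho_E, params$rho_I, params$w_IE,
    params$tau_FR_E, params$tau_FR_I, params$dt, params$w_FB_IE,
    plasticity$tau_w_E, plasticity$tau_w_I,
    as.integer(plasticity$rule == "nonlinear"),
    as.integer(plasticity$dynamic_thresholds),
    plasticity$tau_c, plasticity$weight_floor,
    init$w_EE, init$w_EI, init$c_post_E, init$c_post_I, init$t,
    d$target, d$kind, d$par,
    T, as.integer(record_every), guard, conv_tol, .threshold_eps)
  make_trajectory(res, params, plasticity, drive)
}

#' Run the feedforward motif to weight convergence
#'
#' Repeatedly extends a \code{\link{run_feedforward}} simulation until both
#' weight-change rates are below \code{tol} per unit time (the operational
#' meaning of "at steady state"), divergence is flagged, or \code{max_T} is
#' reached.
#'
#' @inheritParams run_feedforward
#' @param tol convergence tolerance on \code{max(|dw_EE/dt|, |dw_EI/dt|)}
#'   (default 1e-8).
#' @param max_T giving-up horizon.
#' @return An \code{"eiplast_traj"} whose \code{$converged} says whether the
#'   criterion was met.
#' @export
run_to_convergence <- function(params, plasticity,
                               init = weight_state(1.5, 0.5,
                                                   plasticity$c_post_E,
                                                   plasticity$c_post_I),
                               drive = NULL, tol = 1e-8, max_T = 1000,
                               guard = 1e6) {
  run_feedforward(params, plasticity, init, drive = drive, T = max_T,
                  guard = guard, conv_tol = tol)
}

#' @export
print.eiplast_traj <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("E/I plasticity trajectory: %d recorded steps over t in [%g, %g]\n",
              nrow(tr), tr$t[1], x$final$t))
  cat(sprintf("  rule: %s inhibitory plasticity%s\n", x$plasticity$rule,
              if (x$plasticity$dynamic_thresholds) ", dynamic thresholds" else ""))
  if (x$diverged) {
    cat(sprintf("  DIVERGED at t = %g (weights ran away)\n", x$t_event))
  } else {
    cat(sprintf("  final: w_EE = %.4g, w_EI = %.4g, nu_E = %.4g Hz, nu_I = %.4g Hz%s\n",
                x$final$w_EE, x$final$w_EI, x$rates$nu_E, x$rates$nu_I,
                if (x$converged) sprintf(" (converged at t = %g)", x$t_event) else ""))
  }
  invisible(x)
}

#' @export
summary.eiplast_traj <- function(object, ...) {
  tr <- object$trajectory
  half <- tr[tr$t >= stats::median(tr$t), , drop = FALSE]
  att <- tryCatch(line_attractor(object$params,
                                 c_post = object$final$c_post_I),
                  error = function(e) NULL)
  out <- list(diverged = object$diverged, converged = object$converged,
              t_end = object$final$t,
              final = object$final, rates = object$rates,
              nu_E_mean_final_half = mean(half$nu_E),
              nu_E_var_final_half = stats::var(half$nu_E),
              attractor_residual = if (is.null(att)) NA_real_ else
                object$final$w_EI - phase_line_at(att, object$final$w_EE))
  class(out) <- "summary.eiplast_traj"
  out
}

#' @export
print.summary.eiplast_traj <- function(x, ...) {
  cat(sprintf("diverged: %s; converged: %s; t_end = %g\n",
              x$diverged, x$converged, x$t_end))
  print(x$final)
  print(x$rates)
  cat(sprintf("final-half nu_E: mean %.4g Hz, var %.3g\n",
              x$nu_E_mean_final_half, x$nu_E_var_final_half))
  if (is.finite(x$attractor_residual)) {
    cat(sprintf("distance of final point from line attractor: %.3g\n",
                x$attractor_residual))
  }
  invisible(x)
}

#' @export
as.data.frame.eiplast_traj <- function(x, ...) x$trajectory

#' Plot a simulated trajectory
#'
#' Two stacked panels: synaptic weights and population rates against time.
#'
#' @param x an \code{"eiplast_traj"}.
#' @param ... passed to \code{matplot}.
#' @export
plot.eiplast_traj <- function(x, ...) {
  tr <- x$trajectory
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::matplot(tr$t, cbind(tr$w_EE, tr$w_EI), type = "l", lty = 1,
                    col = c("steelblue", "firebrick"),
                    xlab = "time", ylab = "weight", ...)
  graphics::legend("topleft", c("w_EE", "w_EI"), lty = 1, bty = "n",
                   col = c("steelblue", "firebrick"))
  graphics::matplot(tr$t, cbind(tr$nu_E, tr$nu_I), type = "l", lty = 1,
                    col = c("gray30", "gray60"),
                    xlab = "time", ylab = "rate (Hz)")
  graphics::legend("topright", c("nu_E", "nu_I"), lty = 1, bty = "n",
                   col = c("gray30", "gray60"))
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Columns: t, nu_E, nu_I, w_EE, w_EI, c_post_E, c_post_I.
#'
#' @param x an \code{"eiplast_traj"}.
#' @param path output file.
#' @export
write_trajectory <- function(x, path) {
  utils::write.csv(x$trajectory, path, row.names = FALSE)
  invisible(path)
}
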