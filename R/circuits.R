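# Multi-input feedforward circuit with input-specific and unspecific
# inhibition, disinhibition-gated receptive-field formation, and the
# recurrently connected 30-neuron network.

#' Multi-input circuit parameters
#'
#' Configuration of the receptive-field circuit: \code{n_inputs} input
#' patterns, each defined by \code{pattern_size} presynaptic excitatory
#' neurons firing at \code{pattern_rate_hi} for \code{pattern_duration} while
#' the remaining neurons fire at \code{rho_E_base}. Ten input-specific
#' inhibitory populations (\code{n_spec_per_pop} neurons each, wired only to
#' their own pattern's presynaptic neurons) and one unspecific population
#' (\code{N_unsp_I} neurons, wired to all presynaptic neurons) inhibit the
#' postsynaptic neuron(s). Disinhibition is a negative external drive of
#' \code{disinhibition_magnitude} onto one class of inhibitory populations for
#' \code{disinhibition_duration}; for the specific class its release is a
#' linear ramp over \code{release_ramp}. \code{w_fb_spec_IE}/
#' \code{w_fb_unsp_IE} are feedback weights from the postsynaptic excitatory
#' neuron(s) onto the inhibitory populations (used in the recurrent run).
#'
#' @param n_inputs number of input patterns (default 10).
#' @param pattern_size presynaptic neurons per pattern (default 4); the
#'   presynaptic pool has \code{n_inputs * pattern_size} neurons.
#' @param pattern_rate_hi active-pattern rate (Hz, default 4).
#' @param rho_E_base background presynaptic rate (Hz, default 1).
#' @param pattern_duration duration of one pattern presentation (default 0.1
#'   time units, the 100 ms protocol).
#' @param N_spec_I,N_unsp_I total specific / unspecific inhibitory neurons
#'   (defaults 20 and 20; specific neurons are split evenly over the inputs).
#' @param w_spec_IE,w_unsp_IE fixed feedforward E-to-I weights (defaults 0.2
#'   and 0.02).
#' @param w_fb_spec_IE,w_fb_unsp_IE feedback E-to-I weights (defaults 0).
#' @param rho_spec_I,rho_unsp_I baseline external drives onto the inhibitory
#'   classes (Hz, defaults 0).
#' @param disinhibition_magnitude negative drive applied during disinhibition
#'   (default -2).
#' @param disinhibition_duration duration of the disinhibition window
#'   (default 60).
#' @param release_ramp duration of the gradual release ramp for specific
#'   disinhibition (default 100).
#' @param w0_EE,w0_spec_EI,w0_unsp_EI initial feedforward weights (defaults
#'   0.03, 0.01, 0.01).
#' @param tau_w_E,tau_w_I plasticity timescales (defaults 1 and 0.2).
#' @param c_post_E,c_post_I LTD/LTP thresholds (defaults 1 and 1).
#' @param dt Euler step; rates use instantaneous integrators
#'   (\code{tau_FR = dt}, default 1e-4).
#' @return An object of class \code{"multi_input_params"}.
#' @export
multi_input_params <- function(n_inputs = 10, pattern_size = 4,
                               pattern_rate_hi = 4, rho_E_base = 1,
                               pattern_duration = 0.1,
                               N_spec_I = 20, N_unsp_I = 20,
                               w_spec_IE = 0.2, w_unsp_IE = 0.02,
                               w_fb_spec_IE = 0, w_fb_unsp_IE = 0,
                               rho_spec_I = 0, rho_unsp_I = 0,
                               disinhibition_magnitude = -2,
                               disinhibition_duration = 60,
                               release_ramp = 100,
                               w0_EE = 0.03, w0_spec_EI = 0.01,
                               w0_unsp_EI = 0.01,
                               tau_w_E = 1, tau_w_I = 0.2,
                               c_post_E = 1, c_post_I = 1,
                               dt = 1e-4) {
  stopifnot(n_inputs >= 1, pattern_size >= 1, N_spec_I >= 1, N_unsp_I >= 1)
  if (N_spec_I %% n_inputs != 0) {
    stop("N_spec_I must be divisible by n_inputs (even split of specific ",
         "inhibitory neurons over inputs)", call. = FALSE)
  }
  if (pattern_duration <= 0 || dt <= 0 || disinhibition_duration <= 0 ||
      release_ramp <= 0) {
    stop("durations and dt must be > 0", call. = FALSE)
  }
  structure(list(n_inputs = n_inputs, pattern_size = pattern_size,
                 n_pre_E = n_inputs * pattern_size,
                 pattern_rate_hi = pattern_rate_hi, rho_E_base = rho_E_base,
                 pattern_duration = pattern_duration,
                 N_spec_I = N_spec_I, N_unsp_I = N_unsp_I,
                 n_spec_per_pop = N_spec_I %/% n_inputs,
                 w_spec_IE = w_spec_IE, w_unsp_IE = w_unsp_IE,
                 w_fb_spec_IE = w_fb_spec_IE, w_fb_unsp_IE = w_fb_unsp_IE,
                 rho_spec_I = rho_spec_I, rho_unsp_I = rho_unsp_I,
                 disinhibition_magnitude = disinhibition_magnitude,
                 disinhibition_duration = disinhibition_duration,
                 release_ramp = release_ramp,
                 w0_EE = w0_EE, w0_spec_EI = w0_spec_EI,
                 w0_unsp_EI = w0_unsp_EI,
                 tau_w_E = tau_w_E, tau_w_I = tau_w_I,
                 c_post_E = c_post_E, c_post_I = c_post_I, dt = dt),
            class = "multi_input_params")
}

#' Recurrent network parameters
#'
#' @param n_post number of recurrently connected excitatory neurons (default
#'   30).
#' @param w_rec_init_range recurrent weights are drawn uniformly from this
#'   interval (default [0, 0.018], i.e. below the display threshold; a range
#'   ten times wider gives the all-to-all network a recurrent gain above one
#'   and the threshold-linear rates diverge before any plasticity can act).
#' @param pattern_correlation probability that a neuron's pattern in a given
#'   window equals the shared network-wide pattern (1 = fully shared
#'   sequences, 0 = independent sequences; default 0.5). Fully shared
#'   sequences with identical initial feedforward weights make all neurons
#'   adopt the same preferred input (a single assembly); partial correlation
#'   lets different neurons win different inputs while keeping co-tuned
#'   neurons co-active.
#' @param display_threshold recurrent weights below this are zeroed in the
#'   reported adjacency (default 0.03).
#' @param tau_w_rec recurrent plasticity timescale (default 10: recurrent
#'   potentiation slower than the feedforward rule, so that inhibitory
#'   plasticity keeps its dominance margin over the combined feedforward plus
#'   recurrent excitatory plasticity).
#' @param w_rec_max upper bound on recurrent weights (default 0.1). Unlike
#'   the feedforward weights, recurrent weights among co-tuned neurons see
#'   correlated pre- and postsynaptic activity that input-specific inhibition
#'   does not cancel, so without a bound an assembly's recurrent gain
#'   eventually exceeds one and the rates run away.
#' @return An object of class \code{"recurrent_params"}.
#' @export
recurrent_params <- function(n_post = 30, w_rec_init_range = c(0, 0.018),
                             pattern_correlation = 0.5,
                             display_threshold = 0.03, tau_w_rec = 10,
                             w_rec_max = 0.1) {
  stopifnot(n_post >= 2, w_rec_init_range[1] >= 0,
            w_rec_init_range[2] >= w_rec_init_range[1],
            pattern_correlation >= 0, pattern_correlation <= 1,
            w_rec_max > 0)
  structure(list(n_post = n_post, w_rec_init_range = w_rec_init_range,
                 pattern_correlation = pattern_correlation,
                 display_threshold = display_threshold,
                 tau_w_rec = tau_w_rec, w_rec_max = w_rec_max),
            class = "recurrent_params")
}

#' Random input-pattern sequence
#'
#' In each window of \code{pattern_duration}, one pattern is chosen uniformly
#' at random; its \code{pattern_size} presynaptic neurons fire at the high
#' rate while all others fire at the background rate. Seeded and
#' reproducible.
#'
#' @param params a \code{\link{multi_input_params}}.
#' @param n_windows number of pattern windows.
#' @param seed optional integer seed.
#' @param n_post number of postsynaptic neurons (independent columns);
#'   correlation across columns is applied by the caller.
#' @param expand if \code{TRUE}, also return the full per-window rate matrix
#'   (\code{n_windows x n_pre_E}) for \code{n_post = 1}.
#' @return A list with \code{$pattern} (integer matrix, \code{n_windows x
#'   n_post}, values in \code{1..n_inputs}) and, if requested, \code{$rates}.
#' @export
pattern_sequence <- function(params, n_windows, seed = NULL, n_post = 1,
                             expand = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  pat <- matrix(sample.int(params$n_inputs, n_windows * n_post,
                           replace = TRUE),
                nrow = n_windows, ncol = n_post)
  out <- list(pattern = pat)
  if (expand && n_post == 1) {
    rates <- matrix(params$rho_E_base, n_windows, params$n_pre_E)
    for (w in seq_len(n_windows)) {
      idx <- (pat[w, 1] - 1) * params$pattern_size + seq_len(params$pattern_size)
      rates[w, idx] <- params$pattern_rate_hi
    }
    out$rates <- rates
  }
  out
}

# correlated per-neuron pattern sequences: each neuron follows the shared
# sequence with probability `correlation`, otherwise redraws independently
correlated_patterns <- function(params, n_windows, n_post, correlation) {
  shared <- sample.int(params$n_inputs, n_windows, replace = TRUE)
  pat <- matrix(shared, n_windows, n_post)
  if (correlation < 1 && n_post > 1) {
    redraw <- matrix(stats::runif(n_windows * n_post) > correlation,
                     n_windows, n_post)
    pat[redraw] <- sample.int(params$n_inputs, sum(redraw), replace = TRUE)
  }
  pat
}

multi_protocol_times <- function(params, disinhibit, T_baseline, T_post) {
  t_on <- T_baseline
  t_off <- t_on + params$disinhibition_duration
  t_ramp_end <- if (disinhibit == "specific") t_off + params$release_ramp
                else t_off
  total <- t_ramp_end + T_post
  list(t_on = t_on, t_off = t_off, t_ramp_end = t_ramp_end, total = total)
}

run_multi_core <- function(params, plasticity = NULL, rec = NULL,
                           disinhibit, T_baseline, T_post, seed,
                           guard, record_every) {
  steps_per_window <- round(params$pattern_duration / params$dt)
  pt <- multi_protocol_times(params, disinhibit, T_baseline, T_post)
  n_windows <- ceiling(pt$total / params$pattern_duration)
  recurrent <- !is.null(rec)
  n_post <- if (recurrent) rec$n_post else 1L

  if (!is.null(seed)) set.seed(seed)
  pat <- if (recurrent) {
    correlated_patterns(params, n_windows, n_post, rec$pattern_correlation)
  } else {
    matrix(sample.int(params$n_inputs, n_windows, replace = TRUE),
           ncol = 1)
  }
  W_rec <- if (recurrent) {
    W <- matrix(stats::runif(n_post^2, rec$w_rec_init_range[1],
                             rec$w_rec_init_range[2]), n_post, n_post)
    diag(W) <- 0
    W
  } else {
    matrix(0, 1, 1)
  }

  dis_code <- c(none = 0L, specific = 1L, unspecific = 2L)[[disinhibit]]
  res <- cpp_sim_multi(
    params$n_inputs, params$pattern_size, params$pattern_rate_hi,
    params$rho_E_base, as.integer(steps_per_window),
    matrix(as.integer(pat), nrow(pat), ncol(pat)),
    params$w_spec_IE, params$w_unsp_IE,
    params$w_fb_spec_IE, params$w_fb_unsp_IE,
    as.integer(params$n_spec_per_pop), as.integer(params$N_unsp_I),
    params$rho_spec_I, params$rho_unsp_I,
    params$tau_w_E, params$tau_w_I,
    if (recurrent) rec$tau_w_rec else 1,
    params$c_post_E, params$c_post_I, 0,
    matrix(params$w0_EE, n_post, params$n_pre_E),
    matrix(params$w0_spec_EI, n_post, params$n_inputs),
    rep(params$w0_unsp_EI, n_post),
    W_rec, as.integer(recurrent),
    if (recurrent) rec$w_rec_max else 1, params$dt, guard,
    dis_code, params$disinhibition_magnitude,
    pt$t_on, pt$t_off, pt$t_ramp_end, as.integer(record_every))
  res$protocol <- pt
  res$pattern <- pat
  res
}

#' Disinhibition-gated receptive-field run (single postsynaptic neuron)
#'
#' Simulates the multi-input feedforward circuit with plastic feedforward
#' excitatory and inhibitory weights (nonlinear inhibitory rule) under the
#' chosen disinhibition protocol: baseline, disinhibition window, (gradual
#' for \code{"specific"}) release, final settling. Disinhibiting the specific
#' populations induces competition between inputs and forms a receptive
#' field; disinhibiting the unspecific population does not.
#'
#' @param params a \code{\link{multi_input_params}}.
#' @param disinhibit \code{"none"}, \code{"specific"} or \code{"unspecific"}.
#' @param T_baseline,T_post durations of the pre- and post-protocol phases.
#' @param seed integer seed for the pattern sequence.
#' @param guard divergence guard.
#' @param record_every recording stride in steps.
#' @return A list of class \code{"multi_input_result"} with \code{$report}
#'   (a \code{\link{analyze_selectivity}} report), \code{$trajectory}
#'   (data.frame: t, nu_E, mean w_EE per input, w_EI per specific population,
#'   w_EI_unsp), final weights, \code{$diverged} and the protocol times.
#' @export
run_multi_input <- function(params = multi_input_params(),
                            disinhibit = c("none", "specific", "unspecific"),
                            T_baseline = 10, T_post = 10, seed = 1,
                            guard = 1e6, record_every = 1000L) {
  disinhibit <- match.arg(disinhibit)
  res <- run_multi_core(params, rec = NULL, disinhibit = disinhibit,
                        T_baseline = T_baseline, T_post = T_post, seed = seed,
                        guard = guard, record_every = record_every)
  tr <- as.data.frame(res$trajectory)
  names(tr) <- c("t", "nu_E",
                 paste0("w_EE_in", seq_len(params$n_inputs)),
                 paste0("w_EI_spec", seq_len(params$n_inputs)),
                 "w_EI_unsp")
  report <- analyze_selectivity(res$w_EE, params = params)
  structure(list(report = report, trajectory = tr,
                 w_EE = res$w_EE[1, ], w_EI_spec = res$w_EI_spec[1, ],
                 w_EI_unsp = res$w_EI_unsp[1], nu_E = res$nu_E,
                 diverged = res$diverged, t_diverge = res$t_diverge,
                 protocol = res$protocol, disinhibit = disinhibit,
                 seed = seed),
            class = "multi_input_result")
}

#' @export
print.multi_input_result <- function(x, ...) {
  cat(sprintf("multi-input run, disinhibition: %s (seed %d)\n",
              x$disinhibit, x$seed))
  if (x$diverged) cat(sprintf("  DIVERGED at t = %g\n", x$t_diverge))
  r <- x$report
  cat(sprintf("  preferred input %d, selectivity index %.3f\n",
              r$preferred[1], r$selectivity[1]))
  invisible(x)
}

#' Recurrent receptive-field and assembly-formation run
#'
#' Connects \code{rec$n_post} postsynaptic excitatory neurons, each with its
#' own multi-input feedforward circuit, by plastic recurrent excitatory
#' weights (presynaptic partner rate in place of the input rate in the
#' excitatory rule) and runs the specific-disinhibition protocol. Neurons
#' form receptive fields and strong bidirectional connections develop among
#' neurons with similar preferred inputs.
#'
#' @inheritParams run_multi_input
#' @param rec a \code{\link{recurrent_params}}.
#' @return A list of class \code{"recurrent_result"} with \code{$report} (per-
#'   neuron preferences, selectivity, recurrent-weight group statistics),
#'   \code{$W_rec}, \code{$w_EE}, \code{$diverged}, \code{$trajectory}.
#' @export
run_recurrent <- function(params = multi_input_params(
                            w_fb_spec_IE = 0.002, w_fb_unsp_IE = 0.001),
                          rec = recurrent_params(),
                          disinhibit = "specific",
                          T_baseline = 10, T_post = 10, seed = 1,
                          guard = 1e6, record_every = 1000L) {
  res <- run_multi_core(params, rec = rec, disinhibit = disinhibit,
                        T_baseline = T_baseline, T_post = T_post, seed = seed,
                        guard = guard, record_every = record_every)
  tr <- as.data.frame(res$trajectory)
  names(tr) <- c("t", "nu_E_mean", "w_EE_mean", "w_rec_mean")
  report <- analyze_selectivity(res$w_EE, res$W_rec, params = params,
                                rec = rec)
  structure(list(report = report, W_rec = res$W_rec, w_EE = res$w_EE,
                 w_EI_spec = res$w_EI_spec, w_EI_unsp = res$w_EI_unsp,
                 nu_E = res$nu_E, trajectory = tr,
                 diverged = res$diverged, t_diverge = res$t_diverge,
                 protocol = res$protocol, seed = seed),
            class = "recurrent_result")
}

#' @export
print.recurrent_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("recurrent run: %d neurons (seed %d)%s\n",
              nrow(r$mean_w_per_input), x$seed,
              if (x$diverged) sprintf("; DIVERGED at t = %g", x$t_diverge)
              else ""))
  cat(sprintf("  median selectivity %.3f; preferred inputs: %s\n",
              stats::median(r$selectivity),
              paste(r$preferred, collapse = " ")))
  cat(sprintf("  recurrent weight within / across preference groups: %.4g / %.4g\n",
              r$within_mean, r$across_mean))
  invisible(x)
}

#' Receptive-field and connectivity analysis
#'
#' From finished-run weights, computes per-postsynaptic-neuron mean
#' feedforward weight per input, the preferred input (argmax, ties broken by
#' the lowest input index), a selectivity index \eqn{(\max - \mathrm{mean\ of\
#' rest})/\max} in [0, 1], and — when recurrent weights are supplied — the
#' mean recurrent weight within versus across preference groups, the
#' bidirectionality score (mean over pairs of \eqn{\min(w_{ij}, w_{ji})},
#' within vs across groups) and the thresholded adjacency.
#'
#' @param w_EE feedforward weight matrix (\code{n_post x n_pre_E}) or vector.
#' @param W_rec optional recurrent weight matrix (\code{n_post x n_post}).
#' @param params a \code{\link{multi_input_params}}.
#' @param rec a \code{\link{recurrent_params}} (for the display threshold).
#' @return A list of class \code{"rf_report"}.
#' @export
analyze_selectivity <- function(w_EE, W_rec = NULL,
                                params = multi_input_params(),
                                rec = recurrent_params()) {
  if (is.null(dim(w_EE))) w_EE <- matrix(w_EE, nrow = 1)
  n_post <- nrow(w_EE)
  ps <- params$pattern_size
  mean_w <- t(apply(w_EE, 1, function(row) {
    vapply(seq_len(params$n_inputs), function(k) {
      mean(row[(k - 1) * ps + seq_len(ps)])
    }, numeric(1))
  }))
  if (params$n_inputs == 1) mean_w <- matrix(mean_w, ncol = 1)
  preferred <- apply(mean_w, 1, which.max)  # which.max takes the lowest index on ties
  selectivity <- vapply(seq_len(n_post), function(i) {
    m <- mean_w[i, ]
    mx <- max(m)
    if (mx <= 0) return(0)
    rest <- if (length(m) > 1) mean(m[-which.max(m)]) else 0
    max((mx - rest) / mx, 0)
  }, numeric(1))

  out <- list(mean_w_per_input = mean_w, preferred = preferred,
              selectivity = selectivity)
  if (!is.null(W_rec) && nrow(W_rec) == n_post && n_post > 1) {
    same <- outer(preferred, preferred, "==")
    diag(same) <- NA  # exclude self-connections
    off <- !is.na(same)
    within <- same & off
    across <- (!same) & off
    bidir <- pmin(W_rec, t(W_rec))
    out$within_mean <- if (any(within)) mean(W_rec[within]) else NA_real_
    out$across_mean <- if (any(across)) mean(W_rec[across]) else NA_real_
    out$bidir_within <- if (any(within)) mean(bidir[within]) else NA_real_
    out$bidir_across <- if (any(across)) mean(bidir[across]) else NA_real_
    adj <- W_rec
    adj[adj < rec$display_threshold] <- 0
    out$adjacency <- adj
  }
  structure(out, class = "rf_report")
}

#' @export
print.rf_report <- function(x, ...) {
  cat(sprintf("receptive-field report: %d neuron(s)\n",
              length(x$preferred)))
  cat(sprintf("  preferred input(s): %s\n", paste(x$preferred, collapse = " ")))
  cat(sprintf("  selectivity: %s\n",
              paste(sprintf("%.3f", x$selectivity), collapse = " ")))
  if (!is.null(x$within_mean)) {
    cat(sprintf("  recurrent mean weight within/across groups: %.4g / %.4g\n",
                x$within_mean, x$across_mean))
    cat(sprintf("  bidirectionality (min of reciprocal pair) within/across: %.4g / %.4g\n",
                x$bidir_within, x$bidir_across))
  }
  invisible(x)
}
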