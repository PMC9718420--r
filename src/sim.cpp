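#include <Rcpp.h>
using namespace Rcpp;

// Euler integrators for the plasticity models. Update order per step:
// evaluate drive -> update rates -> weight derivatives from the updated
// rates -> update weights/thresholds. Rates use upstream-first order so the
// tau_FR = dt limit is exactly the instantaneous steady state.

static inline double rect(double x) { return x > 0.0 ? x : 0.0; }

// drive_target: 0 none, 1 rho_E, 2 rho_add, 3 rho_I
// drive_kind:   0 constant, 1 step, 2 gaussian_noise, 3 sinusoid
// drive_par: value, rho_base, rho_disr, t_switch, mean, sd, amplitude, omega, offset
static inline double eval_drive(int kind, const double *p, double t) {
  switch (kind) {
  case 1:  return (t < p[3]) ? p[1] : p[2];
  case 2:  return R::rnorm(p[4], p[5]);
  case 3:  return p[8] + p[6] * std::sin(p[7] * t);
  default: return p[0];
  }
}

// [[Rcpp::export]]
List cpp_sim_feedforward(double N_E, double N_I, double rho_E0, double rho_I0,
                         double w_IE, double tau_FR_E, double tau_FR_I,
                         double dt, double w_FB_IE,
                         double tau_w_E, double tau_w_I,
                         int nonlinear, int dynamic_thresholds,
                         double tau_c, double weight_floor,
                         double w_EE, double w_EI, double cE, double cI,
                         double t0,
                         int drive_target, int drive_kind,
                         NumericVector drive_par,
                         double T, int record_every, double guard,
                         double conv_tol, double threshold_eps) {
  const long n_steps = (long)std::llround(T / dt);
  const double *dp = drive_par.begin();
  const bool inst_E = (tau_FR_E == dt), inst_I = (tau_FR_I == dt);

  // initial rates at the steady state of the initial weights and baseline drive
  double rho_E = rho_E0, rho_add = 0.0, rho_I = rho_I0;
  double nu_I = rect(N_E * rho_E * w_IE + rho_I);
  double nu_E = rect(N_E * rho_E * w_EE - N_I * nu_I * w_EI);
  if (w_FB_IE > 0.0) nu_I = rect(N_E * rho_E * w_IE + w_FB_IE * nu_E + rho_I);

  const long n_rec = n_steps / record_every + 2;
  NumericMatrix rec_mat(n_rec, 7);
  long ir = 0;
  bool diverged = false, converged = false;
  double t_event = NA_REAL;
  double t = t0;

  rec_mat(ir, 0) = t; rec_mat(ir, 1) = nu_E; rec_mat(ir, 2) = nu_I;
  rec_mat(ir, 3) = w_EE; rec_mat(ir, 4) = w_EI;
  rec_mat(ir, 5) = cE; rec_mat(ir, 6) = cI;
  ++ir;

  long i;
  for (i = 0; i < n_steps; ++i) {
    t = t0 + (i + 1) * dt;
    rho_E = rho_E0; rho_add = 0.0; rho_I = rho_I0;
    if (drive_target == 1)      rho_E = eval_drive(drive_kind, dp, t);
    else if (drive_target == 2) rho_add = eval_drive(drive_kind, dp, t);
    else if (drive_target == 3) rho_I = eval_drive(drive_kind, dp, t);

    // rates (inhibitory population first)
    double exc_I = N_E * rho_E * w_IE + w_FB_IE * nu_E + rho_I;
    nu_I = inst_I ? rect(exc_I)
                  : rect(nu_I + (-nu_I + rect(exc_I)) * dt / tau_FR_I);
    double exc_E = N_E * rho_E * w_EE - N_I * nu_I * w_EI + rho_add;
    nu_E = inst_E ? rect(exc_E)
                  : rect(nu_E + (-nu_E + rect(exc_E)) * dt / tau_FR_E);

    // plasticity from the updated rates
    double dwee = rho_E * nu_E * (nu_E - cE) / tau_w_E;
    double dwei = nonlinear ? nu_I * nu_E * (nu_E - cI) / tau_w_I
                            : nu_I * (nu_E - cI) / tau_w_I;
    w_EE += dwee * dt; if (w_EE < weight_floor) w_EE = weight_floor;
    w_EI += dwei * dt; if (w_EI < weight_floor) w_EI = weight_floor;
    if (dynamic_thresholds) {
      cE += dwee * dt / tau_c; if (cE < threshold_eps) cE = threshold_eps;
      cI -= dwei * dt / tau_c; if (cI < threshold_eps) cI = threshold_eps;
    }

    bool bad = !R_finite(w_EE) || !R_finite(w_EI) || !R_finite(nu_E) ||
               w_EE > guard || w_EI > guard;
    if (((i + 1) % record_every == 0) || bad || i == n_steps - 1) {
      if (ir < n_rec) {
        rec_mat(ir, 0) = t; rec_mat(ir, 1) = nu_E; rec_mat(ir, 2) = nu_I;
        rec_mat(ir, 3) = w_EE; rec_mat(ir, 4) = w_EI;
        rec_mat(ir, 5) = cE; rec_mat(ir, 6) = cI;
        ++ir;
      }
    }
    if (bad) { diverged = true; t_event = t; break; }
    if (conv_tol > 0.0 &&
        std::fabs(dwee) < conv_tol && std::fabs(dwei) < conv_tol) {
      converged = true; t_event = t; break;
    }
  }

  NumericMatrix out(ir, 7);
  for (long r = 0; r < ir; ++r)
    for (int c = 0; c < 7; ++c) out(r, c) = rec_mat(r, c);

  return List::create(_["trajectory"] = out,
                      _["w_EE"] = w_EE, _["w_EI"] = w_EI,
                      _["c_post_E"] = cE, _["c_post_I"] = cI,
                      _["nu_E"] = nu_E, _["nu_I"] = nu_I, _["t"] = t,
                      _["diverged"] = diverged, _["converged"] = converged,
                      _["t_event"] = t_event);
}

// Multi-input circuit with input-specific and unspecific inhibition and an
// optional plastic recurrent excitatory network. Instantaneous integrators
// (rates at their rectified steady state each step, recurrent and feedback
// terms with a one-step delay). pattern_seq: n_windows x n_post, 1-based
// pattern index active in each window for each postsynaptic neuron.
// disinh_target: 0 none, 1 specific, 2 unspecific.
// [[Rcpp::export]]
List cpp_sim_multi(int n_inputs, int pattern_size,
                   double pattern_rate_hi, double rho_base,
                   int steps_per_window, IntegerMatrix pattern_seq,
                   double w_spec_IE, double w_unsp_IE,
                   double w_fb_spec_IE, double w_fb_unsp_IE,
                   int n_spec_per_pop, int N_unsp,
                   double rho_spec_base, double rho_unsp_base,
                   double tau_w_E, double tau_w_I, double tau_w_rec,
                   double cE, double cI, double weight_floor,
                   NumericMatrix w_EE, NumericMatrix w_EI_spec,
                   NumericVector w_EI_unsp, NumericMatrix W_rec,
                   int recurrent, double w_rec_max, double dt, double guard,
                   int disinh_target, double disinh_mag,
                   double t_dis_on, double t_dis_off, double t_ramp_end,
                   int record_every) {
  const int n_post = pattern_seq.ncol();
  const int n_windows = pattern_seq.nrow();
  const int n_pre = n_inputs * pattern_size;
  const long n_steps = (long)n_windows * steps_per_window;
  const double sum_rho_all = (n_pre - pattern_size) * rho_base +
                             pattern_size * pattern_rate_hi;
  const double sum_hi = pattern_size * pattern_rate_hi;
  const double sum_lo = pattern_size * rho_base;

  std::vector<double> nu_E(n_post, 0.0), nu_E_new(n_post, 0.0);
  std::vector<double> nu_spec(n_inputs, 0.0);
  // flat working copies of the weight matrices (row-major by neuron)
  std::vector<double> wee((size_t)n_post * n_pre), weis((size_t)n_post * n_inputs),
      weiu(n_post), wrec((size_t)n_post * n_post, 0.0);
  for (int n = 0; n < n_post; ++n) {
    for (int j = 0; j < n_pre; ++j) wee[(size_t)n * n_pre + j] = w_EE(n, j);
    for (int k = 0; k < n_inputs; ++k)
      weis[(size_t)n * n_inputs + k] = w_EI_spec(n, k);
    weiu[n] = w_EI_unsp[n];
    if (recurrent)
      for (int m = 0; m < n_post; ++m) wrec[(size_t)n * n_post + m] = W_rec(n, m);
  }
  const long n_rec = n_steps / record_every + 2;
  // recorded columns: t, mean nu_E, then for n_post == 1 the per-input mean
  // w_EE (n_inputs), w_EI_spec (n_inputs), w_EI_unsp; for n_post > 1 the
  // mean feedforward and mean recurrent weight
  const int extra = (n_post == 1) ? (2 * n_inputs + 1) : 2;
  NumericMatrix rec_mat(n_rec, 2 + extra);
  long ir = 0;
  bool diverged = false;
  double t_div = NA_REAL, t = 0.0;

  for (long i = 0; i < n_steps; ++i) {
    t = (i + 1) * dt;
    const int win = (int)(i / steps_per_window);

    // disinhibition protocol (negative external drive onto I populations,
    // entering before the rectifier; specific release is a linear ramp)
    double rho_spec = rho_spec_base, rho_unsp = rho_unsp_base;
    double prot = 0.0;
    if (t >= t_dis_on && t < t_dis_off) prot = disinh_mag;
    else if (t >= t_dis_off && t < t_ramp_end && disinh_target == 1)
      prot = disinh_mag * (1.0 - (t - t_dis_off) / (t_ramp_end - t_dis_off));
    if (disinh_target == 1) rho_spec += prot;
    else if (disinh_target == 2) rho_unsp += prot;

    double max_w = 0.0;
    for (int n = 0; n < n_post; ++n) {
      const int a = pattern_seq(win, n) - 1;  // active pattern, 0-based
      double *wee_n = &wee[(size_t)n * n_pre];
      double *weis_n = &weis[(size_t)n * n_inputs];

      // inhibitory population rates (feedback from this neuron, one-step lag)
      double inh = 0.0;
      for (int k = 0; k < n_inputs; ++k) {
        double s = w_spec_IE * (k == a ? sum_hi : sum_lo) +
                   w_fb_spec_IE * nu_E[n] + rho_spec;
        nu_spec[k] = rect(s);
        inh += n_spec_per_pop * nu_spec[k] * weis_n[k];
      }
      double nu_unsp = rect(w_unsp_IE * sum_rho_all +
                            w_fb_unsp_IE * nu_E[n] + rho_unsp);
      inh += N_unsp * nu_unsp * weiu[n];

      // feedforward + recurrent excitation
      double exc = 0.0;
      for (int j = 0; j < n_pre; ++j) exc += wee_n[j];
      exc *= rho_base;
      double blk = 0.0;
      for (int j = a * pattern_size; j < (a + 1) * pattern_size; ++j)
        blk += wee_n[j];
      exc += (pattern_rate_hi - rho_base) * blk;
      if (recurrent) {
        const double *wr_n = &wrec[(size_t)n * n_post];
        for (int m = 0; m < n_post; ++m) exc += wr_n[m] * nu_E[m];
      }

      double nE = rect(exc - inh);
      nu_E_new[n] = nE;

      // plasticity (rates of this step)
      double fE = dt * nE * (nE - cE) / tau_w_E;
      double fI = dt * nE * (nE - cI) / tau_w_I;
      if (fE != 0.0) {
        const double dlo = rho_base * fE, dhi = pattern_rate_hi * fE;
        for (int j = 0; j < n_pre; ++j) {
          double w = wee_n[j] + ((j / pattern_size == a) ? dhi : dlo);
          wee_n[j] = w < weight_floor ? weight_floor : w;
          if (wee_n[j] > max_w) max_w = wee_n[j];
        }
      } else if (i == 0) {
        for (int j = 0; j < n_pre; ++j)
          if (wee_n[j] > max_w) max_w = wee_n[j];
      }
      if (fI != 0.0) {
        for (int k = 0; k < n_inputs; ++k) {
          double w = weis_n[k] + nu_spec[k] * fI;
          weis_n[k] = w < weight_floor ? weight_floor : w;
        }
        double wu = weiu[n] + nu_unsp * fI;
        weiu[n] = wu < weight_floor ? weight_floor : wu;
      }
    }

    // recurrent plasticity: presynaptic rate is the partner neuron's rate
    if (recurrent) {
      for (int n = 0; n < n_post; ++n) {
        double fE = dt * nu_E_new[n] * (nu_E_new[n] - cE) / tau_w_rec;
        if (fE == 0.0) continue;
        double *wr_n = &wrec[(size_t)n * n_post];
        for (int m = 0; m < n_post; ++m) {
          if (m == n) continue;
          double w = wr_n[m] + nu_E_new[m] * fE;
          if (w < weight_floor) w = weight_floor;
          if (w > w_rec_max) w = w_rec_max;
          wr_n[m] = w;
          if (w > max_w) max_w = w;
        }
      }
    }

    double mean_nu = 0.0;
    bool bad = false;
    for (int n = 0; n < n_post; ++n) {
      nu_E[n] = nu_E_new[n];
      mean_nu += nu_E[n] / n_post;
      if (!R_finite(nu_E[n])) bad = true;
    }
    if (max_w > guard || !R_finite(max_w)) bad = true;

    if (((i + 1) % record_every == 0) || bad || i == n_steps - 1) {
      if (ir < n_rec) {
        rec_mat(ir, 0) = t;
        rec_mat(ir, 1) = mean_nu;
        if (n_post == 1) {
          for (int k = 0; k < n_inputs; ++k) {
            double mw = 0.0;
            for (int j = 0; j < pattern_size; ++j)
              mw += wee[k * pattern_size + j] / pattern_size;
            rec_mat(ir, 2 + k) = mw;
            rec_mat(ir, 2 + n_inputs + k) = weis[k];
          }
          rec_mat(ir, 2 + 2 * n_inputs) = weiu[0];
        } else {
          double mff = 0.0, mrec = 0.0;
          for (size_t q = 0; q < wee.size(); ++q) mff += wee[q];
          mff /= (double)n_post * n_pre;
          if (recurrent) {
            for (size_t q = 0; q < wrec.size(); ++q) mrec += wrec[q];
            mrec /= (double)n_post * (n_post - 1);
          }
          rec_mat(ir, 2) = mff;
          rec_mat(ir, 3) = mrec;
        }
        ++ir;
      }
    }
    if (bad) { diverged = true; t_div = t; break; }
  }

  for (int n = 0; n < n_post; ++n) {
    for (int j = 0; j < n_pre; ++j) w_EE(n, j) = wee[(size_t)n * n_pre + j];
    for (int k = 0; k < n_inputs; ++k)
      w_EI_spec(n, k) = weis[(size_t)n * n_inputs + k];
    w_EI_unsp[n] = weiu[n];
    if (recurrent)
      for (int m = 0; m < n_post; ++m) W_rec(n, m) = wrec[(size_t)n * n_post + m];
  }

  NumericMatrix out(ir, rec_mat.ncol());
  for (long r = 0; r < ir; ++r)
    for (int c = 0; c < rec_mat.ncol(); ++c) out(r, c) = rec_mat(r, c);

  return List::create(_["trajectory"] = out,
                      _["w_EE"] = w_EE, _["w_EI_spec"] = w_EI_spec,
                      _["w_EI_unsp"] = w_EI_unsp, _["W_rec"] = W_rec,
                      _["nu_E"] = NumericVector(nu_E.begin(), nu_E.end()),
                      _["diverged"] = diverged, _["t_diverge"] = t_div,
                      _["t"] = t);
}
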