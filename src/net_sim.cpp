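// Forward-Euler cores for the coupled Izhikevich network and the FORCE
// closed loop.  All randomness (parameter sampling, initial conditions,
// static weights) happens on the R side; these loops are deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static double pget(const List& p, const char* nm) {
  return as<double>(p[nm]);
}

// Gating-variable coupled network (conductance term g_i * s * (E - v_i)).
// State update order within a step: Euler update of v, w with the current
// evaluated at the old state; exponential decay of s and of the per-neuron
// filtered traces; threshold-then-reset with the partial reset rule; spike
// impulses added to s (s_jump/N each) and to the spiking neuron's filtered
// trace (1/tau_s, unit-area kernel).
// [[Rcpp::export]]
List cpp_simulate_net(NumericVector v0, NumericVector w0, double s0,
                      NumericVector eta, NumericVector g, NumericVector theta,
                      List params, NumericVector drive, double dt,
                      int n_steps, int sample_every,
                      bool record_v, bool record_w, double t0) {
  const int n = v0.size();
  const double C = pget(params, "C"), k = pget(params, "k");
  const double vr = pget(params, "v_r"), vt = pget(params, "v_t");
  const double E = pget(params, "E"), tauw = pget(params, "tau_w");
  const double beta = pget(params, "beta"), vpeak = pget(params, "v_peak");
  const double vreset = pget(params, "v_reset"), wjump = pget(params, "w_jump");
  const double taus = pget(params, "tau_s"), sjump = pget(params, "s_jump");
  const double dec = std::exp(-dt / taus);
  const double rjump = 1.0 / taus;

  std::vector<double> v(v0.begin(), v0.end()), w(w0.begin(), w0.end());
  std::vector<double> rr(n, 0.0);
  double s = s0;

  std::vector<double> sp_t; std::vector<int> sp_i;
  const int n_samp = n_steps / sample_every;
  NumericVector samp_t(n_samp), s_tr(n_samp), drv(n_samp);
  NumericMatrix filt(n_samp, n);
  NumericMatrix v_tr = record_v ? NumericMatrix(n_samp, n) : NumericMatrix(0, 0);
  NumericMatrix w_tr = record_w ? NumericMatrix(n_samp, n) : NumericMatrix(0, 0);

  int isamp = 0;
  for (int m = 0; m < n_steps; ++m) {
    const double Iext = drive[m];
    for (int i = 0; i < n; ++i) {
      const double vi = v[i];
      const double I = eta[i] + Iext + g[i] * s * (E - vi);
      v[i] += dt * (k * (vi - vr) * (vi - vt) - w[i] + I) / C;
      w[i] += dt * (beta * (vi - vr) - w[i]) / tauw;
    }
    s *= dec;
    for (int i = 0; i < n; ++i) rr[i] *= dec;
    const double tsp = t0 + m * dt;  // raster time = step left edge
    for (int i = 0; i < n; ++i) {
      if (v[i] >= vpeak) {
        sp_t.push_back(tsp); sp_i.push_back(i + 1);
        // retained membrane cannot exceed the cutoff (guards the runaway
        // ratchet of large retained overshoots when theta is close to 1)
        const double vr2 = vreset + theta[i] * (v[i] - vpeak);
        v[i] = vr2 > vpeak ? vpeak : vr2;
        w[i] += wjump;
        s += sjump / n;
        rr[i] += rjump;
      } else if (!(v[i] > -1e12)) {
        stop("non-finite membrane potential (neuron %d, t = %g ms)",
             i + 1, tsp);
      }
    }
    if ((m + 1) % sample_every == 0) {
      samp_t[isamp] = t0 + (m + 1) * dt;
      s_tr[isamp] = s; drv[isamp] = Iext;
      for (int i = 0; i < n; ++i) filt(isamp, i) = rr[i];
      if (record_v) for (int i = 0; i < n; ++i) v_tr(isamp, i) = v[i];
      if (record_w) for (int i = 0; i < n; ++i) w_tr(isamp, i) = w[i];
      ++isamp;
    }
  }
  return List::create(
    _["spike_times"] = wrap(sp_t), _["spike_ids"] = wrap(sp_i),
    _["trace_times"] = samp_t, _["s_trace"] = s_tr, _["drive"] = drv,
    _["filtered"] = filt, _["v_trace"] = v_tr, _["w_trace"] = w_tr,
    _["v_end"] = wrap(v), _["w_end"] = wrap(w), _["s_end"] = s);
}

// FORCE closed loop.  Recurrent input replaces the gating coupling:
//   I_i = eta_i + g_scale_i * G * (omega0 %*% rr)_i + Q * enc_i * zhat
// where rr are the per-neuron filtered spike trains and zhat = phi' rr.
// The decoder phi is updated by recursive least squares every rls_interval
// steps during the training phase and frozen during the test phase.
// Filtering is double-exponential (rise tau_r, decay tau_s) when tau_r > 0
// so each spike's contribution ramps up continuously instead of jumping;
// tau_r <= 0 falls back to the first-order filter.
// [[Rcpp::export]]
List cpp_force_run(NumericVector v0, NumericVector w0,
                   NumericVector eta, NumericVector theta,
                   NumericVector g_scale, List params,
                   NumericMatrix omega0, NumericVector enc,
                   double G, double Q, double dt, double tau_r,
                   int n_train_steps, int n_test_steps,
                   int rls_interval, double lambda,
                   NumericVector target, int record_every,
                   bool return_P, bool record_rr) {
  const int n = v0.size();
  const double C = pget(params, "C"), k = pget(params, "k");
  const double vr = pget(params, "v_r"), vt = pget(params, "v_t");
  const double tauw = pget(params, "tau_w"), beta = pget(params, "beta");
  const double vpeak = pget(params, "v_peak"), vreset = pget(params, "v_reset");
  const double wjump = pget(params, "w_jump"), taus = pget(params, "tau_s");
  const double dec = std::exp(-dt / taus);
  const bool biexp = tau_r > 0;
  // exact update of the cascade dh/dt = -h/tau_r (+ impulses),
  // dr/dt = -r/tau_s + h:  r <- r*ed + h*cmix, h <- h*er
  const double er = biexp ? std::exp(-dt / tau_r) : 0.0;
  const double cmix = biexp ? (dec - er) / (1.0 / tau_r - 1.0 / taus) : 0.0;
  const double hjump = biexp ? 1.0 / (tau_r * taus) : 0.0;
  const double rjump = 1.0 / taus;
  const int n_steps = n_train_steps + n_test_steps;
  if (target.size() < n_steps) stop("target shorter than the simulation");

  // per-column nonzero structure of the static weights (event-driven adds)
  std::vector<std::vector<int>> nz_row(n);
  std::vector<std::vector<double>> nz_val(n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      if (omega0(i, j) != 0.0) { nz_row[j].push_back(i); nz_val[j].push_back(omega0(i, j)); }

  arma::vec v(v0.begin(), n), w(w0.begin(), n);
  arma::vec rr(n, arma::fill::zeros), u(n, arma::fill::zeros);
  arma::vec hh(n, arma::fill::zeros), uh(n, arma::fill::zeros);
  arma::vec phi(n, arma::fill::zeros);
  arma::mat P = arma::eye(n, n) / lambda;
  double zhat = 0.0;

  const int n_rec = n_steps / record_every;
  NumericVector err_t(n_rec), err_v(n_rec), z_rec(n_rec), y_rec(n_rec);
  NumericMatrix rr_rec = record_rr ? NumericMatrix(n_rec, n)
                                   : NumericMatrix(0, 0);
  int irec = 0;
  double sse = 0.0; long n_test_used = 0; long total_spikes = 0;

  for (int m = 0; m < n_steps; ++m) {
    const bool training = m < n_train_steps;
    for (int i = 0; i < n; ++i) {
      const double vi = v[i];
      const double I = eta[i] + g_scale[i] * G * u[i] + Q * enc[i] * zhat;
      v[i] += dt * (k * (vi - vr) * (vi - vt) - w[i] + I) / C;
      w[i] += dt * (beta * (vi - vr) - w[i]) / tauw;
    }
    if (biexp) {
      rr = rr * dec + hh * cmix;
      u = u * dec + uh * cmix;
      hh *= er; uh *= er;
    } else {
      rr *= dec; u *= dec;
    }
    for (int i = 0; i < n; ++i) {
      if (v[i] >= vpeak) {
        const double vr2 = vreset + theta[i] * (v[i] - vpeak);
        v[i] = vr2 > vpeak ? vpeak : vr2;
        w[i] += wjump;
        const double jmp = biexp ? hjump : rjump;
        if (biexp) hh[i] += jmp; else rr[i] += jmp;
        const std::vector<int>& ri = nz_row[i];
        const std::vector<double>& vi2 = nz_val[i];
        if (biexp) {
          for (size_t q = 0; q < ri.size(); ++q) uh[ri[q]] += vi2[q] * jmp;
        } else {
          for (size_t q = 0; q < ri.size(); ++q) u[ri[q]] += vi2[q] * jmp;
        }
        ++total_spikes;
      } else if (!(v[i] > -1e12)) {
        stop("non-finite membrane potential during FORCE run (neuron %d, t = %g ms)",
             i + 1, m * dt);
      }
    }
    zhat = arma::dot(phi, rr);
    const double e = zhat - target[m];
    if (training && ((m + 1) % rls_interval == 0)) {
      arma::vec Pr = P * rr;
      const double c = 1.0 / (1.0 + arma::dot(rr, Pr));
      phi -= (c * e) * Pr;
      P -= c * (Pr * Pr.t());
      zhat = arma::dot(phi, rr);
    }
    if (!training) { sse += e * e; ++n_test_used; }
    if ((m + 1) % record_every == 0 && irec < n_rec) {
      err_t[irec] = (m + 1) * dt; err_v[irec] = e;
      z_rec[irec] = zhat; y_rec[irec] = target[m];
      if (record_rr) for (int i = 0; i < n; ++i) rr_rec(irec, i) = rr[i];
      ++irec;
    }
  }
  const double mse = n_test_used > 0 ? sse / n_test_used : NA_REAL;
  List out = List::create(
    _["phi"] = NumericVector(phi.begin(), phi.end()),
    _["mse_test"] = mse, _["log_mse_test"] = std::log10(mse),
    _["err_times"] = err_t, _["err_trace"] = err_v,
    _["output"] = z_rec, _["target"] = y_rec,
    _["total_spikes"] = (double)total_spikes);
  if (return_P) out["P"] = wrap(P);
  if (record_rr) out["rr_trace"] = rr_rec;
  return out;
}
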