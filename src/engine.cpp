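// Time-stepping core of the E/I lattice model.
//
// Neurons are indexed 0..n-1 with the nE excitatory neurons first, then the
// nI inhibitory ones.  Square-pulse inputs (external noise events on E,
// EPSPs on I) share one additive accumulator per neuron plus a ring buffer
// of scheduled expiries (pulse width t_max = wsteps * dt, ring length
// wsteps + 1); IPSPs use one exponentially decaying accumulator per E
// neuron.  Per step: (1) expire/decay accumulators, (2) draw Poisson noise
// events, (3) gated forward-Euler membrane update with clamping,
// (4) spike detection against the dynamic threshold, (5) spike effects
// (resource release, waveform scheduling -- visible from the next step on),
// (6) resource recovery.  All randomness comes from R's RNG so runs are
// reproducible from set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_run_chunk(NumericVector V, NumericVector t_last, NumericVector x,
                   NumericVector sq_acc, NumericVector ipsp_acc,
                   NumericMatrix ring, int ring_pos,
                   IntegerVector i2e,     // nI x 12 flat, 0-based E targets
                   IntegerVector e2i_ptr, // length nE + 1, CSR over E sources
                   IntegerVector e2i_idx, // 0-based I consumers of each E
                   List par, double t0, int n_steps,
                   int record_stride, bool record_trace, bool record_raster) {
  const double dt = par["dt"];
  const double tau1 = par["tau1"], tau2_mem = par["tau2_mem"];
  const double Vth0 = par["Vth0"], Vsat = par["Vsat"], Vmin = par["Vmin"];
  const double ta = par["ta"], kappa = par["kappa"];
  const double U = par["U"], tau_rec = par["tau_rec"];
  const double V0d = par["V0d"], V0h = par["V0h"], tau2 = par["tau2"];
  const double mu = par["mu"], base_rate = par["base_rate"];
  const double v_ext = par["v_ext"];
  const bool noise_to_I = par["noise_to_I"];
  const bool std_static = par["std_static"];
  const bool reset_on_spike = par["reset_on_spike"];
  const int nE = par["n_e"], nI = par["n_i"];
  const int n = nE + nI;

  const int wlen = ring.ncol();
  const int wsteps = wlen - 1;
  const double ipsp_decay = std::exp(-dt / tau2);
  const double rec_step = (tau_rec > 0.0) ? -std::expm1(-dt / tau_rec) : 1.0;
  const int n_tgt = noise_to_I ? n : nE;
  const double lam_tot = mu * base_rate * dt * n_tgt;

  const int n_samples = record_trace ? n_steps / record_stride : 0;
  NumericMatrix trace(n_samples, 5); // t, meanVE, meanVI, meanUxE, meanUxI
  IntegerVector spike_counts(n);
  std::vector<int> ras_id;
  std::vector<double> ras_t;
  std::vector<int> spike_buf(n);
  int row = 0;

  for (int s = 0; s < n_steps; s++) {
    const int p = ring_pos;
    for (int i = 0; i < n; i++) { sq_acc[i] -= ring(i, p); ring(i, p) = 0.0; }
    for (int e = 0; e < nE; e++) ipsp_acc[e] *= ipsp_decay;

    if (lam_tot > 0.0) {
      int K = (int) R::rpois(lam_tot);
      const int pexp = (p + wsteps) % wlen;
      for (int k = 0; k < K; k++) {
        int j = (int)(unif_rand() * n_tgt);
        if (j >= n_tgt) j = n_tgt - 1;
        sq_acc[j] += v_ext;
        ring(j, pexp) += v_ext;
      }
    }

    const double t = t0 + (s + 1) * dt;
    int nspk = 0;
    for (int i = 0; i < n; i++) {
      double v = V[i];
      const double exc = sq_acc[i];
      const double inh = (i < nE) ? ipsp_acc[i] : 0.0;
      const double g = (Vsat - v) / Vsat * exc + (Vmin - v) / Vmin * inh;
      const double tau = (v >= 0.0) ? tau1 : tau2_mem;
      v += dt * (g - v) / tau;
      if (v > Vsat) v = Vsat; else if (v < Vmin) v = Vmin;
      if (!(v >= Vmin)) // NaN guard: clamping leaves non-finite values alone
        stop("simulation diverged: non-finite membrane potential at t = %g ms", t);
      V[i] = v;
      if (v >= Vth0) { // vth >= Vth0 always, so spikes need v >= Vth0 first
        const double dsp = t - t_last[i];
        if (dsp > ta) { // outside absolute refractory period
          const double vth = Vth0 + (Vsat - Vth0) * std::exp(-kappa * (dsp - ta));
          if (v >= vth) spike_buf[nspk++] = i;
        }
      }
    }

    for (int k = 0; k < nspk; k++) {
      const int i = spike_buf[k];
      t_last[i] = t;
      const double released = std_static ? U : U * x[i];
      if (!std_static) x[i] -= U * x[i];
      if (reset_on_spike) V[i] = 0.0;
      spike_counts[i]++;
      if (record_raster) { ras_id.push_back(i + 1); ras_t.push_back(t); }
      if (i < nE) {
        const double amp = V0d * released;
        for (int q = e2i_ptr[i]; q < e2i_ptr[i + 1]; q++) {
          const int tgt = nE + e2i_idx[q];
          sq_acc[tgt] += amp;
          ring(tgt, p) += amp; // expires when the ring wraps back: width t_max
        }
      } else {
        const double amp = V0h * released;
        const int ii = i - nE;
        for (int q = 0; q < 12; q++) ipsp_acc[i2e[ii * 12 + q]] += amp;
      }
    }

    if (!std_static) {
      if (rec_step == 1.0)
        for (int i = 0; i < n; i++) x[i] = 1.0;
      else
        for (int i = 0; i < n; i++) x[i] += (1.0 - x[i]) * rec_step;
    }

    if (record_trace && (s + 1) % record_stride == 0) {
      double sVE = 0, sVI = 0, sxE = 0, sxI = 0;
      for (int e = 0; e < nE; e++) { sVE += V[e]; sxE += x[e]; }
      for (int i = nE; i < n; i++) { sVI += V[i]; sxI += x[i]; }
      trace(row, 0) = t;
      trace(row, 1) = sVE / nE;
      trace(row, 2) = sVI / nI;
      trace(row, 3) = U * sxE / nE;
      trace(row, 4) = U * sxI / nI;
      row++;
    }

    ring_pos = (ring_pos + 1) % wlen;
  }

  return List::create(_["ring_pos"] = ring_pos,
                      _["t_end"] = t0 + (double) n_steps * dt,
                      _["trace"] = trace,
                      _["spike_counts"] = spike_counts,
                      _["raster_id"] = wrap(ras_id),
                      _["raster_t"] = wrap(ras_t));
}
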