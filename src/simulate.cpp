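#include <Rcpp.h>
using namespace Rcpp;

// Time-stepped simulation of linearly interacting point processes with
// exponential kernels.  Per step each neuron fires a Bernoulli spike with
// probability max(u, 0) * dt, where u = external drive + synaptic state.
// Synaptic state decays with the exact per-step factor exp(-dt/tau); one
// state per kernel group (excitatory / inhibitory sources), so the two
// populations may use different time constants.  Spikes are delivered after
// a global delay through a ring buffer of pending increments.  Uses R's RNG
// so runs are bit-for-bit reproducible under set.seed().
//
// ptr/tgt: column-compressed adjacency (0-based), sources = columns;
// amp: intensity increment per spike (weight / tau, in spikes/s);
// src_inh: 1 if the source neuron is inhibitory (selects the kernel group).

// [[Rcpp::export]]
List simulate_hawkes_cpp(int n, IntegerVector ptr, IntegerVector tgt,
                         NumericVector amp, IntegerVector src_inh,
                         double y0, double dt,
                         double decay_e, double decay_i, int delay_steps,
                         int n_steps, int warm_steps, double rate_ceiling) {
  if (delay_steps < 1) stop("delay must be at least one time step");
  std::vector< std::vector<double> > spikes(n);
  std::vector<double> sE(n, 0.0), sI(n, 0.0);
  const int buflen = delay_steps + 1;
  std::vector<double> bufE((size_t) buflen * n, 0.0);
  std::vector<double> bufI((size_t) buflen * n, 0.0);
  double max_p = 0.0;

  for (int t = 0; t < n_steps; ++t) {
    const int slot = t % buflen;
    const int wslot = (t + delay_steps) % buflen;
    double *bE = &bufE[(size_t) slot * n];
    double *bI = &bufI[(size_t) slot * n];
    double *wE = &bufE[(size_t) wslot * n];
    double *wI = &bufI[(size_t) wslot * n];
    for (int i = 0; i < n; ++i) {
      sE[i] = sE[i] * decay_e + bE[i];
      bE[i] = 0.0;
      sI[i] = sI[i] * decay_i + bI[i];
      bI[i] = 0.0;
      double u = y0 + sE[i] + sI[i];
      if (u > rate_ceiling) {
        stop("Intensity of neuron %d exceeded the rate ceiling (%g spikes/s) at t = %g s: network activity is exploding.",
             i + 1, rate_ceiling, t * dt);
      }
      double p = (u > 0.0 ? u : 0.0) * dt;
      if (p > max_p) max_p = p;
      if (p > 0.0 && unif_rand() < p) {
        if (t >= warm_steps) spikes[i].push_back((t - warm_steps) * dt);
        if (src_inh[i]) {
          for (int e = ptr[i]; e < ptr[i + 1]; ++e) wI[tgt[e]] += amp[e];
        } else {
          for (int e = ptr[i]; e < ptr[i + 1]; ++e) wE[tgt[e]] += amp[e];
        }
      }
    }
  }

  R_xlen_t total = 0;
  for (int i = 0; i < n; ++i) total += (R_xlen_t) spikes[i].size();
  IntegerVector neuron(total);
  NumericVector time(total);
  R_xlen_t k = 0;
  for (int i = 0; i < n; ++i) {
    for (size_t s = 0; s < spikes[i].size(); ++s, ++k) {
      neuron[k] = i + 1;
      time[k] = spikes[i][s];
    }
  }
  return List::create(_["neuron"] = neuron, _["time"] = time,
                      _["max_step_probability"] = max_p);
}
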