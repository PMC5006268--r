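#include <Rcpp.h>
using namespace Rcpp;

// Synchronous update loop of the spiking model.
//
// w_i / w_p / w_x are the CSC slots of the *outgoing* weight matrix:
// column j lists the postsynaptic targets of presynaptic neuron j.
// Per slice, one uniform draw per neuron is taken in neuron order (the same
// order as R's runif(n)), so runs are reproducible across the R reference
// implementation and this core for a given seed.
//
// Baseline probabilities (no presynaptic spikes) are precomputed; only
// neurons whose input changed in a slice have their probability recomputed,
// which keeps sparse-activity runs cheap.
//
// [[Rcpp::export]]
List inex_core(NumericVector basic_activity,
               IntegerVector w_i, IntegerVector w_p, NumericVector w_x,
               double dt_eff, double history_factor, int n_slices) {
  const int n = basic_activity.size();
  std::vector<double> p0(n), p(n), lam_add(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double lt = basic_activity[i] * dt_eff;
    p0[i] = lt * std::exp(-lt);
    p[i] = p0[i];
  }
  std::vector<int> prev, cur, touched;
  std::vector<char> prev_flag(n, 0);
  std::vector< std::vector<int> > spikes(n);

  for (int k = 0; k < n_slices; ++k) {
    touched.clear();
    for (size_t s = 0; s < prev.size(); ++s) {
      int j = prev[s];
      for (int e = w_p[j]; e < w_p[j + 1]; ++e) {
        int tgt = w_i[e];
        if (lam_add[tgt] == 0.0) touched.push_back(tgt);
        lam_add[tgt] += w_x[e];
      }
    }
    for (size_t s = 0; s < touched.size(); ++s) {
      int t = touched[s];
      double lam = basic_activity[t] + lam_add[t];
      if (lam < 0.0) lam = 0.0;
      double lt = lam * dt_eff;
      p[t] = lt * std::exp(-lt);
    }

    cur.clear();
    for (int i = 0; i < n; ++i) {
      double x = unif_rand();
      if (prev_flag[i]) x *= history_factor;
      if (x < p[i]) {
        cur.push_back(i);
        spikes[i].push_back(k);
      }
    }

    for (size_t s = 0; s < touched.size(); ++s) {
      int t = touched[s];
      lam_add[t] = 0.0;
      p[t] = p0[t];
    }
    for (size_t s = 0; s < prev.size(); ++s) prev_flag[prev[s]] = 0;
    for (size_t s = 0; s < cur.size(); ++s) prev_flag[cur[s]] = 1;
    prev.swap(cur);

    if ((k & 0x3fff) == 0) Rcpp::checkUserInterrupt();
  }

  List out(n);
  for (int i = 0; i < n; ++i)
    out[i] = IntegerVector(spikes[i].begin(), spikes[i].end());
  return out;
}
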