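#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Event-driven simulation kernel for feed-forward Spike-by-Spike networks.
//
// A network is passed in flattened form: populations (input modules and
// inference populations, topologically ordered with inputs first) plus a
// connection table (target, source, weight group, row offset into the
// target's composite weight matrix).  Per time step every spiking population
// draws exactly one spike from its distribution as it was at the start of
// the step; each inference population then applies the multiplicative
// latent-variable update once per afferent spike.

namespace {

// Inverse-CDF categorical draw using R's RNG.  Returns -1 when the
// distribution carries no mass (degenerate population -> no spike).
inline int draw_categorical(const std::vector<double>& p) {
  double tot = 0.0;
  for (double v : p) tot += v;
  if (tot <= 0.0) return -1;
  double u = unif_rand() * tot;
  double c = 0.0;
  int last = -1;
  for (int i = 0; i < (int)p.size(); ++i) {
    if (p[i] > 0.0) {
      c += p[i];
      last = i;
      if (u <= c) return i;
    }
  }
  return last;  // numerical guard: u landed past the last positive bin
}

}  // namespace

// [[Rcpp::export]]
List sbs_simulate_batch_cpp(IntegerVector pop_n,
                            LogicalVector pop_is_input,
                            LogicalVector pop_emits,
                            NumericVector pop_eps_pre,
                            NumericVector pop_eps_post,
                            int eps_breakpoint,
                            IntegerVector conn_target,
                            IntegerVector conn_source,
                            IntegerVector conn_group,
                            IntegerVector conn_offset,
                            List weights,
                            List h0,
                            int n_steps,
                            int record_depth) {
  const int n_pop = pop_n.size();
  const int n_conn = conn_target.size();
  const int n_pat = h0.size();

  // Pre-extract weight matrices as raw pointers (column-major).
  const int n_grp = weights.size();
  std::vector<const double*> wptr(n_grp);
  std::vector<int> wnrow(n_grp);
  std::vector<NumericMatrix> wmat(n_grp);
  for (int g = 0; g < n_grp; ++g) {
    wmat[g] = as<NumericMatrix>(weights[g]);
    wptr[g] = wmat[g].begin();
    wnrow[g] = wmat[g].nrow();
  }

  List out(n_pat);
  std::vector<std::vector<double> > h(n_pop);
  std::vector<int> spike(n_pop);

  for (int pat = 0; pat < n_pat; ++pat) {
    List h0p = h0[pat];
    for (int p = 0; p < n_pop; ++p) {
      NumericVector v = h0p[p];
      h[p].assign(v.begin(), v.end());
    }
    // Seed every snapshot slot with the initial state so that histories
    // deeper than the number of simulated steps fall back to it.
    std::vector<std::vector<std::vector<double> > > hist(record_depth + 1, h);
    std::vector<int> spikes_emitted(n_pop, 0);
    int skipped = 0;

    for (int step = 1; step <= n_steps; ++step) {
      const bool post = (eps_breakpoint > 0 && step > eps_breakpoint);
      // 1) draw all spikes from the start-of-step distributions
      for (int p = 0; p < n_pop; ++p) {
        if (pop_emits[p]) {
          spike[p] = draw_categorical(h[p]);
          if (spike[p] >= 0) ++spikes_emitted[p];
        } else {
          spike[p] = -1;
        }
      }
      // 2) apply the h-dynamic once per afferent spike, in connection order
      for (int c = 0; c < n_conn; ++c) {
        const int src = conn_source[c];
        const int s = spike[src];
        if (s < 0) continue;
        const int tgt = conn_target[c];
        const int g = conn_group[c];
        const int row = conn_offset[c] + s;
        const double* W = wptr[g] + row;  // row `row`, stride wnrow over cols
        const int stride = wnrow[g];
        std::vector<double>& ht = h[tgt];
        const int n = (int)ht.size();
        double denom = 0.0;
        for (int j = 0; j < n; ++j) denom += ht[j] * W[(std::size_t)j * stride];
        if (denom <= 0.0) {  // spike unexplained by current h and W
          ++skipped;
          continue;
        }
        const double eps = post ? pop_eps_post[tgt] : pop_eps_pre[tgt];
        const double inv = 1.0 / (1.0 + eps);
        const double k = eps / denom;
        double tot = 0.0;
        for (int j = 0; j < n; ++j) {
          ht[j] *= inv * (1.0 + k * W[(std::size_t)j * stride]);
          tot += ht[j];
        }
        // renormalize to absorb floating-point drift
        const double itot = 1.0 / tot;
        for (int j = 0; j < n; ++j) ht[j] *= itot;
      }
      // 3) ring buffer of the trailing record_depth+1 snapshots
      const int m = n_steps - step;
      if (m <= record_depth) hist[m] = h;
    }

    List hist_out(record_depth + 1);
    for (int m = 0; m <= record_depth; ++m) {
      List snap(n_pop);
      for (int p = 0; p < n_pop; ++p) snap[p] = wrap(hist[m][p]);
      hist_out[m] = snap;
    }
    List final_h(n_pop);
    for (int p = 0; p < n_pop; ++p) final_h[p] = wrap(h[p]);
    out[pat] = List::create(_["h"] = final_h,
                            _["history"] = hist_out,
                            _["spikes_emitted"] = wrap(spikes_emitted),
                            _["skipped"] = skipped,
                            _["n_steps"] = n_steps);
  }
  return out;
}
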