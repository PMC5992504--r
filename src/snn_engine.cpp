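// Event-driven simulator for deterministic leaky integrate-and-fire networks.
//
// Dynamics per neuron n on arrival of input at tick t:
//   P' = sign(P) * max(|P| - lambda_n * (t - last_update), 0)   (linear leak)
//   P  = P' + sum of weighted inputs arriving at tick t
//   if P >= Theta_n: emit spike, P = 0                          (reset, no refractory)
// Potentials change only when input arrives; simultaneous inputs to one
// neuron are summed before the threshold test; ties are processed in
// (time, presynaptic id) order so runs are bit-reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

struct Delivery {
  int target;
  int pre; // -1 for external injections
  double w;
};

static inline bool deliv_lt(const Delivery& a, const Delivery& b) {
  if (a.target != b.target) return a.target < b.target;
  return a.pre < b.pre;
}

// [[Rcpp::export]]
List snn_simulate_cpp(NumericVector threshold, NumericVector decay,
                      IntegerVector syn_ptr, IntegerVector syn_post,
                      NumericVector syn_weight, IntegerVector syn_delay,
                      IntegerVector ev_time, IntegerVector ev_target,
                      NumericVector ev_weight, int horizon,
                      IntegerVector record_ids, bool strict_threshold) {
  const int n = threshold.size();
  if (decay.size() != n) stop("decay length mismatch");
  if (syn_ptr.size() != n + 1) stop("syn_ptr must have length n+1");

  std::vector<double> pot(n, 0.0);
  std::vector<int> last(n, 0);
  std::vector<int> count(n, 0);
  std::vector<char> rec(n, 0);
  for (int i = 0; i < record_ids.size(); ++i) {
    int id = record_ids[i] - 1; // R ids are 1-based
    if (id < 0 || id >= n) stop("record id out of range");
    rec[id] = 1;
  }
  std::vector<int> rec_neuron;
  std::vector<int> rec_time;

  std::vector<std::vector<Delivery> > bucket(horizon + 1);
  for (int i = 0; i < ev_time.size(); ++i) {
    int t = ev_time[i];
    if (t < 0) stop("event before time zero");
    if (t > horizon) continue; // settles past the horizon
    int tgt = ev_target[i] - 1;
    if (tgt < 0 || tgt >= n) stop("event target out of range");
    bucket[t].push_back(Delivery{tgt, -1, ev_weight[i]});
  }

  std::vector<Delivery> wave;
  for (int t = 0; t <= horizon; ++t) {
    while (!bucket[t].empty()) {
      wave.clear();
      wave.swap(bucket[t]);
      std::sort(wave.begin(), wave.end(), deliv_lt);
      size_t i = 0;
      while (i < wave.size()) {
        int tgt = wave[i].target;
        double input = 0.0;
        while (i < wave.size() && wave[i].target == tgt) {
          input += wave[i].w;
          ++i;
        }
        double p = pot[tgt];
        int dt = t - last[tgt];
        if (dt > 0 && p != 0.0) {
          double mag = std::abs(p) - decay[tgt] * dt;
          p = (p > 0 ? 1.0 : -1.0) * std::max(mag, 0.0);
        }
        p += input;
        last[tgt] = t;
        bool fired = strict_threshold ? (p > threshold[tgt]) : (p >= threshold[tgt]);
        if (fired) {
          ++count[tgt];
          if (rec[tgt]) {
            rec_neuron.push_back(tgt + 1);
            rec_time.push_back(t);
          }
          p = 0.0;
          for (int s = syn_ptr[tgt]; s < syn_ptr[tgt + 1]; ++s) {
            int at = t + syn_delay[s];
            if (at <= horizon)
              bucket[at].push_back(Delivery{syn_post[s] - 1, tgt, syn_weight[s]});
          }
        }
        pot[tgt] = p;
      }
    }
  }

  return List::create(
      _["spike_count"] = IntegerVector(count.begin(), count.end()),
      _["rec_neuron"] = IntegerVector(rec_neuron.begin(), rec_neuron.end()),
      _["rec_time"] = IntegerVector(rec_time.begin(), rec_time.end()),
      _["potential"] = NumericVector(pot.begin(), pot.end()));
}
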