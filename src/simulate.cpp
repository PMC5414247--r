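#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Event-driven simulator of instantaneous spikes with refractory
// suppression and per-edge transmission delays.
//
// Conventions (documented in the package):
//  * refractory window after a spike at t is half-open [t, t + delta):
//    an arrival at exactly t + delta fires;
//  * simultaneous arrivals are processed in ascending target-vertex order;
//    two arrivals at the same vertex at the same instant yield one spike
//    (the second lands inside the refractory window);
//  * free-running mode injects a single kick arrival at t = 0; forced mode
//    injects pulses at 0, p, 2p, ... at force_vertex (the t = 0 pulse is
//    the kick) which obey the same refractory rule.

namespace {

struct Arrival {
  double time;
  int target;
  bool forcing;
};

struct Later {
  bool operator()(const Arrival& a, const Arrival& b) const {
    if (a.time != b.time) return a.time > b.time;
    return a.target > b.target;  // ties: ascending vertex
  }
};

}  // namespace

// [[Rcpp::export]]
List sim_core_cpp(int n, IntegerMatrix edges, NumericVector lags,
                  double delta, int start_vertex, double period,
                  int max_spikes, double t_max) {
  int m = edges.nrow();
  std::vector<std::vector<std::pair<int, double>>> out(n);
  for (int e = 0; e < m; ++e) {
    out[edges(e, 0)].push_back({edges(e, 1), lags[e]});
  }

  std::priority_queue<Arrival, std::vector<Arrival>, Later> pq;
  pq.push({0.0, start_vertex, true});
  long long pulse_idx = 0;  // index of the last injected forcing pulse

  std::vector<double> last(n, R_NegInf);
  std::vector<double> spike_t;
  std::vector<int> spike_v;
  spike_t.reserve(max_spikes);
  spike_v.reserve(max_spikes);

  std::string status = "died_out";
  while (!pq.empty()) {
    Arrival a = pq.top();
    if (a.time > t_max) {
      status = "reached_horizon";
      break;
    }
    pq.pop();
    if (a.forcing && period > 0) {
      ++pulse_idx;
      pq.push({pulse_idx * period, start_vertex, true});
    }
    if (last[a.target] == R_NegInf || a.time >= last[a.target] + delta) {
      last[a.target] = a.time;
      spike_t.push_back(a.time);
      spike_v.push_back(a.target);
      for (const auto& e : out[a.target]) {
        pq.push({a.time + e.second, e.first, false});
      }
      if ((int)spike_t.size() >= max_spikes) {
        status = "reached_cap";
        break;
      }
    }
  }

  return List::create(_["time"] = NumericVector(spike_t.begin(), spike_t.end()),
                      _["vertex"] = IntegerVector(spike_v.begin(), spike_v.end()),
                      _["status"] = status);
}
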