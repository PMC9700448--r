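// Discrete-event core for a feed-forward network of FIFO multi-server
// stations with optional shared server groups, a bed-pool gate in front of
// one station, and shift-driven capacity changes.
//
// All stochastic inputs (arrival times, per-patient per-station service
// times, last station on each patient's path, bed-pool disposition, length
// of stay) are pre-drawn in R from named substreams; this loop is purely
// deterministic, which makes runs bit-reproducible and lets scenarios share
// common random numbers.

#include <Rcpp.h>
#include <queue>
#include <deque>
#include <vector>

using namespace Rcpp;

namespace {

struct Ev {
  double t;
  long long seq;   // insertion order breaks ties
  int type;        // 0 arrival, 1 end_service, 2 bed_release, 3 cap_change
  int a;           // patient index (0-based) or cap-change index
};

struct EvCmp {
  bool operator()(const Ev& x, const Ev& y) const {
    if (x.t != y.t) return x.t > y.t;
    return x.seq > y.seq;
  }
};

}  // namespace

// [[Rcpp::export(name = ".run_des_cpp")]]
List run_des_cpp(NumericVector arrivals,
                 NumericMatrix service,
                 IntegerVector station_group,   // length K, 1-based group ids
                 IntegerVector group_capacity,  // length G
                 IntegerVector last_station,    // length n, 1..K
                 int bed_station,               // 0 = no bed gate
                 IntegerVector pool_id,         // length n, 1-based or 0
                 IntegerVector pool_capacity,   // length P
                 NumericVector los,             // length n, minutes
                 double queue_cap,
                 NumericVector cap_change_times,
                 IntegerVector cap_change_group,
                 IntegerVector cap_change_value) {
  const int n = arrivals.size();
  const int K = station_group.size();
  const int G = group_capacity.size();
  const int P = pool_capacity.size();

  NumericMatrix t_queue(n, K), t_start(n, K), t_end(n, K);
  std::fill(t_queue.begin(), t_queue.end(), NA_REAL);
  std::fill(t_start.begin(), t_start.end(), NA_REAL);
  std::fill(t_end.begin(), t_end.end(), NA_REAL);
  NumericVector bed_queue_t(n, NA_REAL), bed_seize_t(n, NA_REAL),
      bed_release_t(n, NA_REAL);

  std::vector<int> cap(group_capacity.begin(), group_capacity.end());
  std::vector<int> busy(G, 0);
  std::vector<double> busy_integral(G, 0.0), last_change(G, 0.0);
  std::vector<int> freebeds(pool_capacity.begin(), pool_capacity.end());
  std::vector<std::deque<int> > gq(G);       // waiting patients per group
  std::vector<std::deque<int> > bq(P);       // waiting patients per bed pool
  std::vector<int> stage(n, 0);              // current station, 1-based
  std::vector<double> max_q(G, 0.0);

  std::priority_queue<Ev, std::vector<Ev>, EvCmp> fel;
  long long seq = 0;

  for (int i = 0; i < n; ++i) fel.push(Ev{arrivals[i], seq++, 0, i});
  for (int j = 0; j < cap_change_times.size(); ++j)
    fel.push(Ev{cap_change_times[j], seq++, 3, j});

  // forward declarations via lambdas
  auto acc_busy = [&](int g, double t) {
    busy_integral[g] += busy[g] * (t - last_change[g]);
    last_change[g] = t;
  };

  auto start_service = [&](int p, double t) {
    const int s = stage[p];            // 1-based
    const int g = station_group[s - 1] - 1;
    t_start(p, s - 1) = t;
    acc_busy(g, t);
    busy[g] += 1;
    fel.push(Ev{t + service(p, s - 1), seq++, 1, p});
  };

  auto drain_group = [&](int g, double t) {
    while (busy[g] < cap[g] && !gq[g].empty()) {
      int p2 = gq[g].front();
      gq[g].pop_front();
      start_service(p2, t);
    }
  };

  auto arrive_at = [&](int p, int s, double t) {
    stage[p] = s;
    t_queue(p, s - 1) = t;
    const int g = station_group[s - 1] - 1;
    if (busy[g] < cap[g] && gq[g].empty()) {
      start_service(p, t);
    } else {
      gq[g].push_back(p);
      if ((double)gq[g].size() > max_q[g]) max_q[g] = (double)gq[g].size();
      if ((double)gq[g].size() > queue_cap)
        stop("des instability: waiting-line cap exceeded at station group %d",
             g + 1);
    }
  };

  // entering station s2: pass the bed gate first if it sits in front
  auto gate_or_arrive = [&](int p, int s2, double t) {
    if (bed_station > 0 && s2 == bed_station && pool_id[p] > 0) {
      bed_queue_t[p] = t;
      const int pool = pool_id[p] - 1;
      if (freebeds[pool] > 0 && bq[pool].empty()) {
        freebeds[pool] -= 1;
        bed_seize_t[p] = t;
        arrive_at(p, s2, t);
      } else {
        bq[pool].push_back(p);
        if ((double)bq[pool].size() > queue_cap)
          stop("des instability: waiting-line cap exceeded at bed pool %d",
               pool + 1);
      }
    } else {
      arrive_at(p, s2, t);
    }
  };

  auto route_next = [&](int p, double t) {
    const int s = stage[p];
    if (s >= last_station[p]) {
      if (s == K && bed_station > 0 && pool_id[p] > 0)
        fel.push(Ev{t + los[p], seq++, 2, p});  // bed held for the stay
      return;
    }
    gate_or_arrive(p, s + 1, t);
  };

  while (!fel.empty()) {
    Ev ev = fel.top();
    fel.pop();
    switch (ev.type) {
      case 0: {  // external arrival enters station 1 (possibly bed-gated)
        gate_or_arrive(ev.a, 1, ev.t);
        break;
      }
      case 1: {  // end of service
        const int p = ev.a;
        const int s = stage[p];
        const int g = station_group[s - 1] - 1;
        t_end(p, s - 1) = ev.t;
        acc_busy(g, ev.t);
        busy[g] -= 1;
        route_next(p, ev.t);
        drain_group(g, ev.t);
        break;
      }
      case 2: {  // bed release
        const int p = ev.a;
        const int pool = pool_id[p] - 1;
        bed_release_t[p] = ev.t;
        freebeds[pool] += 1;
        if (!bq[pool].empty()) {
          int p2 = bq[pool].front();
          bq[pool].pop_front();
          freebeds[pool] -= 1;
          bed_seize_t[p2] = ev.t;
          arrive_at(p2, bed_station, ev.t);
        }
        break;
      }
      case 3: {  // shift-boundary capacity change
        const int j = ev.a;
        const int g = cap_change_group[j] - 1;
        cap[g] = cap_change_value[j];
        drain_group(g, ev.t);
        break;
      }
    }
  }

  double t_last = 0.0;
  for (int g = 0; g < G; ++g)
    if (last_change[g] > t_last) t_last = last_change[g];

  return List::create(
      _["t_queue"] = t_queue, _["t_start"] = t_start, _["t_end"] = t_end,
      _["bed_queue_t"] = bed_queue_t, _["bed_seize_t"] = bed_seize_t,
      _["bed_release_t"] = bed_release_t,
      _["busy_minutes"] = NumericVector(busy_integral.begin(),
                                        busy_integral.end()),
      _["max_queue"] = NumericVector(max_q.begin(), max_q.end()),
      _["t_last_event"] = t_last);
}
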