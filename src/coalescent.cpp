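// Structured-coalescent simulation of independent biallelic SNP loci under
// divergence/admixture demographies. Continuous time, exact exponential
// waiting times; uses R's RNG so results are reproducible via set.seed().
//
// Node numbering: tips 0..n-1 (time 0), internal nodes n..2n-2 created in
// coalescence order, so a parent always has a larger index than its
// children; descendant marking is a single descending pass.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Event {
  double time;
  int type;     // 0 = divergence, 1 = admixture
  int derived;
  int src1;
  int src2;     // admixture only
  double prop;  // admixture only: P(lineage -> src1)
};

// Reusable workspace to keep the per-locus loop allocation-free.
struct Workspace {
  std::vector<int> parent;             // 2n-1, -1 for root
  std::vector<double> time;            // node times
  std::vector<std::vector<int> > lin;  // lineages per population
  std::vector<char> carrier;           // derived-allele flags
};

static void sim_genealogy(const std::vector<int>& tip_pop,
                          const std::vector<double>& ne,
                          const std::vector<Event>& events,
                          Workspace& w) {
  const int n = (int)tip_pop.size();
  const int n_pops = (int)ne.size();
  w.parent.assign(2 * n - 1, -1);
  w.time.assign(2 * n - 1, 0.0);
  for (int j = 0; j < n_pops; ++j) w.lin[j].clear();
  for (int i = 0; i < n; ++i) w.lin[tip_pop[i]].push_back(i);

  int n_alive = n;
  int next_node = n;
  double t = 0.0;
  size_t e = 0;

  while (n_alive > 1) {
    double rate = 0.0;
    for (int j = 0; j < n_pops; ++j) {
      double k = (double)w.lin[j].size();
      if (k >= 2.0) rate += k * (k - 1.0) / (4.0 * ne[j]);
    }
    double next_ev = (e < events.size()) ? events[e].time :
      std::numeric_limits<double>::infinity();
    double t_coal = (rate > 0.0) ? t + R::rexp(1.0 / rate) :
      std::numeric_limits<double>::infinity();

    if (t_coal < next_ev) {
      // choose population proportional to its pair rate
      double u = R::unif_rand() * rate;
      int pop = -1;
      double acc = 0.0;
      for (int j = 0; j < n_pops; ++j) {
        double k = (double)w.lin[j].size();
        if (k < 2.0) continue;
        acc += k * (k - 1.0) / (4.0 * ne[j]);
        if (u <= acc) { pop = j; break; }
      }
      if (pop < 0) {
        for (int j = n_pops - 1; j >= 0; --j)
          if (w.lin[j].size() >= 2) { pop = j; break; }
      }
      std::vector<int>& L = w.lin[pop];
      int k = (int)L.size();
      int a = (int)(R::unif_rand() * k); if (a == k) a = k - 1;
      int b = (int)(R::unif_rand() * (k - 1)); if (b == k - 1) b = k - 2;
      if (b >= a) b += 1;
      int node = next_node++;
      w.parent[L[a]] = node;
      w.parent[L[b]] = node;
      w.time[node] = t_coal;
      L[a] = node;
      L[b] = L.back();
      L.pop_back();
      t = t_coal;
      n_alive -= 1;
    } else if (std::isfinite(next_ev)) {
      const Event& ev = events[e];
      t = next_ev;
      std::vector<int>& D = w.lin[ev.derived];
      if (ev.type == 0) {
        w.lin[ev.src1].insert(w.lin[ev.src1].end(), D.begin(), D.end());
      } else {
        for (size_t i = 0; i < D.size(); ++i) {
          if (R::unif_rand() < ev.prop) w.lin[ev.src1].push_back(D[i]);
          else w.lin[ev.src2].push_back(D[i]);
        }
      }
      D.clear();
      ++e;
    } else {
      stop("disconnected scenario: lineages cannot coalesce");
    }
  }
}

// Place one mutation on a branch chosen proportional to its length (the
// root has no branch) and flag carrier tips. Returns the derived tip count,
// or -1 when the minor-allele condition fails.
static int drop_mutation(Workspace& w, int n, int min_minor) {
  const int n_nodes = 2 * n - 1;
  double total = 0.0;
  for (int i = 0; i < n_nodes - 1; ++i)
    total += w.time[w.parent[i]] - w.time[i];
  if (total <= 0.0) return -1;
  double u = R::unif_rand() * total;
  int mut_node = n_nodes - 2;
  double acc = 0.0;
  for (int i = 0; i < n_nodes - 1; ++i) {
    acc += w.time[w.parent[i]] - w.time[i];
    if (u <= acc) { mut_node = i; break; }
  }
  std::fill(w.carrier.begin(), w.carrier.end(), 0);
  w.carrier[mut_node] = 1;
  int n_der = (mut_node < n) ? 1 : 0;
  for (int i = mut_node - 1; i >= 0; --i) {
    if (w.carrier[w.parent[i]]) {
      w.carrier[i] = 1;
      if (i < n) ++n_der;
    }
  }
  int minor = std::min(n_der, n - n_der);
  if (minor < min_minor) return -1;
  return n_der;
}

static std::vector<Event> decode_events(const NumericVector& ev_time,
                                        const IntegerVector& ev_type,
                                        const IntegerVector& ev_derived,
                                        const IntegerVector& ev_s1,
                                        const IntegerVector& ev_s2,
                                        const NumericVector& ev_prop) {
  std::vector<Event> events(ev_time.size());
  for (int k = 0; k < ev_time.size(); ++k) {
    events[k].time = ev_time[k];
    events[k].type = ev_type[k];
    events[k].derived = ev_derived[k];
    events[k].src1 = ev_s1[k];
    events[k].src2 = ev_s2[k];
    events[k].prop = ev_prop[k];
  }
  for (size_t k = 1; k < events.size(); ++k)
    if (events[k].time < events[k - 1].time)
      stop("events must be supplied in ascending time order");
  return events;
}

static Workspace make_workspace(int n, int n_pops) {
  Workspace w;
  w.lin.resize(n_pops);
  for (int j = 0; j < n_pops; ++j) w.lin[j].reserve(n);
  w.carrier.assign(std::max(2 * n - 1, 1), 0);
  return w;
}

// [[Rcpp::export]]
List cpp_sim_genealogy(IntegerVector tip_pop, NumericVector ne,
                       NumericVector ev_time, IntegerVector ev_type,
                       IntegerVector ev_derived, IntegerVector ev_s1,
                       IntegerVector ev_s2, NumericVector ev_prop) {
  std::vector<int> tp(tip_pop.begin(), tip_pop.end());
  std::vector<double> nev(ne.begin(), ne.end());
  std::vector<Event> events =
    decode_events(ev_time, ev_type, ev_derived, ev_s1, ev_s2, ev_prop);
  if (tp.size() == 1) {
    return List::create(_["parent"] = IntegerVector::create(NA_INTEGER),
                        _["time"] = NumericVector::create(0.0),
                        _["n_tips"] = 1);
  }
  Workspace w = make_workspace((int)tp.size(), (int)nev.size());
  sim_genealogy(tp, nev, events, w);
  IntegerVector parent(w.parent.size());
  for (size_t i = 0; i < w.parent.size(); ++i)
    parent[i] = (w.parent[i] < 0) ? NA_INTEGER : w.parent[i] + 1;
  return List::create(_["parent"] = parent,
                      _["time"] = NumericVector(w.time.begin(), w.time.end()),
                      _["n_tips"] = (int)tp.size());
}

// Dataset of n_loci independent SNP loci: per locus a fresh genealogy plus a
// single mutation conditioned on pooled minor-allele count >= min_minor;
// the whole locus (genealogy included) is redrawn until the condition holds.
// Gene copies 2i, 2i+1 form diploid individual i.
// [[Rcpp::export]]
IntegerMatrix cpp_sim_dataset(IntegerVector tip_pop, NumericVector ne,
                              NumericVector ev_time, IntegerVector ev_type,
                              IntegerVector ev_derived, IntegerVector ev_s1,
                              IntegerVector ev_s2, NumericVector ev_prop,
                              int n_loci, int min_minor) {
  std::vector<int> tp(tip_pop.begin(), tip_pop.end());
  std::vector<double> nev(ne.begin(), ne.end());
  std::vector<Event> events =
    decode_events(ev_time, ev_type, ev_derived, ev_s1, ev_s2, ev_prop);
  const int n_copies = (int)tp.size();
  if (n_copies % 2 != 0) stop("gene-copy count must be even");
  const int n_ind = n_copies / 2;
  IntegerMatrix out(n_ind, n_loci);
  Workspace w = make_workspace(n_copies, (int)nev.size());
  const int max_tries = 100000;
  for (int l = 0; l < n_loci; ++l) {
    int n_der = -1;
    for (int tries = 0; tries < max_tries && n_der < 0; ++tries) {
      sim_genealogy(tp, nev, events, w);
      n_der = drop_mutation(w, n_copies, min_minor);
    }
    if (n_der < 0) stop("could not satisfy the minor-allele condition");
    for (int i = 0; i < n_ind; ++i)
      out(i, l) = (int)w.carrier[2 * i] + (int)w.carrier[2 * i + 1];
    if (l % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
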