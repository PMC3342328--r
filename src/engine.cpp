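#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Per-damage-event repair probability of a cell carrying i mutations,
// clamped into [0, 1].
static inline double repair_prob(double r0, double delta, long i) {
  double r = r0 - delta * (double)i;
  if (r < 0.0) r = 0.0;
  if (r > 1.0) r = 1.0;
  return r;
}

// Draw an index with probability cnt[k] / total by walking the cumulative
// sum from the lowest occupied class `lo` (classes below are empty — the
// occupied band drifts upward once the ratchet advances). total must equal
// sum(cnt), kept incrementally by the caller.
static inline size_t draw_class(const std::vector<long long>& cnt,
                                size_t lo, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  for (size_t k = lo; k < cnt.size(); ++k) {
    acc += (double)cnt[k];
    if (u < acc) return k;
  }
  // numeric guard: return last occupied class
  for (size_t k = cnt.size(); k-- > lo;) if (cnt[k] > 0) return k;
  return lo;
}

// Stochastic engine for the well-mixed system on a count-vector state.
// One step = one damage event: pick a cell (class i w.p. n_i/N); repair with
// prob R_i; otherwise apoptosis with prob a (a random survivor divides, the
// daughter inheriting the survivor's level); otherwise mutation (i -> i+1).
//
// Sampling: state observables are recorded at step 0 and every
// `sample_every` steps. If acc_len > 0, full occupancy vectors are
// accumulated (summed) at sample points with acc_from < step <= acc_from +
// acc_len, but only while n0 > 0; the first sample with n0 == 0 truncates
// the accumulation window.
// [[Rcpp::export]]
List run_well_mixed_cpp(IntegerVector counts0, double r0, double delta, double a,
                        double n_steps_d, double sample_every_d,
                        bool stop_extinct,
                        double acc_from_d, double acc_len_d) {
  const long long n_steps = (long long)n_steps_d;
  long long sample_every = (long long)sample_every_d;
  if (sample_every < 1) sample_every = 1;

  std::vector<long long> cnt(counts0.begin(), counts0.end());
  long long N = 0;
  for (long long c : cnt) N += c;
  long long n0 = cnt.empty() ? 0 : cnt[0];
  double sum_r = 0.0;
  for (size_t k = 0; k < cnt.size(); ++k)
    sum_r += (double)cnt[k] * repair_prob(r0, delta, (long)k);

  long long n_rep = 0, n_apo = 0, n_mut = 0;
  const long long acc_from = (long long)acc_from_d;
  const long long acc_to = acc_from + (long long)acc_len_d;
  const bool accumulating = acc_len_d > 0;
  bool acc_truncated = false;
  std::vector<double> occ_sum;
  long long occ_n = 0;

  std::vector<double> s_time, s_rbar, s_n0, s_rep, s_apo, s_mut;
  long long extinct_step = -1;

  // recompute mean repair rate exactly at sample points to avoid drift of
  // the incremental sum over ~1e7 floating-point updates; summing the
  // offsets from the level-0 rate keeps rbar exactly r0 when delta == 0
  size_t lo = 0;  // lowest occupied class
  while (lo + 1 < cnt.size() && cnt[lo] == 0) ++lo;

  const double rp0 = repair_prob(r0, delta, 0);
  auto record = [&](long long s) {
    double sr = 0.0;
    for (size_t k = lo; k < cnt.size(); ++k)
      sr += (double)cnt[k] * (repair_prob(r0, delta, (long)k) - rp0);
    sr += rp0 * (double)N;
    sum_r = sr;
    s_time.push_back((double)s);
    s_rbar.push_back(sr / (double)N);
    s_n0.push_back((double)n0);
    s_rep.push_back((double)n_rep);
    s_apo.push_back((double)n_apo);
    s_mut.push_back((double)n_mut);
  };
  record(0);

  for (long long s = 1; s <= n_steps; ++s) {
    size_t i = draw_class(cnt, lo, (double)N);
    double Ri = repair_prob(r0, delta, (long)i);
    double v = unif_rand();
    if (v < Ri) {
      ++n_rep;
    } else if (unif_rand() < a) {
      // apoptosis: dividing cell drawn from the N-1 survivors
      cnt[i]--;
      if (i == 0) --n0;
      sum_r -= Ri;
      size_t j = draw_class(cnt, lo, (double)(N - 1));
      cnt[j]++;
      if (j == 0) ++n0;
      sum_r += repair_prob(r0, delta, (long)j);
      ++n_apo;
    } else {
      // mutation
      cnt[i]--;
      if (i == 0) --n0;
      if (i + 1 >= cnt.size()) cnt.resize(i + 2, 0);
      cnt[i + 1]++;
      sum_r += repair_prob(r0, delta, (long)(i + 1)) - Ri;
      ++n_mut;
    }
    while (lo + 1 < cnt.size() && cnt[lo] == 0) ++lo;

    bool at_sample = (s % sample_every == 0);
    if (at_sample) {
      record(s);
      if (accumulating && !acc_truncated && s > acc_from && s <= acc_to) {
        if (n0 > 0) {
          if (occ_sum.size() < cnt.size()) occ_sum.resize(cnt.size(), 0.0);
          for (size_t k = 0; k < cnt.size(); ++k) occ_sum[k] += (double)cnt[k];
          ++occ_n;
        } else {
          acc_truncated = true;
        }
      }
    }
    if (n0 == 0 && extinct_step < 0) {
      extinct_step = s;
      if (stop_extinct) {
        if (!at_sample) record(s);
        break;
      }
    }
  }

  IntegerVector final_counts(cnt.size());
  for (size_t k = 0; k < cnt.size(); ++k) final_counts[k] = (int)cnt[k];

  return List::create(
      _["time"] = wrap(s_time), _["rbar"] = wrap(s_rbar), _["n0"] = wrap(s_n0),
      _["repairs"] = wrap(s_rep), _["apoptoses"] = wrap(s_apo),
      _["mutations"] = wrap(s_mut), _["final_counts"] = final_counts,
      _["extinct_step"] = (double)extinct_step,
      _["occ_sum"] = wrap(occ_sum), _["occ_n"] = (double)occ_n,
      _["acc_truncated"] = acc_truncated);
}

// Uniform neighbour of `site` (0-based linear index) on a periodic simple
// square/cubic lattice, von Neumann connectivity.
static inline long vn_neighbor(long site, const std::vector<long>& dim) {
  int d = (int)dim.size();
  int k = (int)(unif_rand() * (2 * d));
  if (k >= 2 * d) k = 2 * d - 1;
  int axis = k / 2;
  int dir = (k % 2 == 0) ? -1 : 1;
  // decompose site into coordinates
  long coord[3] = {0, 0, 0};
  long rem = site;
  for (int ax = 0; ax < d; ++ax) {
    coord[ax] = rem % dim[ax];
    rem /= dim[ax];
  }
  coord[axis] = (coord[axis] + dir + dim[axis]) % dim[axis];
  long idx = 0, stride = 1;
  for (int ax = 0; ax < d; ++ax) {
    idx += coord[ax] * stride;
    stride *= dim[ax];
  }
  return idx;
}

// Stochastic engine on a lattice: identical per-cell rules, but on apoptosis
// the dividing cell is a uniformly chosen lattice neighbour of the dead site
// (von Neumann neighbourhood, periodic boundaries). With complete_graph the
// divider is uniform over the other N-1 sites, which reproduces the
// well-mixed law on the same per-site representation.
// [[Rcpp::export]]
List run_lattice_cpp(IntegerVector levels0, IntegerVector dims_in,
                     double r0, double delta, double a,
                     double n_steps_d, double sample_every_d,
                     bool stop_extinct, bool complete_graph) {
  const long long n_steps = (long long)n_steps_d;
  long long sample_every = (long long)sample_every_d;
  if (sample_every < 1) sample_every = 1;

  std::vector<long> lev(levels0.begin(), levels0.end());
  const long N = (long)lev.size();
  std::vector<long> dim(dims_in.begin(), dims_in.end());

  long n0 = 0;
  for (long c = 0; c < N; ++c) if (lev[c] == 0) ++n0;
  long long n_rep = 0, n_apo = 0, n_mut = 0;

  std::vector<double> s_time, s_rbar, s_n0, s_rep, s_apo, s_mut;
  long long extinct_step = -1;

  const double rp0 = repair_prob(r0, delta, 0);
  auto record = [&](long long s) {
    double sr = 0.0;
    for (long c = 0; c < N; ++c) sr += repair_prob(r0, delta, lev[c]) - rp0;
    sr += rp0 * (double)N;
    s_time.push_back((double)s);
    s_rbar.push_back(sr / (double)N);
    s_n0.push_back((double)n0);
    s_rep.push_back((double)n_rep);
    s_apo.push_back((double)n_apo);
    s_mut.push_back((double)n_mut);
  };
  record(0);

  for (long long s = 1; s <= n_steps; ++s) {
    long c = (long)(unif_rand() * N);
    if (c >= N) c = N - 1;
    double Ri = repair_prob(r0, delta, lev[c]);
    double v = unif_rand();
    if (v < Ri) {
      ++n_rep;
    } else if (unif_rand() < a) {
      long p;
      if (complete_graph) {
        p = (long)(unif_rand() * (N - 1));
        if (p >= N - 1) p = N - 2;
        if (p >= c) ++p;
      } else {
        p = vn_neighbor(c, dim);
      }
      if (lev[c] == 0) --n0;
      lev[c] = lev[p];
      if (lev[c] == 0) ++n0;
      ++n_apo;
    } else {
      if (lev[c] == 0) --n0;
      lev[c] += 1;
      ++n_mut;
    }

    bool at_sample = (s % sample_every == 0);
    if (at_sample) record(s);
    if (n0 == 0 && extinct_step < 0) {
      extinct_step = s;
      if (stop_extinct) {
        if (!at_sample) record(s);
        break;
      }
    }
  }

  IntegerVector final_levels(lev.begin(), lev.end());
  return List::create(
      _["time"] = wrap(s_time), _["rbar"] = wrap(s_rbar), _["n0"] = wrap(s_n0),
      _["repairs"] = wrap(s_rep), _["apoptoses"] = wrap(s_apo),
      _["mutations"] = wrap(s_mut), _["final_levels"] = final_levels,
      _["extinct_step"] = (double)extinct_step);
}

// Agent-list engine used solely for per-cell lifetime bookkeeping: each cell
// carries its mutation level and the number of damage events it has
// experienced since birth. At apoptosis the dying cell's event count
// (including the fatal event) is recorded, provided it was born after the
// burn-in; the replacement daughter copies a random survivor's level and
// starts a fresh event count.
// [[Rcpp::export]]
List run_agents_cpp(int N, double r0, double delta, double a,
                    double n_steps_d, double burn_in_steps_d) {
  const long long n_steps = (long long)n_steps_d;
  const long long burn_in = (long long)burn_in_steps_d;
  std::vector<long> lev(N, 0);
  std::vector<long> dmg(N, 0);
  std::vector<long long> born(N, -1);  // -1: present since initialisation
  std::vector<double> lifetimes;
  long long n_rep = 0, n_apo = 0, n_mut = 0;

  for (long long s = 1; s <= n_steps; ++s) {
    int c = (int)(unif_rand() * N);
    if (c >= N) c = N - 1;
    dmg[c] += 1;
    double Ri = repair_prob(r0, delta, lev[c]);
    double v = unif_rand();
    if (v < Ri) {
      ++n_rep;
    } else if (unif_rand() < a) {
      if (born[c] >= burn_in) lifetimes.push_back((double)dmg[c]);
      int p = (int)(unif_rand() * (N - 1));
      if (p >= N - 1) p = N - 2;
      if (p >= c) ++p;
      lev[c] = lev[p];
      dmg[c] = 0;
      born[c] = s;
      ++n_apo;
    } else {
      lev[c] += 1;
      ++n_mut;
    }
  }
  return List::create(_["lifetimes"] = wrap(lifetimes),
                      _["repairs"] = (double)n_rep,
                      _["apoptoses"] = (double)n_apo,
                      _["mutations"] = (double)n_mut);
}
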