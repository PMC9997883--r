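// Act-CPM lattice kernel.
//
// Cells are collections of lattice pixels on a 2D torus. Dynamics proceed by
// Metropolis-accepted identity-copy attempts biased by an energy difference
// combining adhesion, volume- and perimeter-constraint terms, plus a
// protrusion-activity term: pixels recently gained by a cell carry an
// "activity" that decays by 1 per Monte Carlo step (MCS) from max_act, and
// copy attempts from more into less active regions are energetically
// favoured (strength lambda_act / max_act).
//
// One MCS = width*height attempts, each picking a uniform source pixel and a
// uniform Moore neighbour as target. Attempts whose source pixel has no
// unlike neighbour can never change the state, so the kernel skips runs of
// them with a geometric draw and samples the source among interface pixels;
// this is an exact algebraic shortcut, not an approximation: the sequence of
// non-trivial attempts has the same distribution as under naive uniform
// sampling, and the attempt budget per MCS is kept identical.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded through splitmix64. All kernel randomness flows
// from the single 64-bit seed passed in from R.

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      // splitmix64
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1): never exactly 0, so log(u) is safe
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline uint32_t below(uint32_t n) { return (uint32_t)(next() % n); }
};

inline bool metro_accept(Xoshiro& rng, double dh, double temperature) {
  if (dh <= 0.0) return true;
  return rng.unif() < std::exp(-dh / temperature);
}

// ---------------------------------------------------------------------------
// Lattice context. Pixel p = x + y*W (column-major over an R matrix with
// nrow = width). Cell id 0 is the background medium.

struct CPM {
  int W, H, N, ncell, ntype;
  std::vector<int> id;
  std::vector<double> act;
  std::vector<int> nb;  // 8 Moore neighbours per pixel, torus wrap
  // per cell id (index 0 = background, constraint-free)
  std::vector<int> type;
  std::vector<double> Vt, lamV, Pt, lamP, maxact, lamact;
  std::vector<double> vol, perim;
  std::vector<double> J;  // (ntype+1)^2, type 0 = background
  double temperature;

  inline double Jat(int t1, int t2) const { return J[t1 * (ntype + 1) + t2]; }

  void build_neighbours() {
    nb.assign((size_t)N * 8, 0);
    for (int p = 0; p < N; ++p) {
      int x = p % W, y = p / W, k = 0;
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0) continue;
          int nx = (x + dx + W) % W, ny = (y + dy + H) % H;
          nb[(size_t)p * 8 + k++] = nx + ny * W;
        }
    }
  }

  void recount() {
    vol.assign(ncell + 1, 0.0);
    perim.assign(ncell + 1, 0.0);
    for (int p = 0; p < N; ++p) {
      int c = id[p];
      if (c == 0) continue;
      vol[c] += 1.0;
      for (int k = 0; k < 8; ++k)
        if (id[nb[(size_t)p * 8 + k]] != c) perim[c] += 1.0;
    }
  }
};

void cpm_from_r(CPM& c, const IntegerMatrix& identity,
                const NumericMatrix& activity, const NumericMatrix& cell_params,
                const NumericMatrix& adhesion, double temperature) {
  c.W = identity.nrow();
  c.H = identity.ncol();
  c.N = c.W * c.H;
  c.ncell = cell_params.nrow();
  c.ntype = adhesion.nrow() - 1;
  c.temperature = temperature;
  c.id.assign(identity.begin(), identity.end());
  c.act.assign(activity.begin(), activity.end());
  c.type.assign(c.ncell + 1, 0);
  c.Vt.assign(c.ncell + 1, 0.0);
  c.lamV.assign(c.ncell + 1, 0.0);
  c.Pt.assign(c.ncell + 1, 0.0);
  c.lamP.assign(c.ncell + 1, 0.0);
  c.maxact.assign(c.ncell + 1, 0.0);
  c.lamact.assign(c.ncell + 1, 0.0);
  for (int i = 0; i < c.ncell; ++i) {
    c.type[i + 1] = (int)cell_params(i, 0);
    c.Vt[i + 1] = cell_params(i, 1);
    c.lamV[i + 1] = cell_params(i, 2);
    c.Pt[i + 1] = cell_params(i, 3);
    c.lamP[i + 1] = cell_params(i, 4);
    c.maxact[i + 1] = cell_params(i, 5);
    c.lamact[i + 1] = cell_params(i, 6);
  }
  c.J.assign(adhesion.begin(), adhesion.end());
  c.build_neighbours();
  c.recount();
}

// ---------------------------------------------------------------------------
// Energy differences for copying id[src] into tgt.

double dh_adhesion(const CPM& c, int src, int tgt) {
  const int newid = c.id[src], oldid = c.id[tgt];
  const int tn = c.type[newid], to = c.type[oldid];
  double d = 0.0;
  for (int k = 0; k < 8; ++k) {
    int qid = c.id[c.nb[(size_t)tgt * 8 + k]];
    if (qid != newid) d += c.Jat(tn, c.type[qid]);
    if (qid != oldid) d -= c.Jat(to, c.type[qid]);
  }
  return d;
}

double dh_volume(const CPM& c, int src, int tgt) {
  const int newid = c.id[src], oldid = c.id[tgt];
  double d = 0.0;
  if (newid != 0) {
    double dv = c.vol[newid] - c.Vt[newid];
    d += c.lamV[newid] * ((dv + 1.0) * (dv + 1.0) - dv * dv);
  }
  if (oldid != 0) {
    double dv = c.vol[oldid] - c.Vt[oldid];
    d += c.lamV[oldid] * ((dv - 1.0) * (dv - 1.0) - dv * dv);
  }
  return d;
}

double dh_perimeter(const CPM& c, int src, int tgt) {
  const int newid = c.id[src], oldid = c.id[tgt];
  int n_new = 0, n_old = 0;
  for (int k = 0; k < 8; ++k) {
    int qid = c.id[c.nb[(size_t)tgt * 8 + k]];
    if (qid == newid) ++n_new;
    if (qid == oldid) ++n_old;
  }
  double d = 0.0;
  if (newid != 0) {
    double dp = c.perim[newid] - c.Pt[newid];
    double np = dp + (8.0 - 2.0 * n_new);
    d += c.lamP[newid] * (np * np - dp * dp);
  }
  if (oldid != 0) {
    double dp = c.perim[oldid] - c.Pt[oldid];
    double np = dp + (2.0 * n_old - 8.0);
    d += c.lamP[oldid] * (np * np - dp * dp);
  }
  return d;
}

// Geometric mean of activity over {p} plus same-cell Moore neighbours;
// 0 for background pixels and whenever any included activity is 0.
double gm_act(const CPM& c, int p) {
  const int pid = c.id[p];
  if (pid == 0) return 0.0;
  double prod = c.act[p];
  if (prod <= 0.0) return 0.0;
  int n = 1;
  for (int k = 0; k < 8; ++k) {
    int q = c.nb[(size_t)p * 8 + k];
    if (c.id[q] == pid) {
      if (c.act[q] <= 0.0) return 0.0;
      prod *= c.act[q];
      ++n;
    }
  }
  return std::pow(prod, 1.0 / n);
}

// Protrusion-activity term. Parameters are taken from the source pixel's
// cell, or from the target's cell when the source is background (so that
// retraction of an active protrusion by the medium is resisted).
double dh_act(const CPM& c, int src, int tgt) {
  const int sid = c.id[src], tid = c.id[tgt];
  const int ref = (sid != 0) ? sid : tid;
  const double ma = c.maxact[ref], la = c.lamact[ref];
  if (ma <= 0.0 || la == 0.0) return 0.0;
  return -(la / ma) * (gm_act(c, src) - gm_act(c, tgt));
}

inline double dh_total(const CPM& c, int src, int tgt) {
  return dh_adhesion(c, src, tgt) + dh_volume(c, src, tgt) +
         dh_perimeter(c, src, tgt) + dh_act(c, src, tgt);
}

// ---------------------------------------------------------------------------
// Connectedness: probability that two uniformly drawn pixels of a cell lie
// in the same Moore-connected component, C = sum_k (n_k / N)^2.

double connectedness_of(const CPM& c, int cell,
                        std::vector<int>& stamp, int& stamp_val,
                        std::vector<int>& stack) {
  ++stamp_val;
  double total = 0.0, sumsq = 0.0;
  for (int p = 0; p < c.N; ++p)
    if (c.id[p] == cell) total += 1.0;
  if (total == 0.0) return 0.0;
  for (int p0 = 0; p0 < c.N; ++p0) {
    if (c.id[p0] != cell || stamp[p0] == stamp_val) continue;
    double sz = 0.0;
    stack.clear();
    stack.push_back(p0);
    stamp[p0] = stamp_val;
    while (!stack.empty()) {
      int p = stack.back();
      stack.pop_back();
      sz += 1.0;
      for (int k = 0; k < 8; ++k) {
        int q = c.nb[(size_t)p * 8 + k];
        if (c.id[q] == cell && stamp[q] != stamp_val) {
          stamp[q] = stamp_val;
          stack.push_back(q);
        }
      }
    }
    double f = sz / total;
    sumsq += f * f;
  }
  return sumsq;
}

}  // namespace

// ---------------------------------------------------------------------------
// Exported: energy difference of a single candidate copy, by component.
// Shares the exact code paths used inside the simulation loop.

// [[Rcpp::export]]
List cpm_delta_h_kernel(IntegerMatrix identity, NumericMatrix activity,
                        NumericMatrix cell_params, NumericMatrix adhesion,
                        double temperature, int source, int target) {
  CPM c;
  cpm_from_r(c, identity, activity, cell_params, adhesion, temperature);
  int src = source - 1, tgt = target - 1;
  if (src < 0 || src >= c.N || tgt < 0 || tgt >= c.N)
    stop("pixel index out of range");
  if (c.id[src] == c.id[tgt])
    stop("source and target belong to the same cell");
  return List::create(
      _["adhesion"] = dh_adhesion(c, src, tgt),
      _["volume"] = dh_volume(c, src, tgt),
      _["perimeter"] = dh_perimeter(c, src, tgt),
      _["act"] = dh_act(c, src, tgt),
      _["total"] = dh_total(c, src, tgt));
}

// [[Rcpp::export]]
double cpm_gm_act_kernel(IntegerMatrix identity, NumericMatrix activity,
                         int pixel) {
  CPM c;
  c.W = identity.nrow();
  c.H = identity.ncol();
  c.N = c.W * c.H;
  c.id.assign(identity.begin(), identity.end());
  c.act.assign(activity.begin(), activity.end());
  c.build_neighbours();
  return gm_act(c, pixel - 1);
}

// [[Rcpp::export]]
double cpm_connectedness_kernel(IntegerMatrix identity, int cell_id) {
  CPM c;
  c.W = identity.nrow();
  c.H = identity.ncol();
  c.N = c.W * c.H;
  c.id.assign(identity.begin(), identity.end());
  c.build_neighbours();
  std::vector<int> stamp(c.N, 0), stack;
  int stamp_val = 0;
  return connectedness_of(c, cell_id, stamp, stamp_val, stack);
}

// [[Rcpp::export]]
int cpm_metropolis_trials(double dh, double temperature, int n, double seed) {
  Xoshiro rng((uint64_t)seed);
  int acc = 0;
  for (int i = 0; i < n; ++i)
    if (metro_accept(rng, dh, temperature)) ++acc;
  return acc;
}

// ---------------------------------------------------------------------------
// Main simulation kernel: advance `n_mcs` Monte Carlo steps. Optionally logs
// the (torus-unwrapped) centroid of `track_cell` every `log_interval` MCS,
// accumulates the set of pixels that cell ever occupied, and evaluates its
// connectedness at every log point.

// [[Rcpp::export]]
List cpm_run_kernel(IntegerMatrix identity, NumericMatrix activity,
                    NumericMatrix cell_params, NumericMatrix adhesion,
                    double temperature, int n_mcs, double seed,
                    int track_cell, int log_interval, bool log_connectedness) {
  CPM c;
  cpm_from_r(c, identity, activity, cell_params, adhesion, temperature);
  Xoshiro rng((uint64_t)seed);

  // interface ("border") pixels: at least one unlike Moore neighbour
  std::vector<int> border, bpos(c.N, -1);
  auto is_border = [&](int p) {
    for (int k = 0; k < 8; ++k)
      if (c.id[c.nb[(size_t)p * 8 + k]] != c.id[p]) return true;
    return false;
  };
  auto update_border = [&](int p) {
    bool b = is_border(p);
    if (b && bpos[p] < 0) {
      bpos[p] = (int)border.size();
      border.push_back(p);
    } else if (!b && bpos[p] >= 0) {
      int last = border.back();
      border[bpos[p]] = last;
      bpos[last] = bpos[p];
      border.pop_back();
      bpos[p] = -1;
    }
  };
  for (int p = 0; p < c.N; ++p) update_border(p);

  // pixels with positive activity (superset; compacted during decay)
  std::vector<int> active;
  std::vector<char> in_active(c.N, 0);
  for (int p = 0; p < c.N; ++p)
    if (c.act[p] > 0.0) {
      active.push_back(p);
      in_active[p] = 1;
    }

  // explored-pixel accounting for the tracked cell
  std::vector<char> explored(track_cell > 0 ? c.N : 0, 0);
  int explored_count = 0;
  if (track_cell > 0)
    for (int p = 0; p < c.N; ++p)
      if (c.id[p] == track_cell) {
        explored[p] = 1;
        ++explored_count;
      }

  std::vector<int> annihilated_ids;
  bool tracked_annihilated = false;

  // centroid logging with minimal-image unwrapping
  int n_logs = (track_cell > 0) ? (n_mcs / std::max(log_interval, 1) + 1) : 0;
  NumericMatrix track(std::max(n_logs, 0), 3);
  NumericVector connect_log(log_connectedness ? n_logs : 0);
  std::vector<int> stamp(c.N, 0), ccstack;
  int stamp_val = 0;
  double prev_x = 0.0, prev_y = 0.0, unwrap_x = 0.0, unwrap_y = 0.0;
  int log_i = 0;
  double min_connect = 1.0;

  auto log_point = [&](int mcs) {
    // centroid as minimal-image mean offset from the previous logged centroid
    double sx = 0.0, sy = 0.0, n = 0.0;
    bool have_ref = (log_i > 0);
    double rx = prev_x, ry = prev_y;
    for (int p = 0; p < c.N; ++p) {
      if (c.id[p] != track_cell) continue;
      double x = (double)(p % c.W), y = (double)(p / c.W);
      if (!have_ref) {  // first pixel anchors the reference frame
        rx = x;
        ry = y;
        have_ref = true;
      }
      double dx = x - rx, dy = y - ry;
      dx -= c.W * std::round(dx / c.W);
      dy -= c.H * std::round(dy / c.H);
      sx += dx;
      sy += dy;
      n += 1.0;
    }
    if (n == 0.0) return;  // annihilated; caller handles
    double mx = rx + sx / n, my = ry + sy / n;
    if (log_i == 0) {
      unwrap_x = mx;
      unwrap_y = my;
    } else {
      double dx = mx - prev_x, dy = my - prev_y;
      dx -= c.W * std::round(dx / c.W);
      dy -= c.H * std::round(dy / c.H);
      unwrap_x += dx;
      unwrap_y += dy;
    }
    prev_x = mx - c.W * std::floor(mx / c.W);
    prev_y = my - c.H * std::floor(my / c.H);
    track(log_i, 0) = (double)mcs;
    track(log_i, 1) = unwrap_x;
    track(log_i, 2) = unwrap_y;
    if (log_connectedness) {
      double cc = connectedness_of(c, track_cell, stamp, stamp_val, ccstack);
      connect_log[log_i] = cc;
      if (cc < min_connect) min_connect = cc;
    }
    ++log_i;
  };

  if (track_cell > 0) log_point(0);

  const double logN = std::log((double)c.N);
  for (int mcs = 1; mcs <= n_mcs && !tracked_annihilated; ++mcs) {
    long attempts = c.N;
    while (attempts > 0) {
      int nbord = (int)border.size();
      if (nbord == 0) break;
      if (nbord < c.N) {
        // geometric number of trivial (non-interface-source) attempts
        double log1mp = std::log1p(-(double)nbord / c.N);
        long k = (long)std::floor(std::log(rng.unif()) / log1mp);
        if (k >= attempts) break;
        attempts -= k;
      }
      --attempts;
      int src = border[rng.below((uint32_t)nbord)];
      int tgt = c.nb[(size_t)src * 8 + rng.below(8)];
      if (c.id[src] == c.id[tgt]) continue;
      double dh = dh_total(c, src, tgt);
      if (!metro_accept(rng, dh, c.temperature)) continue;

      // apply the copy
      const int newid = c.id[src], oldid = c.id[tgt];
      int n_new = 0, n_old = 0;
      for (int k = 0; k < 8; ++k) {
        int qid = c.id[c.nb[(size_t)tgt * 8 + k]];
        if (qid == newid) ++n_new;
        if (qid == oldid) ++n_old;
      }
      if (newid != 0) {
        c.vol[newid] += 1.0;
        c.perim[newid] += 8.0 - 2.0 * n_new;
      }
      if (oldid != 0) {
        c.vol[oldid] -= 1.0;
        c.perim[oldid] += 2.0 * n_old - 8.0;
      }
      c.id[tgt] = newid;
      c.act[tgt] = c.maxact[newid];  // background assigns 0
      if (c.act[tgt] > 0.0 && !in_active[tgt]) {
        active.push_back(tgt);
        in_active[tgt] = 1;
      }
      if (track_cell > 0 && newid == track_cell && !explored[tgt]) {
        explored[tgt] = 1;
        ++explored_count;
      }
      update_border(tgt);
      for (int k = 0; k < 8; ++k) update_border(c.nb[(size_t)tgt * 8 + k]);
      if (oldid != 0 && c.vol[oldid] <= 0.0) {
        annihilated_ids.push_back(oldid);
        if (oldid == track_cell) {
          tracked_annihilated = true;
          break;
        }
      }
    }

    // activity decay: -1 per MCS, floored at 0
    size_t w = 0;
    for (size_t i = 0; i < active.size(); ++i) {
      int p = active[i];
      if (c.act[p] > 0.0) {
        c.act[p] -= 1.0;
        if (c.act[p] < 0.0) c.act[p] = 0.0;
      }
      if (c.act[p] > 0.0)
        active[w++] = p;
      else
        in_active[p] = 0;
    }
    active.resize(w);

    if (track_cell > 0 && !tracked_annihilated && mcs % log_interval == 0)
      log_point(mcs);
  }
  (void)logN;

  IntegerMatrix out_id(c.W, c.H);
  NumericMatrix out_act(c.W, c.H);
  std::copy(c.id.begin(), c.id.end(), out_id.begin());
  std::copy(c.act.begin(), c.act.end(), out_act.begin());
  if (track_cell > 0 && log_i < n_logs) {
    track = NumericMatrix(wrap(track(Range(0, std::max(log_i - 1, 0)), _)));
    if (log_connectedness && log_i > 0)
      connect_log = connect_log[Range(0, log_i - 1)];
  }
  return List::create(
      _["identity"] = out_id, _["activity"] = out_act, _["track"] = track,
      _["explored"] = explored_count,
      _["connectedness"] = connect_log,
      _["min_connectedness"] = min_connect,
      _["annihilated"] = tracked_annihilated,
      _["annihilated_ids"] = wrap(annihilated_ids),
      _["volumes"] = NumericVector(c.vol.begin() + 1, c.vol.end()),
      _["perimeters"] = NumericVector(c.perim.begin() + 1, c.perim.end()));
}
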