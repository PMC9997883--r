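// Run-and-pause random walk ("Beauchemin-style" T-cell motility model) and
// its disc-coverage fitness. Cells alternate straight runs of duration
// t_free at speed v_free (direction uniform on the circle, redrawn at the
// start of every run) with stationary pauses of duration t_pause. Positions
// are reported at integer time steps, interpolating within runs.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
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
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

}  // namespace

// [[Rcpp::export]]
NumericMatrix beauchemin_track_kernel(double v_free, double t_free,
                                      double t_pause, int duration,
                                      double seed) {
  Xoshiro rng((uint64_t)seed);
  NumericMatrix track(duration + 1, 3);
  double x = 0.0, y = 0.0;
  bool running = true;  // walks start with a run, direction drawn at t = 0
  double theta = 2.0 * M_PI * rng.unif();
  double dx = std::cos(theta), dy = std::sin(theta);
  double time_left = t_free;
  track(0, 0) = 0.0;
  for (int step = 1; step <= duration; ++step) {
    double dt = 1.0;
    while (dt > 0.0) {
      double adv = (time_left < dt) ? time_left : dt;
      if (running) {
        x += v_free * dx * adv;
        y += v_free * dy * adv;
      }
      time_left -= adv;
      dt -= adv;
      if (time_left <= 0.0) {
        running = !running;
        if (running) {
          theta = 2.0 * M_PI * rng.unif();
          dx = std::cos(theta);
          dy = std::sin(theta);
          time_left = t_free;
        } else {
          time_left = t_pause;
        }
      }
    }
    track(step, 0) = (double)step;
    track(step, 1) = x;
    track(step, 2) = y;
  }
  return track;
}

// Count of distinct integer lattice points falling within Euclidean distance
// <= r of at least one sampled track position (the lattice area of the union
// of the track's discs). Each disc contributes one contiguous y-interval per
// integer x-column; the union is resolved per column by an interval sweep,
// which counts every point exactly once without enumerating points.

// [[Rcpp::export]]
double disc_cover_kernel(NumericMatrix track, double r) {
  const int n = track.nrow();
  const double r2 = r * r;
  if (n == 0) return 0.0;
  struct Span {
    int col, y0, y1;
    bool operator<(const Span& o) const {
      if (col != o.col) return col < o.col;
      if (y0 != o.y0) return y0 < o.y0;
      return y1 < o.y1;
    }
  };
  double xmin = R_PosInf, xmax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if (track(i, 1) < xmin) xmin = track(i, 1);
    if (track(i, 1) > xmax) xmax = track(i, 1);
  }
  const int col0 = (int)std::floor(xmin - r) - 1;
  const long ncols = (long)std::floor(xmax + r) + 2 - col0;
  std::vector<Span> spans;
  spans.reserve((size_t)n * (2 * (int)r + 2));
  double px = 0.0, py = 0.0;
  bool have_prev = false;
  for (int i = 0; i < n; ++i) {
    double cx = track(i, 1), cy = track(i, 2);
    if (have_prev && cx == px && cy == py) continue;
    int x0 = (int)std::ceil(cx - r), x1 = (int)std::floor(cx + r);
    for (int ix = x0; ix <= x1; ++ix) {
      double ddx = ix - cx;
      double rem = r2 - ddx * ddx;
      if (rem < 0.0) continue;
      double h = std::sqrt(rem);
      int y0 = (int)std::ceil(cy - h), y1 = (int)std::floor(cy + h);
      if (y0 <= y1) spans.push_back(Span{ix - col0, y0, y1});
    }
    px = cx;
    py = cy;
    have_prev = true;
  }
  if (spans.empty()) return 0.0;
  // group by column: counting sort when the x-span is moderate (two O(N)
  // passes), comparison sort otherwise; then union per column by sweep
  std::vector<Span> sorted;
  if (ncols <= (16L << 20)) {
    std::vector<int> cnt((size_t)ncols + 1, 0);
    for (size_t k = 0; k < spans.size(); ++k) ++cnt[spans[k].col + 1];
    for (long c = 0; c < ncols; ++c) cnt[c + 1] += cnt[c];
    sorted.resize(spans.size());
    for (size_t k = 0; k < spans.size(); ++k)
      sorted[cnt[spans[k].col]++] = spans[k];
  } else {
    sorted.swap(spans);
    std::sort(sorted.begin(), sorted.end());
  }
  double total = 0.0;
  size_t k = 0;
  while (k < sorted.size()) {
    size_t k1 = k;
    while (k1 < sorted.size() && sorted[k1].col == sorted[k].col) ++k1;
    std::sort(sorted.begin() + k, sorted.begin() + k1);
    int lo = sorted[k].y0, hi = sorted[k].y1;
    for (size_t j = k + 1; j < k1; ++j) {
      if (sorted[j].y0 > hi + 1) {
        total += hi - lo + 1;
        lo = sorted[j].y0;
        hi = sorted[j].y1;
      } else if (sorted[j].y1 > hi) {
        hi = sorted[j].y1;
      }
    }
    total += hi - lo + 1;
    k = k1;
  }
  return total;
}
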