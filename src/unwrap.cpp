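#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Quality-guided 2D phase unwrapping. Pixels are integrated flood-fill style
// from the highest-quality seed; the frontier is a max-heap on quality with a
// deterministic row-major tie-break, so results are fully reproducible.
struct QItem {
  double q;
  int idx;   // column-major linear index of the pixel to set
  int from;  // already-unwrapped neighbour it is reached from
};
struct QLess {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.q != b.q) return a.q < b.q;
    // prefer smaller row-major index for equal quality
    return a.idx > b.idx;
  }
};

// floor-based rather than fmod-based: keeps the shared object free of
// versioned libm symbols newer than the runtime glibc provides
static inline double wrap_pi(double x) {
  return x - 2.0 * M_PI * std::floor((x + M_PI) / (2.0 * M_PI));
}

// [[Rcpp::export(name = ".cpp_unwrap_qg")]]
NumericMatrix cpp_unwrap_qg(NumericMatrix wrapped, NumericMatrix quality,
                            int seed_idx) {
  const int nr = wrapped.nrow(), nc = wrapped.ncol(), n = nr * nc;
  NumericMatrix out(nr, nc);
  std::vector<char> done(n, 0);
  std::priority_queue<QItem, std::vector<QItem>, QLess> pq;
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};

  out[seed_idx] = wrapped[seed_idx];
  done[seed_idx] = 1;
  int settled = 1;
  {
    int r = seed_idx % nr, c = seed_idx / nr;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = rr + cc * nr;
      pq.push({quality[j], j, seed_idx});
    }
  }
  while (!pq.empty() && settled < n) {
    QItem it = pq.top(); pq.pop();
    if (done[it.idx]) continue;
    out[it.idx] = out[it.from] + wrap_pi(wrapped[it.idx] - wrapped[it.from]);
    done[it.idx] = 1;
    ++settled;
    int r = it.idx % nr, c = it.idx / nr;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = rr + cc * nr;
      if (!done[j]) pq.push({quality[j], j, it.idx});
    }
  }
  return out;
}
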