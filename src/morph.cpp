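#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Binary morphology support: connected-component labelling, border-connected
// background flood (hole filling) and marker-seeded watershed on an inverted
// density map. All scans are column-major and tie-breaks index-ordered, so
// outputs are deterministic.

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(LogicalMatrix bw, int connectivity) {
  const int nr = bw.nrow(), nc = bw.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  for (int i = 0; i < nr * nc; ++i) {
    if (!bw[i] || lab[i]) continue;
    ++next;
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int r = p % nr, c = p / nr;
      for (int k = 0; k < nnb; ++k) {
        int rr = r + dr8[k], cc = c + dc8[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int j = rr + cc * nr;
        if (bw[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  lab.attr("count") = next;
  return lab;
}

// Background pixels 4-connected to the image border; holes are background
// pixels NOT reached by this flood.
// [[Rcpp::export(name = ".cpp_border_background")]]
LogicalMatrix cpp_border_background(LogicalMatrix bw) {
  const int nr = bw.nrow(), nc = bw.ncol();
  LogicalMatrix reach(nr, nc);
  std::vector<int> stack;
  auto push = [&](int r, int c) {
    int j = r + c * nr;
    if (!bw[j] && !reach[j]) { reach[j] = true; stack.push_back(j); }
  };
  for (int r = 0; r < nr; ++r) { push(r, 0); push(r, nc - 1); }
  for (int c = 0; c < nc; ++c) { push(0, c); push(nr - 1, c); }
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    int r = p % nr, c = p / nr;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      push(rr, cc);
    }
  }
  return reach;
}

struct WItem {
  double d;   // density at pixel (flood descends density)
  int ord;    // insertion order, FIFO tie-break for determinism
  int idx;
  int label;
};
struct WLess {
  bool operator()(const WItem& a, const WItem& b) const {
    if (a.d != b.d) return a.d < b.d;
    return a.ord > b.ord;
  }
};

// Marker-seeded watershed restricted to region (logical mask). Markers is an
// integer matrix, 0 outside seeds. Floods from seeds in order of decreasing
// density, equivalent to watershed on the inverted density map.
// [[Rcpp::export(name = ".cpp_marker_watershed")]]
IntegerMatrix cpp_marker_watershed(NumericMatrix density, LogicalMatrix region,
                                   IntegerMatrix markers) {
  const int nr = density.nrow(), nc = density.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WItem, std::vector<WItem>, WLess> pq;
  int ord = 0;
  for (int i = 0; i < nr * nc; ++i) {
    if (markers[i] > 0 && region[i]) {
      lab[i] = markers[i];
      pq.push({density[i], ord++, i, markers[i]});
    }
  }
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  while (!pq.empty()) {
    WItem it = pq.top(); pq.pop();
    int r = it.idx % nr, c = it.idx / nr;
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int j = rr + cc * nr;
      if (region[j] && lab[j] == 0) {
        lab[j] = it.label;
        pq.push({density[j], ord++, j, it.label});
      }
    }
  }
  return lab;
}
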