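#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Meyer's marker-based watershed with watershed lines.
// topo: flooding surface; markers: 0 = unassigned, >0 = seed labels;
// usable: pixels eligible for flooding (masked-out pixels stay 0).
// 4-connected flooding; pixels reached simultaneously from two or more
// distinct labels become watershed-line pixels (label 0, final).
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix topo, IntegerMatrix markers,
                            LogicalMatrix usable) {
  const int nr = topo.nrow(), nc = topo.ncol();
  IntegerMatrix lab(nr, nc);
  // state: 0 = untouched, 1 = queued, 2 = final
  std::vector<unsigned char> state((size_t)nr * nc, 0);

  struct QEl {
    double v;
    unsigned long ord;
    int r, c;
  };
  struct Cmp {
    bool operator()(const QEl& a, const QEl& b) const {
      if (a.v != b.v) return a.v > b.v;   // min-heap on height
      return a.ord > b.ord;               // FIFO tie-break
    }
  };
  std::priority_queue<QEl, std::vector<QEl>, Cmp> pq;
  unsigned long ord = 0;

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  auto at = [&](int r, int c) -> size_t { return (size_t)r + (size_t)c * nr; };

  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!usable(r, c)) { state[at(r, c)] = 2; continue; }
      if (markers(r, c) > 0) {
        lab(r, c) = markers(r, c);
        state[at(r, c)] = 2;
      }
    }
  // queue unlabeled usable neighbors of markers
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (lab(r, c) <= 0 || state[at(r, c)] != 2 || !usable(r, c)) continue;
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (state[at(rr, cc)] == 0) {
          state[at(rr, cc)] = 1;
          pq.push({topo(rr, cc), ord++, rr, cc});
        }
      }
    }

  while (!pq.empty()) {
    QEl e = pq.top(); pq.pop();
    size_t p = at(e.r, e.c);
    if (state[p] == 2) continue;
    int found = 0; bool conflict = false;
    for (int k = 0; k < 4; ++k) {
      int rr = e.r + dr[k], cc = e.c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (state[at(rr, cc)] == 2 && lab(rr, cc) > 0) {
        if (found == 0) found = lab(rr, cc);
        else if (found != lab(rr, cc)) conflict = true;
      }
    }
    state[p] = 2;
    if (conflict || found == 0) {
      lab(e.r, e.c) = 0;  // watershed line (or isolated)
    } else {
      lab(e.r, e.c) = found;
    }
    for (int k = 0; k < 4; ++k) {
      int rr = e.r + dr[k], cc = e.c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (state[at(rr, cc)] == 0) {
        state[at(rr, cc)] = 1;
        pq.push({topo(rr, cc), ord++, rr, cc});
      }
    }
  }
  return lab;
}

// Connected-component labeling of a binary mask (BFS), connectivity 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> qr, qc;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      qr.clear(); qc.clear();
      qr.push_back(r); qc.push_back(c);
      lab(r, c) = next;
      size_t head = 0;
      while (head < qr.size()) {
        int cr = qr[head], cc0 = qc[head]; ++head;
        for (int k = 0; k < nnb; ++k) {
          int rr = cr + dr8[k], cc = cc0 + dc8[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            qr.push_back(rr); qc.push_back(cc);
          }
        }
      }
    }
  return lab;
}

// For every pixel, squared distances to the nearest and second-nearest of a
// set of generator points, plus the index (1-based) of the nearest.
// Used by the phantom generator to build Voronoi mosaics and boundary bands.
// [[Rcpp::export]]
List cpp_two_nearest(int nrow, int ncol, NumericVector cx, NumericVector cy) {
  const int n = cx.size();
  NumericMatrix d1(nrow, ncol), d2(nrow, ncol);
  IntegerMatrix idx(nrow, ncol);
  for (int c = 0; c < ncol; ++c) {
    double x = c;  // 0-based pixel-center coordinates
    for (int r = 0; r < nrow; ++r) {
      double y = r;
      double b1 = R_PosInf, b2 = R_PosInf;
      int bi = 0;
      for (int i = 0; i < n; ++i) {
        double dx = x - cx[i], dy = y - cy[i];
        double d = dx * dx + dy * dy;
        if (d < b1) { b2 = b1; b1 = d; bi = i + 1; }
        else if (d < b2) { b2 = d; }
      }
      d1(r, c) = b1; d2(r, c) = b2; idx(r, c) = bi;
    }
  }
  return List::create(_["d1"] = d1, _["d2"] = d2, _["nearest"] = idx);
}
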