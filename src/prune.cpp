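// Pruning of affine value pieces for the backward dynamic-programming
// solver of the discrete-dose optimal control problem.
//
// A piece (w, c) represents the affine function w . x + c of the 2-D
// population state x = (P, Q). The stage value function is the upper
// envelope of its pieces over the box [0, box1] x [0, box2] that encloses
// every reachable state. A piece may be discarded exactly when it nowhere
// exceeds the envelope of the remaining pieces; emptiness of the region
// where a piece is maximal is decided by Sutherland-Hodgman clipping of
// the box by the pairwise dominance half-planes. Candidates are processed
// strongest-first (largest value over a coarse grid) so that the greedy
// envelope stays close to minimal, and a final backward filter removes
// any residual mutual redundancy.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Pt { double x, y; };

// clip convex polygon by half-plane a.x + b.y >= c
static void clip(std::vector<Pt> &poly, std::vector<Pt> &tmp,
                 double a, double b, double c) {
  if (poly.empty()) return;
  tmp.clear();
  size_t n = poly.size();
  for (size_t i = 0; i < n; ++i) {
    const Pt &p = poly[i];
    const Pt &q = poly[(i + 1) % n];
    double vp = a * p.x + b * p.y - c;
    double vq = a * q.x + b * q.y - c;
    if (vp >= 0) tmp.push_back(p);
    if ((vp > 0) != (vq > 0) && vp != vq) {
      double t = vp / (vp - vq);
      if (t > 0 && t < 1)
        tmp.push_back({p.x + t * (q.x - p.x), p.y + t * (q.y - p.y)});
    }
  }
  poly.swap(tmp);
}

// does piece i exceed the envelope of `others` anywhere on the box?
static bool beats_somewhere(int i, const std::vector<int> &others,
                            const std::vector<double> &w1,
                            const std::vector<double> &w2,
                            const std::vector<double> &cc,
                            double bx, double by, double tol,
                            std::vector<Pt> &poly, std::vector<Pt> &tmp) {
  poly = {{0, 0}, {bx, 0}, {bx, by}, {0, by}};
  for (int j : others) {
    if (j == i) continue;
    clip(poly, tmp, w1[i] - w1[j], w2[i] - w2[j], cc[j] - cc[i] + tol);
    if (poly.empty()) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".prune_pieces")]]
IntegerVector prune_pieces(NumericMatrix W, NumericVector C,
                           NumericVector box, double tol) {
  const int n = W.nrow();
  if (n <= 1) {
    IntegerVector all(n);
    for (int i = 0; i < n; ++i) all[i] = i + 1;
    return all;
  }
  const double bx = box[0], by = box[1];
  std::vector<double> w1(n), w2(n), cc(n);
  for (int i = 0; i < n; ++i) {
    w1[i] = W(i, 0);
    w2[i] = W(i, 1);
    cc[i] = C[i];
  }

  // strength = maximum over a coarse grid of box points; grid argmaxes are
  // certainly part of the envelope
  const int g = 8;
  std::vector<double> strength(n, -HUGE_VAL);
  std::vector<char> certified(n, 0);
  for (int gi = 0; gi <= g; ++gi) {
    for (int gj = 0; gj <= g; ++gj) {
      double px = bx * gi / g, py = by * gj / g;
      int best = 0;
      double bv = -HUGE_VAL;
      for (int i = 0; i < n; ++i) {
        double v = w1[i] * px + w2[i] * py + cc[i];
        if (v > strength[i]) strength[i] = v;
        if (v > bv) { bv = v; best = i; }
      }
      certified[best] = 1;
    }
  }

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (certified[a] != certified[b]) return certified[a] > certified[b];
    return strength[a] > strength[b];
  });

  // greedy envelope construction, strongest candidates first
  std::vector<int> kept;
  std::vector<Pt> poly, tmp;
  poly.reserve(64);
  tmp.reserve(64);
  for (int idx = 0; idx < n; ++idx) {
    int i = order[idx];
    if (certified[i] || kept.empty() ||
        beats_somewhere(i, kept, w1, w2, cc, bx, by, tol, poly, tmp)) {
      kept.push_back(i);
    }
  }

  // backward filter: drop kept pieces covered by the rest of the kept set
  std::vector<char> alive(kept.size(), 1);
  for (int idx = (int)kept.size() - 1; idx >= 0; --idx) {
    std::vector<int> rest;
    rest.reserve(kept.size() - 1);
    for (size_t j = 0; j < kept.size(); ++j)
      if (alive[j] && (int)j != idx) rest.push_back(kept[j]);
    if (rest.empty()) break;
    if (!beats_somewhere(kept[idx], rest, w1, w2, cc, bx, by, tol,
                         poly, tmp))
      alive[idx] = 0;
  }
  std::vector<int> final_kept;
  for (size_t j = 0; j < kept.size(); ++j)
    if (alive[j]) final_kept.push_back(kept[j]);

  std::sort(final_kept.begin(), final_kept.end());
  IntegerVector out(final_kept.size());
  for (size_t i = 0; i < final_kept.size(); ++i) out[i] = final_kept[i] + 1;
  return out;
}
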