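#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// 8-connected component labelling of a binary mask (nonzero = foreground).
// Returns an integer matrix of labels (0 = background), labelled in scan order.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) != 0 && lab(i, j) == 0) {
        lab(i, j) = ++next;
        q.push(std::make_pair(i, j));
        while (!q.empty()) {
          std::pair<int, int> p = q.front(); q.pop();
          for (int k = 0; k < 8; ++k) {
            int ni = p.first + dr[k], nj = p.second + dc[k];
            if (ni >= 0 && ni < nr && nj >= 0 && nj < nc &&
                mask(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              q.push(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Moore tracing of the outer contour of a single 8-connected component.
// Returns c(n_axial, n_diagonal, n_corner): counts of axial and diagonal chain
// steps and of direction changes between consecutive steps. A one-pixel object
// yields c(0, 0, 0). Inner (hole) boundaries are never visited.
// [[Rcpp::export]]
NumericVector cpp_chain_stats(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  // pad by 1 to avoid bound checks
  std::vector<unsigned char> p((nr + 2) * (nc + 2), 0);
  int area = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mask(i, j) != 0) { p[(i + 1) + (j + 1) * (nr + 2)] = 1; ++area; }
  NumericVector out = NumericVector::create(0.0, 0.0, 0.0);
  if (area <= 1) return out;
  const int R = nr + 2;
  // start: topmost-leftmost foreground (row-major scan like manual tracing)
  int sr = -1, sc = -1;
  for (int i = 1; i <= nr && sr < 0; ++i)
    for (int j = 1; j <= nc; ++j)
      if (p[i + j * R]) { sr = i; sc = j; break; }
  // clockwise Moore neighbourhood starting at W
  const int dr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  std::vector<int> chain;
  chain.reserve(8 * area);
  int cr = sr, cc = sc, backtrack = 1; // came from W; first probe is NW
  int d0 = -1;
  long cap = 8L * area + 16;
  while (cap-- > 0) {
    int found = -1;
    for (int k = 0; k < 8; ++k) {
      int d = (backtrack + k) % 8;
      int nrr = cr + dr[d], ncc = cc + dc[d];
      if (p[nrr + ncc * R]) { found = d; break; }
    }
    if (found < 0) break; // isolated pixel (cannot happen for area > 1)
    // the post-move tracing state is fully determined by (pixel, direction),
    // so repeating the first move from the start pixel closes the cycle
    if (cr == sr && cc == sc && d0 >= 0 && found == d0) break;
    if (d0 < 0) d0 = found;
    int nrr = cr + dr[found], ncc = cc + dc[found];
    chain.push_back(found);
    // backtrack for next iteration: direction from new pixel back to old,
    // then resume clockwise search one step past it
    int bd = 0;
    for (int k = 0; k < 8; ++k)
      if (dr[k] == cr - nrr && dc[k] == cc - ncc) { bd = k; break; }
    backtrack = (bd + 1) % 8;
    cr = nrr; cc = ncc;
  }
  int na = 0, nd = 0, ncorner = 0;
  const int n = (int) chain.size();
  for (int t = 0; t < n; ++t) {
    if (chain[t] % 2 == 1) ++nd; else ++na;
    if (chain[t] != chain[(t + 1) % n]) ++ncorner;
  }
  out[0] = na; out[1] = nd; out[2] = ncorner;
  return out;
}

static inline int nb(const std::vector<unsigned char>& p, int R, int i, int j) {
  return p[i + j * R];
}

// Zhang-Suen thinning of a binary mask to a 1-pixel-wide skeleton.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int R = nr + 2;
  std::vector<unsigned char> p(R * (nc + 2), 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mask(i, j) != 0) p[(i + 1) + (j + 1) * R] = 1;
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      kill.clear();
      for (int j = 1; j <= nc; ++j) {
        for (int i = 1; i <= nr; ++i) {
          if (!p[i + j * R]) continue;
          // neighbours P2..P9 clockwise from N
          int p2 = nb(p, R, i - 1, j),     p3 = nb(p, R, i - 1, j + 1);
          int p4 = nb(p, R, i, j + 1),     p5 = nb(p, R, i + 1, j + 1);
          int p6 = nb(p, R, i + 1, j),     p7 = nb(p, R, i + 1, j - 1);
          int p8 = nb(p, R, i, j - 1),     p9 = nb(p, R, i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (sub == 0) {
            if (p2 * p4 * p6 != 0) continue;
            if (p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0) continue;
            if (p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t t = 0; t < kill.size(); ++t)
        p[kill[t].first + kill[t].second * R] = 0;
    }
  }
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = p[(i + 1) + (j + 1) * R];
  return out;
}
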