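#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Path-halving find.
static int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// 0-dimensional sublevel persistence of a grayscale matrix under
// V-construction (4-neighbour) adjacency.
//
// Pixels are activated in ascending (value, row-major index) order; on
// activation a pixel is unioned with its already-active edge neighbours.
// At a merge the component with the larger (birth, activation-order) dies
// (elder rule; ties on birth resolved by earlier activation surviving) and
// the pair (birth_of_younger, current value) is emitted. Roots surviving
// the full sweep are essential classes. Zero-persistence pairs are kept
// here; the R wrapper filters them.
// [[Rcpp::export]]
List ph0_cubical(NumericMatrix img) {
  const int H = img.nrow(), W = img.ncol(), n = H * W;
  std::vector<double> val(n);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) val[r * W + c] = img(r, c);

  std::vector<int> idx(n);
  for (int p = 0; p < n; ++p) idx[p] = p;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (val[a] != val[b]) return val[a] < val[b];
    return a < b;
  });

  std::vector<int> parent(n, -1), order(n, -1), rootmin(n, -1);
  std::vector<double> birth(n);
  std::vector<double> pb, pd;
  std::vector<int> ploc;
  pb.reserve(n / 4); pd.reserve(n / 4); ploc.reserve(n / 4);

  for (int t = 0; t < n; ++t) {
    const int p = idx[t];
    const double v = val[p];
    parent[p] = p;
    order[p] = t;
    birth[p] = v;
    rootmin[p] = p;
    const int r = p / W, c = p % W;
    int nb[4];
    int nn = 0;
    if (r > 0) nb[nn++] = p - W;
    if (r < H - 1) nb[nn++] = p + W;
    if (c > 0) nb[nn++] = p - 1;
    if (c < W - 1) nb[nn++] = p + 1;
    for (int q0 = 0; q0 < nn; ++q0) {
      const int q = nb[q0];
      if (parent[q] < 0) continue;  // not yet in the sublevel set
      int rp = find_root(parent, p), rq = find_root(parent, q);
      if (rp == rq) continue;
      int win, lose;
      if (birth[rp] < birth[rq] ||
          (birth[rp] == birth[rq] && order[rp] < order[rq])) {
        win = rp; lose = rq;
      } else {
        win = rq; lose = rp;
      }
      pb.push_back(birth[lose]);
      pd.push_back(v);
      ploc.push_back(rootmin[lose]);
      parent[lose] = win;
    }
  }

  std::vector<double> eb;
  std::vector<int> eloc;
  for (int p = 0; p < n; ++p) {
    if (parent[p] == p) {
      eb.push_back(birth[p]);
      eloc.push_back(rootmin[p]);
    }
  }

  const int m = (int)pb.size(), me = (int)eb.size();
  NumericMatrix pairs(m, 2);
  IntegerMatrix locs(m, 2);
  for (int i = 0; i < m; ++i) {
    pairs(i, 0) = pb[i];
    pairs(i, 1) = pd[i];
    locs(i, 0) = ploc[i] / W + 1;  // 1-based (row, col)
    locs(i, 1) = ploc[i] % W + 1;
  }
  NumericVector ess(me);
  IntegerMatrix elocs(me, 2);
  for (int i = 0; i < me; ++i) {
    ess[i] = eb[i];
    elocs(i, 0) = eloc[i] / W + 1;
    elocs(i, 1) = eloc[i] % W + 1;
  }
  return List::create(_["pairs"] = pairs, _["locations"] = locs,
                      _["essential"] = ess, _["essential_locations"] = elocs);
}
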