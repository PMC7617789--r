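#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find labelling of unlabeled cells (label bit == 0) with optional
// periodic wrap; written here because standard image labellers do not
// support periodic boundaries.
//
// boundary: 0 = periodic rows & columns, 1 = periodic columns / closed rows,
//           2 = closed both.  connectivity: 4 or 8.

static int uf_find(std::vector<int> &p, int x) {
  while (p[x] != x) {
    p[x] = p[p[x]];
    x = p[x];
  }
  return x;
}

static void uf_union(std::vector<int> &p, std::vector<int> &sz, int a, int b) {
  a = uf_find(p, a);
  b = uf_find(p, b);
  if (a == b) return;
  if (sz[a] < sz[b]) std::swap(a, b);
  p[b] = a;
  sz[a] += sz[b];
}

// [[Rcpp::export]]
IntegerVector void_sizes_cpp(IntegerMatrix grid, int connectivity,
                             int boundary) {
  const int nr = grid.nrow(), nc = grid.ncol();
  const int N = nr * nc;
  const int *gp = INTEGER(grid);

  std::vector<int> parent(N), sz(N, 1);
  for (int i = 0; i < N; ++i) parent[i] = i;

  // forward scan offsets: right, down (+ down-right, down-left for 8)
  const int DR[4] = {0, 1, 1, 1};
  const int DC[4] = {1, 0, 1, -1};
  const int noff = (connectivity == 8) ? 4 : 2;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int i = r + c * nr;
      if (gp[i] & 1) continue;  // labeled cell, not part of any void
      for (int k = 0; k < noff; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (boundary == 0) {
          if (rr >= nr) rr -= nr;
          if (cc >= nc) cc -= nc;
          if (cc < 0) cc += nc;
        } else if (boundary == 1) {
          if (cc >= nc) cc -= nc;
          if (cc < 0) cc += nc;
          if (rr >= nr) continue;
        } else {
          if (rr >= nr || cc >= nc || cc < 0) continue;
        }
        const int j = rr + cc * nr;
        if (!(gp[j] & 1)) uf_union(parent, sz, i, j);
      }
    }
  }

  std::vector<int> out;
  for (int i = 0; i < N; ++i) {
    if (gp[i] & 1) continue;
    if (uf_find(parent, i) == i) out.push_back(sz[i]);
  }
  return wrap(out);
}
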