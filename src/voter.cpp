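#include <Rcpp.h>
using namespace Rcpp;

// Lattice cell codes: bit 0 = label (1 = labeled), bit 1 = genotype
// (1 = fitter).  Grids are column-major R integer matrices.
//
// boundary: 0 = periodic rows & columns, 1 = periodic columns / closed rows,
//           2 = closed both.
//
// All randomness comes from R's RNG (unif_rand), so runs are reproducible
// under set.seed().

static const int DR8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC8[8] = { 0, 0,-1, 1, -1,  1,-1, 1};

static inline int wrapi(int k, int n) {
  if (k < 0) return k + n;
  if (k >= n) return k - n;
  return k;
}

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// [[Rcpp::export]]
IntegerMatrix voter_run(IntegerMatrix grid, double n_events, int neighborhood,
                        int boundary, bool nonneutral, double selection) {
  IntegerMatrix g = clone(grid);
  const int nr = g.nrow(), nc = g.ncol();
  const int N = nr * nc;
  const int nn = (neighborhood == 8) ? 8 : 4;
  int *gp = INTEGER(g);

  for (double ev = 0; ev < n_events; ev += 1.0) {
    const int i = runif_int(N);
    const int r = i % nr, c = i / nr;

    if (!nonneutral) {
      // Neutral: replace by a uniformly drawn neighbour; at closed edges the
      // lottery is uniform over the neighbours that exist (rejection draw).
      int rr, cc;
      do {
        const int k = runif_int(nn);
        rr = r + DR8[k];
        cc = c + DC8[k];
        if (boundary == 0) {
          rr = wrapi(rr, nr);
          cc = wrapi(cc, nc);
        } else if (boundary == 1) {
          cc = wrapi(cc, nc);
        }
      } while (rr < 0 || rr >= nr || cc < 0 || cc >= nc);
      gp[i] = gp[rr + cc * nr];
    } else {
      int idx[8];
      int m = 0;
      for (int k = 0; k < nn; ++k) {
        int rr = r + DR8[k], cc = c + DC8[k];
        if (boundary == 0) {
          rr = wrapi(rr, nr);
          cc = wrapi(cc, nc);
        } else if (boundary == 1) {
          cc = wrapi(cc, nc);
          if (rr < 0 || rr >= nr) continue;
        } else {
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        }
        idx[m++] = rr + cc * nr;
      }
      if (m == 0) continue;

      if (!R_FINITE(selection)) {
        // Infinite selection: any fitter neighbour wins the contest outright
        // (uniform among fitter neighbours); a fitter site with no fitter
        // neighbour can never be displaced by a normal lineage -> no-op.
        int fit[8];
        int mf = 0;
        for (int t = 0; t < m; ++t)
          if (gp[idx[t]] & 2) fit[mf++] = idx[t];
        if (mf > 0) {
          gp[i] = gp[fit[runif_int(mf)]];
        } else if (!(gp[i] & 2)) {
          gp[i] = gp[idx[runif_int(m)]];
        }
      } else {
        double w[8], tot = 0.0;
        for (int t = 0; t < m; ++t) {
          w[t] = (gp[idx[t]] & 2) ? selection : 1.0;
          tot += w[t];
        }
        double u = unif_rand() * tot;
        int t = 0;
        for (; t < m - 1; ++t) {
          u -= w[t];
          if (u <= 0) break;
        }
        gp[i] = gp[idx[t]];
      }
    }
  }
  return g;
}
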