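// Circular Hough transform accumulator.
//
// Accumulator definition (shared with the brute-force test oracle):
//   A[n, m, r] = number of edge pixels whose Euclidean distance to the
//                candidate centre (row n, col m) rounds to the integer
//                radius r,
// restricted to centres for which the circle lies fully inside the image.
// Votes are normalised per radius by the number of lattice pixels at that
// rounded distance, so a complete one-pixel-thick circle scores 1.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Number of lattice offsets (dx, dy) with round(hypot(dx, dy)) == r.
// [[Rcpp::export]]
IntegerVector circle_support_counts(int rmin, int rmax) {
  int nr = rmax - rmin + 1;
  IntegerVector out(nr);
  for (int dy = -rmax - 1; dy <= rmax + 1; ++dy) {
    for (int dx = -rmax - 1; dx <= rmax + 1; ++dx) {
      int r = (int)std::lround(std::sqrt((double)dx * dx + (double)dy * dy));
      if (r >= rmin && r <= rmax) out[r - rmin]++;
    }
  }
  return out;
}

// edge_rows / edge_cols: 1-based pixel coordinates of edge points.
// Returns the full accumulator, dims (nrow, ncol, nradii).
// [[Rcpp::export]]
IntegerVector hough_accumulate_cpp(IntegerVector edge_rows, IntegerVector edge_cols,
                                   int nrow, int ncol, int rmin, int rmax) {
  int nr = rmax - rmin + 1;
  IntegerVector acc(nrow * ncol * nr, 0);
  int ne = edge_rows.size();
  for (int e = 0; e < ne; ++e) {
    int er = edge_rows[e], ec = edge_cols[e];
    int rlo = std::max(1, er - rmax), rhi = std::min(nrow, er + rmax);
    int clo = std::max(1, ec - rmax), chi = std::min(ncol, ec + rmax);
    for (int cc = clo; cc <= chi; ++cc) {
      double dc = (double)(cc - ec);
      double dc2 = dc * dc;
      for (int rr = rlo; rr <= rhi; ++rr) {
        double dr = (double)(rr - er);
        int rad = (int)std::lround(std::sqrt(dr * dr + dc2));
        if (rad < rmin || rad > rmax) continue;
        // circle must fit fully inside the image
        if (rr - rad < 1 || rr + rad > nrow || cc - rad < 1 || cc + rad > ncol) continue;
        acc[(rad - rmin) * nrow * ncol + (cc - 1) * nrow + (rr - 1)]++;
      }
    }
  }
  acc.attr("dim") = IntegerVector::create(nrow, ncol, nr);
  return acc;
}

// Arg-max of the normalised accumulator with deterministic tie-breaking:
// smallest radius first, then row, then column.
// Returns (row n, col m, radius r, normalised votes).
// [[Rcpp::export]]
NumericVector hough_best_cpp(IntegerVector acc, IntegerVector support,
                             int nrow, int ncol, int rmin, int rmax) {
  int nr = rmax - rmin + 1;
  double best = -1.0;
  int bn = -1, bm = -1, br = -1;
  for (int ri = 0; ri < nr; ++ri) {
    double sup = (double)support[ri];
    if (sup <= 0) continue;
    const int off = ri * nrow * ncol;
    for (int cc = 0; cc < ncol; ++cc) {
      for (int rr = 0; rr < nrow; ++rr) {
        int v = acc[off + cc * nrow + rr];
        if (v <= 0) continue;
        double score = (double)v / sup;
        if (score > best + 1e-12) {
          best = score; bn = rr + 1; bm = cc + 1; br = rmin + ri;
        } else if (std::fabs(score - best) <= 1e-12 && br >= 0) {
          if (rmin + ri < br ||
              (rmin + ri == br && (rr + 1 < bn || (rr + 1 == bn && cc + 1 < bm)))) {
            bn = rr + 1; bm = cc + 1; br = rmin + ri;
          }
        }
      }
    }
  }
  return NumericVector::create(_["n"] = bn, _["m"] = bm, _["r"] = br,
                               _["votes"] = best < 0 ? 0.0 : std::min(best, 1.0));
}
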