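// Sliding-window GLCM + Haralick feature maps.
//
// Mirrors the R reference implementations compute_glcm() + haralick_features()
// exactly (same symmetric counting, direction averaging, 1-based gray-level
// indexing, natural logs, 0*log0 = 0, raw-moment difference variance); the
// equivalence is asserted in the test suite. C++ only because a per-pixel
// N x N co-occurrence tally over whole volumes is the pipeline's hot loop.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double xlogx(double p) { return p > 0.0 ? p * std::log(p) : 0.0; }

// [[Rcpp::export]]
NumericVector glcm_feature_maps_cpp(IntegerMatrix q, LogicalMatrix mask,
                                    int window, int d, int N) {
  const int nr = q.nrow(), nc = q.ncol(), half = window / 2;
  const int NF = 16;
  NumericVector out(Dimension(nr, nc, NF));
  std::fill(out.begin(), out.end(), NA_REAL);

  // direction offsets (drow, dcol): 0, 45, 90, 135 degrees
  const int offs[4][2] = {{0, d}, {-d, d}, {-d, 0}, {-d, -d}};

  std::vector<double> counts((size_t)N * N);
  std::vector<double> px(N), py(N), psum(2 * N + 1), pdiff(N);

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      const int r0 = std::max(0, r - half), r1 = std::min(nr - 1, r + half);
      const int c0 = std::max(0, c - half), c1 = std::min(nc - 1, c + half);

      std::fill(counts.begin(), counts.end(), 0.0);
      double total = 0.0;
      for (int k = 0; k < 4; ++k) {
        const int dr = offs[k][0], dc = offs[k][1];
        for (int cc = c0; cc <= c1; ++cc) {
          const int cc2 = cc + dc;
          if (cc2 < c0 || cc2 > c1) continue;
          for (int rr = r0; rr <= r1; ++rr) {
            const int rr2 = rr + dr;
            if (rr2 < r0 || rr2 > r1) continue;
            if (!mask(rr, cc) || !mask(rr2, cc2)) continue;
            const int a = q(rr, cc), b = q(rr2, cc2);
            counts[(size_t)a * N + b] += 1.0;  // both orderings: symmetric
            counts[(size_t)b * N + a] += 1.0;
            total += 2.0;
          }
        }
      }
      if (total == 0.0) continue;  // isolated pixel: keep NA sentinel

      // normalized G and its marginals; gray level l is index i = l + 1
      std::fill(px.begin(), px.end(), 0.0);
      std::fill(py.begin(), py.end(), 0.0);
      std::fill(psum.begin(), psum.end(), 0.0);
      std::fill(pdiff.begin(), pdiff.end(), 0.0);
      double energy = 0.0, entropy = 0.0, contrast = 0.0, dissim = 0.0;
      double homog = 0.0, maxp = 0.0, autocorr = 0.0;
      for (int lj = 0; lj < N; ++lj) {
        for (int li = 0; li < N; ++li) {
          const double g = counts[(size_t)li * N + lj] / total;
          if (g == 0.0) continue;
          const int i = li + 1, j = lj + 1, dd = i - j;
          px[lj] += g; py[li] += g;
          psum[(size_t)(i + j) - 2] += g;  // psum index k-2 holds p_{x+y}(k)
          pdiff[dd < 0 ? -dd : dd] += g;
          energy += g * g;
          entropy -= xlogx(g);
          contrast += (double)dd * dd * g;
          dissim += (dd < 0 ? -dd : dd) * g;
          homog += g / (1.0 + (double)dd * dd);
          autocorr += (double)i * j * g;
          if (g > maxp) maxp = g;
        }
      }
      double mux = 0.0, muy = 0.0;
      for (int l = 0; l < N; ++l) { mux += (l + 1.0) * px[l]; muy += (l + 1.0) * py[l]; }
      double sx2 = 0.0, sy2 = 0.0;
      for (int l = 0; l < N; ++l) {
        sx2 += (l + 1.0 - mux) * (l + 1.0 - mux) * px[l];
        sy2 += (l + 1.0 - muy) * (l + 1.0 - muy) * py[l];
      }
      const double sx = std::sqrt(sx2), sy = std::sqrt(sy2);
      double corr = 0.0, variance = 0.0, shade = 0.0, prom = 0.0;
      for (int lj = 0; lj < N; ++lj) {
        for (int li = 0; li < N; ++li) {
          const double g = counts[(size_t)li * N + lj] / total;
          if (g == 0.0) continue;
          const double i = li + 1.0, j = lj + 1.0;
          const double ctr = i + j - mux - muy;
          if (sx * sy > 0.0) corr += (i - mux) * (j - muy) * g;
          variance += (i - mux) * (i - mux) * g;
          shade += ctr * ctr * ctr * g;
          prom += ctr * ctr * ctr * ctr * g;
        }
      }
      if (sx * sy > 0.0) corr /= sx * sy;
      double sum_avg = 0.0, sum_ent = 0.0, diff_ent = 0.0, diff_var = 0.0;
      for (int k = 2; k <= 2 * N; ++k) {
        sum_avg += k * psum[(size_t)k - 2];
        sum_ent -= xlogx(psum[(size_t)k - 2]);
      }
      for (int k = 0; k < N; ++k) {
        diff_ent -= xlogx(pdiff[k]);
        diff_var += (double)k * k * pdiff[k];
      }
      double sum_var = 0.0;
      for (int k = 2; k <= 2 * N; ++k)
        sum_var += (k - sum_ent) * (k - sum_ent) * psum[(size_t)k - 2];

      const double f[NF] = {contrast, energy, dissim, entropy, corr, homog,
                            variance, diff_ent, sum_avg, shade, prom, maxp,
                            diff_var, autocorr, sum_ent, sum_var};
      const R_xlen_t base = (R_xlen_t)r + (R_xlen_t)nr * c;
      for (int fi = 0; fi < NF; ++fi)
        out[base + (R_xlen_t)fi * nr * nc] = f[fi];
    }
  }
  return out;
}
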