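#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Nine GLCM summary metrics of a normalized symmetric co-occurrence
// distribution given as merged (i, j, count) triples. Metric order:
// mean, variance, homogeneity, contrast, dissimilarity, entropy, energy,
// correlation, autocorrelation. The mean/variance are row-marginal
// moments of the symmetric matrix; correlation is defined as 1 when the
// marginal variance vanishes (constant window).
static void glcm_metrics_from_pairs(std::vector<int> &keys, int levels,
                                    double *out) {
  std::sort(keys.begin(), keys.end());
  const double total = static_cast<double>(keys.size());
  // first pass: marginal mean
  double mu = 0.0;
  for (size_t k = 0; k < keys.size(); ++k)
    mu += keys[k] / levels;
  mu /= total;
  double var = 0.0, hom = 0.0, con = 0.0, dis = 0.0, ent = 0.0,
         ene = 0.0, cornum = 0.0, autoc = 0.0;
  size_t k = 0;
  while (k < keys.size()) {
    size_t k2 = k;
    while (k2 < keys.size() && keys[k2] == keys[k]) ++k2;
    const double p = (k2 - k) / total;
    const int i = keys[k] / levels;
    const int j = keys[k] % levels;
    const double d = i - j;
    var += (i - mu) * (i - mu) * p;
    hom += p / (1.0 + d * d);
    con += d * d * p;
    dis += std::abs(d) * p;
    ent -= p * std::log(p);
    ene += p * p;
    cornum += (i - mu) * (j - mu) * p;
    autoc += static_cast<double>(i) * j * p;
    k = k2;
  }
  out[0] = mu;
  out[1] = var;
  out[2] = hom;
  out[3] = con;
  out[4] = dis;
  out[5] = ent;
  out[6] = ene;
  out[7] = (var < 1e-15) ? 1.0 : cornum / var;
  out[8] = autoc;
}

// Sliding-window GLCM metrics over a quantized integer grid.
// q: levels in 0..levels-1; windows of wr x wc fully inside the grid;
// offsets: m x 2 integer matrix of (dRow, dCol) displacements, each
// applied symmetrically. Returns nWindows x 9 metric matrix (windows in
// column-major order of their top-left corner).
// [[Rcpp::export(name = ".glcmWindowMetrics")]]
NumericMatrix glcm_window_metrics(IntegerMatrix q, int levels,
                                  int wr, int wc, IntegerMatrix offsets) {
  const int nr = q.nrow(), nc = q.ncol();
  const int outr = nr - wr + 1, outc = nc - wc + 1;
  if (outr < 1 || outc < 1)
    stop("grid smaller than the processing window");
  for (int m = 0; m < offsets.nrow(); ++m) {
    if (std::abs(offsets(m, 0)) >= wr || std::abs(offsets(m, 1)) >= wc)
      stop("window smaller than offset reach");
  }
  NumericMatrix out(outr * outc, 9);
  std::vector<int> keys;
  keys.reserve(2 * offsets.nrow() * wr * wc);
  int w = 0;
  for (int c0 = 0; c0 < outc; ++c0) {
    for (int r0 = 0; r0 < outr; ++r0, ++w) {
      keys.clear();
      for (int m = 0; m < offsets.nrow(); ++m) {
        const int dr = offsets(m, 0), dc = offsets(m, 1);
        const int rlo = std::max(0, -dr), rhi = std::min(wr, wr - dr);
        const int clo = std::max(0, -dc), chi = std::min(wc, wc - dc);
        for (int cc = clo; cc < chi; ++cc) {
          for (int rr = rlo; rr < rhi; ++rr) {
            const int a = q(r0 + rr, c0 + cc);
            const int b = q(r0 + rr + dr, c0 + cc + dc);
            keys.push_back(a * levels + b);
            keys.push_back(b * levels + a);
          }
        }
      }
      if (keys.empty())
        stop("window contains no valid offset pair");
      double met[9];
      glcm_metrics_from_pairs(keys, levels, met);
      for (int j = 0; j < 9; ++j) out(w, j) = met[j];
    }
  }
  return out;
}
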