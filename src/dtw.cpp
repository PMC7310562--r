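#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping of two equal-length curves with the symmetric step
// pattern (diagonal weighted twice) and both endpoints pinned. Local cost is
// the absolute difference. Returns the warping path and its displacement
// summaries; displacement at path step k is (i_k - j_k) / (G - 1), i.e. the
// signed lag of curve a relative to curve b in normalized grid units.

static void dtw_core(const NumericVector& a, const NumericVector& b,
                     std::vector<int>& pi, std::vector<int>& pj) {
  const int G = a.size();
  NumericMatrix D(G, G);
  // local cost
  std::vector<double> drow(G);
  for (int i = 0; i < G; ++i) {
    for (int j = 0; j < G; ++j) {
      double d = std::abs(a[i] - b[j]);
      double best;
      if (i == 0 && j == 0) {
        best = d; // counted once more below via symmetric weight start
      } else {
        double diag = (i > 0 && j > 0) ? D(i - 1, j - 1) + d : R_PosInf;
        double up   = (i > 0) ? D(i - 1, j) : R_PosInf;
        double left = (j > 0) ? D(i, j - 1) : R_PosInf;
        best = std::min(diag, std::min(up, left));
      }
      D(i, j) = best + d;
    }
  }
  // backtrack from (G-1, G-1); prefer the diagonal on ties
  int i = G - 1, j = G - 1;
  pi.push_back(i); pj.push_back(j);
  while (i > 0 || j > 0) {
    double diag = (i > 0 && j > 0) ? D(i - 1, j - 1) : R_PosInf;
    double up   = (i > 0) ? D(i - 1, j) : R_PosInf;
    double left = (j > 0) ? D(i, j - 1) : R_PosInf;
    if (diag <= up && diag <= left) { --i; --j; }
    else if (up <= left) { --i; }
    else { --j; }
    pi.push_back(i); pj.push_back(j);
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
}

// [[Rcpp::export(name = ".dtw_align_cpp")]]
List dtw_align_cpp(NumericVector a, NumericVector b) {
  if (a.size() != b.size() || a.size() < 2)
    stop("curves must have equal length >= 2");
  std::vector<int> pi, pj;
  dtw_core(a, b, pi, pj);
  const int L = pi.size();
  const double Gm1 = a.size() - 1;
  NumericVector disp(L);
  IntegerVector ii(L), jj(L);
  double mean_disp = 0.0, max_disp = 0.0;
  for (int k = 0; k < L; ++k) {
    ii[k] = pi[k] + 1;
    jj[k] = pj[k] + 1;
    disp[k] = (pi[k] - pj[k]) / Gm1;
    mean_disp += disp[k];
    if (std::abs(disp[k]) > std::abs(max_disp)) max_disp = disp[k];
  }
  mean_disp /= L;
  return List::create(_["i"] = ii, _["j"] = jj, _["displacement"] = disp,
                      _["mean_displacement"] = mean_disp,
                      _["max_displacement"] = max_disp);
}

static double zscore_inplace(std::vector<double>& x) {
  const int n = x.size();
  double m = 0.0;
  for (int k = 0; k < n; ++k) m += x[k];
  m /= n;
  double ss = 0.0;
  for (int k = 0; k < n; ++k) ss += (x[k] - m) * (x[k] - m);
  double s = std::sqrt(ss / (n - 1));
  if (s < 1e-12) return s;
  for (int k = 0; k < n; ++k) x[k] = (x[k] - m) / s;
  return s;
}

static double dtw_stat(const std::vector<double>& a, const std::vector<double>& b,
                       bool use_max) {
  NumericVector av(a.begin(), a.end()), bv(b.begin(), b.end());
  std::vector<int> pi, pj;
  dtw_core(av, bv, pi, pj);
  const double Gm1 = a.size() - 1;
  if (use_max) {
    double mx = 0.0;
    for (size_t k = 0; k < pi.size(); ++k) {
      double d = (pi[k] - pj[k]) / Gm1;
      if (std::abs(d) > std::abs(mx)) mx = d;
    }
    return mx;
  }
  double s = 0.0;
  for (size_t k = 0; k < pi.size(); ++k) s += (pi[k] - pj[k]) / Gm1;
  return s / pi.size();
}

// Parametric-bootstrap null shifts for the DTW time-shift statistic.
// For each simulation: resampled residuals (indices supplied, 1-based, drawn
// in R so RNG stays under R control) are added to the pooled-fit fitted
// values, per-species polynomial coefficients are obtained with the
// precomputed projectors Ph/Pm ((X'X)^-1 X'), curves are evaluated on the
// common grid via Gh/Gm, z-scored, and aligned by DTW; the returned value is
// the chosen displacement statistic scaled by disp_to_units.
// [[Rcpp::export(name = ".dtw_boot_cpp")]]
NumericVector dtw_boot_cpp(IntegerMatrix idx_h, IntegerMatrix idx_m,
                           NumericVector fit_h, NumericVector fit_m,
                           NumericVector resid_h, NumericVector resid_m,
                           NumericMatrix Ph, NumericMatrix Pm,
                           NumericMatrix Gh, NumericMatrix Gm,
                           double disp_to_units, bool use_max) {
  const int nsim = idx_h.nrow();
  const int nh = fit_h.size(), nm = fit_m.size();
  const int ph = Ph.nrow(), pm = Pm.nrow();
  const int G = Gh.nrow();
  if (idx_h.ncol() != nh || idx_m.ncol() != nm)
    stop("index matrix dimensions do not match sample counts");
  NumericVector out(nsim);
  std::vector<double> yh(nh), ym(nm), ch(ph), cm(pm), gh(G), gm(G);
  for (int s = 0; s < nsim; ++s) {
    for (int k = 0; k < nh; ++k) yh[k] = fit_h[k] + resid_h[idx_h(s, k) - 1];
    for (int k = 0; k < nm; ++k) ym[k] = fit_m[k] + resid_m[idx_m(s, k) - 1];
    for (int r = 0; r < ph; ++r) {
      double acc = 0.0;
      for (int k = 0; k < nh; ++k) acc += Ph(r, k) * yh[k];
      ch[r] = acc;
    }
    for (int r = 0; r < pm; ++r) {
      double acc = 0.0;
      for (int k = 0; k < nm; ++k) acc += Pm(r, k) * ym[k];
      cm[r] = acc;
    }
    for (int g = 0; g < G; ++g) {
      double acc = 0.0;
      for (int r = 0; r < ph; ++r) acc += Gh(g, r) * ch[r];
      gh[g] = acc;
      acc = 0.0;
      for (int r = 0; r < pm; ++r) acc += Gm(g, r) * cm[r];
      gm[g] = acc;
    }
    if (zscore_inplace(gh) < 1e-12 || zscore_inplace(gm) < 1e-12) {
      out[s] = NA_REAL;
      continue;
    }
    out[s] = dtw_stat(gh, gm, use_max) * disp_to_units;
  }
  return out;
}
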