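// Characteristic-function inversion engine for the causal-mixture z-score
// model.
//
// For template variant j with neighbors k (LD weights u_jk = h_k * r2_jk)
// the model CF is
//   CF_j(t) = exp(-t' S0 t / 2) * prod_k sum_c w_c exp(-u_jk t' B_c t / 2)
// with B_c = diag(sqrt(N)) Sigma_c diag(sqrt(N)).  The density is the
// inverse Fourier integral (2pi)^-d int CF_j(t) cos(t'z) dt, approximated
// by the trapezoidal rule on a fixed symmetric grid shared by all variants
// (in scaled units; per-variant scalar scales s_j are applied by dividing
// the neighbor weights by s_j^2 and the evaluation point by s_j).
//
// The all-null assignment term w0^M exp(-t'S0t/2) -- a pure Gaussian whose
// CF decays slowest of all mixture terms -- is subtracted here and added
// back in closed form by the caller.  This removes the narrow "null spike"
// from the numerical integral, so the grid only needs to resolve the
// remaining terms, all of which contain at least one causal factor.
//
// Two evaluation modes for the neighbor mixture term:
//   quant == 0 : exact exponentials per (grid point, neighbor, component);
//   quant  > 0 : a table of log-mixture values on `quant` log-spaced
//                u-levels, linearly interpolated per neighbor (fast path
//                used inside optimization loops).
//
// Returns the numerically integrated remainder density (can be slightly
// negative through oscillation; the caller floors the total).

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_z_rest_density")]]
NumericVector cpp_z_rest_density(NumericMatrix zs,      // V x d, scaled
                                 IntegerVector ptr,     // V+1, 0-based
                                 NumericVector u,       // neighbor weights
                                 NumericVector s2,      // V, scale^2
                                 NumericMatrix A,       // (d*d) x C, scaled
                                 NumericVector w,       // C comp weights
                                 NumericMatrix S0,      // d x d, scaled
                                 NumericVector grid1,   // symmetric 1-D grid
                                 double step,           // grid spacing
                                 int quant) {           // 0 = exact
  const int V = zs.nrow();
  const int d = zs.ncol();
  const int C = w.size();
  const int G = grid1.size();

  // identify exact-null components (zero covariance): their product over
  // neighbors is the analytically handled Gaussian term
  double w0 = 0.0;
  std::vector<bool> is_null(C, false);
  for (int c = 0; c < C; ++c) {
    bool nul = true;
    for (int e = 0; e < d * d && nul; ++e) {
      if (A(e, c) != 0.0) nul = false;
    }
    is_null[c] = nul;
    if (nul) w0 += w[c];
  }
  const double logw0 = w0 > 0 ? std::log(w0) : R_NegInf;

  // enumerate the half grid: first coordinate >= 0, doubled weight off the
  // t1 = 0 hyperplane (the integrand is even); trapezoid end-weights
  const int mid = (G - 1) / 2;  // index of t = 0
  std::vector<double> tpts;     // T*d coordinates
  std::vector<double> wgt;      // T quadrature weights (incl. step^d)
  std::vector<int> idx(d, 0);
  const double stepd = std::pow(step, d);
  while (true) {
    if (idx[0] >= mid) {
      double tw = 1.0;
      for (int a = 0; a < d; ++a) {
        if (idx[a] == 0 || idx[a] == G - 1) tw *= 0.5;  // trapezoid ends
      }
      if (idx[0] > mid) tw *= 2.0;  // evenness: fold t1 < 0 onto t1 > 0
      for (int a = 0; a < d; ++a) tpts.push_back(grid1[idx[a]]);
      wgt.push_back(tw * stepd);
    }
    int a = d - 1;
    while (a >= 0 && ++idx[a] == G) idx[a--] = 0;
    if (a < 0) break;
  }
  const int T = (int)wgt.size();

  // quadratic forms per grid point: q0 = t'S0t/2, Qc = t'A_c t/2 (c-major)
  std::vector<double> q0(T);
  std::vector<double> Qc((size_t)C * T);
  for (int g = 0; g < T; ++g) {
    const double* t = &tpts[(size_t)g * d];
    double acc0 = 0.0;
    for (int a = 0; a < d; ++a)
      for (int b = 0; b < d; ++b) acc0 += t[a] * S0(a, b) * t[b];
    q0[g] = 0.5 * acc0;
    for (int c = 0; c < C; ++c) {
      double acc = 0.0;
      for (int a = 0; a < d; ++a)
        for (int b = 0; b < d; ++b) acc += t[a] * A(a + d * b, c) * t[b];
      Qc[(size_t)c * T + g] = 0.5 * acc;
    }
  }

  // optional interpolation table over log-spaced scaled-u levels
  double vmin = R_PosInf, vmax = R_NegInf;
  std::vector<double> tab;
  double loglo = 0.0, dl = 1.0;
  int L = 0;
  if (quant > 0) {
    for (int j = 0; j < V; ++j) {
      for (int e = ptr[j]; e < ptr[j + 1]; ++e) {
        const double v = u[e] / s2[j];
        if (v > 0) {
          if (v < vmin) vmin = v;
          if (v > vmax) vmax = v;
        }
      }
    }
    if (!(vmax > 0)) {
      quant = 0;  // no positive weights anywhere: exact path is free
    } else {
      L = quant < 2 ? 2 : quant;
      loglo = std::log(vmin);
      const double loghi = std::log(vmax * (1.0 + 1e-12));
      dl = (loghi - loglo) / (L - 1);
      if (dl <= 0) dl = 1e-12;
      tab.resize((size_t)L * T);
      for (int l = 0; l < L; ++l) {
        const double v = std::exp(loglo + dl * l);
        double* row = &tab[(size_t)l * T];
        for (int g = 0; g < T; ++g) {
          double s = 0.0;
          for (int c = 0; c < C; ++c)
            s += w[c] * std::exp(-v * Qc[(size_t)c * T + g]);
          row[g] = std::log(s);
        }
      }
    }
  }

  const double log2pi = std::log(2.0 * M_PI);
  NumericVector out(V);
  std::vector<double> buf(T);

  for (int j = 0; j < V; ++j) {
    const double is2 = 1.0 / s2[j];
    int M = 0;  // neighbors with positive weight (u = 0 factors are 1)
    for (int g = 0; g < T; ++g) buf[g] = 0.0;
    for (int e = ptr[j]; e < ptr[j + 1]; ++e) {
      const double v = u[e] * is2;
      if (v <= 0) continue;
      ++M;
      if (quant > 0) {
        double x = (std::log(v) - loglo) / dl;
        if (x < 0) x = 0;
        if (x > L - 1) x = L - 1;
        int i0 = (int)x;
        if (i0 > L - 2) i0 = L - 2;
        const double f = x - i0;
        const double* r0 = &tab[(size_t)i0 * T];
        const double* r1 = r0 + T;
        const double f0 = 1.0 - f;
        for (int g = 0; g < T; ++g) buf[g] += f0 * r0[g] + f * r1[g];
      } else {
        for (int g = 0; g < T; ++g) {
          double s = 0.0;
          for (int c = 0; c < C; ++c)
            s += w[c] * std::exp(-v * Qc[(size_t)c * T + g]);
          buf[g] += std::log(s);
        }
      }
    }
    // integrate exp(-q0/s2) * (exp(L) - w0^M) * cos(t'z)
    const double lw0M = w0 > 0 ? M * logw0 : R_NegInf;
    const bool split = (w0 > 0) && (lw0M > -700.0);
    const double ew0M = split ? std::exp(lw0M) : 0.0;
    double acc = 0.0;
    for (int g = 0; g < T; ++g) {
      const double* t = &tpts[(size_t)g * d];
      double dot = 0.0;
      for (int a = 0; a < d; ++a) dot += t[a] * zs(j, a);
      const double rest = split ? ew0M * std::expm1(buf[g] - lw0M)
                                : std::exp(buf[g]);
      acc += wgt[g] * std::exp(-q0[g] * is2) * rest * std::cos(dot);
    }
    out[j] = acc * std::exp(-d * log2pi);
  }
  return out;
}
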