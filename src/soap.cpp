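// SOAP power-spectrum descriptors, analytic gradients, and sparse-GP
// design-row assembly. Energies are sums of per-environment kernel terms;
// forces and virials come from descriptor gradients via the chain rule.
//
// Conventions:
//  - cells are row-major: row k of `cell` is lattice vector k (Angstrom)
//  - descriptor entries are L2-normalised power spectra over species pairs
//  - gradient "entries" are (center i, neighbour j, image vector u = x_j + L - x_i)
//    with dD/du stored per entry; force on j gets -w * dk/du, on i +w * dk/du
//  - virial = -sum_entries dk/du (x) u  (i.e. -dE/dstrain)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

#include "ylm_gen.h"

static const double Y00 = 0.28209479177387814; // 1/sqrt(4 pi)

// exponentially scaled modified spherical Bessel: out[l] = exp(-x) i_l(x)
static void bessel_i_scaled(double x, int lmax, double *out) {
  if (x < 5.0) { // series, cancellation-free
    double ex = std::exp(-x), x2 = x * x;
    for (int l = 0; l <= lmax; ++l) {
      double dfact = 1.0;
      for (int k = 1; k <= 2 * l + 1; k += 2) dfact *= k;
      double term = 1.0, sum = 1.0;
      for (int k = 1; k < 40; ++k) {
        term *= x2 / (2.0 * k * (2.0 * (l + k) + 1.0));
        sum += term;
        if (term < 1e-17 * sum) break;
      }
      out[l] = ex * std::pow(x, l) / dfact * sum;
    }
    return;
  }
  double e2 = std::exp(-2.0 * x);
  out[0] = (1.0 - e2) / (2.0 * x);
  if (lmax >= 1) out[1] = ((x - 1.0) + (x + 1.0) * e2) / (2.0 * x * x);
  for (int l = 2; l <= lmax; ++l)
    out[l] = out[l - 2] - (2.0 * l - 1.0) / x * out[l - 1];
}

// quintic switch: 1 below r_on, 0 above r_cut, C2 at both ends
static inline double fcut(double r, double r_on, double r_cut, double *dfdr) {
  if (r <= r_on) { *dfdr = 0.0; return 1.0; }
  if (r >= r_cut) { *dfdr = 0.0; return 0.0; }
  double w = r_cut - r_on, t = (r - r_on) / w;
  double s = t * t * t * (10.0 + t * (-15.0 + 6.0 * t));
  *dfdr = -t * t * (30.0 + t * (-60.0 + 30.0 * t)) / w;
  return 1.0 - s;
}

// [[Rcpp::export]]
arma::mat cpp_radial_table(int n_max, int l_max, double r_cut,
                           double sigma_atom, int n_grid, int n_quad) {
  const double alpha = 1.0 / (2.0 * sigma_atom * sigma_atom);
  const double sigma_b = r_cut / n_max;
  const double s_hi = r_cut + 5.0 * std::max(sigma_b, sigma_atom);
  if (n_quad % 2 == 0) ++n_quad; // Simpson needs odd point count
  const double h = s_hi / (n_quad - 1);
  arma::mat T(n_grid, n_max * (l_max + 1), arma::fill::zeros);
  std::vector<double> ib(l_max + 1);
  for (int gi = 0; gi < n_grid; ++gi) {
    double r = r_cut * gi / (n_grid - 1.0);
    for (int q = 0; q < n_quad; ++q) {
      double s = q * h;
      double wq = (q == 0 || q == n_quad - 1) ? 1.0 : (q % 2 ? 4.0 : 2.0);
      wq *= h / 3.0;
      bessel_i_scaled(2.0 * alpha * s * r, l_max, ib.data());
      double gauss = std::exp(-alpha * (s - r) * (s - r));
      double common = 4.0 * M_PI * wq * gauss * s * s;
      for (int n = 0; n < n_max; ++n) {
        double rn = n * r_cut / n_max;
        double gn = std::exp(-(s - rn) * (s - rn) / (2.0 * sigma_b * sigma_b));
        for (int l = 0; l <= l_max; ++l)
          T(gi, n * (l_max + 1) + l) += common * gn * ib[l];
      }
    }
  }
  return T;
}

// natural cubic spline second derivatives for uniform grid, per column
static arma::mat spline_second_derivs(const arma::mat &T, double h) {
  int n = T.n_rows, m = T.n_cols;
  arma::mat M(n, m, arma::fill::zeros);
  if (n < 3) return M;
  for (int col = 0; col < m; ++col) {
    // Thomas algorithm for M[1..n-2]
    std::vector<double> cp(n, 0.0), dp(n, 0.0);
    for (int i = 1; i <= n - 2; ++i) {
      double rhs = 6.0 * (T(i + 1, col) - 2.0 * T(i, col) + T(i - 1, col)) / (h * h);
      double diag = 4.0, lower = (i > 1) ? 1.0 : 0.0, upper = (i < n - 2) ? 1.0 : 0.0;
      double denom = diag - lower * cp[i - 1];
      cp[i] = upper / denom;
      dp[i] = (rhs - lower * dp[i - 1]) / denom;
    }
    for (int i = n - 2; i >= 1; --i)
      M(i, col) = dp[i] - cp[i] * M(i + 1, col);
  }
  return M;
}

struct SplineSet {
  const arma::mat *T;
  arma::mat M;
  double h;
  int n;
  // value and derivative of column `col` at r
  inline void eval(double r, int col, double *val, double *der) const {
    double x = r / h;
    int i = (int)std::floor(x);
    if (i < 0) i = 0;
    if (i > n - 2) i = n - 2;
    double xl = i * h, xr = xl + h;
    double A = (xr - r) / h, B = (r - xl) / h;
    double Ti = (*T)(i, col), Tj = (*T)(i + 1, col);
    double Mi = M(i, col), Mj = M(i + 1, col);
    *val = A * Ti + B * Tj +
           ((A * A * A - A) * Mi + (B * B * B - B) * Mj) * h * h / 6.0;
    *der = (Tj - Ti) / h +
           ((3.0 * B * B - 1.0) * Mj - (3.0 * A * A - 1.0) * Mi) * h / 6.0;
  }
};

struct Block { int sa, sb, n1, n2; double w; };

static std::vector<Block> make_blocks(int S, int n_max) {
  std::vector<Block> blocks;
  const double SQ2 = std::sqrt(2.0);
  for (int sa = 0; sa < S; ++sa)
    for (int sb = sa; sb < S; ++sb) {
      if (sa == sb) {
        for (int n1 = 0; n1 < n_max; ++n1)
          for (int n2 = n1; n2 < n_max; ++n2)
            blocks.push_back({sa, sb, n1, n2, n1 == n2 ? 1.0 : SQ2});
      } else {
        for (int n1 = 0; n1 < n_max; ++n1)
          for (int n2 = 0; n2 < n_max; ++n2)
            blocks.push_back({sa, sb, n1, n2, SQ2});
      }
    }
  return blocks;
}

// perpendicular cell heights
static arma::vec heights(const arma::mat &cell) {
  double V = std::abs(arma::det(cell));
  arma::vec h(3);
  for (int k = 0; k < 3; ++k) {
    arma::rowvec b = cell.row((k + 1) % 3), c = cell.row((k + 2) % 3);
    arma::rowvec cr = {b(1) * c(2) - b(2) * c(1), b(2) * c(0) - b(0) * c(2),
                       b(0) * c(1) - b(1) * c(0)};
    h(k) = V / arma::norm(cr);
  }
  return h;
}

// [[Rcpp::export]]
List cpp_soap(IntegerVector species, const arma::mat &pos,
              const arma::mat &cell, LogicalVector pbc, int n_species,
              int n_max, int l_max, double r_cut, double sigma_atom,
              double switch_width, const arma::mat &rtab, bool want_grad,
              IntegerVector mol_id, IntegerMatrix unwrap_shift,
              bool exclude_intra) {
  const int N = species.size();
  const int NLM = (l_max + 1) * (l_max + 1);
  const int S = n_species;
  SplineSet spl;
  spl.T = &rtab;
  spl.h = r_cut / (rtab.n_rows - 1.0);
  spl.n = rtab.n_rows;
  spl.M = spline_second_derivs(rtab, spl.h);

  std::vector<Block> blocks = make_blocks(S, n_max);
  const int D = blocks.size() * (l_max + 1);
  const double r_on = r_cut - switch_width;

  // neighbour image range
  arma::vec hh = heights(cell);
  int nrep[3];
  for (int k = 0; k < 3; ++k)
    nrep[k] = pbc[k] ? (int)std::ceil(r_cut / hh(k)) : 0;

  // gather neighbour entries: center, neighbour, image vector
  std::vector<int> ce, ne;
  std::vector<arma::vec3> uv;
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < N; ++j) {
      for (int a = -nrep[0]; a <= nrep[0]; ++a)
        for (int b = -nrep[1]; b <= nrep[1]; ++b)
          for (int c = -nrep[2]; c <= nrep[2]; ++c) {
            if (i == j && a == 0 && b == 0 && c == 0) continue;
            // intermolecular descriptors: skip neighbours belonging to the
            // same molecule *instance* (same molecule and matching unwrap
            // image), keeping interactions with its periodic copies
            if (exclude_intra && mol_id[i] == mol_id[j] &&
                a == unwrap_shift(j, 0) - unwrap_shift(i, 0) &&
                b == unwrap_shift(j, 1) - unwrap_shift(i, 1) &&
                c == unwrap_shift(j, 2) - unwrap_shift(i, 2))
              continue;
            arma::vec3 u;
            for (int d = 0; d < 3; ++d)
              u(d) = pos(j, d) + a * cell(0, d) + b * cell(1, d) +
                     c * cell(2, d) - pos(i, d);
            double r = arma::norm(u);
            if (r < r_cut && r > 1e-12) {
              ce.push_back(i);
              ne.push_back(j);
              uv.push_back(u);
            }
          }
    }
  }
  const int K = ce.size();

  arma::mat desc(N, D, arma::fill::zeros);
  arma::cube grads;
  if (want_grad) grads.zeros(D, 3, K);

  std::vector<double> ccoef(S * n_max * NLM);
  // ylm_grad always fills the full l<=4 set (25 values)
  std::vector<double> Y(25), dY(75);
  arma::vec p(D), praw(D);

  // entries grouped by center for one-pass accumulation
  std::vector<std::vector<int>> by_center(N);
  for (int e = 0; e < K; ++e) by_center[ce[e]].push_back(e);

  for (int i = 0; i < N; ++i) {
    std::fill(ccoef.begin(), ccoef.end(), 0.0);
    // self contribution (central atom, r = 0): only l = 0 survives
    for (int n = 0; n < n_max; ++n) {
      double v, d;
      spl.eval(0.0, n * (l_max + 1), &v, &d);
      ccoef[(species[i] * n_max + n) * NLM + 0] += v * Y00;
    }
    for (int e : by_center[i]) {
      const arma::vec3 &u = uv[e];
      double r = arma::norm(u);
      double df, f = fcut(r, r_on, r_cut, &df);
      ylm_grad(u(0), u(1), u(2), Y.data(), dY.data());
      int sj = species[ne[e]];
      for (int n = 0; n < n_max; ++n)
        for (int l = 0; l <= l_max; ++l) {
          double v, d;
          spl.eval(r, n * (l_max + 1) + l, &v, &d);
          double ft = f * v;
          for (int m = -l; m <= l; ++m) {
            int lm = l * l + (m + l);
            ccoef[(sj * n_max + n) * NLM + lm] += ft * Y[lm];
          }
        }
    }
    // power spectrum
    for (size_t b = 0; b < blocks.size(); ++b) {
      const Block &B = blocks[b];
      for (int l = 0; l <= l_max; ++l) {
        double acc = 0.0;
        for (int m = -l; m <= l; ++m) {
          int lm = l * l + (m + l);
          acc += ccoef[(B.sa * n_max + B.n1) * NLM + lm] *
                 ccoef[(B.sb * n_max + B.n2) * NLM + lm];
        }
        praw(b * (l_max + 1) + l) = B.w * acc;
      }
    }
    double nrm = arma::norm(praw);
    if (nrm < 1e-300) nrm = 1.0;
    p = praw / nrm;
    desc.row(i) = p.t();

    if (!want_grad) continue;
    // per-entry gradients
    for (int e : by_center[i]) {
      const arma::vec3 &u = uv[e];
      double r = arma::norm(u);
      double df, f = fcut(r, r_on, r_cut, &df);
      ylm_grad(u(0), u(1), u(2), Y.data(), dY.data());
      int sj = species[ne[e]];
      // dc[n][lm][dim]: contribution of this entry to species-sj channels
      std::vector<double> dcs(n_max * NLM * 3, 0.0);
      for (int n = 0; n < n_max; ++n)
        for (int l = 0; l <= l_max; ++l) {
          double v, d;
          spl.eval(r, n * (l_max + 1) + l, &v, &d);
          double rad = df * v + f * d;
          for (int m = -l; m <= l; ++m) {
            int lm = l * l + (m + l);
            for (int dim = 0; dim < 3; ++dim)
              dcs[(n * NLM + lm) * 3 + dim] =
                  rad * (u(dim) / r) * Y[lm] + f * v * dY[3 * lm + dim];
          }
        }
      arma::mat dp(D, 3, arma::fill::zeros);
      for (size_t b = 0; b < blocks.size(); ++b) {
        const Block &B = blocks[b];
        bool hit1 = (B.sa == sj), hit2 = (B.sb == sj);
        if (!hit1 && !hit2) continue;
        for (int l = 0; l <= l_max; ++l) {
          double acc[3] = {0.0, 0.0, 0.0};
          for (int m = -l; m <= l; ++m) {
            int lm = l * l + (m + l);
            double c1 = ccoef[(B.sa * n_max + B.n1) * NLM + lm];
            double c2 = ccoef[(B.sb * n_max + B.n2) * NLM + lm];
            for (int dim = 0; dim < 3; ++dim) {
              double g = 0.0;
              if (hit1) g += dcs[(B.n1 * NLM + lm) * 3 + dim] * c2;
              if (hit2) g += c1 * dcs[(B.n2 * NLM + lm) * 3 + dim];
              acc[dim] += g;
            }
          }
          for (int dim = 0; dim < 3; ++dim)
            dp(b * (l_max + 1) + l, dim) = B.w * acc[dim];
        }
      }
      // normalisation chain rule: dd = (dp - d (d . dp)) / nrm
      arma::rowvec proj = p.t() * dp; // 1x3
      for (int dim = 0; dim < 3; ++dim)
        grads.slice(e).col(dim) = (dp.col(dim) - p * proj(dim)) / nrm;
    }
  }

  IntegerVector Rce(K), Rne(K);
  NumericMatrix Ru(K, 3);
  for (int e = 0; e < K; ++e) {
    Rce[e] = ce[e] + 1;
    Rne[e] = ne[e] + 1;
    for (int d = 0; d < 3; ++d) Ru(e, d) = uv[e](d);
  }
  List out = List::create(_["desc"] = desc, _["entry_center"] = Rce,
                          _["entry_neighbor"] = Rne, _["entry_vec"] = Ru);
  if (want_grad) out["grads"] = grads;
  return out;
}

// Design rows for the sparse-GP linear system and for prediction.
// Kernel: k(d, u_s) = (d . u_s)^zeta, zero across different center species.
// [[Rcpp::export]]
List cpp_gap_rows(const arma::mat &desc, IntegerVector center_species,
                  IntegerVector entry_center, IntegerVector entry_neighbor,
                  NumericMatrix entry_vec, SEXP grads_, const arma::mat &U,
                  IntegerVector sparse_species, double zeta, bool want_grad) {
  const int N = desc.n_rows;
  const int m = U.n_rows;
  arma::mat Kmat = desc * U.t(); // N x m
  for (int i = 0; i < N; ++i)
    for (int t = 0; t < m; ++t)
      if (center_species[i] != sparse_species[t]) Kmat(i, t) = 0.0;
  // clamp tiny negative dots (kernel must stay real for non-integer zeta)
  arma::mat Kz(N, m), Q(N, m);
  for (int i = 0; i < N; ++i)
    for (int t = 0; t < m; ++t) {
      double kk = Kmat(i, t);
      if (kk < 0) kk = 0; // descriptors are non-negative-dot in practice
      Kz(i, t) = std::pow(kk, zeta);
      Q(i, t) = zeta * std::pow(kk, zeta - 1.0);
    }
  arma::rowvec e_row = arma::sum(Kz, 0);
  List out = List::create(_["e_row"] = e_row.t(), _["local"] = Kz);
  if (!want_grad) return out;

  arma::cube grads = as<arma::cube>(grads_);
  const int K = entry_center.size();
  arma::mat f_rows(3 * N, m, arma::fill::zeros);
  arma::mat v_rows(9, m, arma::fill::zeros);
  for (int e = 0; e < K; ++e) {
    int i = entry_center[e] - 1, j = entry_neighbor[e] - 1;
    arma::mat A = U * grads.slice(e); // m x 3 : d(d_i . u_t)/du
    for (int t = 0; t < m; ++t) {
      double coef = Q(i, t);
      if (coef == 0.0) continue;
      for (int d = 0; d < 3; ++d) {
        double g = coef * A(t, d); // dk/du_d
        f_rows(3 * j + d, t) -= g;
        f_rows(3 * i + d, t) += g;
        for (int b = 0; b < 3; ++b)
          v_rows(3 * d + b, t) -= g * entry_vec(e, b);
      }
    }
  }
  out["f_rows"] = f_rows;
  out["v_rows"] = v_rows;
  return out;
}
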