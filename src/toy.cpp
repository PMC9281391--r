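// Analytic toy potential: harmonic bonds/angles inside molecules (with a
// dissociation offset), Lennard-Jones + optional dispersion tail + optional
// switched Coulomb between molecules, summed over all periodic images
// within the cutoff. Molecule partitioning by minimum-image bond graph,
// matching identify_molecules() in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec heights3(const arma::mat &cell) {
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

static inline double sw_quintic(double r, double r_on, double r_cut,
                                double *d) {
  if (r <= r_on) { *d = 0.0; return 1.0; }
  if (r >= r_cut) { *d = 0.0; return 0.0; }
  double w = r_cut - r_on, t = (r - r_on) / w;
  double s = t * t * t * (10.0 + t * (-15.0 + 6.0 * t));
  *d = -t * t * (30.0 + t * (-60.0 + 30.0 * t)) / w;
  return 1.0 - s;
}

// [[Rcpp::export]]
List cpp_toy_eval(IntegerVector species, const arma::mat &pos,
                  const arma::mat &cell, LogicalVector pbc,
                  const arma::mat &bond_k, const arma::mat &bond_r0,
                  double bond_d, const arma::cube &angle_k,
                  const arma::cube &angle_cos0, const arma::mat &eps,
                  const arma::mat &sig, double tail, bool use_tail,
                  NumericVector charge, bool use_charge, double cutoff,
                  double switch_on, NumericVector rcov, double tol,
                  CharacterVector species_names, int max_molecule_size) {
  const int n = species.size();
  double E = 0.0;
  arma::mat F(n, 3, arma::fill::zeros);
  arma::mat W(3, 3, arma::fill::zeros);

  // ---- bond graph by minimum image over +-1 shifts
  int srange[3];
  for (int k = 0; k < 3; ++k) srange[k] = pbc[k] ? 1 : 0;
  std::vector<std::vector<int>> nb(n);
  std::vector<std::vector<arma::ivec3>> nb_shift(n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double best = 1e300;
      arma::ivec3 bs = {0, 0, 0};
      for (int a = -srange[0]; a <= srange[0]; ++a)
        for (int b = -srange[1]; b <= srange[1]; ++b)
          for (int c = -srange[2]; c <= srange[2]; ++c) {
            double d2 = 0;
            for (int d = 0; d < 3; ++d) {
              double u = pos(j, d) - pos(i, d) + a * cell(0, d) +
                         b * cell(1, d) + c * cell(2, d);
              d2 += u * u;
            }
            if (d2 < best) { best = d2; bs = {a, b, c}; }
          }
      double cut = tol * (rcov[species[i]] + rcov[species[j]]);
      if (best <= cut * cut) {
        nb[i].push_back(j); nb_shift[i].push_back(bs);
        nb[j].push_back(i); nb_shift[j].push_back(-bs);
      }
    }

  // ---- BFS unwrap into molecules
  std::vector<int> mol(n, -1);
  arma::imat shift(n, 3, arma::fill::zeros);
  int n_mol = 0;
  for (int root = 0; root < n; ++root) {
    if (mol[root] >= 0) continue;
    mol[root] = n_mol;
    std::vector<int> queue = {root};
    while (!queue.empty()) {
      int i = queue.back(); queue.pop_back();
      for (size_t e = 0; e < nb[i].size(); ++e) {
        int j = nb[i][e];
        arma::ivec3 s = {shift(i, 0) + nb_shift[i][e](0),
                         shift(i, 1) + nb_shift[i][e](1),
                         shift(i, 2) + nb_shift[i][e](2)};
        if (mol[j] < 0) {
          mol[j] = n_mol;
          shift(j, 0) = s(0); shift(j, 1) = s(1); shift(j, 2) = s(2);
          queue.push_back(j);
        } else if (shift(j, 0) != s(0) || shift(j, 1) != s(1) ||
                   shift(j, 2) != s(2)) {
          stop("molecular component %d wraps onto itself through the cell "
               "(periodic polymer)", n_mol + 1);
        }
      }
    }
    ++n_mol;
  }

  // guard against topology-change artefacts: the toy components are
  // small closed-shell molecules, so a merged aggregate is unphysical
  if (max_molecule_size > 0) {
    std::vector<int> msize(n_mol, 0);
    for (int i = 0; i < n; ++i) ++msize[mol[i]];
    for (int m2 = 0; m2 < n_mol; ++m2)
      if (msize[m2] > max_molecule_size)
        stop("molecules merged during evaluation (aggregate of %d atoms)",
             msize[m2]);
  }

  // unwrapped coordinates
  arma::mat P = pos;
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d)
      P(i, d) += shift(i, 0) * cell(0, d) + shift(i, 1) * cell(1, d) +
                 shift(i, 2) * cell(2, d);

  // diameter sanity for the minimum-image bond perception
  if (pbc[0] || pbc[1] || pbc[2]) {
    arma::vec hh = heights3(cell);
    double hmin = 1e300;
    for (int k = 0; k < 3; ++k) if (pbc[k]) hmin = std::min(hmin, hh(k));
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (mol[i] == mol[j]) {
          double d2 = 0;
          for (int d = 0; d < 3; ++d) {
            double u = P(j, d) - P(i, d);
            d2 += u * u;
          }
          if (d2 >= hmin * hmin / 4.0) {
            stop("molecule %d has diameter >= half the smallest cell "
                 "height; minimum-image molecule identification is unsafe",
                 mol[i] + 1);
          }
        }
  }

  // ---- intramolecular bonds
  for (int i = 0; i < n; ++i)
    for (size_t e = 0; e < nb[i].size(); ++e) {
      int j = nb[i][e];
      if (j < i) continue;
      double k0 = bond_k(species[i], species[j]);
      double r0 = bond_r0(species[i], species[j]);
      if (k0 < 0) {
        stop("no bond parameters for %s-%s",
             std::string(species_names[std::min(species[i], species[j])]).c_str(),
             std::string(species_names[std::max(species[i], species[j])]).c_str());
      }
      arma::rowvec u = P.row(j) - P.row(i);
      double r = arma::norm(u);
      E += -bond_d + 0.5 * k0 * (r - r0) * (r - r0);
      arma::rowvec g = k0 * (r - r0) * u / r;
      F.row(j) -= g;
      F.row(i) += g;
      W -= g.t() * u;
    }

  // ---- intramolecular angles (every bonded pair around a centre)
  for (int b = 0; b < n; ++b) {
    int deg = nb[b].size();
    for (int x = 0; x < deg - 1; ++x)
      for (int y = x + 1; y < deg; ++y) {
        int a = nb[b][x], c = nb[b][y];
        double ka = angle_k(species[a], species[b], species[c]);
        if (ka <= 0) continue;
        double c0 = angle_cos0(species[a], species[b], species[c]);
        arma::rowvec u1 = P.row(a) - P.row(b);
        arma::rowvec u2 = P.row(c) - P.row(b);
        double r1 = arma::norm(u1), r2 = arma::norm(u2);
        double cth = arma::dot(u1, u2) / (r1 * r2);
        E += 0.5 * ka * (cth - c0) * (cth - c0);
        double pref = ka * (cth - c0);
        arma::rowvec g1 = pref * (u2 / (r1 * r2) - cth * u1 / (r1 * r1));
        arma::rowvec g2 = pref * (u1 / (r1 * r2) - cth * u2 / (r2 * r2));
        F.row(a) -= g1;
        F.row(c) -= g2;
        F.row(b) += g1 + g2;
        W -= g1.t() * u1 + g2.t() * u2;
      }
  }

  // ---- intermolecular pairs over images within the cutoff
  int nrep[3] = {0, 0, 0};
  if (pbc[0] || pbc[1] || pbc[2]) {
    arma::vec hh = heights3(cell);
    for (int k = 0; k < 3; ++k)
      if (pbc[k]) nrep[k] = (int)std::ceil(cutoff / hh(k));
  }
  double rc2 = cutoff * cutoff;
  for (int a = -nrep[0]; a <= nrep[0]; ++a)
    for (int b = -nrep[1]; b <= nrep[1]; ++b)
      for (int c = -nrep[2]; c <= nrep[2]; ++c) {
        bool zero = (a == 0 && b == 0 && c == 0);
        bool positive = (a > 0) || (a == 0 && b > 0) ||
                        (a == 0 && b == 0 && c > 0);
        if (!zero && !positive) continue;
        double sv[3];
        for (int d = 0; d < 3; ++d)
          sv[d] = a * cell(0, d) + b * cell(1, d) + c * cell(2, d);
        for (int i = 0; i < n; ++i) {
          int j0 = zero ? i + 1 : 0;
          for (int j = j0; j < n; ++j) {
            // skip the *intramolecular* image of a same-molecule pair: it
            // lives at the shift difference of the atoms' unwrap images
            // (non-zero when the molecule wraps across the boundary);
            // other images are genuine self-image interactions
            if (mol[i] == mol[j] &&
                a == shift(j, 0) - shift(i, 0) &&
                b == shift(j, 1) - shift(i, 1) &&
                c == shift(j, 2) - shift(i, 2))
              continue;
            double u[3], r2 = 0;
            for (int d = 0; d < 3; ++d) {
              u[d] = pos(j, d) + sv[d] - pos(i, d);
              r2 += u[d] * u[d];
            }
            if (r2 >= rc2 || r2 < 1e-16) continue;
            double r = std::sqrt(r2);
            int si = species[i], sj = species[j];
            double e = eps(si, sj), s = sig(si, sj);
            double sr6 = std::pow(s / r, 6), sr12 = sr6 * sr6;
            double phi = 4.0 * e * (sr12 - sr6);
            double dphi = 4.0 * e * (-12.0 * sr12 + 6.0 * sr6) / r;
            if (use_tail) {
              phi -= tail * e * sr6;
              dphi += tail * e * 6.0 * sr6 / r;
            }
            if (use_charge) {
              double qq = 14.399645478 * charge[si] * charge[sj];
              phi += qq / r;
              dphi -= qq / r2;
            }
            double dsw, sw = sw_quintic(r, switch_on, cutoff, &dsw);
            E += phi * sw;
            double dtot = dphi * sw + phi * dsw;
            for (int d = 0; d < 3; ++d) {
              double g = dtot * u[d] / r;
              F(j, d) -= g;
              F(i, d) += g;
              for (int d2 = 0; d2 < 3; ++d2) W(d, d2) -= g * u[d2];
            }
          }
        }
      }

  W = (W + W.t()) / 2.0;
  return List::create(_["energy"] = E, _["forces"] = F, _["virial"] = W);
}
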