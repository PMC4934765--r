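// Molecular-mechanics energy engine (Amber functional form) with
// Hawkins-Cramer-Truhlar generalized-Born solvation and an ACE-type
// surface-area term.  Internal units: nm, kJ/mol, elementary charge.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KE = 138.935485;  // kJ mol-1 nm e-2
static const double GB_OFFSET = 0.009;  // nm
static const double SA_PROBE = 0.14;    // nm

struct System {
  int n;
  std::vector<double> x, y, z, q, sig, eps, gbr, gbs;
  // bonded terms
  std::vector<int> bi, bj; std::vector<double> br0, bk;
  std::vector<int> ai, aj, ak; std::vector<double> ath0, akth;
  std::vector<int> di, dj, dk, dl, dn; std::vector<double> dkphi, dgamma;
  // pair classification: 0 full, 1 excluded, 2 one-four
  std::vector<unsigned char> pclass;
  double eps_out, sa_gamma;
  bool gb, sa;
  unsigned char pc(int i, int j) const { return pclass[i * n + j]; }
};

static System unpack(List sys) {
  System s;
  NumericMatrix xyz = sys["xyz"];
  s.n = xyz.nrow();
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = xyz(i, 0); s.y[i] = xyz(i, 1); s.z[i] = xyz(i, 2);
  }
  s.q = as<std::vector<double> >(sys["charge"]);
  s.sig = as<std::vector<double> >(sys["sigma"]);
  s.eps = as<std::vector<double> >(sys["eps"]);
  s.gbr = as<std::vector<double> >(sys["gb_radius"]);
  s.gbs = as<std::vector<double> >(sys["gb_screen"]);
  IntegerMatrix bonds = sys["bonds"];
  NumericMatrix bpar = sys["bond_par"];
  for (int r = 0; r < bonds.nrow(); ++r) {
    s.bi.push_back(bonds(r, 0) - 1); s.bj.push_back(bonds(r, 1) - 1);
    s.br0.push_back(bpar(r, 0)); s.bk.push_back(bpar(r, 1));
  }
  IntegerMatrix ang = sys["angles"];
  NumericMatrix apar = sys["angle_par"];
  for (int r = 0; r < ang.nrow(); ++r) {
    s.ai.push_back(ang(r, 0) - 1); s.aj.push_back(ang(r, 1) - 1);
    s.ak.push_back(ang(r, 2) - 1);
    s.ath0.push_back(apar(r, 0)); s.akth.push_back(apar(r, 1));
  }
  IntegerMatrix dih = sys["dihedrals"];
  NumericMatrix dpar = sys["dihedral_par"];
  for (int r = 0; r < dih.nrow(); ++r) {
    s.di.push_back(dih(r, 0) - 1); s.dj.push_back(dih(r, 1) - 1);
    s.dk.push_back(dih(r, 2) - 1); s.dl.push_back(dih(r, 3) - 1);
    s.dkphi.push_back(dpar(r, 0)); s.dn.push_back((int)dpar(r, 1));
    s.dgamma.push_back(dpar(r, 2));
  }
  s.pclass.assign((size_t)s.n * s.n, 0);
  IntegerMatrix excl = sys["excl"];
  for (int r = 0; r < excl.nrow(); ++r) {
    int i = excl(r, 0) - 1, j = excl(r, 1) - 1;
    s.pclass[i * s.n + j] = 1; s.pclass[j * s.n + i] = 1;
  }
  IntegerMatrix p14 = sys["pairs14"];
  for (int r = 0; r < p14.nrow(); ++r) {
    int i = p14(r, 0) - 1, j = p14(r, 1) - 1;
    s.pclass[i * s.n + j] = 2; s.pclass[j * s.n + i] = 2;
  }
  s.eps_out = as<double>(sys["eps_out"]);
  s.gb = as<bool>(sys["gb"]);
  s.sa = as<bool>(sys["sa"]);
  s.sa_gamma = as<double>(sys["sa_gamma"]);
  return s;
}

static inline double dist(const System& s, int i, int j) {
  double dx = s.x[i] - s.x[j], dy = s.y[i] - s.y[j], dz = s.z[i] - s.z[j];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// HCT pairwise-descreening effective Born radii
static void born_radii(const System& s, std::vector<double>& R) {
  R.assign(s.n, 0.0);
  for (int i = 0; i < s.n; ++i) {
    double rho_i = s.gbr[i] - GB_OFFSET;
    double inv = 1.0 / rho_i;
    for (int j = 0; j < s.n; ++j) {
      if (j == i) continue;
      double rho_j = s.gbr[j] - GB_OFFSET;
      double sj = s.gbs[j] * rho_j;
      double r = dist(s, i, j);
      if (rho_i >= r + sj) continue;
      double U = r + sj;
      double L = (rho_i > std::fabs(r - sj)) ? rho_i : std::fabs(r - sj);
      double term = 0.5 * (1.0 / L - 1.0 / U +
                           0.25 * (r - sj * sj / r) *
                             (1.0 / (U * U) - 1.0 / (L * L)) +
                           0.5 / r * std::log(L / U));
      if (rho_i < sj - r) term += (1.0 / rho_i - 1.0 / L);
      inv -= term;
    }
    R[i] = 1.0 / inv;
  }
}

static void energy_core(const System& s, double out[7]) {
  double e_bond = 0, e_ang = 0, e_dih = 0, e_lj = 0, e_coul = 0,
    e_gb = 0, e_sa = 0;
  for (size_t r = 0; r < s.bi.size(); ++r) {
    double d = dist(s, s.bi[r], s.bj[r]) - s.br0[r];
    e_bond += 0.5 * s.bk[r] * d * d;
  }
  for (size_t r = 0; r < s.ai.size(); ++r) {
    int i = s.ai[r], j = s.aj[r], k = s.ak[r];
    double v1x = s.x[i] - s.x[j], v1y = s.y[i] - s.y[j], v1z = s.z[i] - s.z[j];
    double v2x = s.x[k] - s.x[j], v2y = s.y[k] - s.y[j], v2z = s.z[k] - s.z[j];
    double c = (v1x * v2x + v1y * v2y + v1z * v2z) /
      (std::sqrt(v1x * v1x + v1y * v1y + v1z * v1z) *
       std::sqrt(v2x * v2x + v2y * v2y + v2z * v2z));
    if (c > 1) c = 1; if (c < -1) c = -1;
    double d = std::acos(c) - s.ath0[r];
    e_ang += 0.5 * s.akth[r] * d * d;
  }
  for (size_t r = 0; r < s.di.size(); ++r) {
    int i = s.di[r], j = s.dj[r], k = s.dk[r], l = s.dl[r];
    double b1x = s.x[j] - s.x[i], b1y = s.y[j] - s.y[i], b1z = s.z[j] - s.z[i];
    double b2x = s.x[k] - s.x[j], b2y = s.y[k] - s.y[j], b2z = s.z[k] - s.z[j];
    double b3x = s.x[l] - s.x[k], b3y = s.y[l] - s.y[k], b3z = s.z[l] - s.z[k];
    double n1x = b1y * b2z - b1z * b2y, n1y = b1z * b2x - b1x * b2z,
      n1z = b1x * b2y - b1y * b2x;
    double n2x = b2y * b3z - b2z * b3y, n2y = b2z * b3x - b2x * b3z,
      n2z = b2x * b3y - b2y * b3x;
    double b2n = std::sqrt(b2x * b2x + b2y * b2y + b2z * b2z);
    double mx = n1y * n2z - n1z * n2y, my = n1z * n2x - n1x * n2z,
      mz = n1x * n2y - n1y * n2x;
    double sinp = (mx * b2x + my * b2y + mz * b2z) / b2n;
    double cosp = n1x * n2x + n1y * n2y + n1z * n2z;
    double phi = std::atan2(sinp, cosp);
    e_dih += s.dkphi[r] * (1.0 + std::cos(s.dn[r] * phi - s.dgamma[r]));
  }
  for (int i = 0; i < s.n; ++i) {
    for (int j = i + 1; j < s.n; ++j) {
      unsigned char cls = s.pc(i, j);
      if (cls == 1) continue;
      double r = dist(s, i, j);
      double qq = KE * s.q[i] * s.q[j] / r;
      double sij = 0.5 * (s.sig[i] + s.sig[j]);
      double eij = std::sqrt(s.eps[i] * s.eps[j]);
      double lj = 0.0;
      if (eij > 0 && sij > 0) {
        double sr6 = std::pow(sij / r, 6);
        lj = 4.0 * eij * (sr6 * sr6 - sr6);
      }
      if (cls == 2) { qq /= 1.2; lj /= 2.0; }
      e_coul += qq;
      e_lj += lj;
    }
  }
  if (s.gb) {
    std::vector<double> R;
    born_radii(s, R);
    double pref = -0.5 * KE * (1.0 - 1.0 / s.eps_out);
    for (int i = 0; i < s.n; ++i) {
      e_gb += pref * s.q[i] * s.q[i] / R[i];
      for (int j = i + 1; j < s.n; ++j) {
        double r = dist(s, i, j);
        double rr = R[i] * R[j];
        double f = std::sqrt(r * r + rr * std::exp(-r * r / (4.0 * rr)));
        e_gb += 2.0 * pref * s.q[i] * s.q[j] / f;
      }
    }
    if (s.sa) {
      for (int i = 0; i < s.n; ++i) {
        double rho = s.gbr[i];
        double ratio = rho / R[i];
        double area = 4.0 * M_PI * (rho + SA_PROBE) * (rho + SA_PROBE) *
          std::pow(ratio, 6);
        e_sa += s.sa_gamma * area;
      }
    }
  }
  out[0] = e_bond; out[1] = e_ang; out[2] = e_dih; out[3] = e_lj;
  out[4] = e_coul; out[5] = e_gb; out[6] = e_sa;
}

// [[Rcpp::export]]
NumericVector energy_terms_cpp(List sys) {
  System s = unpack(sys);
  double out[7];
  energy_core(s, out);
  NumericVector res(7);
  for (int i = 0; i < 7; ++i) res[i] = out[i];
  res.names() = CharacterVector::create("bond", "angle", "dihedral", "lj",
                                        "coulomb", "gb", "sa");
  return res;
}

static double total_mm(const System& s) {
  double out[7];
  energy_core(s, out);
  return out[0] + out[1] + out[2] + out[3] + out[4] + out[5] + out[6];
}

// numerical central-difference gradient restricted to move_idx (1-based)
// [[Rcpp::export]]
List energy_grad_cpp(List sys, IntegerVector move_idx) {
  System s = unpack(sys);
  int m = move_idx.size();
  NumericVector grad(3 * m);
  const double h = 2e-6;  // nm
  for (int a = 0; a < m; ++a) {
    int i = move_idx[a] - 1;
    double* coords[3] = { &s.x[i], &s.y[i], &s.z[i] };
    for (int d = 0; d < 3; ++d) {
      double orig = *coords[d];
      *coords[d] = orig + h;
      double ep = total_mm(s);
      *coords[d] = orig - h;
      double em = total_mm(s);
      *coords[d] = orig;
      grad[3 * a + d] = (ep - em) / (2.0 * h);
    }
  }
  double out[7];
  energy_core(s, out);
  double tot = out[0] + out[1] + out[2] + out[3] + out[4] + out[5] + out[6];
  return List::create(_["energy"] = tot, _["grad"] = grad);
}
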