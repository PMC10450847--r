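// Compiled kernels: pairwise forces/energies and the BAOAB Langevin
// integrator. Units: nm, ps, Da (g/mol), kJ/mol. Randomness comes from R's
// RNG so that set.seed() in R makes runs bitwise reproducible.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KB = 0.008314462618; // kJ/mol/K

static inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

struct PairParams {
  double eps, rc_nb, rc_ion, debye, coul;
  bool shifted;
};

// energy + accumulated force on the fly; O(N^2) double loop with 1-2
// exclusions (bonded neighbours within a chain)
static void eval_nonbonded(const std::vector<double>& x,
                           const std::vector<double>& y,
                           const std::vector<double>& z,
                           const NumericVector& box,
                           const NumericVector& sigma,
                           const NumericVector& lambda,
                           const NumericVector& charge,
                           const IntegerVector& chain,
                           const std::vector<std::pair<int,int> >& bonds,
                           const PairParams& pp,
                           std::vector<double>* fx, std::vector<double>* fy,
                           std::vector<double>* fz,
                           double* e_nb, double* e_ion,
                           std::vector<double>* per_chain) {
  int n = x.size();
  std::vector<bool> bonded_next(n, false);
  for (size_t b = 0; b < bonds.size(); ++b) {
    int i = std::min(bonds[b].first, bonds[b].second);
    // consecutive-bead bonds only; mark i -- i+1
    bonded_next[i] = true;
  }
  double rmin_fac = std::pow(2.0, 1.0 / 6.0);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (j == i + 1 && chain[i] == chain[j] && bonded_next[i]) continue;
      double dx = min_image(x[i] - x[j], box[0]);
      double dy = min_image(y[i] - y[j], box[1]);
      double dz = min_image(z[i] - z[j], box[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      double rmax = std::max(pp.rc_nb, pp.rc_ion);
      if (r2 > rmax * rmax) continue;
      double r = std::sqrt(r2);
      if (r < 1e-4) {
        stop("non-finite forces: beads %d and %d overlap (r = %g nm)",
             i + 1, j + 1, r);
      }
      double dudr = 0.0;
      if (r <= pp.rc_nb) {
        double sij = 0.5 * (sigma[i] + sigma[j]);
        double lij = 0.5 * (lambda[i] + lambda[j]);
        double s6 = std::pow(sij / r, 6);
        double ulj = 4.0 * pp.eps * (s6 * s6 - s6);
        double dulj = 24.0 * pp.eps * (s6 - 2.0 * s6 * s6) / r;
        double u;
        bool inner = r <= rmin_fac * sij;
        double s6c = std::pow(sij / pp.rc_nb, 6);
        double uljrc = 4.0 * pp.eps * (s6c * s6c - s6c);
        if (pp.shifted) {
          u = inner ? (ulj - lij * uljrc + (1.0 - lij) * pp.eps)
                    : lij * (ulj - uljrc);
        } else {
          u = inner ? (ulj + (1.0 - lij) * pp.eps) : lij * ulj;
        }
        dudr += inner ? dulj : lij * dulj;
        *e_nb += u;
        if (per_chain) {
          (*per_chain)[chain[i] - 1] += 0.5 * u;
          (*per_chain)[chain[j] - 1] += 0.5 * u;
        }
      }
      double qq = charge[i] * charge[j];
      if (qq != 0.0 && r <= pp.rc_ion) {
        double pref = pp.coul * qq;
        double e = pref * std::exp(-r / pp.debye) / r;
        double u = e;
        if (pp.shifted) u -= pref * std::exp(-pp.rc_ion / pp.debye) / pp.rc_ion;
        *e_ion += u;
        dudr += -e * (1.0 / pp.debye + 1.0 / r);
      }
      if (fx) {
        double fmag = -dudr / r; // force on i along +d
        (*fx)[i] += fmag * dx; (*fx)[j] -= fmag * dx;
        (*fy)[i] += fmag * dy; (*fy)[j] -= fmag * dy;
        (*fz)[i] += fmag * dz; (*fz)[j] -= fmag * dz;
      }
    }
  }
}

static double eval_bonds(const std::vector<double>& x,
                         const std::vector<double>& y,
                         const std::vector<double>& z,
                         const NumericVector& box,
                         const std::vector<std::pair<int,int> >& bonds,
                         double k, double r0,
                         std::vector<double>* fx, std::vector<double>* fy,
                         std::vector<double>* fz) {
  double e = 0.0;
  for (size_t b = 0; b < bonds.size(); ++b) {
    int i = bonds[b].first, j = bonds[b].second;
    double dx = min_image(x[i] - x[j], box[0]);
    double dy = min_image(y[i] - y[j], box[1]);
    double dz = min_image(z[i] - z[j], box[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    e += 0.5 * k * (r - r0) * (r - r0);
    if (fx) {
      double fmag = -k * (r - r0) / r;
      (*fx)[i] += fmag * dx; (*fx)[j] -= fmag * dx;
      (*fy)[i] += fmag * dy; (*fy)[j] -= fmag * dy;
      (*fz)[i] += fmag * dz; (*fz)[j] -= fmag * dz;
    }
  }
  return e;
}

static std::vector<std::pair<int,int> > bond_vec(const IntegerMatrix& bonds0) {
  std::vector<std::pair<int,int> > bonds;
  for (int b = 0; b < bonds0.nrow(); ++b) {
    bonds.push_back(std::make_pair(bonds0(b, 0), bonds0(b, 1)));
  }
  return bonds;
}

// [[Rcpp::export]]
List cpp_system_energy(NumericMatrix pos, NumericVector box,
                       IntegerMatrix bonds0, NumericVector sigma,
                       NumericVector lambda, NumericVector charge,
                       IntegerVector chain, double eps, double bond_k,
                       double bond_r0, double rc_nb, double rc_ion,
                       double debye, double coul, bool shifted) {
  int n = pos.nrow();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i,0); y[i] = pos(i,1); z[i] = pos(i,2); }
  std::vector<std::pair<int,int> > bonds = bond_vec(bonds0);
  int nchain = 0;
  for (int i = 0; i < n; ++i) nchain = std::max(nchain, chain[i]);
  std::vector<double> per_chain(nchain, 0.0);
  double e_nb = 0.0, e_ion = 0.0;
  PairParams pp = {eps, rc_nb, rc_ion, debye, coul, shifted};
  eval_nonbonded(x, y, z, box, sigma, lambda, charge, chain, bonds, pp,
                 NULL, NULL, NULL, &e_nb, &e_ion, &per_chain);
  double e_bond = eval_bonds(x, y, z, box, bonds, bond_k, bond_r0,
                             NULL, NULL, NULL);
  return List::create(_["bonded"] = e_bond, _["nonionic"] = e_nb,
                      _["ionic"] = e_ion,
                      _["per_chain_nonionic"] = NumericVector(per_chain.begin(),
                                                              per_chain.end()));
}

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix pos0, NumericVector box,
                      IntegerMatrix bonds0, NumericVector sigma,
                      NumericVector lambda, NumericVector charge,
                      NumericVector mass, IntegerVector chain,
                      double eps, double bond_k, double bond_r0,
                      double rc_nb, double rc_ion, double debye, double coul,
                      double temperature, double dt_ps, double friction_ps,
                      int n_steps, int save_every) {
  int n = pos0.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) { x[i] = pos0(i,0); y[i] = pos0(i,1); z[i] = pos0(i,2); }
  std::vector<std::pair<int,int> > bonds = bond_vec(bonds0);
  PairParams pp = {eps, rc_nb, rc_ion, debye, coul, true};
  double kT = KB * temperature;
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double s = std::sqrt(kT / mass[i]);
    vx[i] = s * norm_rand(); vy[i] = s * norm_rand(); vz[i] = s * norm_rand();
  }
  double c1 = std::exp(-friction_ps * dt_ps);
  double c2 = std::sqrt(1.0 - c1 * c1);
  std::vector<double> fx(n), fy(n), fz(n);
  double e_nb = 0.0, e_ion = 0.0, e_bond = 0.0;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  eval_nonbonded(x, y, z, box, sigma, lambda, charge, chain, bonds, pp,
                 &fx, &fy, &fz, &e_nb, &e_ion, NULL);
  e_bond = eval_bonds(x, y, z, box, bonds, bond_k, bond_r0, &fx, &fy, &fz);

  int n_frames = (save_every > 0) ? n_steps / save_every : 0;
  NumericVector frames(n_frames > 0 ? (R_xlen_t)n_frames * n * 3 : 0);
  NumericVector pot(n_frames), kin(n_frames);
  int frame = 0;
  for (int step = 0; step < n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt_ps / mass[i];
      vx[i] += h * fx[i]; vy[i] += h * fy[i]; vz[i] += h * fz[i];
      x[i] += 0.5 * dt_ps * vx[i];
      y[i] += 0.5 * dt_ps * vy[i];
      z[i] += 0.5 * dt_ps * vz[i];
    }
    for (int i = 0; i < n; ++i) {
      double s = std::sqrt(kT / mass[i]);
      vx[i] = c1 * vx[i] + c2 * s * norm_rand();
      vy[i] = c1 * vy[i] + c2 * s * norm_rand();
      vz[i] = c1 * vz[i] + c2 * s * norm_rand();
      x[i] += 0.5 * dt_ps * vx[i];
      y[i] += 0.5 * dt_ps * vy[i];
      z[i] += 0.5 * dt_ps * vz[i];
    }
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    e_nb = 0.0; e_ion = 0.0;
    eval_nonbonded(x, y, z, box, sigma, lambda, charge, chain, bonds, pp,
                   &fx, &fy, &fz, &e_nb, &e_ion, NULL);
    e_bond = eval_bonds(x, y, z, box, bonds, bond_k, bond_r0, &fx, &fy, &fz);
    double ke = 0.0;
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt_ps / mass[i];
      vx[i] += h * fx[i]; vy[i] += h * fy[i]; vz[i] += h * fz[i];
      ke += 0.5 * mass[i] * (vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i]);
    }
    if (save_every > 0 && (step + 1) % save_every == 0) {
      R_xlen_t off = (R_xlen_t)frame * n * 3;
      for (int i = 0; i < n; ++i) {
        frames[off + i] = x[i];
        frames[off + n + i] = y[i];
        frames[off + 2 * n + i] = z[i];
      }
      pot[frame] = e_bond + e_nb + e_ion;
      kin[frame] = ke;
      ++frame;
    }
  }
  NumericMatrix final_pos(n, 3), final_vel(n, 3);
  for (int i = 0; i < n; ++i) {
    final_pos(i,0) = x[i]; final_pos(i,1) = y[i]; final_pos(i,2) = z[i];
    final_vel(i,0) = vx[i]; final_vel(i,1) = vy[i]; final_vel(i,2) = vz[i];
  }
  if (n_frames > 0) frames.attr("dim") = IntegerVector::create(n, 3, n_frames);
  return List::create(_["frames"] = frames, _["potential"] = pot,
                      _["kinetic"] = kin, _["final_positions"] = final_pos,
                      _["final_velocities"] = final_vel);
}
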