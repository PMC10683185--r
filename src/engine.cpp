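// Metropolis Monte Carlo core for rigid three-site water around a fixed
// rigid solute.  Periodic cubic box centred on the origin, minimum-image
// convention.  Water-water interactions use an O-O molecule-centre
// spherical cutoff; solute-water interactions are summed in full (the
// solute may span a large fraction of the box, so no centre-based cutoff
// is meaningful for it).  Solute-water coupling supports linear charge
// scaling and soft-core Lennard-Jones for alchemical annihilation.
//
// All randomness is drawn from R's RNG stream (unif_rand), so a set.seed()
// on the R side makes runs bit-identical.  Draw order per attempted move:
// molecule index, tx, ty, tz, axis z, axis phi, angle, acceptance uniform.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double wrap_shift(double x, double L) {
  // lattice shift that brings x into [-L/2, L/2)
  return L * std::floor(x / L + 0.5);
}

static inline double mi(double d, double L) {
  // minimum-image component
  return d - L * std::round(d / L);
}

struct WaterParams {
  double qO, qH, epsO, sigO;
};

// Energy of water i with all other waters (O-O centre cutoff, whole
// molecules included; the O-O minimum image shift is applied to all nine
// site pairs so molecules stay whole).
static double water_water_energy_one(const double* w, int n, int i,
                                     const WaterParams& wp, double L,
                                     double cutoff, double kq) {
  const double cut2 = (cutoff > 0.0) ? cutoff * cutoff : -1.0;
  const double qq[3] = { wp.qO, wp.qH, wp.qH };
  const double s2 = wp.sigO * wp.sigO;
  double e = 0.0;
  const double* wi = w + 9 * (size_t)i;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    const double* wj = w + 9 * (size_t)j;
    double dx = wi[0] - wj[0], dy = wi[1] - wj[1], dz = wi[2] - wj[2];
    double sx = dx - mi(dx, L), sy = dy - mi(dy, L), sz = dz - mi(dz, L);
    double ox = dx - sx, oy = dy - sy, oz = dz - sz;
    double r2 = ox * ox + oy * oy + oz * oz;
    if (cut2 > 0.0 && r2 > cut2) continue;
    // O-O Lennard-Jones
    double sr2 = s2 / r2, sr6 = sr2 * sr2 * sr2;
    e += 4.0 * wp.epsO * (sr6 * sr6 - sr6);
    // nine Coulomb site pairs under the molecule image shift
    for (int a = 0; a < 3; ++a) {
      for (int b = 0; b < 3; ++b) {
        double ax = wi[3 * a] - wj[3 * b] - sx;
        double ay = wi[3 * a + 1] - wj[3 * b + 1] - sy;
        double az = wi[3 * a + 2] - wj[3 * b + 2] - sz;
        double r = std::sqrt(ax * ax + ay * ay + az * az);
        e += kq * qq[a] * qq[b] / r;
      }
    }
  }
  return e;
}

// Solute-water energy for water i at coupling lambda.  Electrostatics are
// scaled linearly in lambda; the O-site Lennard-Jones interaction uses a
// soft-core form 4*eps*lambda*[ (s6/d)^2 - s6/d ], d = alpha*(1-lambda)*s6
// + r^6, which reduces to plain LJ at lambda = 1.  Minimum image is taken
// per solute-atom against the water O and applied to all three sites.
static void solute_water_energy_one(const double* w, int i,
                                    const NumericMatrix& sp,
                                    const NumericVector& sq,
                                    const NumericVector& seps6,  // 4*eps_mix
                                    const NumericVector& ssig6,  // sigma_mix^6
                                    const WaterParams& wp, double L,
                                    double kq, double lambda, double alpha,
                                    double* elec, double* vdw) {
  const int ns = sp.nrow();
  const double qs[3] = { wp.qO, wp.qH, wp.qH };
  double ee = 0.0, ev = 0.0;
  const double* wi = w + 9 * (size_t)i;
  for (int s = 0; s < ns; ++s) {
    double dx = wi[0] - sp(s, 0), dy = wi[1] - sp(s, 1), dz = wi[2] - sp(s, 2);
    double sx = dx - mi(dx, L), sy = dy - mi(dy, L), sz = dz - mi(dz, L);
    // O site: LJ + Coulomb
    double ox = dx - sx, oy = dy - sy, oz = dz - sz;
    double r2 = ox * ox + oy * oy + oz * oz;
    double r6 = r2 * r2 * r2;
    double s6 = ssig6[s];
    if (seps6[s] != 0.0) {
      double denom = alpha * (1.0 - lambda) * s6 + r6;
      double t = s6 / denom;
      ev += lambda * seps6[s] * (t * t - t);
    }
    ee += lambda * kq * sq[s] * qs[0] / std::sqrt(r2);
    // H sites: Coulomb only
    for (int a = 1; a < 3; ++a) {
      double ax = wi[3 * a] - sp(s, 0) - sx;
      double ay = wi[3 * a + 1] - sp(s, 1) - sy;
      double az = wi[3 * a + 2] - sp(s, 2) - sz;
      double r = std::sqrt(ax * ax + ay * ay + az * az);
      ee += lambda * kq * sq[s] * qs[a] / r;
    }
  }
  *elec += ee;
  *vdw += ev;
}

static void full_energy(const double* w, int n, const NumericMatrix& sp,
                        const NumericVector& sq, const NumericVector& seps6,
                        const NumericVector& ssig6, const WaterParams& wp,
                        double L, double cutoff, double kq, double lambda,
                        double alpha, double* sw_elec, double* sw_vdw,
                        double* ww) {
  double se = 0.0, sv = 0.0, e_ww = 0.0;
  for (int i = 0; i < n; ++i) {
    if (sp.nrow() > 0)
      solute_water_energy_one(w, i, sp, sq, seps6, ssig6, wp, L, kq, lambda,
                              alpha, &se, &sv);
    e_ww += water_water_energy_one(w, n, i, wp, L, cutoff, kq);
  }
  *sw_elec = se;
  *sw_vdw = sv;
  *ww = 0.5 * e_ww;  // pair sum counted twice
}

static double solute_water_total(const double* w, int n,
                                 const NumericMatrix& sp,
                                 const NumericVector& sq,
                                 const NumericVector& seps6,
                                 const NumericVector& ssig6,
                                 const WaterParams& wp, double L, double kq,
                                 double lambda, double alpha) {
  double e = 0.0, v = 0.0;
  for (int i = 0; i < n; ++i)
    solute_water_energy_one(w, i, sp, sq, seps6, ssig6, wp, L, kq, lambda,
                            alpha, &e, &v);
  return e + v;
}

static WaterParams as_wp(const List& wplist) {
  WaterParams wp;
  wp.qO = as<double>(wplist["qO"]);
  wp.qH = as<double>(wplist["qH"]);
  wp.epsO = as<double>(wplist["epsilon"]);
  wp.sigO = as<double>(wplist["sigma"]);
  return wp;
}

// Lorentz-Berthelot mixed solute/water-O parameters, prefolded as
// 4*sqrt(eps_s*eps_O) and sigma_mix^6.
static void mix_params(const NumericVector& seps, const NumericVector& ssig,
                       const WaterParams& wp, NumericVector& seps6,
                       NumericVector& ssig6) {
  for (int s = 0; s < seps.size(); ++s) {
    seps6[s] = 4.0 * std::sqrt(seps[s] * wp.epsO);
    double sm = 0.5 * (ssig[s] + wp.sigO);
    double s2 = sm * sm;
    ssig6[s] = s2 * s2 * s2;
  }
}

// [[Rcpp::export]]
NumericVector cpp_state_energy(NumericMatrix waters, NumericMatrix spos,
                               NumericVector sq, NumericVector seps,
                               NumericVector ssig, List wplist, double L,
                               double cutoff, double kq, double lambda,
                               double alpha) {
  WaterParams wp = as_wp(wplist);
  int n = waters.nrow();
  NumericVector seps6(seps.size()), ssig6(seps.size());
  mix_params(seps, ssig, wp, seps6, ssig6);
  std::vector<double> w(9 * (size_t)std::max(n, 1));
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 9; ++k) w[9 * (size_t)i + k] = waters(i, k);
  double se = 0.0, sv = 0.0, ww = 0.0;
  if (n > 0)
    full_energy(w.data(), n, spos, sq, seps6, ssig6, wp, L, cutoff, kq,
                lambda, alpha, &se, &sv, &ww);
  return NumericVector::create(_["sw_elec"] = se, _["sw_vdw"] = sv,
                               _["ww"] = ww);
}

// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix waters, NumericMatrix spos, NumericVector sq,
                NumericVector seps, NumericVector ssig, List wplist, double L,
                double cutoff, double kq, double temperature, double d_trans,
                double d_rot_deg, double n_equil, double n_prod,
                int sample_every, int coord_every, bool coord_full,
                double refresh_every, double lambda, double alpha,
                NumericVector lambda_neighbors) {
  const double RGAS = 1.98720425e-3;
  const double RT = RGAS * temperature;
  WaterParams wp = as_wp(wplist);
  const int n = waters.nrow();
  if (n < 1) stop("state has no water molecules");
  NumericVector seps6(seps.size()), ssig6(seps.size());
  mix_params(seps, ssig, wp, seps6, ssig6);

  // working copy of coordinates
  std::vector<double> w(REAL(waters), REAL(waters) + 9 * (size_t)n);
  // column-major input: reshape to row blocks [x_O y_O z_O x_H1 ... z_H2]
  // (R passes an n x 9 matrix; convert to per-molecule contiguous layout)
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 9; ++k)
      w[9 * (size_t)i + k] = waters(i, k);

  double sw_elec, sw_vdw, ww;
  full_energy(w.data(), n, spos, sq, seps6, ssig6, wp, L, cutoff, kq, lambda,
              alpha, &sw_elec, &sw_vdw, &ww);
  if (!std::isfinite(sw_elec + sw_vdw + ww))
    stop("non-finite initial energy: overlapping atoms in the starting configuration");

  const double d_rot = d_rot_deg * M_PI / 180.0;
  const double total_moves = n_equil + n_prod;
  const int n_nb = lambda_neighbors.size();
  const int n_samp = (sample_every > 0 && n_prod > 0)
                         ? (int)std::floor(n_prod / sample_every) : 0;
  const int n_coord = (coord_every > 0 && n_prod > 0)
                          ? (int)std::floor(n_prod / coord_every) : 0;
  NumericMatrix energies(n_samp, 6);
  NumericMatrix gaps(n_nb > 0 ? n_samp : 0, n_nb);
  const int cwidth = coord_full ? 9 : 3;
  NumericMatrix coords(n_coord * (size_t)(n_coord > 0 ? n : 0), cwidth);

  double acc_equil = 0.0, acc_prod = 0.0, max_drift = 0.0;
  int i_samp = 0, i_coord = 0;
  double cand[9];
  const long long ll_equil = (long long)n_equil;
  const long long ll_total = (long long)total_moves;
  const long long ll_refresh = (long long)refresh_every;

  for (long long step = 1; step <= ll_total; ++step) {
    bool prod = step > ll_equil;
    // --- propose -------------------------------------------------------
    int i = (int)std::floor(unif_rand() * n);
    if (i == n) i = n - 1;
    double tx = (2.0 * unif_rand() - 1.0) * d_trans;
    double ty = (2.0 * unif_rand() - 1.0) * d_trans;
    double tz = (2.0 * unif_rand() - 1.0) * d_trans;
    double az = 2.0 * unif_rand() - 1.0;
    double aphi = 2.0 * M_PI * unif_rand();
    double ang = (2.0 * unif_rand() - 1.0) * d_rot;
    double u_acc = unif_rand();

    double s = std::sqrt(std::max(0.0, 1.0 - az * az));
    double ux = s * std::cos(aphi), uy = s * std::sin(aphi), uz = az;
    double ca = std::cos(ang), sa = std::sin(ang);
    const double* wi = &w[9 * (size_t)i];
    // rotate H sites about axis through O (Rodrigues), then translate all
    cand[0] = wi[0] + tx; cand[1] = wi[1] + ty; cand[2] = wi[2] + tz;
    for (int a = 1; a < 3; ++a) {
      double vx = wi[3 * a] - wi[0], vy = wi[3 * a + 1] - wi[1],
             vz = wi[3 * a + 2] - wi[2];
      double dot = ux * vx + uy * vy + uz * vz;
      double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz,
             cz = ux * vy - uy * vx;
      double rx = vx * ca + cx * sa + ux * dot * (1.0 - ca);
      double ry = vy * ca + cy * sa + uy * dot * (1.0 - ca);
      double rz = vz * ca + cz * sa + uz * dot * (1.0 - ca);
      cand[3 * a] = cand[0] + rx;
      cand[3 * a + 1] = cand[1] + ry;
      cand[3 * a + 2] = cand[2] + rz;
    }
    // wrap O into the box, dragging the H sites with it
    double shx = wrap_shift(cand[0], L), shy = wrap_shift(cand[1], L),
           shz = wrap_shift(cand[2], L);
    for (int a = 0; a < 3; ++a) {
      cand[3 * a] -= shx; cand[3 * a + 1] -= shy; cand[3 * a + 2] -= shz;
    }

    // --- local energy difference ---------------------------------------
    double old_e = 0.0, old_v = 0.0, new_e = 0.0, new_v = 0.0;
    if (spos.nrow() > 0) {
      solute_water_energy_one(w.data(), i, spos, sq, seps6, ssig6, wp, L, kq,
                              lambda, alpha, &old_e, &old_v);
    }
    double old_ww = water_water_energy_one(w.data(), n, i, wp, L, cutoff, kq);
    double saved[9];
    std::copy(&w[9 * (size_t)i], &w[9 * (size_t)i] + 9, saved);
    std::copy(cand, cand + 9, &w[9 * (size_t)i]);
    if (spos.nrow() > 0) {
      solute_water_energy_one(w.data(), i, spos, sq, seps6, ssig6, wp, L, kq,
                              lambda, alpha, &new_e, &new_v);
    }
    double new_ww = water_water_energy_one(w.data(), n, i, wp, L, cutoff, kq);
    double de = (new_e + new_v + new_ww) - (old_e + old_v + old_ww);
    if (!std::isfinite(de))
      stop("non-finite energy change at move %lld (molecule %d)", step, i + 1);

    // --- Metropolis ------------------------------------------------------
    bool accept = (de <= 0.0) || (u_acc < std::exp(-de / RT));
    if (accept) {
      sw_elec += new_e - old_e;
      sw_vdw += new_v - old_v;
      ww += new_ww - old_ww;
      if (prod) acc_prod += 1.0; else acc_equil += 1.0;
    } else {
      std::copy(saved, saved + 9, &w[9 * (size_t)i]);
    }

    // --- periodic full refresh (bounds float drift) ----------------------
    if (ll_refresh > 0 && step % ll_refresh == 0) {
      double fe, fv, fw;
      full_energy(w.data(), n, spos, sq, seps6, ssig6, wp, L, cutoff, kq,
                  lambda, alpha, &fe, &fv, &fw);
      double drift = std::fabs((sw_elec + sw_vdw + ww) - (fe + fv + fw));
      if (drift > max_drift) max_drift = drift;
      sw_elec = fe; sw_vdw = fv; ww = fw;
    }

    // --- sampling ---------------------------------------------------------
    if (prod) {
      long long pstep = step - ll_equil;
      if (sample_every > 0 && pstep % sample_every == 0 && i_samp < n_samp) {
        energies(i_samp, 0) = (double)pstep;
        energies(i_samp, 1) = sw_elec + sw_vdw + ww;
        energies(i_samp, 2) = sw_elec + sw_vdw;
        energies(i_samp, 3) = sw_elec;
        energies(i_samp, 4) = sw_vdw;
        energies(i_samp, 5) = ww;
        if (n_nb > 0) {
          double e_ref = sw_elec + sw_vdw;
          for (int b = 0; b < n_nb; ++b) {
            double e_nb = solute_water_total(w.data(), n, spos, sq, seps6,
                                             ssig6, wp, L, kq,
                                             lambda_neighbors[b], alpha);
            gaps(i_samp, b) = e_nb - e_ref;
          }
        }
        ++i_samp;
      }
      if (coord_every > 0 && pstep % coord_every == 0 && i_coord < n_coord) {
        for (int m = 0; m < n; ++m)
          for (int k = 0; k < cwidth; ++k)
            coords(i_coord * (size_t)n + m, k) = w[9 * (size_t)m + k];
        ++i_coord;
      }
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix wout(n, 9);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 9; ++k) wout(i, k) = w[9 * (size_t)i + k];

  return List::create(
      _["energies"] = energies, _["gaps"] = gaps, _["coords"] = coords,
      _["n_coord_samples"] = n_coord, _["waters_final"] = wout,
      _["acceptance_equil"] = n_equil > 0 ? acc_equil / n_equil : NA_REAL,
      _["acceptance"] = n_prod > 0 ? acc_prod / n_prod : NA_REAL,
      _["max_drift"] = max_drift,
      _["final_energy"] = NumericVector::create(sw_elec, sw_vdw, ww));
}
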