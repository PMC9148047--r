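#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Body-of-revolution (azimuthal mode 0) FDTD leap-frog kernel on a
// non-uniform staggered (r, z) grid.  Field set: Er, Ez, Hphi.
//   Ez lives on radial edges  (nr+1) x nz   (axis handled by the Ampere
//                                            contour update at r = 0)
//   Er lives on axial  edges   nr x (nz+1)
//   Hphi lives on cell centres nr x nz
// Lumped resistive ports (voltage source in series with a resistance,
// applied across a one-cell gap ring) enter the Ez update semi-implicitly.
// First-order Mur absorbing conditions terminate the padded air boundary.
//
// Per-period phasors of the feed voltage/current drive the steady-state
// detector; once the feed-current amplitude has stabilised the full E field
// is projected onto exp(-i omega t) over one final period.

// [[Rcpp::export]]
List fdtd_core(int nr, int nz,
               NumericVector dr, NumericVector dz,
               NumericVector rc, NumericVector re,
               NumericVector dzd,
               NumericVector gzp, NumericVector gzm,
               NumericMatrix cEzA, NumericMatrix cEzB,
               NumericMatrix cErA, NumericMatrix cErB,
               IntegerMatrix pecEz, IntegerMatrix pecEr,
               double dtmu, double dt, double omega,
               int steps_per_period, int max_periods, double tol,
               IntegerVector p_ie, IntegerVector p_j,
               NumericVector p_c1, NumericVector p_c2, NumericVector p_c3,
               NumericVector p_RsA, NumericVector p_Vamp,
               IntegerVector vmon_idx, NumericVector vmon_w,
               IntegerVector imon_idx, NumericVector imon_w,
               NumericVector murR, NumericVector murZlo, NumericVector murZhi) {
  const int nez = (nr + 1) * nz, ner = nr * (nz + 1), nh = nr * nz;
  std::vector<double> Ez(nez, 0.0), Er(ner, 0.0), H(nh, 0.0);
  std::vector<double> EzC(nez, 0.0), EzS(nez, 0.0), ErC(ner, 0.0), ErS(ner, 0.0);
  const int npt = p_ie.size();
  std::vector<double> pOld(npt, 0.0);
  std::vector<double> bR_old(nz), bR_nb(nz);     // Ez at r-boundary and neighbour
  std::vector<double> bZ0_old(nr), bZ0_nb(nr), bZ1_old(nr), bZ1_nb(nr);

#define EZ(ie, j) Ez[(ie) + (nr + 1) * (j)]
#define ER(i, je) Er[(i) + nr * (je)]
#define HP(i, j)  H[(i) + nr * (j)]

  const int N = steps_per_period;
  double prev_amp = -1.0, delta = NA_REAL;
  bool projecting = false, converged = false;
  double Vre = 0, Vim = 0, Ire = 0, Iim = 0;
  long step = 0;
  int periods = 0;
  const double twoN = 2.0 / N;

  for (int per = 0; per < max_periods; ++per) {
    double Ic = 0, Is = 0, Vc = 0, Vs = 0;
    for (int n = 0; n < N; ++n, ++step) {
      // ---- H update: t -> t + dt/2
      for (int j = 0; j < nz; ++j) {
        const double idz = 1.0 / dz[j];
        for (int i = 0; i < nr; ++i) {
          HP(i, j) -= dtmu * ((ER(i, j + 1) - ER(i, j)) * idz -
                              (EZ(i + 1, j) - EZ(i, j)) / dr[i]);
        }
      }
      const double th = (step + 0.5) * dt;
      double Imeas = 0.0;
      for (int q = 0; q < imon_idx.size(); ++q) Imeas += imon_w[q] * H[imon_idx[q]];
      Ic += Imeas * std::cos(omega * th);
      Is += Imeas * std::sin(omega * th);

      // ---- save boundary / port values needed after the E update
      for (int j = 0; j < nz; ++j) { bR_old[j] = EZ(nr, j); bR_nb[j] = EZ(nr - 1, j); }
      for (int i = 0; i < nr; ++i) {
        bZ0_old[i] = ER(i, 0);  bZ0_nb[i] = ER(i, 1);
        bZ1_old[i] = ER(i, nz); bZ1_nb[i] = ER(i, nz - 1);
      }
      for (int p = 0; p < npt; ++p) pOld[p] = EZ(p_ie[p], p_j[p]);

      // ---- Er update (interior axial edges)
      for (int je = 1; je < nz; ++je) {
        const double idzd = 1.0 / dzd[je - 1];
        for (int i = 0; i < nr; ++i) {
          if (pecEr(i, je)) { ER(i, je) = 0.0; continue; }
          const double curl = -(HP(i, je) - HP(i, je - 1)) * idzd;
          ER(i, je) = cErA(i, je) * ER(i, je) + cErB(i, je) * curl;
        }
      }

      // ---- Ez update (axis + interior radial edges)
      for (int j = 0; j < nz; ++j) {
        for (int ie = 0; ie < nr; ++ie) {
          if (pecEz(ie, j)) { EZ(ie, j) = 0.0; continue; }
          const double curl = (ie == 0)
            ? gzp[0] * HP(0, j)
            : gzp[ie] * HP(ie, j) - gzm[ie] * HP(ie - 1, j);
          EZ(ie, j) = cEzA(ie, j) * EZ(ie, j) + cEzB(ie, j) * curl;
        }
      }

      // ---- lumped ports (redo their edges semi-implicitly)
      const double tsrc = th;   // source sampled at the half step
      for (int p = 0; p < npt; ++p) {
        const int ie = p_ie[p], j = p_j[p];
        const double curl = (ie == 0)
          ? gzp[0] * HP(0, j)
          : gzp[ie] * HP(ie, j) - gzm[ie] * HP(ie - 1, j);
        const double Vsrc = p_Vamp[p] * std::sin(omega * tsrc);
        EZ(ie, j) = p_c3[p] * (p_c1[p] * pOld[p] + p_c2[p] * curl -
                               p_c2[p] * Vsrc / p_RsA[p]);
      }

      // ---- first-order Mur absorbing boundaries
      for (int j = 0; j < nz; ++j)
        EZ(nr, j) = bR_nb[j] + murR[j] * (EZ(nr - 1, j) - bR_old[j]);
      for (int i = 0; i < nr; ++i) {
        ER(i, 0)  = bZ0_nb[i] + murZlo[i] * (ER(i, 1) - bZ0_old[i]);
        ER(i, nz) = bZ1_nb[i] + murZhi[i] * (ER(i, nz - 1) - bZ1_old[i]);
      }

      // ---- reference-plane voltage sample and projections at t + dt
      const double te = (step + 1) * dt;
      double Vmeas = 0.0;
      for (int q = 0; q < vmon_idx.size(); ++q) Vmeas += vmon_w[q] * Er[vmon_idx[q]];
      const double cs = std::cos(omega * te), sn = std::sin(omega * te);
      Vc += Vmeas * cs;
      Vs += Vmeas * sn;
      if (projecting) {
        for (int q = 0; q < nez; ++q) { EzC[q] += Ez[q] * cs; EzS[q] += Ez[q] * sn; }
        for (int q = 0; q < ner; ++q) { ErC[q] += Er[q] * cs; ErS[q] += Er[q] * sn; }
      }
    }
    periods = per + 1;
    Vre = twoN * Vc; Vim = -twoN * Vs;
    Ire = twoN * Ic; Iim = -twoN * Is;
    const double amp = std::sqrt(Ire * Ire + Iim * Iim);
    if (!std::isfinite(amp))
      stop("FDTD fields diverged (non-finite feed current); reduce the Courant factor");
    if (projecting) break;
    if (prev_amp >= 0.0) {
      delta = std::fabs(amp - prev_amp) / std::max(amp, 1e-300);
      if (delta < tol) { converged = true; projecting = true; }
    }
    prev_amp = amp;
    if (per == max_periods - 2 && !projecting) projecting = true;
  }

  const double s = twoN;
  NumericVector EzRe(nez), EzIm(nez), ErRe(ner), ErIm(ner);
  for (int q = 0; q < nez; ++q) { EzRe[q] = s * EzC[q]; EzIm[q] = -s * EzS[q]; }
  for (int q = 0; q < ner; ++q) { ErRe[q] = s * ErC[q]; ErIm[q] = -s * ErS[q]; }

  return List::create(
    _["EzRe"] = EzRe, _["EzIm"] = EzIm,
    _["ErRe"] = ErRe, _["ErIm"] = ErIm,
    _["Vre"] = Vre, _["Vim"] = Vim, _["Ire"] = Ire, _["Iim"] = Iim,
    _["periods"] = periods, _["converged"] = converged, _["delta"] = delta);
#undef EZ
#undef ER
#undef HP
}
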