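#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// Event-timeline Bloch engine shared by the single-spin and slab-ensemble
// simulators. The pulse train is flattened in R into parallel event vectors:
//   type 0: free evolution  (relaxation + off-resonance + gradient phase)
//   type 1: RF sub-step     (half precession, rotation, half precession)
//   type 2: record          (store weighted transverse signal)
// Timing enters through small lookup tables so per-atom trigonometry is
// hoisted out of the spin loop:
//   dt_ms[k]    : distinct evolution intervals (type 1 events index the
//                 half-interval class, applied twice around the rotation)
//   grad_amp[g] : distinct values of 2*pi * G[Hz/mm] * dt[ms] / 1000, so the
//                 per-spin gradient phase is grad_amp[g] * z_j
// Conventions (used identically by synthesis and fitting):
//   rotation: right-handed about the transverse axis at azimuth phi
//   precession: Mxy <- Mxy * exp(-i * 2*pi * f * dt) for off-resonance f > 0
//   equilibrium magnetization normalized to 1; proton density applied in R.

// [[Rcpp::export]]
ComplexVector bloch_run_cpp(NumericMatrix theta,      // n_atoms x 4: t1,t2,delta,b1
                            IntegerVector ev_type,
                            NumericVector ev_angle,   // radians, nominal (b1 = 1)
                            NumericVector ev_cphi,
                            NumericVector ev_sphi,
                            IntegerVector ev_rc,      // dt class, -1 = none (1-based from R side? no: 0-based, -1 none)
                            IntegerVector ev_gc,      // grad class, -1 = none
                            NumericVector dt_ms,
                            NumericVector grad_amp,   // radians per mm
                            NumericVector zpos_mm,
                            ComplexMatrix weights) {  // n_spins x n_w
  const int n_atoms = theta.nrow();
  const int n_ev = ev_type.size();
  const int n_dt = dt_ms.size();
  const int n_gc = grad_amp.size();
  const int n_sp = zpos_mm.size();
  const int n_w = weights.ncol();
  if (weights.nrow() != n_sp) stop("weights rows must match number of sub-spins");

  int n_q = 0;
  for (int e = 0; e < n_ev; ++e) if (ev_type[e] == 2) ++n_q;
  if (n_q == 0) stop("event timeline contains no record events");

  ComplexVector out(Dimension(n_q, n_w, n_atoms));
  std::complex<double>* outp = reinterpret_cast<std::complex<double>*>(
      COMPLEX(out));

  // gradient phase tables, shared across atoms
  std::vector<double> cG(static_cast<size_t>(n_gc) * n_sp),
      sG(static_cast<size_t>(n_gc) * n_sp);
  for (int g = 0; g < n_gc; ++g)
    for (int j = 0; j < n_sp; ++j) {
      double ph = grad_amp[g] * zpos_mm[j];
      cG[g * n_sp + j] = std::cos(ph);
      sG[g * n_sp + j] = std::sin(ph);
    }

  std::vector<std::complex<double> > wts(static_cast<size_t>(n_sp) * n_w);
  for (int w = 0; w < n_w; ++w)
    for (int j = 0; j < n_sp; ++j) {
      Rcomplex z = weights(j, w);
      wts[w * n_sp + j] = std::complex<double>(z.r, z.i);
    }

  std::vector<double> Mx(n_sp), My(n_sp), Mz(n_sp);
  std::vector<double> E1(n_dt), E2(n_dt), cD(n_dt), sD(n_dt);
  const double twopi = 2.0 * M_PI;

  for (int a = 0; a < n_atoms; ++a) {
    const double t1 = theta(a, 0), t2 = theta(a, 1);
    const double delta = theta(a, 2), b1 = theta(a, 3);
    for (int k = 0; k < n_dt; ++k) {
      E1[k] = std::exp(-dt_ms[k] / t1);
      E2[k] = std::exp(-dt_ms[k] / t2);
      double ph = twopi * delta * dt_ms[k] / 1000.0;
      cD[k] = std::cos(ph);
      sD[k] = std::sin(ph);
    }
    std::fill(Mx.begin(), Mx.end(), 0.0);
    std::fill(My.begin(), My.end(), 0.0);
    std::fill(Mz.begin(), Mz.end(), 1.0);

    int q = 0;
    for (int e = 0; e < n_ev; ++e) {
      const int ty = ev_type[e];
      if (ty == 2) {
        for (int w = 0; w < n_w; ++w) {
          std::complex<double> acc(0.0, 0.0);
          const std::complex<double>* wp = &wts[static_cast<size_t>(w) * n_sp];
          for (int j = 0; j < n_sp; ++j)
            acc += wp[j] * std::complex<double>(Mx[j], My[j]);
          outp[q + static_cast<size_t>(n_q) * (w + static_cast<size_t>(n_w) * a)] = acc;
        }
        ++q;
        continue;
      }
      const int rc = ev_rc[e], gc = ev_gc[e];
      const double e1 = (rc >= 0) ? E1[rc] : 1.0;
      const double e2 = (rc >= 0) ? E2[rc] : 1.0;
      const double cd = (rc >= 0) ? cD[rc] : 1.0;
      const double sd = (rc >= 0) ? sD[rc] : 0.0;
      const double re1 = 1.0 - e1;
      const double* cgp = (gc >= 0) ? &cG[static_cast<size_t>(gc) * n_sp] : NULL;
      const double* sgp = (gc >= 0) ? &sG[static_cast<size_t>(gc) * n_sp] : NULL;

      if (ty == 0) {
        // free evolution: Mxy *= E2 * exp(-i(thD + thG)), Mz relaxes
        for (int j = 0; j < n_sp; ++j) {
          double c = cd, s = sd;
          if (cgp) {
            double cg = cgp[j], sg = sgp[j];
            c = cd * cg - sd * sg;
            s = sd * cg + cd * sg;
          }
          double mx = Mx[j], my = My[j];
          Mx[j] = e2 * (c * mx + s * my);
          My[j] = e2 * (-s * mx + c * my);
          Mz[j] = e1 * Mz[j] + re1;
        }
      } else {
        // RF sub-step: half precess, rotate, half precess
        const double alpha = b1 * ev_angle[e];
        const double ca = std::cos(alpha), sa = std::sin(alpha);
        const double cphi = ev_cphi[e], sphi = ev_sphi[e];
        for (int j = 0; j < n_sp; ++j) {
          double c = cd, s = sd;
          if (cgp) {
            double cg = cgp[j], sg = sgp[j];
            c = cd * cg - sd * sg;
            s = sd * cg + cd * sg;
          }
          double mx = Mx[j], my = My[j], mz = Mz[j];
          double tx = e2 * (c * mx + s * my);
          double ty2 = e2 * (-s * mx + c * my);
          mz = e1 * mz + re1;
          // rotate about transverse axis at azimuth phi by alpha
          double u = cphi * tx + sphi * ty2;
          double v = -sphi * tx + cphi * ty2;
          double vr = v * ca - mz * sa;
          mz = v * sa + mz * ca;
          tx = cphi * u - sphi * vr;
          ty2 = sphi * u + cphi * vr;
          // second half precession
          Mx[j] = e2 * (c * tx + s * ty2);
          My[j] = e2 * (-s * tx + c * ty2);
          Mz[j] = e1 * mz + re1;
        }
      }
    }
  }
  return out;
}
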