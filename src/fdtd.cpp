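// 2-D TM-polarized FDTD with single-pole Debye dispersion (auxiliary
// differential equation, one polarization-current variable per cell),
// CPML absorbing boundaries, an additive line-current source, and running
// DFT extraction at probe cells and an arbitrary cell subset.
//
// Conventions: e^{+j omega t} time dependence; phasors obtained by DFT
// with kernel e^{-j omega t}. Ez lives at integer nodes and integer time
// steps; the source current is applied at half-integer time steps in
// Ampere's law, so its spectrum is DFTed at t = (n + 1/2) dt, keeping the
// source and field spectra mutually consistent.
//
// Hot loops are segmented so the PML convolution terms only run inside
// the boundary strips; PEC cells are handled through zeroed update
// coefficients (ca = cb = 0 forces Ez = 0 for all time).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

#define RESTRICT __restrict__

static const double EPS0_ = 8.8541878128e-12;
static const double MU0_ = 1.25663706212e-6;

// [[Rcpp::export]]
List fdtd_run_cpp(NumericMatrix eps_inf, NumericMatrix delta_eps,
                  NumericMatrix tau, NumericMatrix sigma_s,
                  LogicalMatrix pec,
                  double dx, double dt,
                  int src_i, int src_j, NumericVector src_waveform,
                  NumericVector freqs,
                  IntegerMatrix probe_ij, IntegerMatrix cell_ij,
                  int pml_cells, double kappa_max, double alpha_max,
                  double sigma_factor,
                  int min_steps, int max_steps, int check_every,
                  double conv_tol) {
  const int nx = eps_inf.nrow(), ny = eps_inf.ncol();
  const int nf = freqs.size();
  const int np = probe_ij.nrow(), nc = cell_ij.nrow();
  const int m_grade = 3;
  const int npml = pml_cells;
  const size_t ncell = (size_t)nx * ny;

  std::vector<double> Ez(ncell, 0.0), Jp(ncell, 0.0);
  std::vector<double> Hx(ncell, 0.0), Hy(ncell, 0.0);
  std::vector<double> psi_ezx(ncell, 0.0), psi_ezy(ncell, 0.0);
  std::vector<double> psi_hyx(ncell, 0.0), psi_hxy(ncell, 0.0);

  // per-cell update coefficients; PEC cells get ca = cb = bj = 0
  std::vector<double> ca(ncell), cb(ncell), cjp(ncell), kj(ncell), bj(ncell);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t k = (size_t)i + (size_t)j * nx;
      double t2 = 2.0 * tau(i, j) + dt;
      double kjv = (2.0 * tau(i, j) - dt) / t2;
      double bjv = 2.0 * EPS0_ * delta_eps(i, j) / t2;
      double den = EPS0_ * eps_inf(i, j) / dt + sigma_s(i, j) / 2.0 + bjv / 2.0;
      kj[k] = kjv;
      cjp[k] = 0.5 * (1.0 + kjv);
      if (pec(i, j)) {
        ca[k] = 0.0; cb[k] = 0.0; bj[k] = 0.0;
      } else {
        ca[k] = (EPS0_ * eps_inf(i, j) / dt - sigma_s(i, j) / 2.0 + bjv / 2.0) / den;
        cb[k] = 1.0 / den;
        bj[k] = bjv;
      }
    }

  // CPML 1-D profiles; a = b = 0 outside the strips
  double eta0 = std::sqrt(MU0_ / EPS0_);
  double smax = sigma_factor * (m_grade + 1) / (eta0 * dx);
  std::vector<double> bEx(nx, 0.0), aEx(nx, 0.0), bHx(nx, 0.0), aHx(nx, 0.0);
  std::vector<double> bEy(ny, 0.0), aEy(ny, 0.0), bHy(ny, 0.0), aHy(ny, 0.0);
  auto prof = [&](double depth_cells, double &b, double &a) {
    double rho = depth_cells / npml;
    if (rho <= 0) { b = 0.0; a = 0.0; return; }
    double sig = smax * std::pow(rho, m_grade);
    double alp = alpha_max * (1.0 - rho);
    double kap = 1.0 + (kappa_max - 1.0) * std::pow(rho, m_grade);
    b = std::exp(-(sig / kap + alp) * dt / EPS0_);
    a = sig * (b - 1.0) / (kap * (sig + kap * alp));
  };
  for (int i = 0; i < nx; ++i) {
    double d = std::max(double(npml - i), double(i - (nx - 1 - npml)));
    if (d > 0) prof(d, bEx[i], aEx[i]);
    double dh = std::max(npml - (i + 0.5), (i + 0.5) - (nx - 1 - npml));
    if (dh > 0) prof(dh, bHx[i], aHx[i]);
  }
  for (int j = 0; j < ny; ++j) {
    double d = std::max(double(npml - j), double(j - (ny - 1 - npml)));
    if (d > 0) prof(d, bEy[j], aEy[j]);
    double dh = std::max(npml - (j + 0.5), (j + 0.5) - (ny - 1 - npml));
    if (dh > 0) prof(dh, bHy[j], aHy[j]);
  }
  // pure-interior index ranges (no PML convolution)
  const int exl = npml, exr = nx - 1 - npml;   // aEx nonzero for i<exl or i>exr
  const int hxl = npml, hxr = nx - 2 - npml;   // aHx nonzero for i<hxl or i>hxr

  std::vector<double> probe_re((size_t)np * nf, 0.0), probe_im((size_t)np * nf, 0.0);
  std::vector<double> cell_re((size_t)nc * nf, 0.0), cell_im((size_t)nc * nf, 0.0);
  std::vector<double> src_re(nf, 0.0), src_im(nf, 0.0);
  std::vector<int> pidx(np), cidx(nc);
  for (int p = 0; p < np; ++p)
    pidx[p] = (probe_ij(p, 0) - 1) + (probe_ij(p, 1) - 1) * nx;
  for (int c = 0; c < nc; ++c)
    cidx[c] = (cell_ij(c, 0) - 1) + (cell_ij(c, 1) - 1) * nx;
  std::vector<double> cosd(nf), sind(nf), cw(nf), sw(nf);
  for (int f = 0; f < nf; ++f) {
    double wdt = 2.0 * M_PI * freqs[f] * dt;
    cosd[f] = std::cos(wdt); sind[f] = std::sin(wdt);
    cw[f] = 1.0; sw[f] = 0.0;  // rotated before first use
  }

  const double hc = dt / (MU0_ * dx);
  const double inv_dx = 1.0 / dx;
  const double jsrc_scale = 1.0 / (dx * dx);
  const int src_k = src_i - 1 + (src_j - 1) * nx;
  const int nsrc = src_waveform.size();

  double *RESTRICT ez = Ez.data();
  double *RESTRICT jp = Jp.data();
  double *RESTRICT hx = Hx.data();
  double *RESTRICT hy = Hy.data();

  double peak = 0.0;
  bool diverged = false, converged = false;
  int step = 0;

  for (step = 0; step < max_steps; ++step) {
    // --- Hx update: Hx -= hc * dx_y Ez ---
    for (int j = 0; j < ny - 1; ++j) {
      size_t row = (size_t)j * nx;
      const double bh = bHy[j], ah = aHy[j];
      if (ah != 0.0) {
        for (int i = 0; i < nx; ++i) {
          size_t k = row + i;
          double d = (ez[k + nx] - ez[k]) * inv_dx;
          psi_hxy[k] = bh * psi_hxy[k] + ah * d;
          hx[k] -= hc * dx * (d + psi_hxy[k]);
        }
      } else {
        for (int i = 0; i < nx; ++i) {
          size_t k = row + i;
          hx[k] -= hc * (ez[k + nx] - ez[k]);
        }
      }
    }
    // --- Hy update: Hy += hc * dx_x Ez ---
    for (int j = 0; j < ny; ++j) {
      size_t row = (size_t)j * nx;
      for (int i = 0; i < hxl; ++i) {
        size_t k = row + i;
        double d = (ez[k + 1] - ez[k]) * inv_dx;
        psi_hyx[k] = bHx[i] * psi_hyx[k] + aHx[i] * d;
        hy[k] += hc * dx * (d + psi_hyx[k]);
      }
      for (int i = hxl; i <= hxr; ++i) {
        size_t k = row + i;
        hy[k] += hc * (ez[k + 1] - ez[k]);
      }
      for (int i = hxr + 1; i < nx - 1; ++i) {
        size_t k = row + i;
        double d = (ez[k + 1] - ez[k]) * inv_dx;
        psi_hyx[k] = bHx[i] * psi_hyx[k] + aHx[i] * d;
        hy[k] += hc * dx * (d + psi_hyx[k]);
      }
    }

    // --- Ez update (+ polarization current), source at (n + 1/2) dt ---
    double isrc = (step < nsrc) ? src_waveform[step] : 0.0;
    for (int j = 1; j < ny - 1; ++j) {
      size_t row = (size_t)j * nx;
      const double be = bEy[j], ae = aEy[j];
      if (ae != 0.0) {
        for (int i = 1; i < nx - 1; ++i) {
          size_t k = row + i;
          double dHydx = (hy[k] - hy[k - 1]) * inv_dx;
          double dHxdy = (hx[k] - hx[k - nx]) * inv_dx;
          double curl = dHydx - dHxdy;
          if (aEx[i] != 0.0) {
            psi_ezx[k] = bEx[i] * psi_ezx[k] + aEx[i] * dHydx;
            curl += psi_ezx[k];
          }
          psi_ezy[k] = be * psi_ezy[k] + ae * dHxdy;
          curl -= psi_ezy[k];
          double eo = ez[k];
          double en = ca[k] * eo + cb[k] * (curl - cjp[k] * jp[k]);
          jp[k] = kj[k] * jp[k] + bj[k] * (en - eo);
          ez[k] = en;
        }
      } else {
        for (int i = 1; i < exl; ++i) {
          size_t k = row + i;
          double dHydx = (hy[k] - hy[k - 1]) * inv_dx;
          double curl = dHydx - (hx[k] - hx[k - nx]) * inv_dx;
          psi_ezx[k] = bEx[i] * psi_ezx[k] + aEx[i] * dHydx;
          curl += psi_ezx[k];
          double eo = ez[k];
          double en = ca[k] * eo + cb[k] * (curl - cjp[k] * jp[k]);
          jp[k] = kj[k] * jp[k] + bj[k] * (en - eo);
          ez[k] = en;
        }
        for (int i = exl; i <= exr; ++i) {
          size_t k = row + i;
          double curl = (hy[k] - hy[k - 1] - hx[k] + hx[k - nx]) * inv_dx;
          double eo = ez[k];
          double en = ca[k] * eo + cb[k] * (curl - cjp[k] * jp[k]);
          jp[k] = kj[k] * jp[k] + bj[k] * (en - eo);
          ez[k] = en;
        }
        for (int i = exr + 1; i < nx - 1; ++i) {
          size_t k = row + i;
          double dHydx = (hy[k] - hy[k - 1]) * inv_dx;
          double curl = dHydx - (hx[k] - hx[k - nx]) * inv_dx;
          psi_ezx[k] = bEx[i] * psi_ezx[k] + aEx[i] * dHydx;
          curl += psi_ezx[k];
          double eo = ez[k];
          double en = ca[k] * eo + cb[k] * (curl - cjp[k] * jp[k]);
          jp[k] = kj[k] * jp[k] + bj[k] * (en - eo);
          ez[k] = en;
        }
      }
    }
    // soft additive current source (linear correction at the source cell)
    if (isrc != 0.0) {
      double dE = -cb[src_k] * isrc * jsrc_scale;
      ez[src_k] += dE;
      jp[src_k] += bj[src_k] * dE;
    }

    // --- DFT accumulation: fields at t = (n+1) dt, source at (n+1/2) dt ---
    for (int f = 0; f < nf; ++f) {
      double c = cw[f] * cosd[f] - sw[f] * sind[f];
      double s = sw[f] * cosd[f] + cw[f] * sind[f];
      cw[f] = c; sw[f] = s;
      double *pr = probe_re.data() + (size_t)f * np;
      double *pi = probe_im.data() + (size_t)f * np;
      for (int p = 0; p < np; ++p) {
        double v = ez[pidx[p]];
        pr[p] += v * c * dt;
        pi[p] -= v * s * dt;
      }
      double *crf = cell_re.data() + (size_t)f * nc;
      double *cif = cell_im.data() + (size_t)f * nc;
      const int *ci = cidx.data();
      for (int q = 0; q < nc; ++q) {
        double v = ez[ci[q]];
        crf[q] += v * c * dt;
        cif[q] -= v * s * dt;
      }
      if (isrc != 0.0) {
        double th = 2.0 * M_PI * freqs[f] * (step + 0.5) * dt;
        src_re[f] += isrc * std::cos(th) * dt;
        src_im[f] -= isrc * std::sin(th) * dt;
      }
    }

    // --- divergence / convergence guards ---
    if ((step + 1) % check_every == 0) {
      double cur = 0.0;
      bool bad = false;
      for (size_t k = 0; k < ncell; ++k) {
        double a2 = std::fabs(ez[k]);
        if (!std::isfinite(a2)) { bad = true; break; }
        if (a2 > cur) cur = a2;
      }
      if (bad || (peak > 0 && cur > 1e8 * peak)) {
        diverged = true;
        break;
      }
      if (cur > peak) peak = cur;
      if (step + 1 >= min_steps && cur < conv_tol * peak) {
        converged = true;
        ++step;
        break;
      }
    }
  }
  if (step >= max_steps && !converged && !diverged) {
    double cur = 0.0;
    for (size_t k = 0; k < ncell; ++k)
      if (std::fabs(ez[k]) > cur) cur = std::fabs(ez[k]);
    converged = std::isfinite(cur) && peak > 0 && cur < conv_tol * peak;
  }

  ComplexMatrix probe_out(np, nf), cell_out(nc, nf);
  for (int f = 0; f < nf; ++f) {
    for (int p = 0; p < np; ++p) {
      probe_out(p, f).r = probe_re[p + (size_t)f * np];
      probe_out(p, f).i = probe_im[p + (size_t)f * np];
    }
    for (int c = 0; c < nc; ++c) {
      cell_out(c, f).r = cell_re[c + (size_t)f * nc];
      cell_out(c, f).i = cell_im[c + (size_t)f * nc];
    }
  }
  ComplexVector src_out(nf);
  for (int f = 0; f < nf; ++f) {
    src_out[f].r = src_re[f];
    src_out[f].i = src_im[f];
  }
  return List::create(_["probe"] = probe_out, _["cells"] = cell_out,
                      _["src_spectrum"] = src_out,
                      _["steps"] = step, _["converged"] = converged,
                      _["diverged"] = diverged, _["peak"] = peak);
}
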