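// Pencil-beam dose/LET deposition kernel.
//
// Coplanar parallel-beam geometry: every spot axis lies in an axial (fixed
// z) plane, so the lateral offset of a voxel splits exactly into an
// in-plane perpendicular distance q and a z offset. Depth along the axis is
// converted to WEPL through the spot's central-axis trace (piecewise-linear
// t -> WEPL map) and looked up in the per-energy depth tables (integral
// dose, track LET, lateral sigma) tabulated on a uniform WEPL grid.
// Point dose = DD(z) * exp(-r^2 / 2 sigma(z)^2) / (2 pi sigma(z)^2), so the
// lateral plane integral recovers DD(z). Contributions below cutoff_rel of
// the spot's on-axis maximum are dropped.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double interp_trace(const double* t, const double* w, int n,
                                  double s) {
  if (s <= t[0]) return w[0];
  if (s >= t[n - 1]) return w[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (t[mid] <= s) lo = mid; else hi = mid;
  }
  double dt = t[hi] - t[lo];
  if (dt <= 0.0) return w[lo];
  return w[lo] + (w[hi] - w[lo]) * (s - t[lo]) / dt;
}

// [[Rcpp::export]]
List cpp_deposit(IntegerVector dims, NumericVector origin,
                 NumericVector spacing,
                 NumericMatrix spot_geo,   // ex, ey, zb, dx, dy per spot
                 IntegerVector spot_trace, // 1-based trace id per spot
                 IntegerVector spot_table, // 1-based table id per spot
                 NumericVector spot_weight,
                 List traces,              // list(t = mm, wepl = cm)
                 List tables,              // list(dz, dose, let, sigma, peak_amp)
                 IntegerVector rowmap,     // length nvox or empty
                 bool accumulate, double cutoff_rel) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const int nspot = spot_geo.nrow();
  const bool want_trip = rowmap.size() > 0;

  NumericVector dose_acc, letnum_acc;
  double *dacc = nullptr, *lacc = nullptr;
  if (accumulate) {
    dose_acc = NumericVector(nvox);
    letnum_acc = NumericVector(nvox);
    dacc = REAL(dose_acc);
    lacc = REAL(letnum_acc);
  }
  std::vector<int> ti, tj;
  std::vector<double> tx;

  // unpack tables once
  const int ntab = tables.size();
  std::vector<const double*> tb_dose(ntab), tb_let(ntab), tb_sig(ntab);
  std::vector<double> tb_dz(ntab), tb_zmax(ntab), tb_cut(ntab), tb_sigmax(ntab);
  std::vector<int> tb_n(ntab);
  for (int k = 0; k < ntab; ++k) {
    List tab = tables[k];
    NumericVector d = tab["dose"], l = tab["let"], s = tab["sigma"];
    tb_dose[k] = REAL(d); tb_let[k] = REAL(l); tb_sig[k] = REAL(s);
    tb_n[k] = d.size();
    tb_dz[k] = as<double>(tab["dz"]);
    tb_zmax[k] = tb_dz[k] * (tb_n[k] - 1);
    tb_cut[k] = cutoff_rel * as<double>(tab["peak_amp"]);
    double smax = 0.0;
    for (int i = 0; i < tb_n[k]; ++i) if (s[i] > smax) smax = s[i];
    tb_sigmax[k] = smax;
  }
  const int ntr = traces.size();
  std::vector<const double*> tr_t(ntr), tr_w(ntr);
  std::vector<int> tr_n(ntr);
  for (int k = 0; k < ntr; ++k) {
    List tr = traces[k];
    NumericVector t = tr["t"], w = tr["wepl"];
    tr_t[k] = REAL(t); tr_w[k] = REAL(w);
    tr_n[k] = t.size();
  }

  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  for (int is = 0; is < nspot; ++is) {
    const int trid = spot_trace[is] - 1;
    const int tbid = spot_table[is] - 1;
    if (trid < 0 || tbid < 0) continue;   // spot missed the image
    const double w_sp = spot_weight[is];
    const double ex = spot_geo(is, 0), ey = spot_geo(is, 1),
                 zb = spot_geo(is, 2), ddx = spot_geo(is, 3),
                 ddy = spot_geo(is, 4);
    const double* tt = tr_t[trid];
    const double* tw = tr_w[trid];
    const int ntt = tr_n[trid];
    const double zmax_tab = tb_zmax[tbid];
    const double cut_abs = tb_cut[tbid];
    const double dz_tab = tb_dz[tbid];
    const int n_tab = tb_n[tbid];
    const double* Dtab = tb_dose[tbid];
    const double* Ltab = tb_let[tbid];
    const double* Stab = tb_sig[tbid];

    // geometric extent of the deposit: axis from s=0 to where wepl hits the
    // table end (or the trace end), plus the lateral reach
    double smax_mm = tt[ntt - 1];
    if (tw[ntt - 1] > zmax_tab) {
      // find t where wepl = zmax_tab (wepl nondecreasing)
      int lo = 0, hi = ntt - 1;
      while (hi - lo > 1) {
        int mid = (lo + hi) / 2;
        if (tw[mid] <= zmax_tab) lo = mid; else hi = mid;
      }
      double dw = tw[hi] - tw[lo];
      smax_mm = (dw > 0) ? tt[lo] + (tt[hi] - tt[lo]) * (zmax_tab - tw[lo]) / dw
                         : tt[lo];
    }
    const double rmax_mm = 10.0 * tb_sigmax[tbid] *
      std::sqrt(2.0 * std::log(1.0 / cutoff_rel)) + sx + sy;
    // in-plane bbox around the axis segment
    const double ax0 = ex, ay0 = ey;
    const double ax1 = ex + ddx * smax_mm, ay1 = ey + ddy * smax_mm;
    const double xlo = std::min(ax0, ax1) - rmax_mm,
                 xhi = std::max(ax0, ax1) + rmax_mm;
    const double ylo = std::min(ay0, ay1) - rmax_mm,
                 yhi = std::max(ay0, ay1) + rmax_mm;
    int ix0 = std::max(0, (int)std::floor((xlo - ox) / sx));
    int ix1 = std::min(nx - 1, (int)std::ceil((xhi - ox) / sx));
    int iy0 = std::max(0, (int)std::floor((ylo - oy) / sy));
    int iy1 = std::min(ny - 1, (int)std::ceil((yhi - oy) / sy));
    int iz0 = std::max(0, (int)std::floor((zb - rmax_mm - oz) / sz));
    int iz1 = std::min(nz - 1, (int)std::ceil((zb + rmax_mm - oz) / sz));
    if (ix1 < ix0 || iy1 < iy0 || iz1 < iz0) continue;

    for (int iy = iy0; iy <= iy1; ++iy) {
      const double cy = oy + iy * sy;
      const double ry = cy - ey;
      for (int ix = ix0; ix <= ix1; ++ix) {
        const double cx = ox + ix * sx;
        const double rx = cx - ex;
        const double s = rx * ddx + ry * ddy;          // mm along axis
        if (s < -0.5 * sx || s > smax_mm + 0.5 * sx) continue;
        const double q_mm = rx * ddy - ry * ddx;       // in-plane offset
        const double zw = interp_trace(tt, tw, ntt, std::max(s, 0.0));
        if (zw >= zmax_tab) continue;
        // table lookup (uniform grid)
        const double fj = zw / dz_tab;
        int j = (int)fj;
        if (j >= n_tab - 1) j = n_tab - 2;
        const double fr = fj - j;
        const double dose0 = Dtab[j] + (Dtab[j + 1] - Dtab[j]) * fr;
        if (dose0 <= 0.0) continue;
        const double let0 = Ltab[j] + (Ltab[j + 1] - Ltab[j]) * fr;
        const double sig_cm = Stab[j] + (Stab[j + 1] - Stab[j]) * fr;
        const double two_s2 = 2.0 * sig_cm * sig_cm;    // cm^2
        const double amp = dose0 / (M_PI * two_s2);     // on-axis point dose
        const double q_cm2 = q_mm * q_mm * 0.01;
        const double colfac = amp * std::exp(-q_cm2 / two_s2);
        if (colfac < cut_abs) continue;
        // z reach at this column
        const double arg = 2.0 * std::log(colfac / cut_abs);
        const double zr_mm = 10.0 * sig_cm * std::sqrt(arg > 0 ? arg : 0);
        int jz0 = std::max(iz0, (int)std::ceil((zb - zr_mm - oz) / sz));
        int jz1 = std::min(iz1, (int)std::floor((zb + zr_mm - oz) / sz));
        const R_xlen_t base = (R_xlen_t)ix + (R_xlen_t)iy * nx;
        for (int iz = jz0; iz <= jz1; ++iz) {
          const double cz = oz + iz * sz;
          const double dz2_cm2 = (cz - zb) * (cz - zb) * 0.01;
          const double val = colfac * std::exp(-dz2_cm2 / two_s2);
          if (val < cut_abs) continue;
          const R_xlen_t idx = base + (R_xlen_t)iz * nx * ny;
          if (accumulate) {
            dacc[idx] += w_sp * val;
            lacc[idx] += w_sp * val * let0;
          }
          if (want_trip) {
            const int row = rowmap[idx];
            if (row > 0) {
              ti.push_back(row);
              tj.push_back(is + 1);
              tx.push_back(val);
            }
          }
        }
      }
    }
  }

  List out;
  if (accumulate) {
    out["dose"] = dose_acc;
    out["letnum"] = letnum_acc;
  }
  if (want_trip) {
    out["i"] = IntegerVector(ti.begin(), ti.end());
    out["j"] = IntegerVector(tj.begin(), tj.end());
    out["x"] = NumericVector(tx.begin(), tx.end());
  }
  return out;
}
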