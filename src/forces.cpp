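// Compiled force kernel for the vertex model.
//
// Evaluates, in one pass over the flattened cell cycles ("slots"), the
// per-cell shoelace areas, perimeters and vertex-mean centroids, and the
// total per-vertex force
//     F = -grad E + F_ext
// with the same term structure as the reference R implementation
// (area elasticity, junctional tension, perimeter contractility,
// hair-cell centroid repulsion, shear/compression on hair cells).
// The R level keeps the reference implementation; this kernel is the
// fast path used by the integrator.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double min_image(double d, double L) {
  if (!R_finite(L)) return d;
  return d - L * std::nearbyint(d / L);
}

// [[Rcpp::export]]
List vm_geometry_cpp(NumericMatrix pos,
                     IntegerVector slot_v,      // 1-based vertex id per slot
                     IntegerVector slot_nxt,    // 1-based next vertex id
                     IntegerVector slot_cell,   // 1-based cell id per slot
                     IntegerVector starts,      // 1-based slot index of cycle start
                     IntegerVector klen,        // cycle length per alive cell
                     IntegerVector alive_ids,   // 1-based cell ids (alive)
                     int n_cells,
                     NumericVector domain) {    // length 2 or 0 (planar)
  const int ns = slot_v.size();
  const double Lx = domain.size() == 2 ? domain[0] : R_PosInf;
  const double Ly = domain.size() == 2 ? domain[1] : R_PosInf;

  NumericVector dx(ns), dy(ns), len(ns), ux(ns), uy(ns);
  NumericVector area(n_cells, NA_REAL), perim(n_cells, NA_REAL);
  NumericMatrix centroid(n_cells, 2);
  std::fill(centroid.begin(), centroid.end(), NA_REAL);

  const int nc = alive_ids.size();
  for (int ci = 0; ci < nc; ++ci) {
    const int cell = alive_ids[ci] - 1;
    const int s0 = starts[ci] - 1;
    const int k = klen[ci];
    double a = 0.0, per = 0.0, cx = 0.0, cy = 0.0;
    double uxx = 0.0, uyy = 0.0;
    for (int s = s0; s < s0 + k; ++s) {
      const int v = slot_v[s] - 1;
      const int w = slot_nxt[s] - 1;
      const double ddx = min_image(pos(w, 0) - pos(v, 0), Lx);
      const double ddy = min_image(pos(w, 1) - pos(v, 1), Ly);
      dx[s] = ddx; dy[s] = ddy;
      const double l = std::sqrt(ddx * ddx + ddy * ddy);
      len[s] = l;
      ux[s] = uxx; uy[s] = uyy;       // unwrapped coord relative to start
      a += uxx * ddy - uyy * ddx;
      per += l;
      cx += uxx; cy += uyy;
      uxx += ddx; uyy += ddy;
    }
    area[cell] = 0.5 * a;
    perim[cell] = per;
    const int v0 = slot_v[s0] - 1;
    centroid(cell, 0) = pos(v0, 0) + cx / k;
    centroid(cell, 1) = pos(v0, 1) + cy / k;
  }
  return List::create(_["dx"] = dx, _["dy"] = dy, _["len"] = len,
                      _["ux"] = ux, _["uy"] = uy, _["area"] = area,
                      _["perim"] = perim, _["centroid"] = centroid);
}

// [[Rcpp::export]]
List vm_force_cpp(NumericMatrix pos,
                  IntegerVector slot_v, IntegerVector slot_nxt,
                  IntegerVector slot_prv,     // 1-based slot index of previous slot
                  IntegerVector slot_cell,
                  IntegerVector starts, IntegerVector klen,
                  IntegerVector alive_ids, int n_cells,
                  NumericVector domain,
                  NumericVector alpha_eff,    // per cell id: alpha
                  NumericVector A0_eff,       // per cell id: preferred area
                  NumericVector Gamma_eff,    // per cell id: Gamma * scale
                  NumericVector t_slot,       // per slot: junction tension
                  IntegerVector hc_cells,     // 1-based ids of hair cells
                  double sigma, double D, double kappa, bool rep_min_image,
                  double rep_fmax,
                  double eta, double zeta, double y0) {
  const int ns = slot_v.size();
  const int nv = pos.nrow();
  const double Lx = domain.size() == 2 ? domain[0] : R_PosInf;
  const double Ly = domain.size() == 2 ? domain[1] : R_PosInf;

  // pass 1: geometry
  List g = vm_geometry_cpp(pos, slot_v, slot_nxt, slot_cell, starts, klen,
                           alive_ids, n_cells, domain);
  NumericVector dx = g["dx"], dy = g["dy"], len = g["len"];
  NumericVector area = g["area"], perim = g["perim"];
  NumericMatrix centroid = g["centroid"];

  NumericMatrix F(nv, 2);

  // per-cell coefficients
  std::vector<double> ca(n_cells, 0.0), cp(n_cells, 0.0);
  for (int i = 0; i < alive_ids.size(); ++i) {
    const int cell = alive_ids[i] - 1;
    ca[cell] = alpha_eff[cell] * (area[cell] - A0_eff[cell]);
    cp[cell] = Gamma_eff[cell] * perim[cell];
  }

  // pass 2: area, perimeter and tension terms (accumulate +dE/dv, negate)
  for (int s = 0; s < ns; ++s) {
    const int v = slot_v[s] - 1;
    const int cell = slot_cell[s] - 1;
    const int sp = slot_prv[s] - 1;
    const double inv = len[s] > 0 ? 1.0 / len[s] : 0.0;
    const double invp = len[sp] > 0 ? 1.0 / len[sp] : 0.0;
    const double uhx = dx[s] * inv,  uhy = dy[s] * inv;
    const double phx = dx[sp] * invp, phy = dy[sp] * invp;
    double gx = ca[cell] * 0.5 * (dy[s] + dy[sp]);
    double gy = -ca[cell] * 0.5 * (dx[s] + dx[sp]);
    gx += cp[cell] * (phx - uhx);
    gy += cp[cell] * (phy - uhy);
    gx += t_slot[sp] * phx - t_slot[s] * uhx;
    gy += t_slot[sp] * phy - t_slot[s] * uhy;
    F(v, 0) -= gx;
    F(v, 1) -= gy;
  }

  // repulsion between hair-cell centroids (ordered pairs double count)
  const int nh = hc_cells.size();
  std::vector<double> repx(n_cells, 0.0), repy(n_cells, 0.0);
  if (sigma > 0 && nh >= 2) {
    for (int i = 0; i < nh - 1; ++i) {
      const int a = hc_cells[i] - 1;
      for (int j = i + 1; j < nh; ++j) {
        const int b = hc_cells[j] - 1;
        double rx = centroid(b, 0) - centroid(a, 0);
        double ry = centroid(b, 1) - centroid(a, 1);
        if (rep_min_image) { rx = min_image(rx, Lx); ry = min_image(ry, Ly); }
        const double R2 = rx * rx + ry * ry;
        if (R2 == 0.0) stop("coincident hair-cell centroids");
        double w = 2.0 * sigma * kappa *
          std::pow(D * D / R2, kappa / 2.0) / R2;
        if (R_finite(rep_fmax)) {
          const double wcap = rep_fmax / std::sqrt(R2);
          if (w > wcap) w = wcap;
        }
        repx[a] -= w * rx; repy[a] -= w * ry;   // -dE/dc for cell a
        repx[b] += w * rx; repy[b] += w * ry;
      }
    }
  }

  // distribute repulsion and add external shear/compression per HC vertex
  if ((sigma > 0 && nh >= 2) || eta != 0.0 || zeta != 0.0) {
    std::vector<char> is_hc(n_cells, 0);
    for (int i = 0; i < nh; ++i) is_hc[hc_cells[i] - 1] = 1;
    for (int i = 0; i < alive_ids.size(); ++i) {
      const int cell = alive_ids[i] - 1;
      if (!is_hc[cell]) continue;
      const int k = klen[i];
      double ycm = centroid(cell, 1) - y0;
      ycm = min_image(ycm, Ly);
      const double fx = repx[cell] / k + eta * ycm;
      const double fy = repy[cell] / k + zeta * ycm / k;
      const int s0 = starts[i] - 1;
      for (int s = s0; s < s0 + k; ++s) {
        const int v = slot_v[s] - 1;
        F(v, 0) += fx;
        F(v, 1) += fy;
      }
    }
  }

  return List::create(_["F"] = F, _["area"] = area, _["perim"] = perim,
                      _["len"] = len, _["centroid"] = centroid);
}

// Area-only check used by the step-halving loop.
// [[Rcpp::export]]
NumericVector vm_areas_cpp(NumericMatrix pos,
                           IntegerVector slot_v, IntegerVector slot_nxt,
                           IntegerVector starts, IntegerVector klen,
                           IntegerVector alive_ids, int n_cells,
                           NumericVector domain) {
  const double Lx = domain.size() == 2 ? domain[0] : R_PosInf;
  const double Ly = domain.size() == 2 ? domain[1] : R_PosInf;
  NumericVector area(n_cells, NA_REAL);
  for (int ci = 0; ci < alive_ids.size(); ++ci) {
    const int cell = alive_ids[ci] - 1;
    const int s0 = starts[ci] - 1;
    const int k = klen[ci];
    double a = 0.0, uxx = 0.0, uyy = 0.0;
    for (int s = s0; s < s0 + k; ++s) {
      const int v = slot_v[s] - 1;
      const int w = slot_nxt[s] - 1;
      const double ddx = min_image(pos(w, 0) - pos(v, 0), Lx);
      const double ddy = min_image(pos(w, 1) - pos(v, 1), Ly);
      a += uxx * ddy - uyy * ddx;
      uxx += ddx; uyy += ddy;
    }
    area[cell] = 0.5 * a;
  }
  return area;
}
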