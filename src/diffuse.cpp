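#include <Rcpp.h>
using namespace Rcpp;

// Explicit flux-form advection-diffusion sweep on a mass matrix.
// Faces touching land carry zero flux; mass is exchanged symmetrically so
// conservation is exact. Diffusive flux uses the density (mass/area)
// gradient; advection is first-order upwind. `nsub` substeps of dt/nsub
// days each are taken; fluxes within a substep are computed from the
// density frozen at the start of that substep.
// [[Rcpp::export]]
NumericMatrix cpp_propagate(NumericMatrix m0, LogicalMatrix water,
                            NumericVector dx_km, double dy_km,
                            NumericMatrix area, double D, double dt,
                            int nsub,
                            Nullable<NumericMatrix> u_ = R_NilValue,
                            Nullable<NumericMatrix> v_ = R_NilValue) {
  int ny = m0.nrow(), nx = m0.ncol();
  NumericMatrix m = clone(m0);
  bool has_u = u_.isNotNull(), has_v = v_.isNotNull();
  NumericMatrix u, v;
  if (has_u) u = NumericMatrix(u_);
  if (has_v) v = NumericMatrix(v_);
  double dts = dt / nsub;
  NumericMatrix c(ny, nx);
  for (int s = 0; s < nsub; ++s) {
    for (int j = 0; j < nx; ++j)
      for (int i = 0; i < ny; ++i)
        c(i, j) = m(i, j) / area(i, j);
    for (int j = 0; j + 1 < nx; ++j) {
      for (int i = 0; i < ny; ++i) {
        if (!water(i, j) || !water(i, j + 1)) continue;
        // fx is the mass flux from cell (i,j+1) into cell (i,j)
        double fx = D * (c(i, j + 1) - c(i, j)) / dx_km[i] * dy_km * dts;
        if (has_u) {
          double uf = 0.5 * (u(i, j) + u(i, j + 1));
          fx -= uf * (uf >= 0 ? c(i, j) : c(i, j + 1)) * dy_km * dts;
        }
        m(i, j) += fx;
        m(i, j + 1) -= fx;
      }
    }
    for (int j = 0; j < nx; ++j) {
      for (int i = 0; i + 1 < ny; ++i) {
        if (!water(i, j) || !water(i + 1, j)) continue;
        double dxf = 0.5 * (dx_km[i] + dx_km[i + 1]);
        double fy = D * (c(i + 1, j) - c(i, j)) / dy_km * dxf * dts;
        if (has_v) {
          double vf = 0.5 * (v(i, j) + v(i + 1, j));
          fy -= vf * (vf >= 0 ? c(i, j) : c(i + 1, j)) * dxf * dts;
        }
        m(i, j) += fy;
        m(i + 1, j) -= fy;
      }
    }
  }
  return m;
}

// Chamfer (8-neighbour, metric-weighted) distance transform with land
// impassable. Seeds have distance 0; returns km distances (Inf where
// unreachable). Iterated forward/backward raster sweeps until stable.
// [[Rcpp::export]]
NumericMatrix cpp_chamfer(LogicalMatrix seed, LogicalMatrix water,
                          NumericVector dx_km, double dy_km) {
  int ny = seed.nrow(), nx = seed.ncol();
  NumericMatrix d(ny, nx);
  std::fill(d.begin(), d.end(), R_PosInf);
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i)
      if (seed(i, j) && water(i, j)) d(i, j) = 0.0;
  const int dr[8] = {0, 0, 1, -1, 1, 1, -1, -1};
  const int dc[8] = {1, -1, 0, 0, 1, -1, 1, -1};
  bool changed = true;
  int iter = 0;
  while (changed && iter < ny + nx) {
    changed = false;
    ++iter;
    // two alternating sweep orders propagate along all directions quickly
    for (int pass = 0; pass < 2; ++pass) {
      int js = pass == 0 ? 0 : nx - 1, je = pass == 0 ? nx : -1, jd = pass == 0 ? 1 : -1;
      for (int j = js; j != je; j += jd) {
        int is = pass == 0 ? 0 : ny - 1, ie = pass == 0 ? ny : -1, id = pass == 0 ? 1 : -1;
        for (int i = is; i != ie; i += id) {
          if (!water(i, j)) continue;
          double best = d(i, j);
          for (int k = 0; k < 8; ++k) {
            int ii = i - dr[k], jj = j - dc[k];
            if (ii < 0 || ii >= ny || jj < 0 || jj >= nx) continue;
            if (!water(ii, jj)) continue;
            double w;
            if (dr[k] == 0) w = dx_km[i];
            else if (dc[k] == 0) w = dy_km;
            else w = std::sqrt(0.25 * (dx_km[i] + dx_km[ii]) * (dx_km[i] + dx_km[ii]) + dy_km * dy_km);
            double cand = d(ii, jj) + w;
            if (cand < best) best = cand;
          }
          if (best < d(i, j)) {
            d(i, j) = best;
            changed = true;
          }
        }
      }
    }
  }
  return d;
}
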