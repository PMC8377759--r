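#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// R arrays are column-major: node (i,j,k) zero-based lives at i + nx*(j + ny*k).
static inline R_xlen_t nd(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Edge-centred dielectric maps. ex holds edges parallel to x between nodes
// (i,j,k) and (i+1,j,k); midpoints inside any probe-inflated atom sphere get
// eps_in, all others eps_out.
// [[Rcpp::export]]
List cpp_dielectric_maps(NumericVector origin, double h, IntegerVector dims,
                         NumericMatrix xyz, NumericVector rad, double probe,
                         double eps_in, double eps_out) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector ex((R_xlen_t)(nx - 1) * ny * nz, eps_out);
  NumericVector ey((R_xlen_t)nx * (ny - 1) * nz, eps_out);
  NumericVector ez((R_xlen_t)nx * ny * (nz - 1), eps_out);
  int na = xyz.nrow();
  for (int a = 0; a < na; ++a) {
    double R = rad[a] + probe;
    if (R <= 0) continue;
    double R2 = R * R;
    double cx = xyz(a, 0), cy = xyz(a, 1), cz = xyz(a, 2);
    // fractional node coordinates of the atom centre
    double fx = (cx - origin[0]) / h;
    double fy = (cy - origin[1]) / h;
    double fz = (cz - origin[2]) / h;
    double Rh = R / h;
    // x-edges: midpoint at (i + 0.5, j, k)
    {
      int i0 = std::max(0, (int)std::floor(fx - Rh - 0.5));
      int i1 = std::min(nx - 2, (int)std::ceil(fx + Rh - 0.5));
      int j0 = std::max(0, (int)std::floor(fy - Rh));
      int j1 = std::min(ny - 1, (int)std::ceil(fy + Rh));
      int k0 = std::max(0, (int)std::floor(fz - Rh));
      int k1 = std::min(nz - 1, (int)std::ceil(fz + Rh));
      for (int k = k0; k <= k1; ++k) {
        double dz = origin[2] + h * k - cz;
        for (int j = j0; j <= j1; ++j) {
          double dy = origin[1] + h * j - cy;
          double dyz = dy * dy + dz * dz;
          if (dyz > R2) continue;
          for (int i = i0; i <= i1; ++i) {
            double dx = origin[0] + h * (i + 0.5) - cx;
            if (dx * dx + dyz <= R2)
              ex[nd(i, j, k, nx - 1, ny)] = eps_in;
          }
        }
      }
    }
    // y-edges: midpoint at (i, j + 0.5, k)
    {
      int i0 = std::max(0, (int)std::floor(fx - Rh));
      int i1 = std::min(nx - 1, (int)std::ceil(fx + Rh));
      int j0 = std::max(0, (int)std::floor(fy - Rh - 0.5));
      int j1 = std::min(ny - 2, (int)std::ceil(fy + Rh - 0.5));
      int k0 = std::max(0, (int)std::floor(fz - Rh));
      int k1 = std::min(nz - 1, (int)std::ceil(fz + Rh));
      for (int k = k0; k <= k1; ++k) {
        double dz = origin[2] + h * k - cz;
        for (int j = j0; j <= j1; ++j) {
          double dy = origin[1] + h * (j + 0.5) - cy;
          double dyz = dy * dy + dz * dz;
          if (dyz > R2) continue;
          for (int i = i0; i <= i1; ++i) {
            double dx = origin[0] + h * i - cx;
            if (dx * dx + dyz <= R2)
              ey[nd(i, j, k, nx, ny - 1)] = eps_in;
          }
        }
      }
    }
    // z-edges: midpoint at (i, j, k + 0.5)
    {
      int i0 = std::max(0, (int)std::floor(fx - Rh));
      int i1 = std::min(nx - 1, (int)std::ceil(fx + Rh));
      int j0 = std::max(0, (int)std::floor(fy - Rh));
      int j1 = std::min(ny - 1, (int)std::ceil(fy + Rh));
      int k0 = std::max(0, (int)std::floor(fz - Rh - 0.5));
      int k1 = std::min(nz - 2, (int)std::ceil(fz + Rh - 0.5));
      for (int k = k0; k <= k1; ++k) {
        double dz = origin[2] + h * (k + 0.5) - cz;
        for (int j = j0; j <= j1; ++j) {
          double dy = origin[1] + h * j - cy;
          double dyz = dy * dy + dz * dz;
          if (dyz > R2) continue;
          for (int i = i0; i <= i1; ++i) {
            double dx = origin[0] + h * i - cx;
            if (dx * dx + dyz <= R2)
              ez[nd(i, j, k, nx, ny)] = eps_in;
          }
        }
      }
    }
  }
  return List::create(_["ex"] = ex, _["ey"] = ey, _["ez"] = ez);
}

// Node-centred kappa^2 map (A^-2): bulk value everywhere except nodes inside
// any atom sphere inflated by the Stern (ion-exclusion) layer, which get 0.
// [[Rcpp::export]]
NumericVector cpp_kappa_map(NumericVector origin, double h, IntegerVector dims,
                            NumericMatrix xyz, NumericVector rad, double stern,
                            double kappa2_bulk) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector kap((R_xlen_t)nx * ny * nz, kappa2_bulk);
  int na = xyz.nrow();
  for (int a = 0; a < na; ++a) {
    double R = rad[a] + stern;
    if (R <= 0) continue;
    double R2 = R * R;
    double cx = xyz(a, 0), cy = xyz(a, 1), cz = xyz(a, 2);
    int i0 = std::max(0, (int)std::floor((cx - R - origin[0]) / h));
    int i1 = std::min(nx - 1, (int)std::ceil((cx + R - origin[0]) / h));
    int j0 = std::max(0, (int)std::floor((cy - R - origin[1]) / h));
    int j1 = std::min(ny - 1, (int)std::ceil((cy + R - origin[1]) / h));
    int k0 = std::max(0, (int)std::floor((cz - R - origin[2]) / h));
    int k1 = std::min(nz - 1, (int)std::ceil((cz + R - origin[2]) / h));
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + h * k - cz;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + h * j - cy;
        double dyz = dy * dy + dz * dz;
        if (dyz > R2) continue;
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + h * i - cx;
          if (dx * dx + dyz <= R2) kap[nd(i, j, k, nx, ny)] = 0.0;
        }
      }
    }
  }
  return kap;
}

// Per-atom Debye-Hueckel boundary condition: fills the six grid faces with
// sum_i celec * q_i * exp(-kappa * r) / (eps_out * r); interior stays 0.
// [[Rcpp::export]]
NumericVector cpp_boundary_peratom(NumericVector origin, double h,
                                   IntegerVector dims, NumericMatrix xyz,
                                   NumericVector q, double kappa,
                                   double eps_out, double celec) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector u((R_xlen_t)nx * ny * nz, 0.0);
  int na = xyz.nrow();
  for (int k = 0; k < nz; ++k) {
    bool kface = (k == 0 || k == nz - 1);
    double z = origin[2] + h * k;
    for (int j = 0; j < ny; ++j) {
      bool jkface = kface || j == 0 || j == ny - 1;
      double y = origin[1] + h * j;
      for (int i = 0; i < nx; ++i) {
        if (!(jkface || i == 0 || i == nx - 1)) continue;
        double x = origin[0] + h * i;
        double s = 0.0;
        for (int a = 0; a < na; ++a) {
          double dx = x - xyz(a, 0), dy = y - xyz(a, 1), dz = z - xyz(a, 2);
          double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (r < 1e-6) r = 1e-6;
          s += q[a] * std::exp(-kappa * r) / r;
        }
        u[nd(i, j, k, nx, ny)] = celec * s / eps_out;
      }
    }
  }
  return u;
}

// Gauss-Seidel successive over-relaxation sweep for the linearized PBE in
// reduced units (u in kT/e, lengths in grid units of h):
//   u0 = (sum_e eps_e u_nbr + b0) / (sum_e eps_e + eps_out kappa2 h^2)
// with b = 4 pi celec q / h at charged nodes (plus any Picard source term).
// Boundary faces are Dirichlet (left untouched). Converges when the maximum
// absolute change in a sweep drops below tol * max|u|.
// [[Rcpp::export]]
List cpp_sor(NumericVector u_in, NumericVector ex, NumericVector ey,
             NumericVector ez, NumericVector kap2, double eps_out, double h,
             NumericVector b, double omega, double tol, int maxit) {
  NumericVector u = clone(u_in);
  IntegerVector dims = u.attr("dim");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double h2 = h * h;
  std::vector<double> hist;
  hist.reserve(maxit);
  double maxchange = R_PosInf;
  int it = 0;
  bool converged = false;
  for (it = 1; it <= maxit; ++it) {
    maxchange = 0.0;
    double umax = 0.0;
    for (int k = 1; k < nz - 1; ++k) {
      for (int j = 1; j < ny - 1; ++j) {
        R_xlen_t base = nd(1, j, k, nx, ny);
        for (int i = 1; i < nx - 1; ++i, ++base) {
          double exm = ex[nd(i - 1, j, k, nx - 1, ny)];
          double exp_ = ex[nd(i, j, k, nx - 1, ny)];
          double eym = ey[nd(i, j - 1, k, nx, ny - 1)];
          double eyp = ey[nd(i, j, k, nx, ny - 1)];
          double ezm = ez[nd(i, j, k - 1, nx, ny)];
          double ezp = ez[nd(i, j, k, nx, ny)];
          double num = exm * u[base - 1] + exp_ * u[base + 1] +
                       eym * u[base - nx] + eyp * u[base + nx] +
                       ezm * u[base - (R_xlen_t)nx * ny] +
                       ezp * u[base + (R_xlen_t)nx * ny] + b[base];
          double den = exm + exp_ + eym + eyp + ezm + ezp +
                       eps_out * kap2[base] * h2;
          double unew = (1.0 - omega) * u[base] + omega * num / den;
          double d = std::fabs(unew - u[base]);
          if (d > maxchange) maxchange = d;
          double au = std::fabs(unew);
          if (au > umax) umax = au;
          u[base] = unew;
        }
      }
    }
    double scale = umax > 1e-12 ? umax : 1.0;
    hist.push_back(maxchange / scale);
    if (maxchange <= tol * scale) {
      converged = true;
      break;
    }
  }
  if (it > maxit) it = maxit;
  u.attr("dim") = dims;
  return List::create(_["u"] = u, _["iterations"] = it,
                      _["residual"] = hist.empty() ? NA_REAL : hist.back(),
                      _["history"] = wrap(hist), _["converged"] = converged);
}
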