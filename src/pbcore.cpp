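#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Finite-difference Poisson / linearized PB relaxation on a regular cubic
// grid.  Potentials are in kcal/mol/e, charges in e, lengths in Angstrom.
// The grid is column-major with x fastest (R array layout, dims nx,ny,nz).
//
// epsx[i,j,k] is the dielectric on the edge between nodes (i,j,k) and
// (i+1,j,k); analogously epsy, epsz.  Arrays are passed with full nx*ny*nz
// length; the last slab along the edge axis is unused.
//
// src holds 4*pi*ke*q_node/h for each node (zero away from spread charges),
// kap2 holds eps_out*kappabar^2*h^2 per node (zero at zero ionic strength).
// Dirichlet boundary: the outermost layer of phi is held fixed.

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export(name = ".sor_solve")]]
List sor_solve(NumericVector phi_, IntegerVector dims,
               NumericVector epsx, NumericVector epsy, NumericVector epsz,
               NumericVector src, NumericVector kap2,
               double omega, double tol, int maxit) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector phi = clone(phi_);
  double *p = REAL(phi);
  const double *ex = REAL(epsx), *ey = REAL(epsy), *ez = REAL(epsz);
  const double *s = REAL(src), *k2 = REAL(kap2);

  double maxphi = 1e-30;
  for (R_xlen_t t = 0; t < phi.size(); ++t)
    if (std::fabs(p[t]) > maxphi) maxphi = std::fabs(p[t]);

  int it = 0;
  double maxdel = 0.0;
  for (it = 1; it <= maxit; ++it) {
    maxdel = 0.0;
    for (int color = 0; color < 2; ++color) {
      for (int k = 1; k < nz - 1; ++k) {
        for (int j = 1; j < ny - 1; ++j) {
          int i0 = 1 + ((j + k + 1 + color) % 2);
          for (int i = i0; i < nx - 1; i += 2) {
            const int c = idx3(i, j, k, nx, ny);
            const double exm = ex[idx3(i - 1, j, k, nx, ny)], exp_ = ex[c];
            const double eym = ey[idx3(i, j - 1, k, nx, ny)], eyp = ey[c];
            const double ezm = ez[idx3(i, j, k - 1, nx, ny)], ezp = ez[c];
            const double denom = exm + exp_ + eym + eyp + ezm + ezp + k2[c];
            const double num = exm * p[c - 1] + exp_ * p[c + 1] +
                               eym * p[c - nx] + eyp * p[c + nx] +
                               ezm * p[c - nx * ny] + ezp * p[c + nx * ny] +
                               s[c];
            const double pnew = (1.0 - omega) * p[c] + omega * num / denom;
            const double d = std::fabs(pnew - p[c]);
            if (d > maxdel) maxdel = d;
            p[c] = pnew;
            if (std::fabs(pnew) > maxphi) maxphi = std::fabs(pnew);
          }
        }
      }
    }
    if (maxdel <= tol * maxphi) break;
  }
  return List::create(_["phi"] = phi, _["iterations"] = it,
                      _["residual"] = maxdel / maxphi,
                      _["converged"] = (maxdel <= tol * maxphi));
}

static inline double spline_eps(double d, double w, double eps_in,
                                double eps_out) {
  // cubic smoothstep across the molecular boundary, window +/- w
  if (d <= -w) return eps_in;
  if (d >= w) return eps_out;
  const double t = (d + w) / (2.0 * w);
  const double h = t * t * (3.0 - 2.0 * t);
  // harmonic blend: correct series resistance across a radial boundary
  return 1.0 / ((1.0 - h) / eps_in + h / eps_out);
}

// Edge-centred dielectric maps from atom spheres (coords n x 3, radii n).
// d = signed distance to the union-of-spheres surface (negative inside).
// [[Rcpp::export(name = ".edge_dielectric")]]
List edge_dielectric(NumericMatrix coords, NumericVector radii,
                     NumericVector origin, double h, IntegerVector dims,
                     double eps_in, double eps_out, double w) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nat = coords.nrow();
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  NumericVector epsx(ntot, eps_out), epsy(ntot, eps_out), epsz(ntot, eps_out);

  if (nat == 0)
    return List::create(_["epsx"] = epsx, _["epsy"] = epsy, _["epsz"] = epsz);

  double maxr = 0.0;
  for (int a = 0; a < nat; ++a)
    if (radii[a] > maxr) maxr = radii[a];
  const double reach = maxr + w;

  for (int axis = 0; axis < 3; ++axis) {
    double *out = (axis == 0) ? REAL(epsx) : (axis == 1) ? REAL(epsy)
                                                         : REAL(epsz);
    for (int k = 0; k < nz; ++k) {
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          double x = origin[0] + h * i, y = origin[1] + h * j,
                 z = origin[2] + h * k;
          if (axis == 0) x += 0.5 * h;
          if (axis == 1) y += 0.5 * h;
          if (axis == 2) z += 0.5 * h;
          double dmin = 1e30;
          for (int a = 0; a < nat; ++a) {
            const double dx = x - coords(a, 0), dy = y - coords(a, 1),
                         dz = z - coords(a, 2);
            const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
            const double d = r - radii[a];
            if (d < dmin) dmin = d;
            if (dmin <= -w) break;
          }
          if (dmin < reach)
            out[idx3(i, j, k, nx, ny)] = spline_eps(dmin, w, eps_in, eps_out);
        }
      }
    }
  }
  return List::create(_["epsx"] = epsx, _["epsy"] = epsy, _["epsz"] = epsz);
}

// Dirichlet boundary values on the six faces from a sum of screened
// Coulomb monopoles: phi = ke/eps * sum_a q_a exp(-kappa*(r-R_a))/r
// (kappa = 0 gives the plain Coulombic condition).
// [[Rcpp::export(name = ".coulomb_boundary")]]
NumericVector coulomb_boundary(NumericVector phi_, IntegerVector dims,
                               NumericVector origin, double h,
                               NumericMatrix coords, NumericVector q,
                               double ke, double eps, double kappa) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector phi = clone(phi_);
  double *p = REAL(phi);
  const int nat = coords.nrow();
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        if (i != 0 && i != nx - 1 && j != 0 && j != ny - 1 && k != 0 &&
            k != nz - 1)
          continue;
        const double x = origin[0] + h * i, y = origin[1] + h * j,
                     z = origin[2] + h * k;
        double v = 0.0;
        for (int a = 0; a < nat; ++a) {
          const double dx = x - coords(a, 0), dy = y - coords(a, 1),
                       dz = z - coords(a, 2);
          double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (r < 1e-6) r = 1e-6;
          double scr = 1.0;
          if (kappa > 0) scr = std::exp(-kappa * r);
          v += ke * q[a] * scr / (eps * r);
        }
        p[idx3(i, j, k, nx, ny)] = v;
      }
    }
  }
  return phi;
}

// Minimum cross-set heavy-atom distance matrix between residue groups.
// ra, rb: 1-based residue index per atom.  Returns nra x nrb matrix of
// minimum interatomic distances.
// [[Rcpp::export(name = ".res_min_dist")]]
NumericMatrix res_min_dist(NumericMatrix xa, IntegerVector ra, int nra,
                           NumericMatrix xb, IntegerVector rb, int nrb) {
  NumericMatrix out(nra, nrb);
  std::fill(out.begin(), out.end(), R_PosInf);
  const int na = xa.nrow(), nb = xb.nrow();
  for (int i = 0; i < na; ++i) {
    const double xi = xa(i, 0), yi = xa(i, 1), zi = xa(i, 2);
    const int ri = ra[i] - 1;
    for (int j = 0; j < nb; ++j) {
      const double dx = xi - xb(j, 0), dy = yi - xb(j, 1), dz = zi - xb(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      const int rj = rb[j] - 1;
      if (d2 < out(ri, rj) * out(ri, rj)) out(ri, rj) = std::sqrt(d2);
    }
  }
  return out;
}
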