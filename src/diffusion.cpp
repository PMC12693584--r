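// Forward Kolmogorov solver for the density of derived-allele frequencies
// under genic selection, used to compute expected site-frequency spectra.
//
// d phi/d tau = -d/dx [ M(x) phi ] + 1/2 d^2/dx^2 [ V(x) phi ]
//   M(x) = gamma * x(1-x)          (gamma = 2*N_a*s_het, <0 deleterious)
//   V(x) = x(1-x) / nu             (tau in units of 2*N_a generations)
//
// Written in flux form F = A*phi - D*dphi/dx with effective drift
// A = M - D', D = V/2, and discretized with a Scharfetter-Gummel
// (exponential-fitting) finite-volume scheme on a non-uniform grid.
// Boundaries are one-way absorbing (fixation / loss); new mutations are
// injected into the first interior cell at a rate calibrated so that the
// discrete neutral stationary solution satisfies pi = theta exactly.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Bernoulli function B(z) = z / (exp(z) - 1), numerically stable.
static inline double bern(double z) {
  if (std::fabs(z) < 1e-8) return 1.0 - 0.5 * z;
  if (z > 500.0) return 0.0;
  if (z < -500.0) return -z;
  return z / std::expm1(z);
}

struct Operator {
  // tridiagonal action: (L phi)_j = lo[j]*phi[j-1] + di[j]*phi[j] + up[j]*phi[j+1]
  std::vector<double> lo, di, up;
};

// Build the spatial operator L (flux divergence / cell width) for given
// nu and gamma on cell centres x with cell widths w.
static Operator build_operator(const NumericVector& x, const NumericVector& w,
                               double nu, double gamma) {
  int G = x.size();
  Operator op;
  op.lo.assign(G, 0.0);
  op.di.assign(G, 0.0);
  op.up.assign(G, 0.0);

  // interior faces between cells j and j+1
  for (int j = 0; j < G - 1; ++j) {
    double xf = 0.5 * (x[j] + x[j + 1]);
    double del = x[j + 1] - x[j];
    double D = xf * (1.0 - xf) / (2.0 * nu);
    double A = gamma * xf * (1.0 - xf) - (1.0 - 2.0 * xf) / (2.0 * nu);
    double Pe = A * del / D;
    double a = (D / del) * bern(-Pe);  // coefficient on phi_j   (flux up)
    double b = (D / del) * bern(Pe);   // coefficient on phi_j+1 (flux down)
    // F = a*phi_j - b*phi_{j+1}; cell j loses F, cell j+1 gains F
    op.di[j]     -= a / w[j];
    op.up[j]     += b / w[j];
    op.lo[j + 1] += a / w[j + 1];
    op.di[j + 1] -= b / w[j + 1];
  }

  // left boundary (loss): one-way outflow from cell 0 towards x = 0
  {
    double xf = 0.5 * x[0];
    double del = x[0];
    double D = xf * (1.0 - xf) / (2.0 * nu);
    double A = gamma * xf * (1.0 - xf) - (1.0 - 2.0 * xf) / (2.0 * nu);
    double Pe = A * del / D;
    // flux at lower face into the cell: -(D/del)*B(Pe)*phi_0  (phi_ghost = 0)
    op.di[0] -= (D / del) * bern(Pe) / w[0];
  }
  // right boundary (fixation): one-way outflow from cell G-1 towards x = 1
  {
    double xf = 0.5 * (x[G - 1] + 1.0);
    double del = 1.0 - x[G - 1];
    double D = xf * (1.0 - xf) / (2.0 * nu);
    double A = gamma * xf * (1.0 - xf) - (1.0 - 2.0 * xf) / (2.0 * nu);
    double Pe = A * del / D;
    // flux at upper face out of the cell: (D/del)*B(-Pe)*phi_{G-1}
    op.di[G - 1] -= (D / del) * bern(-Pe) / w[G - 1];
  }
  return op;
}

// Thomas algorithm for (diag + scale*L) phi = rhs where L is the tridiagonal
// operator; diag is added to the main diagonal.
static std::vector<double> tridiag_solve(const Operator& op, double diag,
                                         double scale,
                                         const std::vector<double>& rhs) {
  int G = rhs.size();
  std::vector<double> c(G), d(G), phi(G);
  double b0 = diag + scale * op.di[0];
  c[0] = scale * op.up[0] / b0;
  d[0] = rhs[0] / b0;
  for (int j = 1; j < G; ++j) {
    double a = scale * op.lo[j];
    double b = diag + scale * op.di[j];
    double m = b - a * c[j - 1];
    c[j] = scale * op.up[j] / m;
    d[j] = (rhs[j] - a * d[j - 1]) / m;
  }
  phi[G - 1] = d[G - 1];
  for (int j = G - 2; j >= 0; --j) phi[j] = d[j] - c[j] * phi[j + 1];
  return phi;
}

// Stationary density: solve L phi = -source, with source S injected into
// the first cell (as a density rate S / w_0).
// [[Rcpp::export(name = ".diff_stationary")]]
NumericVector diff_stationary(NumericVector x, NumericVector w, double nu,
                              double gamma, double S) {
  int G = x.size();
  Operator op = build_operator(x, w, nu, gamma);
  std::vector<double> rhs(G, 0.0);
  rhs[0] = -S / w[0];
  std::vector<double> phi = tridiag_solve(op, 0.0, 1.0, rhs);
  NumericVector out(G);
  for (int j = 0; j < G; ++j) out[j] = phi[j] < 0 ? 0.0 : phi[j];
  return out;
}

// Transient integration for duration T (units of 2*N_a generations) with
// implicit Euler and a geometrically growing time step. Early exit once the
// density is stationary to within tolerance.
// [[Rcpp::export(name = ".diff_transient")]]
NumericVector diff_transient(NumericVector x, NumericVector w,
                             NumericVector phi0, double nu, double T,
                             double gamma, double S, double dt0,
                             double growth, double dt_max) {
  int G = x.size();
  Operator op = build_operator(x, w, nu, gamma);
  std::vector<double> phi(phi0.begin(), phi0.end());
  std::vector<double> rhs(G);
  double t = 0.0, dt = dt0;
  int check = 0;
  while (t < T) {
    if (dt > T - t) dt = T - t;
    // (I - dt L) phi_new = phi + dt * source
    for (int j = 0; j < G; ++j) rhs[j] = phi[j];
    rhs[0] += dt * S / w[0];
    std::vector<double> nphi = tridiag_solve(op, 1.0, -dt, rhs);
    // stationarity monitor (every 16 steps): max |dphi| / (dt * scale)
    if (((++check) & 15) == 0) {
      double rel = 0.0, scale = 0.0;
      for (int j = 0; j < G; ++j) scale = std::max(scale, nphi[j]);
      for (int j = 0; j < G; ++j)
        rel = std::max(rel, std::fabs(nphi[j] - phi[j]));
      phi.swap(nphi);
      if (scale > 0 && rel / (dt * scale) < 1e-10) break;
    } else {
      phi.swap(nphi);
    }
    t += dt;
    dt = std::min(dt * growth, dt_max);
  }
  NumericVector out(G);
  for (int j = 0; j < G; ++j) out[j] = phi[j] < 0 ? 0.0 : phi[j];
  return out;
}
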