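#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Matrix-free conjugate-gradient solution of the discrete Laplace problem
//   div( eps * grad V ) = 0
// on a regular grid, with Dirichlet nodes marked in `isfix` (their value is
// taken from `init`) and zero-normal-flux (Neumann) conditions on every
// exterior face not covered by Dirichlet nodes.
//
// Axisymmetric (r,z) grids use finite-volume radial weights so the operator
// stays symmetric positive definite: the transmissibility of the r-face
// between nodes i and i+1 is (i+1/2), and the z-face weight of node i is the
// control-volume integral of r (i for i>0, 1/8 on the axis node i=0, where
// the control volume is the half-cell [0, h/2]).
//
// Permittivity is per-node; face values are harmonic means (exact for
// series flux through piecewise-constant media). The uniform-permittivity
// case is specialised: it is the hot path and needs no divisions.

static inline double hmean(double a, double b) { return 2.0 * a * b / (a + b); }

namespace {

// Apply the (negated) Laplace operator restricted to free nodes:
//   out[k] = diag_k * x[k] - sum_f T_f * x[nb]   for free k,
// out[k] = 0 at Dirichlet nodes. Contributions from Dirichlet neighbours
// use x[nb] as-is (callers zero Dirichlet entries of x when a homogeneous
// operator is wanted).
template <bool UNIFORM, bool THREED, bool AXISYM>
void apply_op(int n1, int n2, int n3, const int *fix, const double *eps,
              const double *x, double *out) {
  const R_xlen_t s1 = 1, s2 = n1, s3 = (R_xlen_t)n1 * n2;
  for (int m = 0; m < n3; ++m) {
    for (int j = 0; j < n2; ++j) {
      const R_xlen_t base = (R_xlen_t)m * s3 + (R_xlen_t)j * s2;
      for (int i = 0; i < n1; ++i) {
        const R_xlen_t k = base + i;
        if (fix[k]) { out[k] = 0.0; continue; }
        double diag = 0.0, acc = 0.0, T;
        const double e0 = UNIFORM ? 1.0 : eps[k];
        // direction 1 (r in axisymmetric mode, x otherwise)
        if (i + 1 < n1) {
          T = UNIFORM ? 1.0 : hmean(e0, eps[k + s1]);
          if (AXISYM) T *= (i + 0.5);
          diag += T; acc += T * x[k + s1];
        }
        if (i > 0) {
          T = UNIFORM ? 1.0 : hmean(e0, eps[k - s1]);
          if (AXISYM) T *= (i - 0.5);
          diag += T; acc += T * x[k - s1];
        }
        // direction 2 (z in axisymmetric mode, y otherwise)
        const double wz = AXISYM ? (i > 0 ? (double)i : 0.125) : 1.0;
        if (j + 1 < n2) {
          T = wz * (UNIFORM ? 1.0 : hmean(e0, eps[k + s2]));
          diag += T; acc += T * x[k + s2];
        }
        if (j > 0) {
          T = wz * (UNIFORM ? 1.0 : hmean(e0, eps[k - s2]));
          diag += T; acc += T * x[k - s2];
        }
        // direction 3 (z in 3-D)
        if (THREED) {
          if (m + 1 < n3) {
            T = UNIFORM ? 1.0 : hmean(e0, eps[k + s3]);
            diag += T; acc += T * x[k + s3];
          }
          if (m > 0) {
            T = UNIFORM ? 1.0 : hmean(e0, eps[k - s3]);
            diag += T; acc += T * x[k - s3];
          }
        }
        out[k] = diag * x[k] - acc;
      }
    }
  }
}

struct Grid {
  int n1, n2, n3;            // n3 == 1 for axisymmetric (r,z)
  bool axisym;
  const double *eps;         // may be nullptr (uniform eps = 1)
  const int *fix;            // 1 = Dirichlet

  void apply(const double *x, double *out) const {
    const bool uni = eps == nullptr, td = n3 > 1;
    if (uni && td)            apply_op<true,  true,  false>(n1, n2, n3, fix, eps, x, out);
    else if (uni && axisym)   apply_op<true,  false, true >(n1, n2, n3, fix, eps, x, out);
    else if (uni)             apply_op<true,  false, false>(n1, n2, n3, fix, eps, x, out);
    else if (td)              apply_op<false, true,  false>(n1, n2, n3, fix, eps, x, out);
    else if (axisym)          apply_op<false, false, true >(n1, n2, n3, fix, eps, x, out);
    else                      apply_op<false, false, false>(n1, n2, n3, fix, eps, x, out);
  }
};

inline double dot(const std::vector<double> &a, const std::vector<double> &b) {
  double s = 0.0;
  for (size_t k = 0; k < a.size(); ++k) s += a[k] * b[k];
  return s;
}

}  // namespace

// [[Rcpp::export]]
List cpp_solve_laplace(IntegerVector dims, NumericVector init,
                       IntegerVector isfix, SEXP eps_, bool axisym,
                       double tol, int maxit) {
  Grid g;
  g.n1 = dims[0];
  g.n2 = dims[1];
  g.n3 = dims.size() > 2 ? dims[2] : 1;
  g.axisym = axisym;
  g.fix = INTEGER(isfix);
  g.eps = Rf_isNull(eps_) ? nullptr : REAL(eps_);
  const R_xlen_t N = (R_xlen_t)g.n1 * g.n2 * g.n3;
  if (init.size() != N || isfix.size() != N)
    stop("grid size mismatch");

  NumericVector x = clone(init);
  double *xp = REAL(x);
  std::vector<double> r(N), p(N), Ap(N);

  // initial residual r = -A x (equation is A x = 0 with Dirichlet data in x)
  g.apply(xp, r.data());
  for (R_xlen_t k = 0; k < N; ++k) r[k] = -r[k];
  double rr = dot(r, r);
  const double norm0 = std::sqrt(rr);
  if (norm0 == 0.0)
    return List::create(_["V"] = x, _["iter"] = 0, _["relres"] = 0.0,
                        _["converged"] = true);

  p = r;
  int it = 0;
  double relres = 1.0;
  for (it = 1; it <= maxit; ++it) {
    g.apply(p.data(), Ap.data());
    double pAp = dot(p, Ap);
    if (pAp <= 0.0) stop("conjugate gradient breakdown (non-SPD operator)");
    double alpha = rr / pAp;
    for (R_xlen_t k = 0; k < N; ++k) {
      if (!g.fix[k]) xp[k] += alpha * p[k];
      r[k] -= alpha * Ap[k];
    }
    double rr_new = dot(r, r);
    relres = std::sqrt(rr_new) / norm0;
    if (relres <= tol) break;
    double beta = rr_new / rr;
    rr = rr_new;
    for (R_xlen_t k = 0; k < N; ++k) p[k] = r[k] + beta * p[k];
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["V"] = x, _["iter"] = std::min(it, maxit),
                      _["relres"] = relres, _["converged"] = relres <= tol);
}
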