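#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Action of a generator exponential on a real statevector,
// y = exp(theta * A) v, for sparse A in compressed-sparse-column form
// (the slots of a Matrix::dgCMatrix).  Segmented Taylor series: the
// rotation is split into ceil(|theta| * ||A||_inf) segments so each
// partial series converges rapidly; terms are accumulated until they drop
// below tol relative to the running result.  A is anti-Hermitian in all
// uses, so the series is numerically benign (unitary target).
// [[Rcpp::export]]
NumericVector exp_action_csc(IntegerVector Ap, IntegerVector Ai,
                             NumericVector Ax, double theta,
                             NumericVector v, double tol, int max_terms,
                             double inf_norm) {
  const int n = v.size();
  if (theta == 0.0) return clone(v);
  std::vector<double> y(v.begin(), v.end());
  std::vector<double> term(n), tmp(n);
  int s = (int)std::ceil(std::fabs(theta) * inf_norm);
  if (s < 1) s = 1;
  const double h = theta / s;
  for (int seg = 0; seg < s; ++seg) {
    std::copy(y.begin(), y.end(), term.begin());
    for (int k = 1; k <= max_terms; ++k) {
      std::fill(tmp.begin(), tmp.end(), 0.0);
      for (int col = 0; col < n; ++col) {
        const double tv = term[col];
        if (tv == 0.0) continue;
        for (int idx = Ap[col]; idx < Ap[col + 1]; ++idx)
          tmp[Ai[idx]] += Ax[idx] * tv;
      }
      const double c = h / k;
      double tn = 0.0, yn = 0.0;
      for (int j = 0; j < n; ++j) {
        term[j] = c * tmp[j];
        y[j] += term[j];
        tn += term[j] * term[j];
        yn += y[j] * y[j];
      }
      if (std::sqrt(tn) <= tol * std::sqrt(yn)) break;
    }
  }
  return NumericVector(y.begin(), y.end());
}

// Plain sparse matrix-vector product for the same CSC layout; used in the
// pool-gradient sweep where hundreds of small products are issued.
// [[Rcpp::export]]
NumericVector spmv_csc(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                       NumericVector v) {
  const int n = v.size();
  NumericVector out(n);
  for (int col = 0; col < n; ++col) {
    const double tv = v[col];
    if (tv == 0.0) continue;
    for (int idx = Ap[col]; idx < Ap[col + 1]; ++idx)
      out[Ai[idx]] += Ax[idx] * tv;
  }
  return out;
}

static double csc_inf_norm(const int* Ap, const int* Ai, const double* Ax,
                           int n) {
  std::vector<double> rowsum(n, 0.0);
  for (int col = 0; col < n; ++col)
    for (int idx = Ap[col]; idx < Ap[col + 1]; ++idx)
      rowsum[Ai[idx]] += std::fabs(Ax[idx]);
  double m = 0.0;
  for (int j = 0; j < n; ++j) if (rowsum[j] > m) m = rowsum[j];
  return m;
}

static void csc_spmv(const int* Ap, const int* Ai, const double* Ax, int n,
                     const double* v, double* out) {
  std::fill(out, out + n, 0.0);
  for (int col = 0; col < n; ++col) {
    const double tv = v[col];
    if (tv == 0.0) continue;
    for (int idx = Ap[col]; idx < Ap[col + 1]; ++idx)
      out[Ai[idx]] += Ax[idx] * tv;
  }
}

static void csc_exp_inplace(const int* Ap, const int* Ai, const double* Ax,
                            int n, double theta, double inf_norm,
                            std::vector<double>& y, double tol,
                            int max_terms, std::vector<double>& term,
                            std::vector<double>& tmp) {
  if (theta == 0.0) return;
  int s = (int)std::ceil(std::fabs(theta) * inf_norm);
  if (s < 1) s = 1;
  const double h = theta / s;
  for (int seg = 0; seg < s; ++seg) {
    std::copy(y.begin(), y.end(), term.begin());
    for (int k = 1; k <= max_terms; ++k) {
      csc_spmv(Ap, Ai, Ax, n, term.data(), tmp.data());
      const double c = h / k;
      double tn = 0.0, yn = 0.0;
      for (int j = 0; j < n; ++j) {
        term[j] = c * tmp[j];
        y[j] += term[j];
        tn += term[j] * term[j];
        yn += y[j] * y[j];
      }
      if (std::sqrt(tn) <= tol * std::sqrt(yn)) break;
    }
  }
}

// Energy and full analytic parameter gradient of a product-of-exponentials
// ansatz, all in one call: a forward sweep storing the intermediate
// states and a backward sweep propagating H|psi> through the adjoint
// rotations.  All matrices are dgCMatrix slots; statevectors are real.
// [[Rcpp::export]]
List energy_gradient_csc(List mats, NumericVector thetas, S4 H,
                         NumericVector ref, double tol, int max_terms) {
  const int N = mats.size();
  const int n = ref.size();
  std::vector<std::vector<double> > states(N + 1);
  std::vector<double> term(n), tmp(n);
  states[0].assign(ref.begin(), ref.end());

  std::vector<const int*> Aps(N), Ais(N);
  std::vector<const double*> Axs(N);
  std::vector<double> norms(N);
  for (int k = 0; k < N; ++k) {
    S4 A(mats[k]);
    IntegerVector p = A.slot("p"), i = A.slot("i");
    NumericVector x = A.slot("x");
    Aps[k] = INTEGER(p); Ais[k] = INTEGER(i); Axs[k] = REAL(x);
    RObject cached = A.attr(".inf_norm");
    norms[k] = cached.isNULL() ? csc_inf_norm(Aps[k], Ais[k], Axs[k], n)
                               : as<double>(cached);
  }
  for (int k = 0; k < N; ++k) {
    states[k + 1] = states[k];
    csc_exp_inplace(Aps[k], Ais[k], Axs[k], n, thetas[k], norms[k],
                    states[k + 1], tol, max_terms, term, tmp);
  }
  S4 Hm(H);
  IntegerVector Hp = Hm.slot("p"), Hi = Hm.slot("i");
  NumericVector Hx = Hm.slot("x");
  std::vector<double> hpsi(n);
  csc_spmv(INTEGER(Hp), INTEGER(Hi), REAL(Hx), n, states[N].data(),
           hpsi.data());
  double energy = 0.0;
  for (int j = 0; j < n; ++j) energy += states[N][j] * hpsi[j];

  NumericVector grad(N);
  std::vector<double> lambda(hpsi);
  for (int k = N - 1; k >= 0; --k) {
    csc_spmv(Aps[k], Ais[k], Axs[k], n, states[k + 1].data(), tmp.data());
    double g = 0.0;
    for (int j = 0; j < n; ++j) g += lambda[j] * tmp[j];
    grad[k] = 2.0 * g;
    if (k > 0)
      csc_exp_inplace(Aps[k], Ais[k], Axs[k], n, -thetas[k], norms[k],
                      lambda, tol, max_terms, term, tmp);
  }
  return List::create(Named("energy") = energy, Named("gradient") = grad);
}
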