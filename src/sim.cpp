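// Forward solution of the linear compartmental system
//   dC/dt = M C(t) + K1 * C_B(t) * e1,   C(0) = 0
// by piecewise propagation with the exact matrix exponential, treating the
// input C_B as piecewise linear between grid nodes.  For each distinct step
// size h the propagator Phi = expm(M h) and the forcing integrals
//   G0 = int_0^h expm(M (h-s)) ds,  G1 = int_0^h expm(M (h-s)) s ds
// are obtained in one exponential of the Van Loan block matrix
//   [[M, I, 0], [0, 0, I], [0, 0, 0]].
// Rate constants arrive in min^-1, the time grid in seconds; conversion to
// per-second happens here and nowhere else.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Propagator {
  double h;
  mat Phi;
  vec g0;  // G0 * e1
  vec g1;  // G1 * e1
};

void van_loan(const mat& M, double h, mat& Phi, mat& G0, mat& G1) {
  const uword n = M.n_rows;
  mat A(3 * n, 3 * n, fill::zeros);
  A.submat(0, 0, n - 1, n - 1) = M;
  A.submat(0, n, n - 1, 2 * n - 1) = eye(n, n);
  A.submat(n, 2 * n, 2 * n - 1, 3 * n - 1) = eye(n, n);
  mat E = expmat(A * h);
  Phi = E.submat(0, 0, n - 1, n - 1);
  G0 = E.submat(0, n, n - 1, 2 * n - 1);
  G1 = E.submat(0, 2 * n, n - 1, 3 * n - 1);
}

// Propagators for every step of the grid, cached per distinct step size.
std::vector<int> step_propagators(const vec& grid, const mat& Ms,
                                  std::vector<Propagator>& cache) {
  const uword T = grid.n_elem;
  std::vector<int> which(T - 1);
  for (uword k = 0; k + 1 < T; ++k) {
    double h = grid[k + 1] - grid[k];
    if (!(h > 0))
      Rcpp::stop("time grid must be strictly increasing");
    int found = -1;
    for (size_t j = 0; j < cache.size(); ++j)
      if (std::abs(cache[j].h - h) < 1e-9) { found = (int)j; break; }
    if (found < 0) {
      Propagator pr;
      pr.h = h;
      mat G0, G1;
      van_loan(Ms, h, pr.Phi, G0, G1);
      pr.g0 = G0.col(0);
      pr.g1 = G1.col(0);
      cache.push_back(pr);
      found = (int)cache.size() - 1;
    }
    which[k] = found;
  }
  return which;
}

}  // namespace

// States on the full grid (n_states x n_times).  M_min in min^-1.
// [[Rcpp::export(name = ".cpp_solve_states")]]
arma::mat cpp_solve_states(const arma::mat& M_min, double K1_min,
                           const arma::vec& grid, const arma::vec& cb) {
  if (grid.n_elem != cb.n_elem)
    Rcpp::stop("grid and input values differ in length");
  if (!M_min.is_finite() || !cb.is_finite() || !std::isfinite(K1_min))
    Rcpp::stop("non-finite numerical input");
  const mat Ms = M_min / 60.0;
  const double K1s = K1_min / 60.0;
  const uword n = Ms.n_rows, T = grid.n_elem;

  std::vector<Propagator> cache;
  std::vector<int> which = step_propagators(grid, Ms, cache);

  mat out(n, T, fill::zeros);
  vec x(n, fill::zeros);
  for (uword k = 0; k + 1 < T; ++k) {
    const Propagator& pr = cache[which[k]];
    double a = cb[k];
    double b = (cb[k + 1] - cb[k]) / pr.h;
    x = pr.Phi * x + K1s * (a * pr.g0 + b * pr.g1);
    out.col(k + 1) = x;
  }
  return out;
}

// Frame-mean tissue output for one parameter set.  alpha weights the states,
// Vb adds the blood spill-in.  start_idx/end_idx are 0-based indices of the
// frame boundaries within the grid; the frame mean is the trapezoidal
// integral of C_T between them divided by the frame duration.
// [[Rcpp::export(name = ".cpp_sim_frames")]]
arma::vec cpp_sim_frames(const arma::mat& M_min, double K1_min,
                         const arma::vec& alpha, double Vb,
                         const arma::vec& grid, const arma::vec& cb,
                         const arma::ivec& start_idx,
                         const arma::ivec& end_idx) {
  if (grid.n_elem != cb.n_elem)
    Rcpp::stop("grid and input values differ in length");
  const mat Ms = M_min / 60.0;
  const double K1s = K1_min / 60.0;
  const uword n = Ms.n_rows, T = grid.n_elem;
  if (alpha.n_elem != n)
    Rcpp::stop("alpha length does not match the number of states");

  std::vector<Propagator> cache;
  std::vector<int> which = step_propagators(grid, Ms, cache);
  if (n > 3) Rcpp::stop("at most 3 tissue compartments supported");

  // fixed-size scratch copies keep the hot loop free of armadillo overhead
  double P[8][9], g0a[8][3], g1a[8][3], hh[8];
  if (cache.size() > 8) Rcpp::stop("too many distinct step sizes");
  for (size_t j = 0; j < cache.size(); ++j) {
    for (uword c = 0; c < n; ++c)
      for (uword r = 0; r < n; ++r) P[j][c * n + r] = cache[j].Phi(r, c);
    for (uword r = 0; r < n; ++r) {
      g0a[j][r] = cache[j].g0[r];
      g1a[j][r] = cache[j].g1[r];
    }
    hh[j] = cache[j].h;
  }
  const double al[3] = {alpha[0], n > 1 ? alpha[1] : 0.0,
                        n > 2 ? alpha[2] : 0.0};

  double x0 = 0, x1 = 0, x2 = 0;
  std::vector<double> cum(T, 0.0);  // cumulative trapezoid of C_T
  double ct_prev = Vb * cb[0];
  for (uword k = 0; k + 1 < T; ++k) {
    const int j = which[k];
    const double a = K1s * cb[k];
    const double b = K1s * (cb[k + 1] - cb[k]) / hh[j];
    const double* p = P[j];
    double y0, y1 = 0, y2 = 0;
    if (n == 3) {
      y0 = p[0] * x0 + p[3] * x1 + p[6] * x2 + a * g0a[j][0] + b * g1a[j][0];
      y1 = p[1] * x0 + p[4] * x1 + p[7] * x2 + a * g0a[j][1] + b * g1a[j][1];
      y2 = p[2] * x0 + p[5] * x1 + p[8] * x2 + a * g0a[j][2] + b * g1a[j][2];
    } else if (n == 2) {
      y0 = p[0] * x0 + p[2] * x1 + a * g0a[j][0] + b * g1a[j][0];
      y1 = p[1] * x0 + p[3] * x1 + a * g0a[j][1] + b * g1a[j][1];
    } else {
      y0 = p[0] * x0 + a * g0a[j][0] + b * g1a[j][0];
    }
    x0 = y0; x1 = y1; x2 = y2;
    double ct = al[0] * x0 + al[1] * x1 + al[2] * x2 + Vb * cb[k + 1];
    cum[k + 1] = cum[k] + 0.5 * (ct_prev + ct) * hh[j];
    ct_prev = ct;
  }

  const uword nf = start_idx.n_elem;
  vec means(nf);
  for (uword i = 0; i < nf; ++i) {
    int s = start_idx[i], e = end_idx[i];
    if (s < 0 || e <= s || (uword)e >= T)
      Rcpp::stop("frame boundary indices outside the grid");
    means[i] = (cum[e] - cum[s]) / (grid[e] - grid[s]);
  }
  return means;
}
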