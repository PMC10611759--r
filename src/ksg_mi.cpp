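#include <Rcpp.h>
#include <Rmath.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Kraskov-Stoegbauer-Grassberger (algorithm 1) mutual-information estimate
// between two 3-D variables, Chebyshev (max) norm throughout.
// X, Y point to n x 3 column-major blocks. psi_tab[m] = digamma(m),
// m = 0..n. Returns I in nats (clipped at 0).
static double ksg_pair3(const double* X, const double* Y, int n, int k,
                        std::vector<double>& dx, std::vector<double>& dy,
                        const std::vector<double>& psi_tab) {
  const double *x0 = X, *x1 = X + n, *x2 = X + 2 * n;
  const double *y0 = Y, *y1 = Y + n, *y2 = Y + 2 * n;
  std::vector<double> heap(k);  // k smallest joint distances (max-heap)
  double psi_sum = 0.0;
  for (int i = 0; i < n; ++i) {
    const double xi0 = x0[i], xi1 = x1[i], xi2 = x2[i];
    const double yi0 = y0[i], yi1 = y1[i], yi2 = y2[i];
    int hsz = 0;
    for (int j = 0; j < n; ++j) {
      double mx = std::fabs(xi0 - x0[j]);
      double a = std::fabs(xi1 - x1[j]);
      if (a > mx) mx = a;
      a = std::fabs(xi2 - x2[j]);
      if (a > mx) mx = a;
      double my = std::fabs(yi0 - y0[j]);
      a = std::fabs(yi1 - y1[j]);
      if (a > my) my = a;
      a = std::fabs(yi2 - y2[j]);
      if (a > my) my = a;
      dx[j] = mx;
      dy[j] = my;
      if (j == i) continue;
      double dj = mx > my ? mx : my;
      if (hsz < k) {
        heap[hsz++] = dj;
        if (hsz == k) std::make_heap(heap.begin(), heap.end());
      } else if (dj < heap[0]) {
        std::pop_heap(heap.begin(), heap.end());
        heap[k - 1] = dj;
        std::push_heap(heap.begin(), heap.end());
      }
    }
    const double eps = heap[0];  // distance to the k-th nearest neighbour
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (dx[j] < eps) ++nx;
      if (dy[j] < eps) ++ny;
    }
    // self (distance 0) is counted, giving exactly psi(n_marginal + 1)
    psi_sum += psi_tab[nx] + psi_tab[ny];
  }
  double I = ::Rf_digamma((double)k) + psi_tab[n] - psi_sum / n;
  return I > 0.0 ? I : 0.0;
}

static std::vector<double> digamma_table(int n) {
  std::vector<double> tab(n + 1);
  tab[0] = 0.0;  // unused
  for (int m = 1; m <= n; ++m) tab[m] = ::Rf_digamma((double)m);
  return tab;
}

// [[Rcpp::export(name = ".ksg_mi_pair")]]
double ksg_mi_pair(NumericMatrix X, NumericMatrix Y, int k) {
  int n = X.nrow();
  if (X.ncol() != 3 || Y.ncol() != 3)
    stop("X and Y must be n x 3 matrices");
  if (Y.nrow() != n) stop("X and Y must have the same number of rows");
  if (n <= k) stop("need more samples than k");
  std::vector<double> dx(n), dy(n);
  std::vector<double> psi_tab = digamma_table(n);
  return ksg_pair3(REAL(X), REAL(Y), n, k, dx, dy, psi_tab);
}

// Pairwise MI over residues. coords: n_frames x (3 * n_res) matrix with the
// three columns of residue r contiguous. Returns the symmetric
// n_res x n_res MI matrix (diagonal 0; callers map MI to the generalized
// correlation and set the diagonal to 1).
// [[Rcpp::export(name = ".ksg_mi_matrix")]]
NumericMatrix ksg_mi_matrix(NumericMatrix coords, int n_res, int k) {
  int n = coords.nrow();
  if (coords.ncol() != 3 * n_res) stop("coords must have 3*n_res columns");
  if (n <= k) stop("need more frames than k");
  NumericMatrix out(n_res, n_res);
  const double* base = REAL(coords);
  std::vector<double> dx(n), dy(n);
  std::vector<double> psi_tab = digamma_table(n);
  for (int a = 0; a < n_res; ++a) {
    const double* Xa = base + (size_t)(3 * a) * n;
    for (int b = a + 1; b < n_res; ++b) {
      const double* Yb = base + (size_t)(3 * b) * n;
      double I = ksg_pair3(Xa, Yb, n, k, dx, dy, psi_tab);
      out(a, b) = I;
      out(b, a) = I;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
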