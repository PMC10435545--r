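#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact (O(n^2)) t-SNE. Intended for the clustering subsample (n of order
// 10^3), where the quadratic cost is unproblematic and no approximation
// error is introduced. The initial map Y0 is supplied by the caller so that
// all randomness goes through R's RNG.

static void compute_sq_dist(const NumericMatrix &X, std::vector<double> &D) {
  const int n = X.nrow(), d = X.ncol();
  for (int i = 0; i < n; ++i) {
    D[(size_t)i * n + i] = 0.0;
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = X(i, k) - X(j, k);
        s += diff * diff;
      }
      D[(size_t)i * n + j] = s;
      D[(size_t)j * n + i] = s;
    }
  }
}

// Binary search for the Gaussian bandwidth of row i matching log(perplexity).
static void perplexity_row(const std::vector<double> &D, int n, int i,
                           double log_perp, std::vector<double> &P) {
  double beta = 1.0, beta_min = -1.0, beta_max = -1.0;
  const double tol = 1e-5;
  for (int iter = 0; iter < 50; ++iter) {
    double sum_p = 0.0, sum_dp = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) { P[j] = 0.0; continue; }
      double p = std::exp(-beta * D[(size_t)i * n + j]);
      P[j] = p;
      sum_p += p;
      sum_dp += D[(size_t)i * n + j] * p;
    }
    if (sum_p <= 0) sum_p = 1e-300;
    double H = std::log(sum_p) + beta * sum_dp / sum_p;
    double diff = H - log_perp;
    if (std::fabs(diff) < tol) break;
    if (diff > 0) {
      beta_min = beta;
      beta = (beta_max < 0) ? beta * 2.0 : (beta + beta_max) / 2.0;
    } else {
      beta_max = beta;
      beta = (beta_min < 0) ? beta / 2.0 : (beta + beta_min) / 2.0;
    }
  }
  double sum_p = 0.0;
  for (int j = 0; j < n; ++j) sum_p += P[j];
  if (sum_p <= 0) sum_p = 1e-300;
  for (int j = 0; j < n; ++j) P[j] /= sum_p;
}

// [[Rcpp::export]]
NumericMatrix cpp_tsne_exact(NumericMatrix X, NumericMatrix Y0,
                             double perplexity = 30.0, int max_iter = 500,
                             double eta = 200.0, double exaggeration = 12.0,
                             int exag_iter = 100) {
  const int n = X.nrow();
  const int m = Y0.ncol();
  if (Y0.nrow() != n) stop("Y0 must have one row per observation");
  if (perplexity >= (n - 1) / 3.0)
    stop("perplexity too large for the number of points");

  std::vector<double> D((size_t)n * n);
  compute_sq_dist(X, D);

  // symmetrized input affinities
  std::vector<double> P((size_t)n * n, 0.0);
  {
    std::vector<double> row(n);
    double log_perp = std::log(perplexity);
    for (int i = 0; i < n; ++i) {
      perplexity_row(D, n, i, log_perp, row);
      for (int j = 0; j < n; ++j) P[(size_t)i * n + j] = row[j];
    }
    double sum = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        double v = (P[(size_t)i * n + j] + P[(size_t)j * n + i]) / (2.0 * n);
        P[(size_t)i * n + j] = std::max(v, 1e-12);
      }
    for (size_t k = 0; k < P.size(); ++k) sum += P[k];
    (void)sum;
  }

  NumericMatrix Y = clone(Y0);
  std::vector<double> dY((size_t)n * m, 0.0), uY((size_t)n * m, 0.0),
      gains((size_t)n * m, 1.0), Q((size_t)n * n, 0.0);

  for (int iter = 0; iter < max_iter; ++iter) {
    double mult = (iter < exag_iter) ? exaggeration : 1.0;
    double momentum = (iter < 250) ? 0.5 : 0.8;

    // Student-t affinities in the map
    double sum_q = 0.0;
    for (int i = 0; i < n; ++i) {
      Q[(size_t)i * n + i] = 0.0;
      for (int j = i + 1; j < n; ++j) {
        double s = 0.0;
        for (int k = 0; k < m; ++k) {
          double diff = Y(i, k) - Y(j, k);
          s += diff * diff;
        }
        double q = 1.0 / (1.0 + s);
        Q[(size_t)i * n + j] = q;
        Q[(size_t)j * n + i] = q;
        sum_q += 2.0 * q;
      }
    }
    if (sum_q <= 0) sum_q = 1e-300;

    // gradient
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < m; ++k) dY[(size_t)i * m + k] = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double q = Q[(size_t)i * n + j];
        double coef = (mult * P[(size_t)i * n + j] - q / sum_q) * q;
        for (int k = 0; k < m; ++k)
          dY[(size_t)i * m + k] += 4.0 * coef * (Y(i, k) - Y(j, k));
      }
    }

    // update with adaptive gains and momentum
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < m; ++k) {
        size_t idx = (size_t)i * m + k;
        double g = gains[idx];
        g = ((dY[idx] > 0) != (uY[idx] > 0)) ? g + 0.2 : g * 0.8;
        if (g < 0.01) g = 0.01;
        gains[idx] = g;
        uY[idx] = momentum * uY[idx] - eta * g * dY[idx];
        Y(i, k) += uY[idx];
      }

    // recentre
    for (int k = 0; k < m; ++k) {
      double mean = 0.0;
      for (int i = 0; i < n; ++i) mean += Y(i, k);
      mean /= n;
      for (int i = 0; i < n; ++i) Y(i, k) -= mean;
    }
  }
  return Y;
}
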