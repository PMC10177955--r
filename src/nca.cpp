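#include <Rcpp.h>
using namespace Rcpp;

// Regularized NCA objective and analytic gradient for a continuous
// response.
//
//   d_w(i,j) = sum_r w_r^2 * delta_r(i,j),  delta_r = |dx| (L1) or dx^2 (L2)
//   p_ij     = exp(-d_ij/sigma) / sum_{k != i} exp(-d_ik/sigma),  p_ii = 0
//   f(w)     = (1/n) sum_i sum_{j != i} p_ij * l(y_i, y_j) + lambda sum_r w_r^2
//
// with l the absolute (default) or squared difference.  The softmax is
// computed with a per-row max shift so duplicate rows (d = 0) and large
// weights do not overflow.
//
// d f / d w_r = (2 w_r / (n sigma)) * sum_i [ f_i * S1_ir - S2_ir ]
//               + 2 lambda w_r
// where f_i = sum_j p_ij l_ij, S1_ir = sum_j p_ij delta_r(i,j),
// S2_ir = sum_j p_ij l_ij delta_r(i,j).
//
// [[Rcpp::export]]
List nca_objective_cpp(NumericVector w, NumericMatrix X, NumericVector y,
                       double lambda, double sigma, bool dist_l1,
                       bool loss_abs, bool want_grad) {
  const int n = X.nrow(), p = X.ncol();
  if (w.size() != p) stop("length(w) must equal ncol(X)");
  if (y.size() != n) stop("length(y) must equal nrow(X)");

  NumericMatrix D(n, n);
  for (int r = 0; r < p; ++r) {
    const double wr2 = w[r] * w[r];
    if (wr2 == 0.0) continue;
    for (int j = 0; j < n; ++j) {
      const double xjr = X(j, r);
      for (int i = 0; i < j; ++i) {
        const double dx = X(i, r) - xjr;
        D(i, j) += wr2 * (dist_l1 ? std::fabs(dx) : dx * dx);
      }
    }
  }
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < j; ++i) D(j, i) = D(i, j);

  NumericMatrix P(n, n);
  NumericVector fi(n);
  double value = 0.0;
  for (int i = 0; i < n; ++i) {
    double m = R_PosInf;
    for (int j = 0; j < n; ++j)
      if (j != i && D(i, j) < m) m = D(i, j);
    double Z = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double e = std::exp(-(D(i, j) - m) / sigma);
      P(i, j) = e;
      Z += e;
    }
    double f_i = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      P(i, j) /= Z;
      const double dy = y[i] - y[j];
      f_i += P(i, j) * (loss_abs ? std::fabs(dy) : dy * dy);
    }
    fi[i] = f_i;
    value += f_i;
  }
  value /= n;
  double pen = 0.0;
  for (int r = 0; r < p; ++r) pen += w[r] * w[r];
  value += lambda * pen;

  NumericVector grad(p);
  if (want_grad) {
    for (int r = 0; r < p; ++r) {
      double total = 0.0;
      for (int i = 0; i < n; ++i) {
        const double xir = X(i, r);
        double S1 = 0.0, S2 = 0.0;
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          const double dx = xir - X(j, r);
          const double del = dist_l1 ? std::fabs(dx) : dx * dx;
          const double pij = P(i, j);
          S1 += pij * del;
          const double dy = y[i] - y[j];
          S2 += pij * (loss_abs ? std::fabs(dy) : dy * dy) * del;
        }
        total += fi[i] * S1 - S2;
      }
      grad[r] = 2.0 * w[r] / (n * sigma) * total + 2.0 * lambda * w[r];
    }
  }

  return List::create(_["value"] = value, _["gradient"] = grad);
}

// Leave-one-out style kernel-regression prediction of new points from a
// trained weight vector: yhat_i = sum_j p_ij y_j over the training set.
// [[Rcpp::export]]
NumericVector nca_predict_cpp(NumericVector w, NumericMatrix Xtrain,
                              NumericVector ytrain, NumericMatrix Xnew,
                              double sigma, bool dist_l1) {
  const int ntr = Xtrain.nrow(), nnew = Xnew.nrow(), p = Xtrain.ncol();
  if (Xnew.ncol() != p) stop("feature dimension mismatch");
  NumericVector out(nnew);
  std::vector<double> d(ntr);
  for (int i = 0; i < nnew; ++i) {
    std::fill(d.begin(), d.end(), 0.0);
    for (int r = 0; r < p; ++r) {
      const double wr2 = w[r] * w[r];
      if (wr2 == 0.0) continue;
      const double xir = Xnew(i, r);
      for (int j = 0; j < ntr; ++j) {
        const double dx = xir - Xtrain(j, r);
        d[j] += wr2 * (dist_l1 ? std::fabs(dx) : dx * dx);
      }
    }
    double m = *std::min_element(d.begin(), d.end());
    double Z = 0.0, s = 0.0;
    for (int j = 0; j < ntr; ++j) {
      const double e = std::exp(-(d[j] - m) / sigma);
      Z += e;
      s += e * ytrain[j];
    }
    out[i] = s / Z;
  }
  return out;
}
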