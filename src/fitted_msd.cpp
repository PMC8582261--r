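// Kabsch-fitted per-atom MSD kernels. The 3x3 SVD route gives the fitted
// MSD from the singular values without forming the aligned coordinates:
//   msd = (|P|^2 + |Q|^2 - 2 (s1 + s2 + d s3)) / M,  d = sign(det(V U^T)),
// and the gradient of the fitted MSD w.r.t. the mobile coordinates is
//   (2/M) (Pc - Qc R)   with R = V diag(1,1,d) U^T  (row convention).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static void center_rows(mat& X) {
  rowvec c = mean(X, 0);
  X.each_row() -= c;
}

static double msd_pair(const mat& Pc, const mat& Qc, double p2, double q2,
                       bool want_R, mat& Rout) {
  const double m = (double)Pc.n_rows;
  mat H = Pc.t() * Qc; // 3 x 3
  mat U, V;
  vec s;
  if (!svd(U, s, V, H)) Rcpp::stop("SVD failure in fitted MSD");
  double d = det(V * U.t()) < 0 ? -1.0 : 1.0;
  double tr = s(0) + s(1) + d * s(2);
  if (want_R) {
    mat D = eye(3, 3);
    D(2, 2) = d;
    Rout = V * D * U.t();
  }
  double msd = (p2 + q2 - 2.0 * tr) / m;
  return msd > 0 ? msd : 0.0;
}

// Fitted per-atom MSD of one probe against a stack of reference frames
// (frames: M x 3 x N cube), optionally with gradients w.r.t. the probe.
// [[Rcpp::export]]
Rcpp::List fitted_msd_stack(const arma::mat& probe, const arma::cube& frames,
                            bool grad) {
  mat Pc = probe;
  center_rows(Pc);
  double p2 = accu(Pc % Pc);
  const uword n = frames.n_slices;
  vec d2(n);
  cube g;
  if (grad) g.set_size(probe.n_rows, 3, n);
  mat R;
  for (uword j = 0; j < n; ++j) {
    mat Qc = frames.slice(j);
    center_rows(Qc);
    double q2 = accu(Qc % Qc);
    d2(j) = msd_pair(Pc, Qc, p2, q2, grad, R);
    if (grad) g.slice(j) = (2.0 / probe.n_rows) * (Pc - Qc * R);
  }
  if (grad) {
    return Rcpp::List::create(Rcpp::Named("d2") = d2, Rcpp::Named("grad") = g);
  }
  return Rcpp::List::create(Rcpp::Named("d2") = d2);
}

// All-pairs fitted RMSD between two frame stacks (flattened rows: each row
// one frame, coordinates atom-major x1 y1 z1 x2 ...).
// [[Rcpp::export]]
arma::mat pairwise_fitted_rmsd(const arma::mat& a, const arma::mat& b,
                               int n_atoms, bool symmetric) {
  const uword fa = a.n_rows, fb = b.n_rows;
  auto unpack = [n_atoms](const mat& X, uword i) {
    mat M(n_atoms, 3);
    for (int k = 0; k < n_atoms; ++k) {
      M(k, 0) = X(i, 3 * k);
      M(k, 1) = X(i, 3 * k + 1);
      M(k, 2) = X(i, 3 * k + 2);
    }
    center_rows(M);
    return M;
  };
  std::vector<mat> A(fa), B;
  std::vector<double> a2(fa), b2;
  for (uword i = 0; i < fa; ++i) {
    A[i] = unpack(a, i);
    a2[i] = accu(A[i] % A[i]);
  }
  if (!symmetric) {
    B.resize(fb);
    b2.resize(fb);
    for (uword j = 0; j < fb; ++j) {
      B[j] = unpack(b, j);
      b2[j] = accu(B[j] % B[j]);
    }
  }
  mat out(fa, fb, fill::zeros);
  mat R;
  for (uword i = 0; i < fa; ++i) {
    uword j0 = symmetric ? i + 1 : 0;
    for (uword j = j0; j < fb; ++j) {
      const mat& Q = symmetric ? A[j] : B[j];
      double q2 = symmetric ? a2[j] : b2[j];
      double v = std::sqrt(msd_pair(A[i], Q, a2[i], q2, false, R));
      out(i, j) = v;
      if (symmetric) out(j, i) = v;
    }
  }
  return out;
}

// Fitted per-atom MSD between two M x 3 coordinate sets.
// [[Rcpp::export]]
double fitted_msd_pair(const arma::mat& a, const arma::mat& b) {
  mat Pc = a, Qc = b;
  center_rows(Pc);
  center_rows(Qc);
  mat R;
  return msd_pair(Pc, Qc, accu(Pc % Pc), accu(Qc % Qc), false, R);
}
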