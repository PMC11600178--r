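#include <Rcpp.h>
using namespace Rcpp;

// Exact one-step propagation of the linear GLE embedding:
//   X_{n+1} = F X_n + L eta,  eta ~ N(0, I)
// columns of X are independent replicas (axes x probes); rows are the state
// (position, velocity, one auxiliary Ornstein-Uhlenbeck force per Maxwell
// mode). F is the matrix exponential of the drift over one step and L the
// Cholesky factor of the exact one-step noise covariance, both computed in R.
// Uses R's RNG so runs are reproducible under set.seed().
// [[Rcpp::export]]
List gle_propagate_cpp(NumericMatrix F, NumericMatrix L, NumericMatrix X0,
                       int n_steps, int save_every, IntegerVector save_rows) {
  const int d = F.nrow(), nc = X0.ncol(), nr = save_rows.size();
  std::vector<double> X(d * nc), Y(d * nc), eta(d);
  for (int j = 0; j < nc; j++)
    for (int i = 0; i < d; i++) X[j * d + i] = X0(i, j);
  const int n_saved = n_steps / save_every;
  List out(nr);
  std::vector<NumericMatrix> mats;
  for (int r = 0; r < nr; r++) {
    NumericMatrix m(n_saved, nc);
    mats.push_back(m);
    out[r] = m;
  }
  int row = 0;
  for (int step = 1; step <= n_steps; step++) {
    for (int j = 0; j < nc; j++) {
      double *xj = &X[j * d], *yj = &Y[j * d];
      for (int i = 0; i < d; i++) eta[i] = norm_rand();
      for (int i = 0; i < d; i++) {
        double acc = 0.0;
        for (int k = 0; k < d; k++) acc += F(i, k) * xj[k] + L(i, k) * eta[k];
        yj[i] = acc;
      }
    }
    std::swap(X, Y);
    if (step % save_every == 0) {
      for (int r = 0; r < nr; r++) {
        const int sr = save_rows[r] - 1;
        for (int j = 0; j < nc; j++) mats[r](row, j) = X[j * d + sr];
      }
      row++;
    }
  }
  return out;
}
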