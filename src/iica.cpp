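// Gibbs sampler for the finite-truncation infinite-ICA model
//   Z = H (W * B) + E
// with per-(source, sample) Bernoulli mask B under a Beta(alpha/Q, 1)
// sparsity prior. The mask update integrates the sample's source weights
// out of the likelihood (column-collapsed update), which lets redundant
// source entries die even when the conditional weights would entrench
// them; W, pi, H and the noise variance follow by conjugate draws. All
// randomness comes from R's RNG so seeding on the R side is reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// log-odds contribution of activating source q for a column whose other
// active mixing columns are Hs: data z, noise variance se2, weight prior sw2
static double collapsedLogBF(const mat &Hs, const vec &hq, const vec &z,
                             double se2, double sw2) {
  double hh = dot(hq, hq), hz = dot(hq, z);
  double hMh, hMz;
  if (Hs.n_cols == 0) {
    hMh = hh / se2;
    hMz = hz / se2;
  } else {
    mat A = Hs.t() * Hs;
    A.diag() += se2 / sw2;
    vec a = Hs.t() * hq;
    vec b = Hs.t() * z;
    mat Ai = inv_sympd(A);
    hMh = (hh - dot(a, Ai * a)) / se2;
    hMz = (hz - dot(a, Ai * b)) / se2;
  }
  double t = sw2 * hMh;
  return -0.5 * std::log1p(t) + 0.5 * sw2 * hMz * hMz / (1.0 + t);
}

// [[Rcpp::export(name = ".iicaGibbs")]]
Rcpp::List iicaGibbs(const arma::mat &Zc, arma::mat H, arma::mat W,
                     arma::mat B, arma::vec piQ, double se2, int sweeps,
                     double alpha, double sw2, double sh2, bool updateMask) {
  const int N = Zc.n_rows, D = Zc.n_cols, Q = H.n_cols;
  // trace(0) is the pre-sweep residual error, then one entry per sweep
  vec trace(sweeps + 1, fill::zeros);
  mat A = W % B;
  {
    mat R0 = Zc - H * A;
    trace(0) = accu(R0 % R0) / (N * D);
  }

  for (int s = 0; s < sweeps; ++s) {
    if (updateMask) {
      for (int q = 0; q < Q; ++q) {
        const vec hq = H.col(q);
        double lp = std::log(piQ(q)) - std::log(1.0 - piQ(q));
        for (int i = 0; i < D; ++i) {
          // active rows in column i, excluding q
          uvec act = find(B.col(i) > 0.5);
          act = act.elem(find(act != (uword)q));
          mat Hs = H.cols(act);
          double lo = lp + collapsedLogBF(Hs, hq, Zc.col(i), se2, sw2);
          double p1 = 1.0 / (1.0 + std::exp(-std::max(-35.0,
                                            std::min(35.0, lo))));
          B(q, i) = (R::runif(0.0, 1.0) < p1) ? 1.0 : 0.0;
        }
        double mq = accu(B.row(q));
        piQ(q) = R::rbeta(alpha / Q + mq, 1.0 + D - mq);
        piQ(q) = std::min(std::max(piQ(q), 1e-12), 1.0 - 1e-12);
      }
    }
    // W | B, H, se2 : per-column conjugate Gaussian on the active set
    for (int i = 0; i < D; ++i) {
      uvec act = find(B.col(i) > 0.5);
      for (int q = 0; q < Q; ++q) W(q, i) = R::rnorm(0.0, std::sqrt(sw2));
      if (act.n_elem > 0) {
        mat Hs = H.cols(act);
        mat P = Hs.t() * Hs / se2;
        P.diag() += 1.0 / sw2;
        mat L = chol(P, "lower");
        vec mu = solve(trimatu(L.t()),
                       solve(trimatl(L), Hs.t() * Zc.col(i) / se2));
        vec eps(act.n_elem);
        for (uword j = 0; j < act.n_elem; ++j) eps(j) = R::rnorm(0.0, 1.0);
        vec ws = mu + solve(trimatu(L.t()), eps);
        for (uword j = 0; j < act.n_elem; ++j) W(act(j), i) = ws(j);
      }
    }
    A = W % B;
    // H | A, se2 : rows share the posterior precision A A' / se2 + I / sh2
    mat prec = A * A.t() / se2;
    prec.diag() += 1.0 / sh2;
    mat Lp = chol(prec, "lower");
    mat M = solve(trimatu(Lp.t()),
                  solve(trimatl(Lp), A * Zc.t() / se2));  // Q x N means
    mat eps(Q, N);
    for (int q = 0; q < Q; ++q)
      for (int n = 0; n < N; ++n) eps(q, n) = R::rnorm(0.0, 1.0);
    H = (M + solve(trimatu(Lp.t()), eps)).t();
    // noise variance | residual : conjugate inverse-gamma
    mat R0 = Zc - H * A;
    double rss = accu(R0 % R0);
    se2 = 1.0 / R::rgamma(1.0 + N * D / 2.0, 1.0 / (1.0 + rss / 2.0));
    if (se2 < 1e-12) se2 = 1e-12;
    trace(s + 1) = rss / (N * D);
  }
  return Rcpp::List::create(
      Rcpp::Named("H") = H, Rcpp::Named("W") = W, Rcpp::Named("B") = B,
      Rcpp::Named("piQ") = piQ, Rcpp::Named("se2") = se2,
      Rcpp::Named("trace") = trace);
}
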