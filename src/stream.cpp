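// Streaming online predictors (direct multi-step strategy).
//
// Both streams process regressors phi(j) = row j of Phi (1-based j), with
// prediction targets y(j + q - 1): the prediction made at decision time
// k = j - 1 (when y(j - 1) is the newest observation) aims q samples
// ahead. Model updates are delayed by q samples so that no target that is
// still in the future at prediction time has entered the model:
// at step j the pair (phi(j - q), y(j - 1)) is learned, then
// yhat(j + q - 1) = f(phi(j)) is emitted.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double kern1(int kind, const rowvec& a, const rowvec& b,
                           double sigma, double cc, int pp, double ss,
                           double tt) {
  switch (kind) {
    case 0: {
      rowvec d = a - b;
      return std::exp(-dot(d, d) / (2.0 * sigma * sigma));
    }
    case 1: return std::pow(dot(a, b) + cc, pp);
    default: return std::tanh(ss * dot(a, b) + tt);
  }
}

static inline void kernvec(int kind, const mat& dict, int m, const rowvec& phi,
                           double sigma, double cc, int pp, double ss,
                           double tt, vec& out) {
  for (int i = 0; i < m; ++i)
    out(i) = kern1(kind, dict.row(i), phi, sigma, cc, pp, ss, tt);
}

// [[Rcpp::export]]
Rcpp::List rls_stream_cpp(const arma::mat& Phi, const arma::vec& y, int q,
                          double lambda, double p0) {
  const int N = Phi.n_rows, d = Phi.n_cols;
  vec theta(d, fill::zeros);
  mat P(d, d, fill::eye);
  P *= p0;
  vec yhat(N);
  yhat.fill(datum::nan);
  for (int j = 1; j <= N; ++j) {
    if (j - q >= 1) {
      rowvec ph = Phi.row(j - q - 1);
      double target = y(j - 1 - 1);  // y(j - 1), 1-based
      vec Pphi = P * ph.t();
      double denom = lambda + as_scalar(ph * Pphi);
      vec g = Pphi / denom;
      double err = target - dot(ph, theta);
      theta += g * err;
      P = (P - g * Pphi.t()) / lambda;
      P = 0.5 * (P + P.t());
    }
    if (j + q - 1 <= N)
      yhat(j + q - 1 - 1) = dot(Phi.row(j - 1), theta);
  }
  return Rcpp::List::create(Rcpp::Named("yhat") = yhat,
                            Rcpp::Named("theta") = theta);
}

// [[Rcpp::export]]
Rcpp::List krls_stream_cpp(const arma::mat& Phi, const arma::vec& y, int q,
                           int kind, double sigma, double cc, int pp,
                           double ss, double tt, double R, double lambda,
                           bool ald, double nu, int cap) {
  const int N = Phi.n_rows, d = Phi.n_cols;
  mat dict(cap, d, fill::zeros);
  mat Q(cap, cap, fill::zeros);
  mat P(cap, cap, fill::zeros);
  vec a(cap, fill::zeros);
  int m = 0;
  const double ridge = R * lambda;
  vec yhat(N);
  yhat.fill(datum::nan);
  vec K(cap), z(cap);

  for (int j = 1; j <= N; ++j) {
    if (j - q >= 1) {
      rowvec ph = Phi.row(j - q - 1);
      double target = y(j - 1 - 1);  // y(j - 1), 1-based
      double kself = kern1(kind, ph, ph, sigma, cc, pp, ss, tt);
      if (m == 0) {
        double k0 = ridge + kself;
        if (k0 <= 0.0)
          Rcpp::stop("R*lambda + kappa(phi, phi) must be positive");
        dict.row(0) = ph;
        Q(0, 0) = 1.0 / k0;
        P(0, 0) = 1.0;
        a(0) = target / k0;
        m = 1;
      } else {
        kernvec(kind, dict, m, ph, sigma, cc, pp, ss, tt, K);
        vec Km = K.head(m);
        vec zm = Q.submat(0, 0, m - 1, m - 1) * Km;
        double delta = ridge + kself - dot(zm, Km);
        double e = target - dot(Km, a.head(m));
        bool grow = (!ald || delta > nu) && m < cap;
        if (grow) {
          if (delta <= 0.0)
            Rcpp::stop("numerical degeneracy in KRLS growth: delta = %g <= 0"
                       " (dictionary size %d)", delta, m);
          Q.submat(0, 0, m - 1, m - 1) += zm * zm.t() / delta;
          for (int i = 0; i < m; ++i) {
            Q(i, m) = -zm(i) / delta;
            Q(m, i) = -zm(i) / delta;
          }
          Q(m, m) = 1.0 / delta;
          a.head(m) -= zm * (e / delta);
          a(m) = e / delta;
          P(m, m) = 1.0;  // off-diagonal block stays zero
          dict.row(m) = ph;
          ++m;
        } else {
          vec Pz = P.submat(0, 0, m - 1, m - 1) * zm;
          vec qv = Pz / (1.0 + dot(zm, Pz));
          P.submat(0, 0, m - 1, m - 1) -= qv * Pz.t();
          a.head(m) += (Q.submat(0, 0, m - 1, m - 1) * qv) * e;
        }
      }
    }
    if (j + q - 1 <= N && m > 0) {
      rowvec ph = Phi.row(j - 1);
      kernvec(kind, dict, m, ph, sigma, cc, pp, ss, tt, K);
      yhat(j + q - 1 - 1) = dot(K.head(m), a.head(m));
    } else if (j + q - 1 <= N) {
      yhat(j + q - 1 - 1) = 0.0;
    }
  }
  return Rcpp::List::create(Rcpp::Named("yhat") = yhat,
                            Rcpp::Named("dict_size") = m);
}
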