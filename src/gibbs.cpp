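// Two-kernel Bayesian mixed model: y = 1*mu + g + b + e with
// g ~ N(0, G sg2), b ~ N(0, B sb2), e ~ N(0, I se2).
// Gibbs sampling in the eigenbases of G and B: with G = Ug Dg Ug', the
// full conditional of alpha = Ug' g is diagonal-normal, which keeps every
// update O(n^2) (two matrix-vector products per kernel per iteration).
// Variance components get scaled-inverse-chi-square (inverse-gamma) full
// conditionals. Uses R's RNG so set.seed() in R controls the chain.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export(name = ".gibbsTwoKernelCpp")]]
NumericMatrix gibbsTwoKernelCpp(const arma::vec& y,
                                const arma::mat& Ug, const arma::vec& dg,
                                const arma::mat& Ub, const arma::vec& db,
                                int nIter, int burnIn, int thin,
                                double df0, double Sg0, double Sb0,
                                double Se0) {
  const int n = y.n_elem;
  const arma::uvec ig = arma::find(dg > 1e-10 * dg.max());
  const arma::uvec ib = arma::find(db > 1e-10 * db.max());
  const arma::mat Ugp = Ug.cols(ig);   // kept eigenvectors
  const arma::vec dgp = dg.elem(ig);
  const arma::mat Ubp = Ub.cols(ib);
  const arma::vec dbp = db.elem(ib);
  const int qg = ig.n_elem, qb = ib.n_elem;

  double vy = arma::var(y);
  double mu = arma::mean(y);
  double sg2 = vy / 3.0, sb2 = vy / 3.0, se2 = vy / 3.0;
  arma::vec g(n, arma::fill::zeros), b(n, arma::fill::zeros);
  arma::vec alphag(qg, arma::fill::zeros), alphab(qb, arma::fill::zeros);

  const int nKeep = (nIter - burnIn + thin - 1) / thin;
  NumericMatrix out(nKeep, 4);
  colnames(out) = CharacterVector::create("mu", "sigma_g2", "sigma_b2",
                                          "sigma_e2");
  RNGScope scope;
  int row = 0;
  for (int it = 1; it <= nIter; ++it) {
    // mu | rest (flat prior)
    double rmean = arma::mean(y - g - b);
    mu = R::rnorm(rmean, std::sqrt(se2 / n));

    // alpha_g | rest: y* = Ug'(y - mu - b); var_i = 1/(1/se2 + 1/(d_i sg2))
    arma::vec rg = Ugp.t() * (y - mu - b);
    for (int i = 0; i < qg; ++i) {
      double v = 1.0 / (1.0 / se2 + 1.0 / (dgp(i) * sg2));
      alphag(i) = R::rnorm(v * rg(i) / se2, std::sqrt(v));
    }
    g = Ugp * alphag;

    // alpha_b | rest
    arma::vec rb = Ubp.t() * (y - mu - g);
    for (int i = 0; i < qb; ++i) {
      double v = 1.0 / (1.0 / se2 + 1.0 / (dbp(i) * sb2));
      alphab(i) = R::rnorm(v * rb(i) / se2, std::sqrt(v));
    }
    b = Ubp * alphab;

    // variance components: inverse-gamma full conditionals
    double ssg = arma::accu(arma::square(alphag) / dgp);
    sg2 = (ssg + df0 * Sg0) / R::rchisq(df0 + qg);
    double ssb = arma::accu(arma::square(alphab) / dbp);
    sb2 = (ssb + df0 * Sb0) / R::rchisq(df0 + qb);
    arma::vec e = y - mu - g - b;
    double sse = arma::dot(e, e);
    se2 = (sse + df0 * Se0) / R::rchisq(df0 + n);

    if (it > burnIn && ((it - burnIn - 1) % thin == 0)) {
      out(row, 0) = mu;
      out(row, 1) = sg2;
      out(row, 2) = sb2;
      out(row, 3) = se2;
      ++row;
    }
  }
  return out;
}
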