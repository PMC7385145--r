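#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for BayesB whole-genome regression:
//   y = mu + X beta + e
// with a spike-slab prior on each marker effect
//   beta_j ~ pi N(0, s2b_j) + (1 - pi) delta_0,
// marker variances s2b_j ~ scaled-inv-chi2(dfBeta, Sbeta), scale
// Sbeta ~ Gamma(rGamma, sGamma), pi ~ Beta(piCounts*piPrior,
// piCounts*(1-piPrior)), and residual variance
// sigma2e ~ scaled-inv-chi2(dfE, Se). Uses R's RNG, so results are
// reproducible under set.seed(). commonVariance = one shared slab
// variance (Bayesian ridge degeneracy used for validation).
// [[Rcpp::export(name = ".bayesbGibbs")]]
List bayesbGibbs(NumericVector y, NumericMatrix X,
                 int nIter, int burnIn, int thin,
                 double dfBeta, double Sbeta0,
                 double rGamma, double sGamma, bool updateScale,
                 double piInit, double piCounts, double piPrior,
                 bool updatePi, bool commonVariance,
                 double dfE, double Se) {
  const int n = y.size(), p = X.ncol();
  NumericVector beta(p, 0.0), s2b(p, Sbeta0);
  NumericVector xx(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xx[j] = s;
  }
  double mu = mean(y);
  NumericVector e = clone(y);
  for (int i = 0; i < n; ++i) e[i] -= mu;
  double sigma2e = std::max(1e-10, var(y) * 0.5);
  double Sbeta = Sbeta0, pi = piInit;

  NumericVector betaMean(p, 0.0), inclProb(p, 0.0);
  double muMean = 0.0, s2eMean = 0.0, piMean = 0.0, s2bMean = 0.0;
  int nSaved = 0;

  for (int it = 0; it < nIter; ++it) {
    int nIn = 0;
    double sumBeta2 = 0.0;
    for (int j = 0; j < p; ++j) {
      if (xx[j] <= 0.0) { beta[j] = 0.0; continue; }
      double old = beta[j];
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * e[i];
      rhs += xx[j] * old;
      rhs /= sigma2e;
      double C = xx[j] / sigma2e + 1.0 / s2b[j];
      double logOdds = std::log(pi) - std::log1p(-pi) +
        0.5 * rhs * rhs / C - 0.5 * std::log(s2b[j] * C);
      double probIn = (pi >= 1.0) ? 1.0 : 1.0 / (1.0 + std::exp(-logOdds));
      double bNew = 0.0;
      if (unif_rand() < probIn) {
        bNew = R::rnorm(rhs / C, std::sqrt(1.0 / C));
        ++nIn;
        sumBeta2 += bNew * bNew;
      }
      if (bNew != old) {
        double d = bNew - old;
        for (int i = 0; i < n; ++i) e[i] -= X(i, j) * d;
      }
      beta[j] = bNew;
    }
    if (commonVariance) {
      double s2 = (dfBeta * Sbeta + sumBeta2) / R::rchisq(dfBeta + nIn);
      for (int j = 0; j < p; ++j) s2b[j] = s2;
    } else {
      for (int j = 0; j < p; ++j) {
        if (beta[j] != 0.0)
          s2b[j] = (dfBeta * Sbeta + beta[j] * beta[j]) /
            R::rchisq(dfBeta + 1.0);
        else
          s2b[j] = dfBeta * Sbeta / R::rchisq(dfBeta);
      }
    }
    if (updateScale) {
      double sumInv = 0.0;
      for (int j = 0; j < p; ++j) sumInv += 1.0 / s2b[j];
      double shape = rGamma + 0.5 * p * dfBeta;
      double rate = sGamma + 0.5 * dfBeta * sumInv;
      Sbeta = R::rgamma(shape, 1.0 / rate);
    }
    if (updatePi) {
      pi = R::rbeta(piCounts * piPrior + nIn,
                    piCounts * (1.0 - piPrior) + p - nIn);
      pi = std::min(std::max(pi, 1e-9), 1.0 - 1e-9);
    }
    // intercept
    double eBar = mean(e);
    double muNew = R::rnorm(mu + eBar, std::sqrt(sigma2e / n));
    for (int i = 0; i < n; ++i) e[i] -= (muNew - mu);
    mu = muNew;
    // residual variance
    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    sigma2e = (sse + dfE * Se) / R::rchisq((double)n + dfE);
    if (!R_finite(sigma2e) || !R_finite(mu))
      stop("chain divergence (non-finite state) at iteration %d", it + 1);

    if (it >= burnIn && ((it - burnIn) % thin == 0)) {
      ++nSaved;
      for (int j = 0; j < p; ++j) {
        betaMean[j] += beta[j];
        if (beta[j] != 0.0) inclProb[j] += 1.0;
      }
      muMean += mu;
      s2eMean += sigma2e;
      piMean += pi;
      s2bMean += s2b[0];
    }
  }
  if (nSaved == 0) stop("no post-burn-in samples saved");
  for (int j = 0; j < p; ++j) {
    betaMean[j] /= nSaved;
    inclProb[j] /= nSaved;
  }
  return List::create(_["beta"] = betaMean, _["inclProb"] = inclProb,
                      _["mu"] = muMean / nSaved,
                      _["sigma2e"] = s2eMean / nSaved,
                      _["pi"] = piMean / nSaved,
                      _["sigma2b"] = s2bMean / nSaved,
                      _["nSamples"] = nSaved);
}
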