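// Time-series fitting cores: piecewise-linear temporal segmentation
// (LandTrendr-style) and harmonic LASSO change detection (CCDC-style).
// Per-pixel throughput is the reason these live in C++.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// piecewise-linear least squares with fixed knots (continuous fit)
// ---------------------------------------------------------------------------

static arma::mat pwl_design(const arma::vec& x, const arma::uvec& vidx) {
  // basis: intercept, x, hinge at each interior vertex
  const arma::uword n = x.n_elem, nv = vidx.n_elem;
  const double x0 = arma::mean(x); // centre to keep XtX well conditioned
  arma::mat X(n, nv, arma::fill::ones); // nv cols: 1, x, nv-2 hinges
  X.col(1) = x - x0;
  for (arma::uword j = 1; j + 1 < nv; ++j) {
    double k = x(vidx(j));
    for (arma::uword i = 0; i < n; ++i)
      X(i, j + 1) = std::max(0.0, x(i) - k);
  }
  return X;
}

static bool pwl_fit(const arma::vec& x, const arma::vec& y,
                    const arma::uvec& vidx, arma::vec& fitted, double& sse) {
  arma::mat X = pwl_design(x, vidx);
  arma::vec beta;
  if (!arma::solve(beta, X, y)) beta = arma::pinv(X) * y;
  fitted = X * beta;
  arma::vec r = y - fitted;
  sse = arma::dot(r, r);
  return true;
}

static double pwl_sse(const arma::vec& x, const arma::vec& y,
                      const arma::uvec& vidx) {
  arma::vec f; double sse;
  pwl_fit(x, y, vidx, f, sse);
  return sse;
}

static arma::uvec drop_elem(const arma::uvec& v, arma::uword pos) {
  arma::uvec out(v.n_elem - 1);
  arma::uword k = 0;
  for (arma::uword i = 0; i < v.n_elem; ++i) if (i != pos) out(k++) = v(i);
  return out;
}

// [[Rcpp::export(name = ".lt_despike_cpp")]]
NumericVector lt_despike_cpp(NumericVector y, double spikeThreshold) {
  // A spike is a strict one-year local extremum whose neighbours agree
  // with each other: the correction proportion 1 - |y[i+1] - y[i-1]| /
  // max(|jump up|, |jump down|) exceeds the threshold. Spikes are
  // replaced by the neighbour midpoint; at threshold 1.0 nothing is
  // damped. Trend corners (non-extremum vertices) are never touched.
  int n = y.size();
  NumericVector out = clone(y);
  if (n < 3 || spikeThreshold >= 1.0) return out;
  for (int i = 1; i < n - 1; ++i) {
    double d1 = y[i] - y[i - 1], d2 = y[i] - y[i + 1];
    if (d1 * d2 <= 0) continue; // not a strict local extremum
    double h = std::max(std::fabs(d1), std::fabs(d2));
    if (h <= 0) continue;
    double prop = 1.0 - std::fabs(y[i + 1] - y[i - 1]) / h;
    if (prop > spikeThreshold)
      out[i] = 0.5 * (y[i - 1] + y[i + 1]);
  }
  return out;
}

// recovery-rate rule: a segment moving in the recovery direction faster than
// recoveryThreshold of the series range per year is disallowed
static bool segments_allowed(const arma::vec& x, const arma::vec& fit,
                             const arma::uvec& vidx, double recoveryThreshold,
                             bool preventOneYearRecovery, int recoverySign,
                             double rng) {
  if (recoverySign == 0 || rng <= 0) return true;
  for (arma::uword s = 0; s + 1 < vidx.n_elem; ++s) {
    double dv = fit(vidx(s + 1)) - fit(vidx(s));
    double dur = x(vidx(s + 1)) - x(vidx(s));
    if (dur <= 0) continue;
    bool recovering = (dv * recoverySign) > 0;
    if (!recovering) continue;
    double rate = (std::fabs(dv) / rng) / dur;
    if (rate > recoveryThreshold + 1e-12) return false;
    if (preventOneYearRecovery && dur <= 1.0 + 1e-9) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".lt_fit_cpp")]]
List lt_fit_cpp(NumericVector years, NumericVector vals, int maxSegments,
                double spikeThreshold, int vertexCountOvershoot,
                bool preventOneYearRecovery, double recoveryThreshold,
                double pvalThreshold, double bestModelProportion,
                int recoverySign) {
  const int n = vals.size();
  arma::vec x(years.begin(), n), y0(vals.begin(), n);
  NumericVector yd = lt_despike_cpp(vals, spikeThreshold);
  arma::vec y(yd.begin(), n);
  double rng = y.max() - y.min();
  double tol0 = std::max(1e-12, 1e-9 * std::max(rng, 1.0));

  // --- vertex oversearch: insert max-|residual| points ---
  arma::uvec vidx = {0, (arma::uword)(n - 1)};
  arma::uword vmax = std::min<arma::uword>(n, maxSegments + 1 + vertexCountOvershoot);
  while (vidx.n_elem < vmax) {
    arma::vec f; double sse;
    pwl_fit(x, y, vidx, f, sse);
    arma::vec r = arma::abs(y - f);
    // exclude existing vertices
    for (arma::uword i = 0; i < vidx.n_elem; ++i) r(vidx(i)) = -1.0;
    arma::uword best = r.index_max();
    if (r(best) < tol0) break; // exact fit: stop adding vertices
    vidx = arma::sort(arma::join_cols(vidx, arma::uvec({best})));
  }

  // --- prune down to maxSegments + 1 vertices ---
  while ((int)vidx.n_elem > maxSegments + 1) {
    double bestSse = arma::datum::inf; arma::uword bestPos = 1;
    for (arma::uword j = 1; j + 1 < vidx.n_elem; ++j) {
      double s = pwl_sse(x, y, drop_elem(vidx, j));
      if (s < bestSse) { bestSse = s; bestPos = j; }
    }
    vidx = drop_elem(vidx, bestPos);
  }

  // --- nested candidate models by weakest-vertex removal ---
  std::vector<arma::uvec> cands;
  arma::uvec cur = vidx;
  cands.push_back(cur);
  while (cur.n_elem > 2) {
    double bestSse = arma::datum::inf; arma::uword bestPos = 1;
    for (arma::uword j = 1; j + 1 < cur.n_elem; ++j) {
      double s = pwl_sse(x, y, drop_elem(cur, j));
      if (s < bestSse) { bestSse = s; bestPos = j; }
    }
    cur = drop_elem(cur, bestPos);
    cands.push_back(cur);
  }

  // --- evaluate candidates ---
  const double ybar = arma::mean(y);
  const double sst = arma::accu(arma::square(y - ybar));
  int nc = cands.size();
  std::vector<arma::vec> fits(nc);
  std::vector<double> pvals(nc, 1.0);
  std::vector<bool> allowed(nc, false);
  for (int c = 0; c < nc; ++c) {
    arma::vec f; double sse;
    pwl_fit(x, y, cands[c], f, sse);
    fits[c] = f;
    int npar = cands[c].n_elem; // intercept + slope + hinges = #vertices
    int df2 = n - npar;
    double p;
    if (sse <= tol0 * tol0) p = 0.0;
    else if (df2 <= 0 || sst <= sse) p = 1.0;
    else {
      double Fstat = ((sst - sse) / std::max(1, npar - 1)) / (sse / df2);
      p = R::pf(Fstat, std::max(1, npar - 1), df2, 0, 0);
    }
    pvals[c] = p;
    allowed[c] = segments_allowed(x, f, cands[c], recoveryThreshold,
                                  preventOneYearRecovery, recoverySign, rng);
  }

  // --- selection: p-value screen then bestModelProportion ---
  int chosen = -1;
  double pmin = 2.0;
  for (int c = 0; c < nc; ++c)
    if (allowed[c] && pvals[c] < pmin) pmin = pvals[c];
  if (pmin <= 1.5) { // at least one admissible model
    double cutoff = (bestModelProportion > 0) ? pmin / bestModelProportion : pmin;
    if (pmin > pvalThreshold) cutoff = pmin; // all fail screen: take min-p
    arma::uword mostV = 0;
    for (int c = 0; c < nc; ++c) {
      if (!allowed[c] || pvals[c] > cutoff + 1e-15) continue;
      if (cands[c].n_elem > mostV) { mostV = cands[c].n_elem; chosen = c; }
    }
  }
  bool fallback = false;
  arma::vec fitted;
  arma::uvec vout;
  if (chosen < 0) { // nothing admissible: flat mean model
    fallback = true;
    fitted = arma::vec(n); fitted.fill(ybar);
    vout = {0, (arma::uword)(n - 1)};
  } else {
    fitted = fits[chosen];
    vout = cands[chosen];
  }

  return List::create(
    _["vertex_idx"] = IntegerVector(vout.begin(), vout.end()),
    _["fitted"] = NumericVector(fitted.begin(), fitted.end()),
    _["despiked"] = yd,
    _["p_value"] = (chosen >= 0) ? pvals[chosen] : NA_REAL,
    _["fallback"] = fallback);
}

// ---------------------------------------------------------------------------
// harmonic LASSO (coordinate descent, unpenalized intercept)
// ---------------------------------------------------------------------------

// Solves min (1/2n)||y - Xb||^2 + lambda * sum_{j>0} |b_j| on the
// standardized problem; X must contain an intercept column first.
static arma::vec lasso_cd(const arma::mat& X, const arma::vec& y,
                          double lambda, int maxIter, double tol = 1e-8) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  if (lambda <= 0.0) { // OLS
    arma::vec beta;
    if (!arma::solve(beta, X, y)) beta = arma::pinv(X) * y;
    return beta;
  }
  // standardize non-intercept columns
  arma::vec mu(p, arma::fill::zeros), sd(p, arma::fill::ones);
  arma::mat Z = X;
  for (arma::uword j = 1; j < p; ++j) {
    mu(j) = arma::mean(X.col(j));
    double s = arma::stddev(X.col(j), 1);
    sd(j) = (s > 1e-12) ? s : 1.0;
    Z.col(j) = (X.col(j) - mu(j)) / sd(j);
  }
  double ybar = arma::mean(y);
  arma::vec yc = y - ybar;
  arma::vec b(p, arma::fill::zeros); // b(0) handled at the end
  arma::vec r = yc;
  for (int it = 0; it < maxIter; ++it) {
    double maxDelta = 0.0;
    for (arma::uword j = 1; j < p; ++j) {
      double zj = arma::dot(Z.col(j), r) / n + b(j); // col var = 1
      double bj = 0.0;
      if (zj > lambda) bj = zj - lambda;
      else if (zj < -lambda) bj = zj + lambda;
      double d = bj - b(j);
      if (d != 0.0) { r -= d * Z.col(j); b(j) = bj; }
      maxDelta = std::max(maxDelta, std::fabs(d));
    }
    if (maxDelta < tol) break;
  }
  // back-transform to original scale
  arma::vec beta(p, arma::fill::zeros);
  double icpt = ybar;
  for (arma::uword j = 1; j < p; ++j) {
    beta(j) = b(j) / sd(j);
    icpt -= beta(j) * mu(j);
  }
  beta(0) = icpt;
  return beta;
}

// [[Rcpp::export(name = ".lasso_cd_cpp")]]
NumericVector lasso_cd_cpp(NumericMatrix X, NumericVector y, double lambda,
                           int maxIter) {
  arma::mat Xm(X.begin(), X.nrow(), X.ncol(), false);
  arma::vec yv(y.begin(), y.size(), false);
  arma::vec b = lasso_cd(Xm, yv, lambda, maxIter);
  return NumericVector(b.begin(), b.end());
}

// harmonic design at fractional-year times: 1, t, cos/sin of 1,2,3 cycles/yr
static arma::mat harmonic_design(const arma::vec& t) {
  arma::mat X(t.n_elem, 8);
  X.col(0).ones();
  X.col(1) = t;
  for (int h = 1; h <= 3; ++h) {
    X.col(2 * h)     = arma::cos(2.0 * M_PI * h * t);
    X.col(2 * h + 1) = arma::sin(2.0 * M_PI * h * t);
  }
  return X;
}

// [[Rcpp::export(name = ".harmonic_design_cpp")]]
NumericMatrix harmonic_design_cpp(NumericVector t) {
  arma::vec tv(t.begin(), t.size(), false);
  arma::mat X = harmonic_design(tv);
  return wrap(X);
}

// [[Rcpp::export(name = ".harmonic_fit_cpp")]]
List harmonic_fit_cpp(NumericVector t, NumericVector y, double lambda,
                      int maxIter) {
  arma::vec tv(t.begin(), t.size()), yv(y.begin(), y.size());
  arma::mat X = harmonic_design(tv);
  arma::vec b = lasso_cd(X, yv, lambda, maxIter);
  arma::vec r = yv - X * b;
  double rmse = std::sqrt(arma::dot(r, r) / r.n_elem);
  return List::create(_["coef"] = NumericVector(b.begin(), b.end()),
                      _["rmse"] = rmse);
}

// ---------------------------------------------------------------------------
// CCDC-style sequential break detection across breakpoint bands
// ---------------------------------------------------------------------------

// t: sorted fractional-year times; Y: n x B observation matrix;
// bpCols: 0-based columns used for break scoring. Returns segment index
// ranges, break times, and per-band coefficients + RMSE per segment.
// [[Rcpp::export(name = ".ccdc_fit_cpp")]]
List ccdc_fit_cpp(NumericVector t, NumericMatrix Y, IntegerVector bpCols,
                  double lambda, int minObservations, double chi2Threshold,
                  double minNumOfYearsScaler, int maxIterations) {
  const int n = t.size(), B = Y.ncol();
  arma::vec tv(t.begin(), n);
  arma::mat Ym(Y.begin(), n, B);
  arma::mat D = harmonic_design(tv);
  const double rmseFloor = 1e-4; // reflectance units; guards noise-free input
  const int minFitObs = 12;

  std::vector<int> segStart, segEnd;           // 0-based inclusive
  std::vector<double> breakTimes;              // NA -> NaN
  std::vector<arma::mat> segCoefs;             // 8 x B per segment
  std::vector<arma::vec> segRmse;              // B per segment

  int i = 0;
  bool firstSegment = true;
  while (i < n) {
    double minSpan = firstSegment ? 1.0 : minNumOfYearsScaler * 1.0;
    // initialization window
    int e = i + minFitObs - 1;
    while (e < n && (tv(e) - tv(i)) < minSpan) ++e;
    if (e >= n) break; // tail too short for a model
    // fit all bands on [i, e]
    arma::mat coefs(8, B);
    arma::vec rmse(B);
    int nLastFit = e - i + 1;
    auto refit = [&](int from, int to) {
      int nw = to - from + 1;
      double span = tv(to) - tv(from);
      // adaptive model order: short windows cannot support all three
      // harmonics without overfitting, and a trend term estimated on a
      // short span extrapolates wildly during monitoring
      int ncoef = (nw >= 24) ? 8 : (nw >= 18) ? 6 : 4;
      bool useSlope = span >= 3.0;
      arma::uvec cols(ncoef - (useSlope ? 0 : 1));
      arma::uword ci = 0;
      for (int c = 0; c < ncoef; ++c) {
        if (c == 1 && !useSlope) continue;
        cols(ci++) = c;
      }
      arma::mat Xw = D.submat(arma::regspace<arma::uvec>(from, to), cols);
      for (int b = 0; b < B; ++b) {
        arma::vec yw = Ym.col(b).subvec(from, to);
        arma::vec beta = lasso_cd(Xw, yw, lambda, maxIterations);
        coefs.col(b).zeros();
        for (arma::uword k = 0; k < cols.n_elem; ++k)
          coefs(cols(k), b) = beta(k);
        arma::vec r = yw - Xw * beta;
        // df-corrected: raw residual SD from a fit on few observations is
        // biased low and would trigger false breaks
        double df = std::max(1.0, (double)nw - (double)cols.n_elem);
        rmse(b) = std::max(rmseFloor, std::sqrt(arma::dot(r, r) / df));
      }
      nLastFit = nw;
    };
    refit(i, e);

    int j = e + 1, runStart = -1, runLen = 0, segClose = -1;
    double tBreak = NA_REAL;
    while (j < n) {
      double score = 0.0;
      for (int k = 0; k < bpCols.size(); ++k) {
        int b = bpCols[k];
        double pred = arma::dot(D.row(j), coefs.col(b));
        double z = (Ym(j, b) - pred) / rmse(b);
        score += z * z;
      }
      if (score > chi2Threshold) {
        if (runLen == 0) runStart = j;
        ++runLen;
        if (runLen >= minObservations) { // confirmed break
          segClose = runStart - 1;
          tBreak = tv(runStart);
          break;
        }
      } else {
        runLen = 0; runStart = -1;
        e = j; // absorb stable observation
        if (e - i + 1 >= (int)std::ceil(1.2 * nLastFit)) refit(i, e);
      }
      ++j;
    }
    if (segClose < 0) segClose = n - 1; // ran off the end: final segment
    refit(i, segClose);
    segStart.push_back(i);
    segEnd.push_back(segClose);
    breakTimes.push_back(tBreak);
    segCoefs.push_back(coefs);
    segRmse.push_back(rmse);
    if (std::isnan(tBreak)) { i = n; }
    else { i = (int)(std::find(tv.begin(), tv.end(), tBreak) - tv.begin());
           firstSegment = false; }
  }

  int S = segStart.size();
  List coefList(S), rmseList(S);
  NumericVector tStart(S), tEnd(S), tBr(S);
  IntegerVector iStart(S), iEnd(S);
  for (int s = 0; s < S; ++s) {
    iStart[s] = segStart[s] + 1; // 1-based for R
    iEnd[s] = segEnd[s] + 1;
    tStart[s] = tv(segStart[s]);
    tEnd[s] = tv(segEnd[s]);
    tBr[s] = breakTimes[s];
    coefList[s] = wrap(segCoefs[s]);
    rmseList[s] = NumericVector(segRmse[s].begin(), segRmse[s].end());
  }
  return List::create(_["i_start"] = iStart, _["i_end"] = iEnd,
                      _["t_start"] = tStart, _["t_end"] = tEnd,
                      _["t_break"] = tBr, _["coefs"] = coefList,
                      _["rmse"] = rmseList);
}
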