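#include <Rcpp.h>
using namespace Rcpp;

// EM for the saturated nominal diagnosis model.
//
// X      : N x J integer responses, 1-based option codes
// hmap   : per item, integer vector of length L mapping full-pattern index
//          to reduced-pattern index (1-based)
// P0     : per item, H_j x C_j initial conditional-probability block
// prior0 : length-L initial structural distribution
// variant: 0 = standard EM (shared prior, mean-posterior structural update),
//          1 = respondent-specific carried posteriors (each respondent's
//              previous posterior acts as their prior at the next iteration)
//
// Likelihoods are accumulated multiplicatively: probabilities are clipped
// at `clip`, so a respondent's conditional likelihood is bounded below by
// clip^J, far above the double underflow threshold for realistic J.
// Reduced-pattern rows with expected count below `starve_tol` keep their
// previous values and are flagged.  Convergence requires
// max |delta P| < tol AND relative log-likelihood change < ll_tol.
// [[Rcpp::export]]
List em_gndm_cpp(const IntegerMatrix X, const List hmap, const List P0,
                 const NumericVector prior0, const double tol,
                 const double ll_tol, const int max_iter, const int variant,
                 const double clip, const double starve_tol) {
  const int N = X.nrow(), J = X.ncol();
  const int L = prior0.size();

  std::vector<NumericMatrix> P(J), Rcnt(J);
  std::vector<IntegerVector> hm(J);
  std::vector<LogicalVector> starved(J);
  int maxC = 0;
  for (int j = 0; j < J; ++j) {
    NumericMatrix pj = clone(as<NumericMatrix>(P0[j]));
    P[j] = pj;
    Rcnt[j] = NumericMatrix(pj.nrow(), pj.ncol());
    hm[j] = hmap[j];
    starved[j] = LogicalVector(pj.nrow());
    if (pj.ncol() > maxC) maxC = pj.ncol();
  }
  NumericVector prior = clone(prior0);
  NumericMatrix priorMat;  // carried-posterior variant only
  if (variant == 1) {
    priorMat = NumericMatrix(N, L);
    for (int l = 0; l < L; ++l)
      for (int i = 0; i < N; ++i) priorMat(i, l) = prior0[l];
  }

  NumericMatrix post(N, L);
  double *w = REAL(post);              // reused as work matrix
  std::vector<double> rowsum(N), acol(maxC);
  std::vector<double> trace;
  double ll_prev = R_NegInf;
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    // W(i, l) = p(alpha_l) * prod_j P_{x_ij}(eta_{j, h(l)})
    if (variant == 0) {
      for (int l = 0; l < L; ++l) {
        double *wl = w + (size_t)N * l;
        const double pl = std::max(prior[l], clip);
        for (int i = 0; i < N; ++i) wl[i] = pl;
      }
    } else {
      const double *pm = REAL(priorMat);
      for (size_t t = 0; t < (size_t)N * L; ++t)
        w[t] = std::max(pm[t], clip);
    }
    for (int j = 0; j < J; ++j) {
      const int *xj = &X(0, j);
      const int *hj = INTEGER(hm[j]);
      const double *pj = REAL(P[j]);
      const int H = P[j].nrow(), C = P[j].ncol();
      for (int l = 0; l < L; ++l) {
        const int h = hj[l] - 1;
        for (int c = 0; c < C; ++c)
          acol[c] = std::max(pj[h + (size_t)H * c], clip);
        double *wl = w + (size_t)N * l;
        for (int i = 0; i < N; ++i) wl[i] *= acol[xj[i] - 1];
      }
    }

    // normalize to posteriors; marginal log-likelihood
    std::fill(rowsum.begin(), rowsum.end(), 0.0);
    for (int l = 0; l < L; ++l) {
      const double *wl = w + (size_t)N * l;
      for (int i = 0; i < N; ++i) rowsum[i] += wl[i];
    }
    double ll = 0.0;
    for (int i = 0; i < N; ++i) ll += std::log(rowsum[i]);
    for (int l = 0; l < L; ++l) {
      double *wl = w + (size_t)N * l;
      for (int i = 0; i < N; ++i) wl[i] /= rowsum[i];
    }
    trace.push_back(ll);

    // M-step: expected counts R_jhc and new blocks
    double delta = 0.0;
    for (int j = 0; j < J; ++j) {
      NumericMatrix &R_j = Rcnt[j];
      std::fill(R_j.begin(), R_j.end(), 0.0);
      double *rj = REAL(R_j);
      const int *xj = &X(0, j);
      const int *hj = INTEGER(hm[j]);
      const int H = R_j.nrow(), C = R_j.ncol();
      for (int l = 0; l < L; ++l) {
        const int h = hj[l] - 1;
        const double *wl = w + (size_t)N * l;
        for (int i = 0; i < N; ++i) rj[h + (size_t)H * (xj[i] - 1)] += wl[i];
      }
      NumericMatrix &pj = P[j];
      for (int h = 0; h < H; ++h) {
        double tot = 0.0;
        for (int c = 0; c < C; ++c) tot += rj[h + (size_t)H * c];
        if (tot < starve_tol) {
          starved[j][h] = true;  // keep previous values
          continue;
        }
        starved[j][h] = false;
        double s = 0.0;
        for (int c = 0; c < C; ++c) {
          double v = rj[h + (size_t)H * c] / tot;
          v = std::min(std::max(v, clip), 1.0 - clip);
          acol[c] = v;
          s += v;
        }
        for (int c = 0; c < C; ++c) {
          const double v = acol[c] / s;
          const double d = std::fabs(v - pj(h, c));
          if (d > delta) delta = d;
          pj(h, c) = v;
        }
      }
    }

    // structural update
    for (int l = 0; l < L; ++l) {
      const double *wl = w + (size_t)N * l;
      double s = 0.0;
      for (int i = 0; i < N; ++i) s += wl[i];
      prior[l] = s / N;
    }
    if (variant == 1) {
      double *pm = REAL(priorMat);
      std::copy(w, w + (size_t)N * L, pm);
    }

    const double rel = std::fabs(ll - ll_prev) /
      (std::fabs(ll_prev) + 1e-300);
    if (iter > 1 && delta < tol && rel < ll_tol) {
      converged = true;
      break;
    }
    ll_prev = ll;
  }
  if (iter > max_iter) iter = max_iter;

  List Pout(J), Rout(J), Sout(J);
  for (int j = 0; j < J; ++j) {
    Pout[j] = P[j];
    Rout[j] = Rcnt[j];
    Sout[j] = starved[j];
  }
  return List::create(
    _["P"] = Pout, _["structural"] = prior, _["posterior"] = post,
    _["counts"] = Rout, _["starved"] = Sout,
    _["trace"] = NumericVector(trace.begin(), trace.end()),
    _["iterations"] = iter, _["converged"] = converged);
}
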