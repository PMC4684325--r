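#include <Rcpp.h>
using namespace Rcpp;

// Vesicle-depletion recursion shared by depression (nu > 0) and facilitation
// (nu < 0).  d is clipped to [0, 2]; d(1) = 1 (full availability before any
// stimulation).  One independent recursion per channel (row of s).
// [[Rcpp::export]]
NumericMatrix stp_recurse_cpp(NumericMatrix s, NumericVector nu, NumericVector tau) {
  int D = s.nrow(), T = s.ncol();
  NumericMatrix d(D, T);
  for (int i = 0; i < D; ++i) {
    double di = 1.0;
    if (T > 0) d(i, 0) = 1.0;
    for (int t = 1; t < T; ++t) {
      double upd;
      if (nu[i] >= 0.0) {
        upd = di - nu[i] * s(i, t - 1) * di + (1.0 - di) / tau[i];
      } else {
        upd = di - nu[i] * s(i, t - 1) * (2.0 - di) + (1.0 - di) / tau[i];
      }
      if (upd < 0.0) upd = 0.0;
      if (upd > 2.0) upd = 2.0;
      di = upd;
      d(i, t) = di;
    }
  }
  return d;
}

static inline double dexp_val(double x, const double *ph) {
  // ph = (phi1, phi2, phi3, phi4); y = phi1 + phi2 * exp(-exp(phi3 * (x - phi4)))
  double u = ph[2] * (x - ph[3]);
  if (u > 30.0) return ph[0];
  if (u < -30.0) return ph[0] + ph[1];
  return ph[0] + ph[1] * std::exp(-std::exp(u));
}

// Jackknife-shrunken NMSE of prediction p against target r.  fold: 0-based
// contiguous fold id per bin; den_fold[k]: sum over bins outside fold k of
// (r - mean of r outside fold k)^2; den_all: sum (r - rbar)^2.
// Returns (e_mse, sigma_mse, e).
static void shrunk_cost_core(const double *p, const double *r, const int *fold,
                             int T, int nfold, const double *den_fold,
                             double den_all, double *out3) {
  std::vector<double> sse_fold(nfold, 0.0);
  double sse = 0.0;
  for (int t = 0; t < T; ++t) {
    double d = p[t] - r[t];
    d *= d;
    sse += d;
    sse_fold[fold[t]] += d;
  }
  double e_mse = sse / den_all;
  double ebar = 0.0;
  std::vector<double> ek(nfold);
  for (int k = 0; k < nfold; ++k) {
    ek[k] = (sse - sse_fold[k]) / den_fold[k];
    ebar += ek[k];
  }
  ebar /= nfold;
  double ss = 0.0;
  for (int k = 0; k < nfold; ++k) {
    double d = ek[k] - ebar;
    ss += d * d;
  }
  double sigma = std::sqrt((double)(nfold - 1) / nfold * ss);
  double e;
  if (e_mse >= 1.0) {
    e = e_mse;  // no shrinkage above chance level; keeps descent informative
  } else {
    double rect = 1.0 - std::pow(sigma / (1.0 - e_mse), 2.0);
    if (rect < 0.0) rect = 0.0;
    e = 1.0 - (1.0 - e_mse) * rect;
    if (e < 0.0) e = 0.0;
    if (e > 1.0) e = 1.0;
  }
  out3[0] = e_mse;
  out3[1] = sigma;
  out3[2] = e;
}

// [[Rcpp::export]]
NumericVector shrunk_cost_cpp(NumericVector p, NumericVector r, IntegerVector fold,
                              int nfold, NumericVector den_fold, double den_all) {
  NumericVector out(3);
  shrunk_cost_core(REAL(p), REAL(r), INTEGER(fold), p.size(), nfold,
                   REAL(den_fold), den_all, REAL(out));
  out.names() = CharacterVector::create("e_mse", "sigma_mse", "e");
  return out;
}

// Cost of a linear-stage output after the optional downstream path used while
// fitting: boundary normalization (mean/sd/min over the estimation set, the
// positive-definite form) followed by the double-exponential nonlinearity.
static double downstream_cost(const std::vector<double> &lin, const double *r,
                              const int *fold, int T, int nfold,
                              const double *den_fold, double den_all,
                              bool use_dexp, const double *dexp_par,
                              std::vector<double> &work) {
  double out3[3];
  if (!use_dexp) {
    shrunk_cost_core(lin.data(), r, fold, T, nfold, den_fold, den_all, out3);
    return out3[2];
  }
  double mu = 0.0;
  for (int t = 0; t < T; ++t) mu += lin[t];
  mu /= T;
  double ss = 0.0;
  for (int t = 0; t < T; ++t) {
    double d = lin[t] - mu;
    ss += d * d;
  }
  double sd = std::sqrt(ss / (T - 1));
  if (sd < 1e-12) sd = 1.0;
  double zmin = R_PosInf;
  for (int t = 0; t < T; ++t) {
    work[t] = (lin[t] - mu) / sd;
    if (work[t] < zmin) zmin = work[t];
  }
  for (int t = 0; t < T; ++t) work[t] = dexp_val(work[t] - zmin, dexp_par);
  shrunk_cost_core(work.data(), r, fold, T, nfold, den_fold, den_all, out3);
  return out3[2];
}

// One probe sweep of non-greedy coordinate descent for a module whose output
// is linear in its parameters: output = out0 (current) and probing parameter j
// adds +/- delta * X[, j].  Evaluates all 2P probes and returns the best.
// [[Rcpp::export]]
List linear_sweep_cpp(NumericMatrix X, NumericVector out0, double delta,
                      NumericVector r, IntegerVector fold, int nfold,
                      NumericVector den_fold, double den_all,
                      bool use_dexp, NumericVector dexp_par) {
  int T = out0.size(), P = X.ncol();
  std::vector<double> lin(T), work(T);
  const double *x0 = REAL(out0);
  const double *rr = REAL(r);
  const int *fl = INTEGER(fold);
  const double *df = REAL(den_fold);
  const double *dp = use_dexp ? REAL(dexp_par) : NULL;
  double best_cost = R_PosInf;
  int best_j = -1, best_sign = 0;
  for (int j = 0; j < P; ++j) {
    const double *xj = &X(0, j);
    for (int s = 0; s < 2; ++s) {
      double sg = s == 0 ? 1.0 : -1.0;
      for (int t = 0; t < T; ++t) lin[t] = x0[t] + sg * delta * xj[t];
      double c = downstream_cost(lin, rr, fl, T, nfold, df, den_all,
                                 use_dexp, dp, work);
      if (R_finite(c) && c < best_cost) {
        best_cost = c;
        best_j = j + 1;
        best_sign = (int)sg;
      }
    }
  }
  return List::create(_["j"] = best_j, _["sign"] = best_sign,
                      _["cost"] = best_cost);
}

// [[Rcpp::export]]
NumericVector norm_dexp_cost_cpp(NumericVector lin, NumericVector r,
                                 IntegerVector fold, int nfold,
                                 NumericVector den_fold, double den_all,
                                 bool use_dexp, NumericVector dexp_par,
                                 bool affine = false) {
  int T = lin.size();
  std::vector<double> v(REAL(lin), REAL(lin) + T), work(T);
  const double *rr = REAL(r);
  if (affine) {
    // least-squares gain/offset calibration of the prediction before the
    // cost: used while the output nonlinearity (which absorbs scale and
    // offset) is removed from a chain with no explicit baseline parameter
    double mp = 0.0, mr = 0.0;
    for (int t = 0; t < T; ++t) { mp += v[t]; mr += rr[t]; }
    mp /= T; mr /= T;
    double sxy = 0.0, sxx = 0.0;
    for (int t = 0; t < T; ++t) {
      sxy += (v[t] - mp) * (rr[t] - mr);
      sxx += (v[t] - mp) * (v[t] - mp);
    }
    double alpha = sxx > 1e-300 ? sxy / sxx : 0.0;
    for (int t = 0; t < T; ++t) v[t] = mr + alpha * (v[t] - mp);
  }
  double c = downstream_cost(v, rr, INTEGER(fold), T, nfold,
                             REAL(den_fold), den_all, use_dexp,
                             use_dexp ? REAL(dexp_par) : NULL, work);
  return NumericVector::create(c);
}

// causal multichannel convolution: out(t) = sum_f sum_i H(f,i) X(f, t-i+1),
// zero-padded before stimulus onset
// [[Rcpp::export]]
NumericVector causal_conv_cpp(NumericMatrix X, NumericMatrix H) {
  int C = X.nrow(), T = X.ncol(), U = H.ncol();
  NumericVector out(T);
  for (int f = 0; f < C; ++f) {
    for (int i = 0; i < U; ++i) {
      double h = H(f, i);
      if (h == 0.0) continue;
      for (int t = i; t < T; ++t) out[t] += h * X(f, t - i);
    }
  }
  return out;
}
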