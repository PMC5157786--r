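#include <Rcpp.h>
using namespace Rcpp;

// log pmf of the right-truncated negative binomial (mean/dispersion
// parameterisation) at d, truncated to {0,...,upper}. theta == 0 is the
// exact truncated-Poisson branch. Terms are accumulated relative to the
// r = 0 term, whose magnitude is representable for the joint-capacity
// truncation bounds (upper <= 28) used here.
// log-space fallback for extreme means or wide truncation bounds, where
// the term ratios relative to r = 0 could overflow a double
static double trunc_nb_logpmf_safe(int d, double lam, double theta,
                                   int upper) {
  std::vector<double> lt(upper + 1);
  lt[0] = 0.0;
  double lq = (theta > 0.0)
    ? log(theta * lam) - log1p(theta * lam) : log(lam);
  double invth = (theta > 0.0) ? 1.0 / theta : 0.0;
  for (int r = 1; r <= upper; ++r)
    lt[r] = lt[r - 1] + lq +
      ((theta > 0.0) ? log(r - 1.0 + invth) - log((double)r)
                     : -log((double)r));
  double m = *std::max_element(lt.begin(), lt.end()), S = 0.0;
  for (int r = 0; r <= upper; ++r) S += exp(lt[r] - m);
  return lt[d] - m - log(S);
}

static double trunc_nb_logpmf(int d, double lam, double theta, int upper) {
  if (d < 0 || d > upper) return R_NegInf;
  if (upper == 0) return 0.0; // saturated area: point mass at 0
  if (lam > 1e8 || upper > 40)
    return trunc_nb_logpmf_safe(d, lam, theta, upper);
  // terms relative to the r = 0 term (which cancels in the ratio td/S)
  double td = (d == 0) ? 1.0 : 0.0, t = 1.0, S = 1.0;
  if (theta > 0.0) {
    double q = theta * lam / (1.0 + theta * lam);
    double invth = 1.0 / theta;
    for (int r = 1; r <= upper; ++r) {
      t *= (r - 1.0 + invth) / r * q;
      S += t;
      if (r == d) td = t;
    }
  } else {
    for (int r = 1; r <= upper; ++r) {
      t *= lam / r;
      S += t;
      if (r == d) td = t;
    }
  }
  return log(td) - log(S);
}

// [[Rcpp::export]]
NumericVector cpp_trunc_nb_logpmf(IntegerVector d, NumericVector lam,
                                  double theta, IntegerVector upper) {
  int n = d.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = trunc_nb_logpmf(d[i], lam[i], theta, upper[i]);
  return out;
}

// Per-patient in-clinic path log-probabilities for one joint area.
// Intervals are supplied deduplicated: row u of the unique table carries
// (d_u, upper_u, logdt_u, Z_u); (uid, pid) map each observed interval to
// its unique row and its patient. Returns sum of interval log-pmfs per
// patient (patients with no intervals contribute 0).
// [[Rcpp::export]]
NumericVector cpp_area_path_loglik(IntegerVector uid, IntegerVector pid,
                                   int npat, IntegerVector d_u,
                                   IntegerVector upper_u,
                                   NumericVector logdt_u, NumericMatrix Z_u,
                                   double log_lambda0, NumericVector beta,
                                   double theta) {
  int U = d_u.size(), p = beta.size();
  if (Z_u.ncol() != p) stop("beta length does not match design columns");
  NumericVector lpm(U);
  for (int u = 0; u < U; ++u) {
    double eta = log_lambda0 + logdt_u[u];
    for (int j = 0; j < p; ++j) eta += Z_u(u, j) * beta[j];
    lpm[u] = trunc_nb_logpmf(d_u[u], exp(eta), theta, upper_u[u]);
  }
  NumericVector out(npat);
  int n = uid.size();
  for (int i = 0; i < n; ++i) out[pid[i]] += lpm[uid[i]];
  return out;
}
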