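#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursion for the two-state HMM with a
// previous-state-dependent observation density.
//
// bv: T x 2 matrix of speed-density values (columns: stop, run)
// ba: T x 4 matrix of angle-density values b^theta_ij, columns ordered
//     (i=stop,j=stop), (i=stop,j=run), (i=run,j=stop), (i=run,j=run);
//     row 0 is ignored (the first displacement has no preceding angle and
//     uses the speed-only emission weighted by the initial distribution).
// A:  2 x 2 transition matrix, rows = previous state, cols = current state.
// pi: length-2 initial state distribution.
//
// Returns the log-likelihood and, optionally, the posterior run
// probabilities p_t = P(state_t = run | data).
// [[Rcpp::export]]
List fb_two_state(NumericMatrix bv, NumericMatrix ba, NumericMatrix A,
                  NumericVector pi, bool want_posterior) {
  const int T = bv.nrow();
  if (T < 1) stop("empty emission matrix");
  NumericMatrix alpha(T, 2);
  NumericVector c(T);

  double a0 = pi[0] * bv(0, 0);
  double a1 = pi[1] * bv(0, 1);
  c[0] = a0 + a1;
  if (c[0] <= 0.0 || !R_finite(c[0]))
    stop("zero observation density at step 1");
  alpha(0, 0) = a0 / c[0];
  alpha(0, 1) = a1 / c[0];

  for (int t = 1; t < T; ++t) {
    // b_ij(y_t) = bv(t, j) * ba(t, 2*i + j)
    double s0 = alpha(t - 1, 0) * A(0, 0) * ba(t, 0) * bv(t, 0) +
                alpha(t - 1, 1) * A(1, 0) * ba(t, 2) * bv(t, 0);
    double s1 = alpha(t - 1, 0) * A(0, 1) * ba(t, 1) * bv(t, 1) +
                alpha(t - 1, 1) * A(1, 1) * ba(t, 3) * bv(t, 1);
    c[t] = s0 + s1;
    if (c[t] <= 0.0 || !R_finite(c[t]))
      stop("zero observation density at step %d", t + 1);
    alpha(t, 0) = s0 / c[t];
    alpha(t, 1) = s1 / c[t];
  }

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]);

  List out = List::create(Named("loglik") = loglik);
  if (want_posterior) {
    NumericMatrix beta(T, 2);
    beta(T - 1, 0) = 1.0;
    beta(T - 1, 1) = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      double b0 = A(0, 0) * ba(t + 1, 0) * bv(t + 1, 0) * beta(t + 1, 0) +
                  A(0, 1) * ba(t + 1, 1) * bv(t + 1, 1) * beta(t + 1, 1);
      double b1 = A(1, 0) * ba(t + 1, 2) * bv(t + 1, 0) * beta(t + 1, 0) +
                  A(1, 1) * ba(t + 1, 3) * bv(t + 1, 1) * beta(t + 1, 1);
      beta(t, 0) = b0 / c[t + 1];
      beta(t, 1) = b1 / c[t + 1];
    }
    NumericVector p_run(T);
    for (int t = 0; t < T; ++t) {
      double g0 = alpha(t, 0) * beta(t, 0);
      double g1 = alpha(t, 1) * beta(t, 1);
      p_run[t] = g1 / (g0 + g1);
    }
    out["p_run"] = p_run;
  }
  return out;
}

// Pooled negative log-likelihood over a list of per-track emission pairs.
// emis: list of lists with elements "bv" and "ba" as above.
// [[Rcpp::export]]
double pooled_nll_cpp(List emis, NumericMatrix A, NumericVector pi) {
  double nll = 0.0;
  for (int n = 0; n < emis.size(); ++n) {
    List e = emis[n];
    List r = fb_two_state(e["bv"], e["ba"], A, pi, false);
    nll -= as<double>(r["loglik"]);
  }
  return nll;
}
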