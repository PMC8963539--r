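#include <Rcpp.h>
using namespace Rcpp;

// One-sided (x >= 0) truncated-normal draw with mean mu and sd s, using R's
// RNG stream. Inverse-CDF for the easy regime, exponential rejection
// (Robert 1995) deep in the tail.
static double rtruncnorm_pos(double mu, double s) {
  double alpha = -mu / s;  // standardized lower bound
  if (alpha < 5.0) {
    double plo = R::pnorm(alpha, 0.0, 1.0, 1, 0);
    double u = R::runif(plo, 1.0);
    if (u >= 1.0) u = 1.0 - 1e-16;
    return mu + s * R::qnorm(u, 0.0, 1.0, 1, 0);
  }
  // tail: sample z >= alpha via exponential proposal
  double lambda = 0.5 * (alpha + std::sqrt(alpha * alpha + 4.0));
  for (int it = 0; it < 1000; ++it) {
    double z = alpha + R::exp_rand() / lambda;
    double rho = std::exp(-0.5 * (z - lambda) * (z - lambda));
    if (R::unif_rand() <= rho) return mu + s * z;
  }
  return mu + s * alpha;  // fallback, essentially never reached
}

// Gibbs sampler for a linear sparse-coding model with nonnegative
// (exponential-prior) intensities and a discrete context/side state.
//
// G        : n x n Gram matrix of projective fields (A'A)
// B        : n x T matrix of feedforward drives A'I per trial
// sigma_n2 : pixel noise variance
// lambda   : n x K matrix of exponential prior rates per context/side combo
// logprior : T x K per-trial log prior over the K combos (from the cue)
// n_burn, n_samples : sweeps discarded / summed into the response
// state_every : sweeps between task-state resamplings (1 = every sweep;
//               larger values make beliefs persist within a trial)
//
// Returns a list: counts (T x n summed intensity samples) and state_freq
// (T x K fraction of retained sweeps spent in each combo).
// [[Rcpp::export]]
List gibbs_v1_session_cpp(NumericMatrix G, NumericMatrix B, double sigma_n2,
                          NumericMatrix lambda, NumericMatrix logprior,
                          int n_burn, int n_samples, int state_every = 1) {
  const int n = G.nrow();
  const int T = B.ncol();
  const int K = lambda.ncol();
  NumericMatrix counts(T, n);
  NumericMatrix state_freq(T, K);
  std::vector<double> x(n), v(n), logw(K);
  std::vector<double> s2(n), sdev(n);
  for (int i = 0; i < n; ++i) {
    s2[i] = sigma_n2 / G(i, i);
    sdev[i] = std::sqrt(s2[i]);
  }
  // per-combo sum of log lambda (constant part of the state posterior)
  std::vector<double> loglam_sum(K, 0.0);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < n; ++i) loglam_sum[k] += std::log(lambda(i, k));

  RNGScope scope;
  const int total = n_burn + n_samples;
  for (int t = 0; t < T; ++t) {
    std::fill(x.begin(), x.end(), 0.0);
    std::fill(v.begin(), v.end(), 0.0);
    int state = 0;
    for (int sweep = 0; sweep < total; ++sweep) {
      if (sweep % state_every == 0) {
        // sample the context/side state given x
        double mx = R_NegInf;
        for (int k = 0; k < K; ++k) {
          double lw = logprior(t, k) + loglam_sum[k];
          for (int i = 0; i < n; ++i) lw -= lambda(i, k) * x[i];
          logw[k] = lw;
          if (lw > mx) mx = lw;
        }
        double z = 0.0;
        for (int k = 0; k < K; ++k) { logw[k] = std::exp(logw[k] - mx); z += logw[k]; }
        double u = R::unif_rand() * z;
        state = K - 1;
        double acc = 0.0;
        for (int k = 0; k < K; ++k) { acc += logw[k]; if (u <= acc) { state = k; break; } }
      }
      // Gibbs sweep over intensities
      for (int i = 0; i < n; ++i) {
        double gii = G(i, i);
        double m = (B(i, t) - (v[i] - gii * x[i])) / gii;
        double mu = m - lambda(i, state) * s2[i];
        double xn = rtruncnorm_pos(mu, sdev[i]);
        double d = xn - x[i];
        if (d != 0.0) {
          for (int j = 0; j < n; ++j) v[j] += G(j, i) * d;
          x[i] = xn;
        }
      }
      if (sweep >= n_burn) {
        for (int i = 0; i < n; ++i) counts(t, i) += x[i];
        state_freq(t, state) += 1.0;
      }
    }
    for (int k = 0; k < K; ++k) state_freq(t, k) /= n_samples;
  }
  return List::create(Named("counts") = counts,
                      Named("state_freq") = state_freq);
}
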