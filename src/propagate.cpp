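// Master-equation propagation under a sampled voltage waveform.
// P(t_{i+1}) = expm(W(V_i) * dt) * P(t_i), with the generator W assembled
// from the model's edge list at each sample voltage. Exact matrix
// exponentials are cached per distinct voltage quantized to `quantum` mV;
// fluctuating waveforms revisit voltage values, stepped ones even more so.

#include <RcppArmadillo.h>
#include <unordered_map>

// [[Rcpp::depends(RcppArmadillo)]]

static arma::mat assemble_generator(const Rcpp::IntegerVector& from,
                                    const Rcpp::IntegerVector& to,
                                    const Rcpp::NumericVector& amplitude,
                                    const Rcpp::NumericVector& charge,
                                    const Rcpp::NumericVector& multiplicity,
                                    int n_states, double V, double vt) {
  arma::mat W(n_states, n_states, arma::fill::zeros);
  const int m = from.size();
  for (int k = 0; k < m; ++k) {
    double rate = multiplicity[k] * amplitude[k] * std::exp(charge[k] * V / vt);
    W(to[k] - 1, from[k] - 1) += rate;
  }
  for (int i = 0; i < n_states; ++i) {
    double col = 0.0;
    for (int j = 0; j < n_states; ++j)
      if (j != i) col += W(j, i);
    W(i, i) = -col;
  }
  return W;
}

// [[Rcpp::export]]
arma::mat cpp_propagate(Rcpp::IntegerVector from, Rcpp::IntegerVector to,
                        Rcpp::NumericVector amplitude, Rcpp::NumericVector charge,
                        Rcpp::NumericVector multiplicity, int n_states,
                        Rcpp::NumericVector V, double dt, double vt,
                        Rcpp::NumericVector p0, double quantum) {
  const int T = V.size();
  arma::mat traj(n_states, T);
  arma::vec p(p0.begin(), n_states);
  traj.col(0) = p;

  std::unordered_map<long long, arma::mat> cache;
  const size_t cache_cap = 50000;   // bound memory on long non-repeating waveforms

  for (int i = 0; i < T - 1; ++i) {
    double v = V[i];
    if (!std::isfinite(v)) Rcpp::stop("non-finite voltage sample");
    long long key = (long long) std::llround(v / quantum);
    double vq = key * quantum;
    auto it = cache.find(key);
    if (it == cache.end()) {
      arma::mat W = assemble_generator(from, to, amplitude, charge,
                                       multiplicity, n_states, vq, vt);
      arma::mat P = arma::expmat(W * dt);
      if (!P.is_finite()) Rcpp::stop("non-finite propagator entries");
      if (cache.size() >= cache_cap) cache.clear();
      it = cache.emplace(key, std::move(P)).first;
    }
    p = it->second * p;
    traj.col(i + 1) = p;
  }
  return traj;
}

// Exact single-voltage propagator, exposed for tests and for step protocols.
// [[Rcpp::export]]
arma::mat cpp_expm(arma::mat W, double dt) {
  return arma::expmat(W * dt);
}
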