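#include <Rcpp.h>
using namespace Rcpp;

// Single-site-flip Metropolis sampler for the coupled-site titration
// Hamiltonian. Dimensionless energy of microstate s (occupancies 0/1):
//   E/kT = ln10 * sum_i s_i (pH - pKa_i) + sum_{i<j} Wbeta_ij s_i s_j
// where Wbeta is the pair-coupling matrix already divided by RT (applied
// when both members of a pair are protonated). Uses R's RNG so that
// set.seed() makes runs reproducible.
//
// attempt_cum: cumulative site-pick probabilities (length M, last == 1),
// allowing designed slow-exchanging sites.
// [[Rcpp::export]]
IntegerMatrix metropolis_occupancy(NumericVector pKa, NumericMatrix Wbeta,
                                   double pH, int n_steps, int record_every,
                                   NumericVector attempt_cum,
                                   IntegerVector init) {
  const int M = pKa.size();
  const double ln10 = std::log(10.0);
  std::vector<int> s(init.begin(), init.end());
  const int n_rec = n_steps / record_every;
  IntegerMatrix out(n_rec, M);
  int rec = 0;
  for (int step = 1; step <= n_steps; ++step) {
    // lazy step (5%): guarantees aperiodicity even when every move has
    // dE = 0 (e.g. uncoupled sites at pH == pKa, where deterministic
    // acceptance would otherwise conserve total-proton parity per step)
    if (unif_rand() < 0.05) {
      if (step % record_every == 0) {
        for (int j = 0; j < M; ++j) out(rec, j) = s[j];
        ++rec;
      }
      continue;
    }
    // pick a site according to the attempt weights
    double u = unif_rand();
    int k = 0;
    while (k < M - 1 && u > attempt_cum[k]) ++k;
    const int ds = 1 - 2 * s[k];
    double field = ln10 * (pH - pKa[k]);
    for (int j = 0; j < M; ++j)
      if (j != k) field += Wbeta(k, j) * s[j];
    const double dE = ds * field;
    if (dE <= 0.0 || unif_rand() < std::exp(-dE))
      s[k] += ds;
    if (step % record_every == 0) {
      for (int j = 0; j < M; ++j) out(rec, j) = s[j];
      ++rec;
    }
  }
  return out;
}
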