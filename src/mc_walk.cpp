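#include <Rcpp.h>
using namespace Rcpp;

// Metropolis walk over saved conformations grouped into conformers.
// Each step proposes a uniformly random conformation of a uniformly random
// *other* conformer and accepts when the Boltzmann factor exceeds a
// uniform(0,1) draw; the currently occupied conformer is tallied every step,
// accepted or not. Visits are returned per batch (rows) for batch-means
// standard errors. Uses R's RNG, so results are reproducible via set.seed().
// [[Rcpp::export]]
IntegerMatrix mc_walk_cpp(NumericVector energy, IntegerVector conf_offset,
                          IntegerVector conf_count, double steps_d,
                          double inv_kt, int n_batches) {
  const int k = conf_count.size();
  const long long steps = (long long)steps_d;
  long long n_total = 0;
  for (int i = 0; i < k; ++i) n_total += conf_count[i];

  IntegerMatrix visits(n_batches, k);
  // start at a uniformly random conformation over the whole set
  long long cur = (long long)(unif_rand() * (double)n_total);
  if (cur >= n_total) cur = n_total - 1;
  int cur_conf = 0;
  while (cur_conf < k - 1 &&
         cur >= (long long)conf_offset[cur_conf] + conf_count[cur_conf])
    ++cur_conf;
  double e_cur = energy[(R_xlen_t)cur];

  const long long batch_len = steps / n_batches;
  for (long long s = 0; s < steps; ++s) {
    int j = (int)(unif_rand() * (k - 1));
    if (j >= k - 1) j = k - 2;
    if (j >= cur_conf) ++j;
    int c_in = (int)(unif_rand() * conf_count[j]);
    if (c_in >= conf_count[j]) c_in = conf_count[j] - 1;
    long long cand = (long long)conf_offset[j] + c_in;
    double bf = std::exp(-(energy[(R_xlen_t)cand] - e_cur) * inv_kt);
    double r = unif_rand();
    if (bf > r) {
      cur = cand;
      cur_conf = j;
      e_cur = energy[(R_xlen_t)cand];
    }
    int b = (int)(s / batch_len);
    if (b >= n_batches) b = n_batches - 1;
    ++visits(b, cur_conf);
  }
  return visits;
}
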