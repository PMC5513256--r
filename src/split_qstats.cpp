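#include <Rcpp.h>
using namespace Rcpp;

// Incidence-frequency statistics over repeated random k-way partitions of
// each of a set of abundance samples.
//
// counts: S x n_draws integer matrix of per-species counts (columns are
// independent draws from one assemblage). For each draw, n_splits random
// partitions into k groups (sizes differing by at most one) are generated;
// the per-species group allocation is sampled by a sequential conditional
// hypergeometric chain, which is equivalent in law to permuting the n
// individuals and dealing them into the k groups.
//
// Returns an integer matrix with n_draws * n_splits rows (split index
// fastest) and k columns: column j holds q_j, the number of species found
// in exactly j of the k groups.
// [[Rcpp::export]]
IntegerMatrix split_qstats_cpp(IntegerMatrix counts, int n_splits, int k) {
  const int S = counts.nrow(), n_draws = counts.ncol();
  if (k < 2) stop("k must be >= 2");
  IntegerMatrix Q(n_draws * n_splits, k);
  std::vector<int> spc;     // indices of observed species for this draw
  std::vector<int> rem(S);  // per-species not-yet-assigned individuals
  std::vector<int> incid(S);

  for (int d = 0; d < n_draws; ++d) {
    spc.clear();
    long n = 0;
    for (int i = 0; i < S; ++i) {
      int c = counts(i, d);
      if (c > 0) { spc.push_back(i); n += c; }
    }
    if (n < k) stop("draw has fewer individuals than k groups");
    const int sobs = (int) spc.size();
    // group sizes: first n % k groups get one extra
    std::vector<long> sizes(k, n / k);
    for (int g = 0; g < (int)(n % k); ++g) sizes[g]++;

    for (int sp = 0; sp < n_splits; ++sp) {
      for (int j = 0; j < sobs; ++j) { rem[j] = counts(spc[j], d); incid[j] = 0; }
      long pool = n;
      for (int g = 0; g < k - 1; ++g) {
        long cap = sizes[g];
        long rest = pool;  // individuals still unassigned, species j..end
        for (int j = 0; j < sobs && cap > 0; ++j) {
          const int rj = rem[j];
          if (rj == 0) { continue; }
          rest -= rj;  // others available after species j
          int x;
          if (rest == 0) x = (int) cap;               // last species takes the rest
          else x = (int) ::Rf_rhyper((double) rj, (double) rest, (double) cap);
          if (x > 0) {
            rem[j] -= x;
            cap -= x;
            incid[j]++;
          }
        }
        pool -= sizes[g];
      }
      int qrow = d * n_splits + sp;
      for (int j = 0; j < sobs; ++j) {
        int inc = incid[j] + (rem[j] > 0 ? 1 : 0);  // last group gets leftovers
        Q(qrow, inc - 1)++;
      }
    }
  }
  return Q;
}
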