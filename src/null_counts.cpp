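#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Batch kernel for the seed-randomization null: for every trial column of
// `trials` (1-based node indices, k rows), form the second-degree set
// (union of neighbors of the trial seeds, minus the seeds and the bait)
// and count its distinct members in every pathway.
//
// adj:      list of integer vectors, 1-based neighbor indices per node
//           (self-loops already excluded)
// members:  list of integer vectors, 1-based node indices per tested pathway
// bait:     1-based bait node index, or 0 when the bait is absent
//
// Returns an integer matrix with one row per pathway, one column per trial.
// [[Rcpp::export]]
IntegerMatrix cpp_null_pathway_counts(List adj, List members,
                                      IntegerMatrix trials, int bait,
                                      int n_nodes) {
  const int k = trials.nrow();
  const int n_trials = trials.ncol();
  const int n_path = members.size();

  std::vector<std::vector<int> > A(n_nodes + 1);
  for (int i = 0; i < n_nodes; ++i) {
    IntegerVector v = adj[i];
    A[i + 1].assign(v.begin(), v.end());
  }
  std::vector<std::vector<int> > M(n_path);
  for (int p = 0; p < n_path; ++p) {
    IntegerVector v = members[p];
    M[p].assign(v.begin(), v.end());
  }

  IntegerMatrix counts(n_path, n_trials);
  std::vector<char> in_set(n_nodes + 1, 0);
  std::vector<char> is_seed(n_nodes + 1, 0);
  std::vector<int> touched;
  touched.reserve(1024);

  for (int t = 0; t < n_trials; ++t) {
    touched.clear();
    for (int j = 0; j < k; ++j) is_seed[trials(j, t)] = 1;
    for (int j = 0; j < k; ++j) {
      const std::vector<int>& nb = A[trials(j, t)];
      for (size_t q = 0; q < nb.size(); ++q) {
        const int v = nb[q];
        if (!in_set[v]) {
          in_set[v] = 1;
          touched.push_back(v);
        }
      }
    }
    for (int p = 0; p < n_path; ++p) {
      int c = 0;
      const std::vector<int>& mem = M[p];
      for (size_t q = 0; q < mem.size(); ++q) {
        const int v = mem[q];
        if (in_set[v] && !is_seed[v] && v != bait) ++c;
      }
      counts(p, t) = c;
    }
    for (size_t q = 0; q < touched.size(); ++q) in_set[touched[q]] = 0;
    for (int j = 0; j < k; ++j) is_seed[trials(j, t)] = 0;
  }
  return counts;
}
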