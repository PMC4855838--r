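// Depth-first branch-and-bound over EM combinations.
//
// Each unordered combination of k candidate columns is visited exactly
// once: a node sorts its candidate list by descending single-mode variance
// gain on the node's residual (ties towards the lexicographically lowest
// mode id) and the child at position t only receives the candidates after
// position t. Within a branch, modes are therefore appended in the
// step-wise greedy order of the set being scored. A child subtree is
// pruned when theta_so_far plus the sum of the (k - depth) largest
// single-mode gains available to it cannot exceed the incumbent; since
// gains are sorted, once one child is pruned all later siblings are too.
// Leaves (depth k-1) are scored in a single vectorized pass.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

namespace {

struct SearchState {
  const arma::mat* E;
  double total_ss;
  int k;
  const arma::ivec* id_rank;
  bool prune;
  double prune_tol;
  double max_nodes;
  double best_theta;
  std::vector<int> best_seq;
  double nodes_evaluated;
  double nodes_pruned;
  bool aborted;
  std::vector<int> chosen;
};

// gains (fraction of total_ss) of candidate columns on residual V;
// clipped projections stored in P (cand x experiments)
arma::vec cand_gains(const arma::mat& E, const arma::uvec& cand,
                     const arma::mat& V, double total_ss, arma::mat& P) {
  P = E.cols(cand).t() * V;
  P.transform([](double x) { return x > 0.0 ? x : 0.0; });
  return arma::sum(P % P, 1) / total_ss;
}

// order positions by descending gain, ties towards lowest id rank
arma::uvec gain_order(const arma::vec& gains, const arma::uvec& cand,
                      const arma::ivec& id_rank) {
  arma::uvec ord = arma::regspace<arma::uvec>(0, gains.n_elem - 1);
  std::stable_sort(ord.begin(), ord.end(), [&](arma::uword a, arma::uword b) {
    if (gains[a] != gains[b]) return gains[a] > gains[b];
    return id_rank[cand[a]] < id_rank[cand[b]];
  });
  return ord;
}

void dfs(SearchState& st, const arma::mat& Viter, double theta,
         const arma::uvec& cand) {
  if (st.aborted) return;
  const arma::mat& E = *st.E;
  const int depth = static_cast<int>(st.chosen.size());
  const int slots = st.k - depth;
  if (static_cast<int>(cand.n_elem) < slots) return;

  arma::mat P;
  arma::vec gains = cand_gains(E, cand, Viter, st.total_ss, P);
  arma::uvec ord = gain_order(gains, cand, *st.id_rank);

  if (slots == 1) {
    // vectorized leaf evaluation: every candidate completes a combination
    st.nodes_evaluated += static_cast<double>(cand.n_elem);
    arma::uword best = ord[0];
    if (theta + gains[best] > st.best_theta) {
      st.best_theta = theta + gains[best];
      st.best_seq = st.chosen;
      st.best_seq.push_back(static_cast<int>(cand[best]));
    }
    if (st.nodes_evaluated > st.max_nodes) st.aborted = true;
    return;
  }

  for (arma::uword t = 0; t < cand.n_elem; ++t) {
    if (st.aborted) return;
    const arma::uword n_left = cand.n_elem - t;
    if (static_cast<int>(n_left) < slots) break;
    if (st.prune) {
      double bound = theta;
      for (int s = 0; s < slots; ++s) bound += gains[ord[t + s]];
      if (bound <= st.best_theta + st.prune_tol) {
        // gains are sorted: all later siblings have an equal-or-worse bound
        st.nodes_pruned += static_cast<double>(n_left);
        break;
      }
    }
    const arma::uword pos = ord[t];
    const arma::uword col = cand[pos];
    arma::mat Vchild = Viter - E.col(col) * P.row(pos);
    arma::uvec rest(n_left - 1);
    for (arma::uword s = t + 1; s < cand.n_elem; ++s) rest[s - t - 1] = cand[ord[s]];
    st.chosen.push_back(static_cast<int>(col));
    dfs(st, Vchild, theta + gains[pos], rest);
    st.chosen.pop_back();
  }
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List bnb_search_cpp(const arma::mat& E, const arma::mat& V,
                          double total_ss, int k, double incumbent_theta,
                          Rcpp::IntegerVector incumbent_seq,
                          Rcpp::IntegerVector id_rank, bool prune,
                          double prune_tol, double max_nodes) {
  SearchState st;
  st.E = &E;
  st.total_ss = total_ss;
  st.k = k;
  arma::ivec rank_vec(id_rank.begin(), id_rank.size());
  st.id_rank = &rank_vec;
  st.prune = prune;
  st.prune_tol = prune_tol;
  st.max_nodes = max_nodes;
  st.best_theta = incumbent_theta;
  st.best_seq.assign(incumbent_seq.begin(), incumbent_seq.end());
  for (int& i : st.best_seq) i -= 1;  // to 0-based
  st.nodes_evaluated = 0.0;
  st.nodes_pruned = 0.0;
  st.aborted = false;

  arma::uvec cand = arma::regspace<arma::uvec>(0, E.n_cols - 1);
  dfs(st, V, 0.0, cand);

  Rcpp::IntegerVector seq(st.best_seq.size());
  for (size_t i = 0; i < st.best_seq.size(); ++i) seq[i] = st.best_seq[i] + 1;
  return Rcpp::List::create(
      Rcpp::Named("theta") = st.best_theta,
      Rcpp::Named("sequence") = seq,
      Rcpp::Named("nodes_evaluated") = st.nodes_evaluated,
      Rcpp::Named("nodes_pruned") = st.nodes_pruned,
      Rcpp::Named("complete") = !st.aborted);
}
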