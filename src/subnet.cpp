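#include <Rcpp.h>
using namespace Rcpp;

// Coherence score of a selection: total edge weight over unordered pairs of
// selected genes (one per locus). W is symmetric with zero diagonal.
static double selection_score(const std::vector<int>& sel,
                              const NumericMatrix& W) {
  double s = 0.0;
  const int L = sel.size();
  for (int i = 0; i < L; ++i)
    for (int j = i + 1; j < L; ++j)
      s += W(sel[i], sel[j]);
  return s;
}

// true if a is lexicographically smaller than b (gene indices are assigned
// in lexicographic order of gene symbols by the R caller)
static bool lex_less(const std::vector<int>& a, const std::vector<int>& b) {
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] != b[i]) return a[i] < b[i];
  }
  return false;
}

// [[Rcpp::export]]
List exhaustive_opt_cpp(List cand, NumericMatrix W) {
  const int L = cand.size();
  std::vector<std::vector<int>> cands(L);
  for (int l = 0; l < L; ++l) {
    IntegerVector v = cand[l];
    cands[l] = std::vector<int>(v.begin(), v.end()); // already 0-based
  }
  std::vector<int> idx(L, 0), cur(L), best(L);
  for (int l = 0; l < L; ++l) cur[l] = cands[l][0];
  best = cur;
  double best_score = selection_score(cur, W);
  // odometer with the last locus fastest: lexicographic tuple order, so the
  // first strict improvement rule keeps the lexicographically smallest optimum
  while (true) {
    int pos = L - 1;
    while (pos >= 0 && idx[pos] + 1 >= (int)cands[pos].size()) {
      idx[pos] = 0;
      cur[pos] = cands[pos][0];
      --pos;
    }
    if (pos < 0) break;
    ++idx[pos];
    cur[pos] = cands[pos][idx[pos]];
    double s = selection_score(cur, W);
    if (s > best_score) {
      best_score = s;
      best = cur;
    }
  }
  return List::create(_["selection"] = IntegerVector(best.begin(), best.end()),
                      _["score"] = best_score);
}

// [[Rcpp::export]]
List anneal_opt_cpp(List cand, NumericMatrix W, int n_restarts, int n_steps,
                    double t0, double alpha) {
  const int L = cand.size();
  std::vector<std::vector<int>> cands(L);
  std::vector<int> free_loci; // loci with more than one candidate
  for (int l = 0; l < L; ++l) {
    IntegerVector v = cand[l];
    cands[l] = std::vector<int>(v.begin(), v.end());
    if (cands[l].size() > 1) free_loci.push_back(l);
  }
  RNGScope scope;
  std::vector<int> overall_best;
  double overall_score = -1.0;
  IntegerMatrix restart_best(n_restarts, L);
  NumericVector restart_scores(n_restarts);
  for (int r = 0; r < n_restarts; ++r) {
    std::vector<int> cur(L);
    for (int l = 0; l < L; ++l) {
      int j = (int)std::floor(unif_rand() * cands[l].size());
      if (j >= (int)cands[l].size()) j = cands[l].size() - 1;
      cur[l] = cands[l][j];
    }
    double cur_score = selection_score(cur, W);
    std::vector<int> best = cur;
    double best_score = cur_score;
    if (!free_loci.empty()) {
      double temp = t0;
      for (int step = 0; step < n_steps; ++step) {
        int l = free_loci[(int)std::floor(unif_rand() * free_loci.size())
                          % free_loci.size()];
        const std::vector<int>& cl = cands[l];
        int j = (int)std::floor(unif_rand() * cl.size()) % cl.size();
        int newg = cl[j];
        int oldg = cur[l];
        if (newg != oldg) {
          double delta = 0.0;
          for (int m = 0; m < L; ++m) {
            if (m == l) continue;
            delta += W(newg, cur[m]) - W(oldg, cur[m]);
          }
          if (delta >= 0.0 || unif_rand() < std::exp(delta / temp)) {
            cur[l] = newg;
            cur_score += delta;
            if (cur_score > best_score ||
                (cur_score == best_score && lex_less(cur, best))) {
              best_score = cur_score;
              best = cur;
            }
          }
        }
        temp *= alpha;
      }
    }
    // recompute to wash out accumulated floating-point drift
    best_score = selection_score(best, W);
    restart_scores[r] = best_score;
    for (int l = 0; l < L; ++l) restart_best(r, l) = best[l];
    if (best_score > overall_score ||
        (best_score == overall_score && lex_less(best, overall_best))) {
      overall_score = best_score;
      overall_best = best;
    }
  }
  return List::create(
      _["selection"] = IntegerVector(overall_best.begin(), overall_best.end()),
      _["score"] = overall_score,
      _["restart_selections"] = restart_best,
      _["restart_scores"] = restart_scores);
}
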