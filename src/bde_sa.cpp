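// BDeu scoring and simulated-annealing structure search for discrete
// Bayesian networks. Data are samples x nodes integer matrices with
// values in [0, levels[j]). Family scores are memoised per (child,
// parent bitmask), so the annealing loop mostly costs a cycle check.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <random>

using namespace Rcpp;

typedef std::vector<std::vector<bool>> AdjMat;

// BDeu family log score:
// sum_j [ lgamma(a_j) - lgamma(a_j + N_j)
//         + sum_k lgamma(a_jk + N_jk) - lgamma(a_jk) ]
// with a_jk = ess / (q * r), a_j = ess / q.
static double family_score(const IntegerMatrix& data,
                           const IntegerVector& levels,
                           int child, const std::vector<int>& parents,
                           double ess) {
  const int n_samples = data.nrow();
  const int r = levels[child];
  long long q = 1;
  for (int p : parents) q *= levels[p];
  if (n_samples == 0) return 0.0;
  std::vector<int> counts((size_t)(q * r), 0);
  for (int s = 0; s < n_samples; ++s) {
    long long cfg = 0, stride = 1;
    for (int p : parents) {
      cfg += (long long)data(s, p) * stride;
      stride *= levels[p];
    }
    counts[(size_t)(cfg * r + data(s, child))]++;
  }
  const double a_jk = ess / (double)(q * r);
  const double a_j = ess / (double)q;
  double score = 0.0;
  for (long long j = 0; j < q; ++j) {
    int nj = 0;
    double inner = 0.0;
    for (int k = 0; k < r; ++k) {
      int njk = counts[(size_t)(j * r + k)];
      nj += njk;
      if (njk > 0)
        inner += std::lgamma(a_jk + njk) - std::lgamma(a_jk);
    }
    if (nj > 0)
      score += std::lgamma(a_j) - std::lgamma(a_j + nj) + inner;
  }
  return score;
}

static std::vector<int> mask_to_parents(uint64_t mask, int n) {
  std::vector<int> out;
  for (int i = 0; i < n; ++i)
    if (mask & (uint64_t(1) << i)) out.push_back(i);
  return out;
}

struct FamilyCache {
  const IntegerMatrix& data;
  const IntegerVector& levels;
  double ess;
  std::unordered_map<uint64_t, double> memo;
  FamilyCache(const IntegerMatrix& d, const IntegerVector& l, double e)
    : data(d), levels(l), ess(e) {}
  double score(int child, uint64_t pmask) {
    uint64_t key = (uint64_t(child) << 40) | pmask;
    auto it = memo.find(key);
    if (it != memo.end()) return it->second;
    double s = family_score(data, levels, child,
                            mask_to_parents(pmask, levels.size()), ess);
    memo.emplace(key, s);
    return s;
  }
};

// [[Rcpp::export(name = ".cpp_bde_family_score")]]
double cpp_bde_family_score(IntegerMatrix data, IntegerVector levels,
                            int child, IntegerVector parents, double ess) {
  std::vector<int> ps(parents.begin(), parents.end());
  return family_score(data, levels, child, ps, ess);
}

// is there a directed path from u to v in adj (excluding trivial u==v)?
static bool has_path(const AdjMat& adj, int u, int v) {
  const int n = adj.size();
  std::vector<bool> seen(n, false);
  std::vector<int> stack{u};
  seen[u] = true;
  while (!stack.empty()) {
    int x = stack.back();
    stack.pop_back();
    for (int y = 0; y < n; ++y) {
      if (adj[x][y] && !seen[y]) {
        if (y == v) return true;
        seen[y] = true;
        stack.push_back(y);
      }
    }
  }
  return false;
}

static uint64_t parent_mask(const AdjMat& adj, int child) {
  uint64_t m = 0;
  const int n = adj.size();
  for (int p = 0; p < n; ++p)
    if (adj[p][child]) m |= (uint64_t(1) << p);
  return m;
}

// [[Rcpp::export(name = ".cpp_sa_search")]]
List cpp_sa_search(IntegerMatrix data, IntegerVector levels, double ess,
                   int max_parents, double t_initial, double cooling_factor,
                   double t_reanneal, int max_accepted_before_cooling,
                   int max_proposed_before_cooling,
                   int min_accepted_before_reanneal, int max_restarts,
                   double proposal_budget, int seed) {
  const int n = levels.size();
  if (n < 2) stop("need at least 2 nodes");
  if (proposal_budget <= 0) stop("proposal budget must be positive");
  FamilyCache cache(data, levels, ess);
  std::mt19937 rng((uint32_t)seed);
  std::uniform_int_distribution<int> node_dist(0, n - 1);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  AdjMat adj(n, std::vector<bool>(n, false));
  std::vector<int> n_parents(n, 0);
  std::vector<double> fam(n);

  auto random_restart = [&]() {
    for (auto& row : adj) std::fill(row.begin(), row.end(), false);
    std::fill(n_parents.begin(), n_parents.end(), 0);
    // random topological order, sparse forward edges
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    std::shuffle(order.begin(), order.end(), rng);
    double p_edge = std::min(0.5, 2.0 / n);
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (unif(rng) < p_edge && n_parents[order[j]] < max_parents) {
          adj[order[i]][order[j]] = true;
          n_parents[order[j]]++;
        }
      }
    }
    for (int v = 0; v < n; ++v) fam[v] = cache.score(v, parent_mask(adj, v));
  };

  random_restart();
  double total = 0.0;
  for (int v = 0; v < n; ++v) total += fam[v];

  AdjMat best_adj = adj;
  double best = total;

  double T = t_initial;
  long long proposed = 0, accepted = 0;
  int proposed_since_cool = 0, accepted_since_cool = 0;
  int restarts = 0;
  double best_at_last_reanneal = best;
  bool pending_reanneal_check = false;
  std::vector<double> trace;

  while (proposed < (long long)proposal_budget) {
    // propose a move on a random ordered pair
    int u = node_dist(rng), v = node_dist(rng);
    if (u == v) { continue; }
    proposed++;
    proposed_since_cool++;

    int move; // 0 add u->v, 1 delete u->v, 2 reverse u->v
    if (!adj[u][v]) move = 0;
    else move = (unif(rng) < 0.5) ? 1 : 2;

    bool valid = true;
    double delta = 0.0;
    double new_fam_v = 0.0, new_fam_u = 0.0;

    if (move == 0) {
      if (n_parents[v] >= max_parents || has_path(adj, v, u)) valid = false;
      else {
        new_fam_v = cache.score(v, parent_mask(adj, v) | (uint64_t(1) << u));
        delta = new_fam_v - fam[v];
      }
    } else if (move == 1) {
      new_fam_v = cache.score(v, parent_mask(adj, v) & ~(uint64_t(1) << u));
      delta = new_fam_v - fam[v];
    } else {
      if (n_parents[u] >= max_parents) valid = false;
      else {
        adj[u][v] = false;
        bool alt = has_path(adj, u, v);
        adj[u][v] = true;
        if (alt) valid = false;
        else {
          new_fam_v = cache.score(v, parent_mask(adj, v) & ~(uint64_t(1) << u));
          new_fam_u = cache.score(u, parent_mask(adj, u) | (uint64_t(1) << v));
          delta = (new_fam_v - fam[v]) + (new_fam_u - fam[u]);
        }
      }
    }

    if (valid && (delta >= 0.0 || unif(rng) < std::exp(delta / T))) {
      if (move == 0) {
        adj[u][v] = true;
        n_parents[v]++;
        fam[v] = new_fam_v;
      } else if (move == 1) {
        adj[u][v] = false;
        n_parents[v]--;
        fam[v] = new_fam_v;
      } else {
        adj[u][v] = false;
        adj[v][u] = true;
        n_parents[v]--;
        n_parents[u]++;
        fam[v] = new_fam_v;
        fam[u] = new_fam_u;
      }
      total += delta;
      accepted++;
      accepted_since_cool++;
      if (total > best) {
        best = total;
        best_adj = adj;
      }
    }

    if (accepted_since_cool >= max_accepted_before_cooling ||
        proposed_since_cool >= max_proposed_before_cooling) {
      if (accepted_since_cool < min_accepted_before_reanneal) {
        // acceptance stagnated: re-anneal, and restart from a random
        // DAG when the previous re-anneal brought no improvement
        if (pending_reanneal_check && best <= best_at_last_reanneal &&
            restarts < max_restarts) {
          random_restart();
          total = 0.0;
          for (int w = 0; w < n; ++w) total += fam[w];
          if (total > best) { best = total; best_adj = adj; }
          T = t_initial;
          restarts++;
          pending_reanneal_check = false;
        } else {
          T = t_reanneal;
          pending_reanneal_check = true;
        }
        best_at_last_reanneal = best;
      } else {
        T *= cooling_factor;
      }
      trace.push_back(best);
      accepted_since_cool = 0;
      proposed_since_cool = 0;
    }
  }

  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) out(i, j) = best_adj[i][j] ? 1 : 0;
  return List::create(_["adjacency"] = out, _["score"] = best,
                      _["n_proposed"] = (double)proposed,
                      _["n_accepted"] = (double)accepted,
                      _["n_restarts"] = restarts,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}

// [[Rcpp::export(name = ".cpp_exhaustive_search")]]
List cpp_exhaustive_search(IntegerMatrix data, IntegerVector levels,
                           double ess) {
  const int n = levels.size();
  if (n > 5) stop("exhaustive search refuses more than 5 nodes");
  if (n < 1) stop("need at least 1 node");
  // precompute all family scores
  FamilyCache cache(data, levels, ess);
  const int n_edges = n * (n - 1);
  std::vector<std::pair<int, int>> edges;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j) edges.push_back({i, j});

  double best = R_NegInf;
  uint64_t best_mask = 0;
  long long n_dags = 0;
  const uint64_t top = uint64_t(1) << n_edges;
  std::vector<uint64_t> pmask(n);
  std::vector<int> indeg(n);
  for (uint64_t mask = 0; mask < top; ++mask) {
    std::fill(pmask.begin(), pmask.end(), 0);
    for (int e = 0; e < n_edges; ++e)
      if (mask & (uint64_t(1) << e))
        pmask[edges[e].second] |= (uint64_t(1) << edges[e].first);
    // acyclicity by repeated source elimination
    uint64_t alive = (uint64_t(1) << n) - 1;
    bool progress = true;
    while (alive && progress) {
      progress = false;
      for (int v = 0; v < n; ++v) {
        if ((alive & (uint64_t(1) << v)) && (pmask[v] & alive) == 0) {
          alive &= ~(uint64_t(1) << v);
          progress = true;
        }
      }
    }
    if (alive) continue; // cyclic
    n_dags++;
    double s = 0.0;
    for (int v = 0; v < n; ++v) s += cache.score(v, pmask[v]);
    if (s > best) {
      best = s;
      best_mask = mask;
    }
  }
  IntegerMatrix out(n, n);
  for (int e = 0; e < n_edges; ++e)
    if (best_mask & (uint64_t(1) << e))
      out(edges[e].first, edges[e].second) = 1;
  return List::create(_["adjacency"] = out, _["score"] = best,
                      _["n_dags"] = (double)n_dags);
}
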