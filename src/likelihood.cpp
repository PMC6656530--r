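// Core numerics for the noisy censored random walk model:
//  - exact list/corpus log-likelihood via absorbing-chain fundamental matrices
//  - grid search over the emission probability p_emit
//  - MAP stochastic edge-toggle search
//  - bulk walk simulation (shares R's RNG stream for determinism)
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Log-likelihood of one censored list given adjacency G (via its transition
// matrix A and degrees). uidx: 0-based node indices of the list's unique
// items in first-occurrence order; upos: 0-based index into uidx for every
// emission. Lost mass to unlisted nodes is intentional: that mass
// corresponds to emitting an item outside this list.
static double list_loglik(const arma::mat& A, const arma::vec& deg, double twoE,
                          const arma::uvec& uidx, const arma::uvec& upos,
                          double p) {
  if (twoE <= 0.0) return NEG_INF;
  for (arma::uword k = 0; k < uidx.n_elem; ++k)
    if (deg(uidx(k)) <= 0.0) return NEG_INF;  // isolated listed node: walk undefined

  // initial item: stationary probability degree / 2|E|
  double ll = std::log(deg(uidx(upos(0))) / twoE);
  if (upos.n_elem == 1) return ll;

  const arma::mat Al = A.submat(uidx, uidx);  // list-order restriction of A
  arma::uword s = 1;                          // unique items observed so far
  for (arma::uword n = 1; n < upos.n_elem; ++n) {
    const arma::uword i = upos(n);      // target (unique index)
    const arma::uword j = upos(n - 1);  // last emitted item (walker position)
    arma::vec col(s);
    if (i < s) {
      // perseveration: column of R' = p_emit * Q[, i]
      col = p * Al(arma::span(0, s - 1), arma::span(i, i));
    } else {
      // new item: column of R
      col = Al(arma::span(0, s - 1), arma::span(i, i));
    }
    double prob;
    if (s == 1) {
      prob = col(0);  // Q' is the 1x1 zero matrix (no self-loops), E = 1
    } else {
      arma::mat M = arma::eye(s, s) -
        (1.0 - p) * Al(arma::span(0, s - 1), arma::span(0, s - 1));
      arma::vec z;
      const bool ok = arma::solve(z, M, col, arma::solve_opts::no_approx);
      if (!ok || !z.is_finite()) return NEG_INF;           // E does not exist
      if (arma::norm(M * z - col, "inf") > 1e-8) return NEG_INF;
      prob = z(j);
    }
    if (!(prob > 0.0)) return NEG_INF;
    ll += std::log(prob);
    if (i == s) ++s;
  }
  return ll;
}

static arma::mat transition_from_adjacency(const arma::mat& G, arma::vec& deg) {
  deg = arma::sum(G, 1);
  arma::mat A = G;
  for (arma::uword i = 0; i < G.n_rows; ++i)
    if (deg(i) > 0.0) A.row(i) /= deg(i);
  return A;
}

static double corpus_ll(const arma::mat& A, const arma::vec& deg, double twoE,
                        const List& uidx, const List& upos, double p) {
  double total = 0.0;
  const int L = uidx.size();
  for (int l = 0; l < L; ++l) {
    const arma::uvec ui = as<arma::uvec>(uidx[l]);
    const arma::uvec up = as<arma::uvec>(upos[l]);
    const double ll = list_loglik(A, deg, twoE, ui, up, p);
    if (ll == NEG_INF) return NEG_INF;
    total += ll;
  }
  return total;
}

// [[Rcpp::export]]
double cpp_corpus_loglik(const arma::mat& G, const List& uidx, const List& upos,
                         double p) {
  arma::vec deg;
  const arma::mat A = transition_from_adjacency(G, deg);
  return corpus_ll(A, deg, arma::accu(deg), uidx, upos, p);
}

// [[Rcpp::export]]
arma::vec cpp_pemit_grid(const arma::mat& G, const List& uidx, const List& upos,
                         const arma::vec& grid) {
  arma::vec deg;
  const arma::mat A = transition_from_adjacency(G, deg);
  const double twoE = arma::accu(deg);
  arma::vec out(grid.n_elem);
  for (arma::uword g = 0; g < grid.n_elem; ++g)
    out(g) = corpus_ll(A, deg, twoE, uidx, upos, grid(g));
  return out;
}

// grid fit with ties broken toward the smaller p value; returns index or -1
// when every grid value has -Inf likelihood
static int grid_fit(const arma::mat& G, const List& uidx, const List& upos,
                    const arma::vec& grid, double& best_ll) {
  arma::vec deg;
  const arma::mat A = transition_from_adjacency(G, deg);
  const double twoE = arma::accu(deg);
  best_ll = NEG_INF;
  int best = -1;
  for (arma::uword g = 0; g < grid.n_elem; ++g) {
    const double ll = corpus_ll(A, deg, twoE, uidx, upos, grid(g));
    if (ll > best_ll) { best_ll = ll; best = (int)g; }
  }
  return best;
}

// MAP search: propose an edge toggle, accept iff the log posterior strictly
// increases (evaluated at the current p_emit, or at the grid optimum while
// the current state has -Inf likelihood); re-fit p_emit by full grid search
// after each acceptance. Converged after `patience` consecutive
// non-improving proposals. Uses R's RNG.
// [[Rcpp::export]]
List cpp_estimate(arma::mat G, const arma::mat& prior_lo, double logprior,
                  const List& uidx, const List& upos, const arma::vec& grid,
                  int patience, int max_iter, const arma::umat& cooc,
                  double cooc_prob) {
  const arma::uword M = G.n_rows;
  const double grid_const = -std::log((double)grid.n_elem);  // uniform p_emit prior

  double ll;
  int pidx = grid_fit(G, uidx, upos, grid, ll);
  double p = (pidx >= 0) ? grid(pidx) : grid(0);
  double logpost = (ll == NEG_INF) ? NEG_INF : ll + logprior + grid_const;

  std::vector<int> trace_iter;
  std::vector<double> trace_lp;
  int since = 0, accepted = 0, iter = 0;
  bool converged = false;

  while (iter < max_iter) {
    ++iter;
    // choose a pair: co-occurring pair with prob cooc_prob, else uniform
    arma::uword i, j;
    if (cooc.n_rows > 0 && unif_rand() < cooc_prob) {
      const arma::uword r = std::min((arma::uword)(unif_rand() * cooc.n_rows),
                                     cooc.n_rows - 1);
      i = cooc(r, 0); j = cooc(r, 1);
    } else {
      i = std::min((arma::uword)(unif_rand() * M), M - 1);
      j = std::min((arma::uword)(unif_rand() * (M - 1)), M - 2);
      if (j >= i) ++j;
    }
    // toggle
    const double newval = 1.0 - G(i, j);
    G(i, j) = newval; G(j, i) = newval;
    const double dprior = (newval > 0.5) ? prior_lo(i, j) : -prior_lo(i, j);

    bool accept;
    double ll_new, lp_new;
    int pidx_new = pidx;
    if (logpost == NEG_INF) {
      // escape route: evaluate the proposal at its own grid optimum
      pidx_new = grid_fit(G, uidx, upos, grid, ll_new);
      lp_new = (ll_new == NEG_INF) ? NEG_INF : ll_new + logprior + dprior + grid_const;
      accept = lp_new > logpost;
    } else {
      ll_new = cpp_corpus_loglik(G, uidx, upos, p);
      lp_new = (ll_new == NEG_INF) ? NEG_INF : ll_new + logprior + dprior + grid_const;
      accept = lp_new > logpost;
    }

    if (accept) {
      logprior += dprior;
      // full grid re-fit after the successful toggle
      pidx = grid_fit(G, uidx, upos, grid, ll);
      p = (pidx >= 0) ? grid(pidx) : p;
      logpost = (ll == NEG_INF) ? NEG_INF : ll + logprior + grid_const;
      ++accepted;
      since = 0;
      trace_iter.push_back(iter);
      trace_lp.push_back(logpost);
    } else {
      G(i, j) = 1.0 - newval; G(j, i) = 1.0 - newval;  // revert
      if (++since >= patience) { converged = true; break; }
    }
  }

  return List::create(_["adjacency"] = G, _["p_emit"] = p,
                      _["log_likelihood"] = ll, _["log_prior"] = logprior,
                      _["log_posterior"] = logpost,
                      _["trace_iter"] = trace_iter, _["trace_lp"] = trace_lp,
                      _["n_proposals"] = iter, _["n_accepted"] = accepted,
                      _["converged"] = converged);
}

static std::vector<std::vector<int>> neighbor_lists(const arma::mat& G) {
  std::vector<std::vector<int>> nb(G.n_rows);
  for (arma::uword i = 0; i < G.n_rows; ++i)
    for (arma::uword j = 0; j < G.n_cols; ++j)
      if (G(i, j) > 0.0) nb[i].push_back((int)j);
  return nb;
}

// Simulate one noisy censored walk until n_emit emissions. start0 < 0 draws
// the start from the stationary distribution (degree-proportional); first
// visits always emit, revisits emit with probability p. Returns 0-based
// emitted node indices.
// [[Rcpp::export]]
IntegerVector cpp_simulate_list(const arma::mat& G, double p, int n_emit,
                                int start0, double max_steps) {
  const arma::uword M = G.n_rows;
  const std::vector<std::vector<int>> nb = neighbor_lists(G);
  arma::vec deg = arma::sum(G, 1);
  const double twoE = arma::accu(deg);
  if (twoE <= 0.0) stop("network has no edges");

  int cur;
  if (start0 < 0) {
    double u = unif_rand() * twoE, acc = 0.0;
    cur = (int)M - 1;
    for (arma::uword i = 0; i < M; ++i) {
      acc += deg(i);
      if (u <= acc) { cur = (int)i; break; }
    }
  } else {
    cur = start0;
  }
  if (deg(cur) <= 0.0) stop("start node is isolated");

  std::vector<bool> visited(M, false);
  std::vector<int> out;
  out.reserve(n_emit);
  visited[cur] = true;
  out.push_back(cur);
  double steps = 0.0;
  while ((int)out.size() < n_emit) {
    if (++steps > max_steps)
      stop("emission target not reached within max_steps (unreachable under p_emit?)");
    const std::vector<int>& nbs = nb[cur];
    const int k = std::min((int)(unif_rand() * nbs.size()),
                           (int)nbs.size() - 1);
    cur = nbs[k];
    if (!visited[cur]) {
      visited[cur] = true;
      out.push_back(cur);
    } else if (unif_rand() < p) {
      out.push_back(cur);
    }
  }
  return wrap(out);
}

// Bulk simulation of n_lists independent lists (stationary starts);
// returns an n_lists x n_emit matrix of 0-based node indices.
// [[Rcpp::export]]
IntegerMatrix cpp_simulate_lists(const arma::mat& G, double p, int n_emit,
                                 int n_lists, double max_steps) {
  IntegerMatrix out(n_lists, n_emit);
  for (int l = 0; l < n_lists; ++l) {
    IntegerVector li = cpp_simulate_list(G, p, n_emit, -1, max_steps);
    for (int k = 0; k < n_emit; ++k) out(l, k) = li[k];
  }
  return out;
}

// Monte-Carlo distribution of the NEXT emitted item: start the walk at
// start0 with `visited0` already observed, run until the next emission.
// Returns counts per node plus one trailing count of walks that never
// emitted within max_steps.
// [[Rcpp::export]]
IntegerVector cpp_next_emission_counts(const arma::mat& G, double p, int start0,
                                       const IntegerVector& visited0,
                                       int n_reps, double max_steps) {
  const arma::uword M = G.n_rows;
  const std::vector<std::vector<int>> nb = neighbor_lists(G);
  IntegerVector counts(M + 1);
  for (int r = 0; r < n_reps; ++r) {
    std::vector<bool> visited(M, false);
    for (int v : visited0) visited[v] = true;
    int cur = start0;
    double steps = 0.0;
    int emitted = -1;
    while (steps++ < max_steps) {
      const std::vector<int>& nbs = nb[cur];
      if (nbs.empty()) break;
      const int k = std::min((int)(unif_rand() * nbs.size()),
                             (int)nbs.size() - 1);
      cur = nbs[k];
      if (!visited[cur]) { emitted = cur; break; }
      if (unif_rand() < p) { emitted = cur; break; }
    }
    if (emitted >= 0) counts[emitted]++; else counts[M]++;
  }
  return counts;
}
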