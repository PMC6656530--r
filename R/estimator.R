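#' Unnormalized log posterior of a network and emission probability
#'
#' `corpus_log_likelihood + network_log_prior + log P(p_emit)`, where the
#' prior over `p_emit` is uniform on the 101-point grid (a constant,
#' included for completeness).
#'
#' @param net semantic network whose nodes cover the corpus vocabulary.
#' @param p_emit emission probability.
#' @param corpus a [fluency_corpus()].
#' @param prior an [edge_prior()].
#' @param pemit_grid the grid defining the uniform `p_emit` prior.
#' @return log posterior (possibly `-Inf`).
#' @export
log_posterior <- function(net, p_emit, corpus, prior,
                          pemit_grid = seq(0, 1, by = 0.01)) {
  corpus_log_likelihood(corpus, net, p_emit) +
    network_log_prior(net, prior) - log(length(pemit_grid))
}

#' Grid search for the emission probability
#'
#' Maximizes the corpus log-likelihood over the `p_emit` grid
#' `{0.00, 0.01, ..., 1.00}` given a fixed network; ties are broken toward
#' the smaller value.
#'
#' @param net semantic network.
#' @param corpus a [fluency_corpus()].
#' @param pemit_grid candidate values.
#' @return list with `p_emit` (the maximizer) and `log_likelihood`; errors
#'   when every grid value has `-Inf` likelihood.
#' @export
fit_pemit <- function(net, corpus, pemit_grid = seq(0, 1, by = 0.01)) {
  nodes <- igraph::V(net)$name
  if (!all(corpus$vocabulary %in% nodes))
    stop("corpus vocabulary must be a subset of the network nodes")
  enc <- prepare_corpus(corpus, nodes)
  lls <- cpp_pemit_grid(network_adjacency(net),
                        lapply(enc, `[[`, "uidx"), lapply(enc, `[[`, "upos"),
                        pemit_grid)
  if (all(is.infinite(lls) & lls < 0))
    stop("estimation failure: every p_emit grid value has -Inf likelihood")
  best <- which.max(lls)  # first maximum = smallest p on an ascending grid
  list(p_emit = pemit_grid[best], log_likelihood = lls[best])
}

#' Naive adjacent-pair network
#'
#' Links every pair of items that appear adjacently in any list of the
#' corpus. Used as the initial state of the MAP search (any observed
#' transition then has an edge, so every list has finite likelihood at
#' `p_emit > 0`) and as a baseline in recovery benchmarks.
#'
#' @param corpus a [fluency_corpus()].
#' @return semantic network on the corpus vocabulary.
#' @export
naive_network <- function(corpus) {
  edges <- do.call(rbind, lapply(corpus$lists, function(fl) {
    it <- fl$items
    if (length(it) < 2L) return(NULL)
    cbind(it[-length(it)], it[-1])
  }))
  if (!is.null(edges)) edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  semantic_network(edges = edges, nodes = corpus$vocabulary)
}

# internal: unique unordered pairs (0-based index matrix) co-occurring
# within some list; proposal pool for the search heuristic
cooccurrence_pairs <- function(corpus, nodes) {
  pairs <- do.call(rbind, lapply(corpus$lists, function(fl) {
    u <- unique(match(fl$items, nodes))
    if (length(u) < 2L) return(NULL)
    t(utils::combn(sort(u), 2L))
  }))
  if (is.null(pairs)) return(matrix(0L, 0L, 2L))
  unique(pairs) - 1L
}

#' MAP estimation of a semantic network
#'
#' Greedy stochastic ascent on the posterior of Eq-style
#' `P(G, p_emit | X)`: repeatedly propose toggling one node pair (with
#' probability `cooc_prob` a pair co-occurring within some list, otherwise
#' a uniformly random pair) and accept the toggle iff the log posterior
#' strictly increases. After each accepted toggle `p_emit` is re-fitted by
#' a full grid search. The search converges after `patience` (default 300)
#' consecutive non-improving proposals. The search starts from the
#' [naive_network()] of the corpus and is fully deterministic given `seed`.
#'
#' @param corpus a [fluency_corpus()].
#' @param prior an [edge_prior()]; defaults to a reference-free prior under
#'   which every pair has probability 0.5 (a flat prior over graphs).
#' @param seed integer seed for the search RNG; `NULL` uses the ambient RNG
#'   state.
#' @param max_iters proposal budget.
#' @param patience consecutive non-improving proposals declaring
#'   convergence.
#' @param pemit_grid grid for the emission probability.
#' @param cooc_prob probability of proposing a co-occurring pair.
#' @return object of class `estimation_result`: `network`, `p_emit`,
#'   `log_posterior`, `log_likelihood`, `log_prior`, `trace` (data frame of
#'   accepted-toggle iteration and log posterior), `seed`, `converged`,
#'   `n_proposals`, `n_accepted`.
#' @export
estimate_network <- function(corpus, prior = edge_prior(), seed = NULL,
                             max_iters = 20000L, patience = 300L,
                             pemit_grid = seq(0, 1, by = 0.01),
                             cooc_prob = 0.5) {
  if (length(corpus$lists) < 1L) stop("corpus must contain at least one list")
  if (!is.null(seed)) set.seed(seed)
  nodes <- corpus$vocabulary
  enc <- prepare_corpus(corpus, nodes)
  uidx <- lapply(enc, `[[`, "uidx")
  upos <- lapply(enc, `[[`, "upos")

  init <- naive_network(corpus)
  G0 <- network_adjacency(init, nodes = nodes)
  P1 <- prior_p1_matrix(nodes, prior)
  lo <- log(P1) - log1p(-P1)             # log-odds of each pair
  lo[is.na(lo)] <- 0
  up <- upper.tri(P1)
  logprior0 <- if (length(nodes) > 1L)
    sum(ifelse(G0[up] == 1, log(P1[up]), log1p(-P1[up]))) else 0

  fit <- cpp_estimate(G0, lo, logprior0, uidx, upos, pemit_grid,
                      as.integer(patience), as.integer(max_iters),
                      cooccurrence_pairs(corpus, nodes), cooc_prob)
  if (is.infinite(fit$log_posterior))
    stop("estimation failure: no finite-posterior network found within max_iters")
  net <- igraph::graph_from_adjacency_matrix(
    matrix(fit$adjacency, length(nodes), length(nodes),
           dimnames = list(nodes, nodes)),
    mode = "undirected")
  structure(list(network = net, p_emit = fit$p_emit,
                 log_posterior = fit$log_posterior,
                 log_likelihood = fit$log_likelihood,
                 log_prior = fit$log_prior,
                 trace = data.frame(iteration = as.integer(fit$trace_iter),
                                    log_posterior = fit$trace_lp),
                 seed = seed, converged = fit$converged,
                 n_proposals = fit$n_proposals, n_accepted = fit$n_accepted),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf(
    paste0("<estimation_result: %d nodes, %d edges, p_emit=%.2f, ",
           "log posterior=%.3f, %s after %d proposals (%d accepted)>\n"),
    igraph::vcount(x$network), igraph::ecount(x$network), x$p_emit,
    x$log_posterior, if (x$converged) "converged" else "stopped",
    x$n_proposals, x$n_accepted))
  invisible(x)
}

#' Edge-recovery precision/recall/F1 against a true network
#'
#' Compares edge sets over the union of both node sets (an edge counts as
#' recovered only if both endpoints match by label).
#'
#' @param estimated,truth semantic networks.
#' @return named numeric vector `precision`, `recall`, `f1`.
#' @export
edge_recovery <- function(estimated, truth) {
  ekey <- function(g) {
    el <- igraph::as_edgelist(g, names = TRUE)
    if (nrow(el) == 0L) return(character(0))
    apply(cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])), 1,
          paste, collapse = "\r")
  }
  e <- ekey(estimated); t <- ekey(truth)
  tp <- length(intersect(e, t))
  precision <- if (length(e)) tp / length(e) else NA_real_
  recall <- if (length(t)) tp / length(t) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}
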