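#' Transition matrix of a random walk on a semantic network
#'
#' Row-stochastic matrix `A[i, j] = G[i, j] / degree(i)` over the full node
#' set. Rows of isolated nodes are left at zero and flagged via the
#' `"isolated"` attribute; a walk starting from such a node is undefined and
#' any list visiting one has probability zero.
#'
#' @param net semantic network.
#' @return matrix with attribute `isolated` (named logical vector).
#' @export
build_transition_matrix <- function(net) {
  G <- network_adjacency(net)
  deg <- rowSums(G)
  A <- G
  nz <- deg > 0
  A[nz, ] <- G[nz, , drop = FALSE] / deg[nz]
  attr(A, "isolated") <- deg == 0
  A
}

#' Stationary probability of an initial item
#'
#' The probability of the first item of a list is the stationary
#' distribution of the walk: `degree(item) / (2 * ecount)`.
#'
#' @param net semantic network with at least one edge.
#' @param item node label.
#' @return probability.
#' @export
initial_item_prob <- function(net, item) {
  validate_network(net)
  if (!item %in% igraph::V(net)$name) stop("item is not a node of the network: ", item)
  m <- igraph::ecount(net)
  if (m < 1L) stop("network has no edges; the stationary distribution is undefined")
  unname(igraph::degree(net, item) / (2 * m))
}

#' Probability of the next emitted item
#'
#' Exact probability that, starting the walk at the last emitted item of
#' `prefix`, the next *emitted* item is `next_item`. Previously observed
#' items re-emit with probability `p_emit` per visit (a perseveration);
#' probability mass flowing to nodes that are neither in the prefix nor
#' equal to `next_item` is lost (it corresponds to emitting a different
#' item). Computed with the fundamental matrix `E = (I - Q')^-1` of the
#' censored absorbing chain, where `Q' = (1 - p_emit) Q` collects censored
#' moves among observed items and the target column of
#' `R' = [p_emit * Q, R]` carries the emission. Returns 0 when `I - Q'` is
#' singular or the target is unreachable.
#'
#' @param prefix character vector of items emitted so far (repeats allowed).
#' @param next_item candidate next item (new node or a repeat).
#' @param net semantic network containing all involved items.
#' @param p_emit emission probability in `[0, 1]`.
#' @return probability.
#' @export
transition_prob <- function(prefix, next_item, net, p_emit) {
  if (length(prefix) < 1L) stop("prefix must be non-empty")
  if (!is.numeric(p_emit) || p_emit < 0 || p_emit > 1)
    stop("p_emit must lie in [0, 1]")
  A <- build_transition_matrix(net)
  items <- c(prefix, next_item)
  if (!all(items %in% rownames(A)))
    stop("all items must be nodes of the network")
  if (any(attr(A, "isolated")[unique(items)])) return(0)
  uniq <- unique(prefix)
  s <- length(uniq)
  j <- match(prefix[length(prefix)], uniq)
  persev <- next_item %in% uniq
  colv <- as.numeric(A[uniq, next_item])   # restriction of A's column to observed rows
  if (persev) colv <- p_emit * colv        # re-emission column of R' = [p_emit*Q, R]
  if (s == 1L) return(colv[1])  # Q' is 1x1 zero (no self-loops)
  Qp <- (1 - p_emit) * A[uniq, uniq, drop = FALSE]
  M <- diag(s) - Qp
  z <- tryCatch(solve(M, colv), error = function(e) NULL)
  if (is.null(z) || any(!is.finite(z))) return(0)
  if (max(abs(M %*% z - colv)) > 1e-8) return(0)
  max(z[j], 0)
}

#' Distribution over the next emitted item
#'
#' Evaluates [transition_prob()] for every node of the network (new items
#' and perseverations alike). When the prefix together with the candidates
#' covers all nodes and `p_emit > 0`, the probabilities sum to 1; when
#' unlisted nodes would remain, the sum is below 1 by the lost mass.
#'
#' @inheritParams transition_prob
#' @return named numeric vector over all nodes.
#' @export
next_emission_distribution <- function(prefix, net, p_emit) {
  nodes <- igraph::V(net)$name
  setNames(vapply(nodes, function(x) transition_prob(prefix, x, net, p_emit),
                  numeric(1)), nodes)
}

#' Log-likelihood of a fluency list
#'
#' `log P(X_1 | G) + sum_n log P(X_n | X_1..X_{n-1}, G, p_emit)`:
#' the stationary probability of the initial item plus the log of every
#' subsequent transition probability under the noisy censored walk. Exactly
#' `-Inf` when any factor is zero — in particular, with `p_emit = 0` any
#' list containing a repeat is impossible.
#'
#' @param fl a [fluency_list()] (or plain character vector of items).
#' @param net semantic network containing all list items.
#' @param p_emit emission probability.
#' @return log-probability (possibly `-Inf`).
#' @export
list_log_likelihood <- function(fl, net, p_emit) {
  items <- if (inherits(fl, "fluency_list")) fl$items else as.character(fl)
  if (length(items) < 1L) stop("empty list")
  if (!is.numeric(p_emit) || p_emit < 0 || p_emit > 1)
    stop("p_emit must lie in [0, 1]")
  nodes <- igraph::V(net)$name
  corp <- fluency_corpus("x", list(fluency_list("x", "l", items)))
  enc <- prepare_corpus(corp, nodes)
  G <- network_adjacency(net)
  cpp_corpus_loglik(G, lapply(enc, `[[`, "uidx"), lapply(enc, `[[`, "upos"),
                    p_emit)
}

#' Log-likelihood of a fluency corpus
#'
#' Sum of per-list log-likelihoods; invariant to the order of lists.
#'
#' @param corpus a [fluency_corpus()].
#' @inheritParams list_log_likelihood
#' @return log-probability (possibly `-Inf`).
#' @export
corpus_log_likelihood <- function(corpus, net, p_emit) {
  if (!is.numeric(p_emit) || p_emit < 0 || p_emit > 1)
    stop("p_emit must lie in [0, 1]")
  nodes <- igraph::V(net)$name
  if (!all(corpus$vocabulary %in% nodes))
    stop("corpus vocabulary must be a subset of the network nodes")
  enc <- prepare_corpus(corpus, nodes)
  G <- network_adjacency(net)
  cpp_corpus_loglik(G, lapply(enc, `[[`, "uidx"), lapply(enc, `[[`, "upos"),
                    p_emit)
}
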