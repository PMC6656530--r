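#' Build a reference association network from cue-response pairs
#'
#' Adjoins each cue-response pair with an undirected edge; duplicate and
#' reversed pairs collapse, self-pairs are ignored. Typically used with
#' pairs extracted from free-association norms (e.g., the USF norms).
#'
#' @param pairs two-column matrix or data frame of labels.
#' @return semantic network. Empty input yields an empty reference (every
#'   node pair is then "unknown" to the prior).
#' @export
build_reference_from_pairs <- function(pairs) {
  if (is.null(pairs) || NROW(pairs) == 0L) return(semantic_network())
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "character"
  pairs[, 1] <- normalize_label(pairs[, 1])
  pairs[, 2] <- normalize_label(pairs[, 2])
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0L) return(semantic_network())
  semantic_network(edges = pairs)
}

#' Edge-wise network prior
#'
#' The prior probability of an edge is Bernoulli according to its status in
#' a reference association network: `p_in_ref` when the pair is an edge of
#' the reference, `p_out_ref` when both labels are reference nodes but not
#' adjacent, and `p_unknown` when either label is absent from the
#' reference. The defaults (2/3, 0.4, 0.5) are the fixed-prior reduction of
#' a hierarchical edge model fitted against the USF free-association
#' network.
#'
#' @param reference semantic network (may be empty / NULL).
#' @param p_in_ref,p_out_ref,p_unknown edge probabilities in (0, 1).
#' @return object of class `edge_prior`.
#' @export
edge_prior <- function(reference = NULL, p_in_ref = 2 / 3, p_out_ref = 0.4,
                       p_unknown = 0.5) {
  if (is.null(reference)) reference <- semantic_network()
  validate_network(reference)
  ps <- c(p_in_ref, p_out_ref, p_unknown)
  if (any(ps <= 0) || any(ps >= 1))
    stop("prior edge probabilities must lie strictly inside (0, 1)")
  structure(list(reference = reference, p_in_ref = p_in_ref,
                 p_out_ref = p_out_ref, p_unknown = p_unknown),
            class = "edge_prior")
}

#' @export
print.edge_prior <- function(x, ...) {
  cat(sprintf(
    "<edge_prior: reference %d nodes / %d edges; p(in)=%.3f p(out)=%.3f p(unknown)=%.3f>\n",
    igraph::vcount(x$reference), igraph::ecount(x$reference),
    x$p_in_ref, x$p_out_ref, x$p_unknown))
  invisible(x)
}

# internal: matrix of P(G_ij = 1) for every pair of `nodes` under the prior
prior_p1_matrix <- function(nodes, prior) {
  n <- length(nodes)
  in_ref <- nodes %in% igraph::V(prior$reference)$name
  P <- matrix(prior$p_unknown, n, n, dimnames = list(nodes, nodes))
  if (any(in_ref)) {
    both <- outer(in_ref, in_ref, `&`)
    P[both] <- prior$p_out_ref
    if (igraph::ecount(prior$reference) > 0) {
      refA <- network_adjacency(prior$reference, nodes = nodes)
      P[both & refA == 1] <- prior$p_in_ref
    }
  }
  diag(P) <- NA_real_
  P
}

#' Log prior probability that an edge is present
#'
#' @param i,j distinct node labels.
#' @param prior an [edge_prior()].
#' @return `log P(G_ij = 1)`.
#' @export
edge_log_prior <- function(i, j, prior) {
  if (identical(as.character(i), as.character(j)))
    stop("self-pairs have no edge prior")
  refnodes <- igraph::V(prior$reference)$name
  if (!(i %in% refnodes) || !(j %in% refnodes)) return(log(prior$p_unknown))
  if (igraph::ecount(prior$reference) > 0 &&
      igraph::are_adjacent(prior$reference, i, j))
    return(log(prior$p_in_ref))
  log(prior$p_out_ref)
}

#' Log prior probability of a network
#'
#' Product over unordered node pairs of the edge-wise Bernoulli prior,
#' using the complement probability for absent edges. Evaluated only over
#' the pairs of the network's own node set (the participant's observed
#' vocabulary).
#'
#' @param net semantic network.
#' @param prior an [edge_prior()].
#' @return log-probability (always finite).
#' @export
network_log_prior <- function(net, prior) {
  nodes <- igraph::V(net)$name
  if (length(nodes) < 2L) return(0)
  P1 <- prior_p1_matrix(nodes, prior)
  G <- network_adjacency(net)
  up <- upper.tri(P1)
  sum(ifelse(G[up] == 1, log(P1[up]), log1p(-P1[up])))
}
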