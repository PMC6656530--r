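#' Simulate a random walk on a semantic network
#'
#' Each step moves to a uniformly random neighbor. With
#' `start = "stationary"` the start node is drawn from the stationary
#' distribution (degree-proportional), matching the model's assumption for
#' initial items.
#'
#' @param net semantic network.
#' @param start node label, or `"stationary"`.
#' @param n_steps number of steps (the returned walk has `n_steps + 1`
#'   nodes).
#' @return character vector of visited node labels.
#' @export
random_walk <- function(net, start = "stationary", n_steps) {
  validate_network(net)
  nodes <- igraph::V(net)$name
  deg <- igraph::degree(net)
  if (identical(start, "stationary")) {
    if (sum(deg) == 0) stop("network has no edges")
    start <- sample(nodes, 1L, prob = deg)
  }
  if (!start %in% nodes) stop("start is not a node of the network")
  if (deg[[start]] == 0L) stop("start node is isolated; the walk is undefined")
  adj <- igraph::adjacent_vertices(net, nodes)
  adj <- lapply(adj, function(v) nodes[as.integer(v)])
  walk <- character(n_steps + 1L)
  walk[1L] <- start
  cur <- start
  for (k in seq_len(n_steps)) {
    nb <- adj[[cur]]
    cur <- if (length(nb) == 1L) nb else sample(nb, 1L)
    walk[k + 1L] <- cur
  }
  walk
}

#' Censor a walk into a fluency list
#'
#' First visits are always emitted; each revisit is emitted independently
#' with probability `p_emit` (a perseveration) and hidden otherwise. With
#' `p_emit = 0` censoring is deterministic and the output is the order of
#' first visits.
#'
#' @param walk character vector of visited nodes.
#' @param p_emit emission probability in `[0, 1]`.
#' @return character vector of emitted items.
#' @export
censor_walk <- function(walk, p_emit) {
  if (!is.numeric(p_emit) || p_emit < 0 || p_emit > 1)
    stop("p_emit must lie in [0, 1]")
  seen <- character(0)
  out <- character(0)
  for (x in walk) {
    if (!x %in% seen) {
      seen <- c(seen, x)
      out <- c(out, x)
    } else if (p_emit > 0 && runif(1) < p_emit) {
      out <- c(out, x)
    }
  }
  out
}

#' Simulate one fluency list
#'
#' Runs a noisy censored random walk from a stationary start until exactly
#' `n_emissions` items have been emitted.
#'
#' @param net semantic network.
#' @param p_emit emission probability.
#' @param n_emissions number of emitted items (>= 1).
#' @param participant_id,list_id identifiers for the returned list.
#' @param max_steps walk-step budget; exceeding it (e.g., `p_emit = 0` with
#'   `n_emissions` above the reachable unique nodes) is an error.
#' @return a [fluency_list()].
#' @export
simulate_list <- function(net, p_emit, n_emissions, participant_id = "sim",
                          list_id = "l1", max_steps = 1e6) {
  validate_network(net)
  if (n_emissions < 1L) stop("n_emissions must be >= 1")
  if (!is.numeric(p_emit) || p_emit < 0 || p_emit > 1)
    stop("p_emit must lie in [0, 1]")
  nodes <- igraph::V(net)$name
  idx <- cpp_simulate_list(network_adjacency(net), p_emit,
                           as.integer(n_emissions), -1L, max_steps)
  fluency_list(participant_id, list_id, nodes[idx + 1L])
}

#' Simulate a fluency corpus
#'
#' @param net semantic network.
#' @param p_emit emission probability.
#' @param n_lists number of lists.
#' @param n_emissions emissions per list (recycled to `n_lists`).
#' @param participant_id identifier.
#' @inheritParams simulate_list
#' @return a [fluency_corpus()].
#' @export
simulate_corpus <- function(net, p_emit, n_lists, n_emissions,
                            participant_id = "sim", max_steps = 1e6) {
  n_emissions <- rep_len(n_emissions, n_lists)
  lists <- lapply(seq_len(n_lists), function(l)
    simulate_list(net, p_emit, n_emissions[l], participant_id,
                  paste0("l", l), max_steps))
  fluency_corpus(participant_id, lists)
}

#' Specification of a two-group synthetic cohort
#'
#' Describes the generating conditions of a healthy-like group A and an
#' impaired-like group B: group B networks are the shared base network plus
#' `spurious_edges` uniformly random non-edges turned on, and the groups
#' may differ in `p_emit`, lists per participant and emissions per list.
#'
#' @param n_nodes number of base-network nodes.
#' @param base_type `"smallworld"` (default) for a Watts-Strogatz ring —
#'   the canonical model of the clustered, short-path structure reported
#'   for healthy semantic networks — or `"random"` for an Erdos-Renyi
#'   `G(n, m)` graph. Both are resampled until connected.
#' @param base_edges edge count of the `"random"` base.
#' @param ws_nei,ws_p Watts-Strogatz ring neighborhood (each node links to
#'   its `ws_nei` nearest neighbors on each side) and rewiring probability.
#' @param group_a,group_b lists with elements `n_participants`, `n_lists`,
#'   `n_emissions`, `p_emit`, `spurious_edges`.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_nodes = 15, base_type = c("smallworld", "random"),
                        base_edges = 22, ws_nei = 2, ws_p = 0.05,
                        group_a = list(n_participants = 10, n_lists = 14,
                                       n_emissions = 12, p_emit = 0.05,
                                       spurious_edges = 0),
                        group_b = list(n_participants = 10, n_lists = 6,
                                       n_emissions = 9, p_emit = 0.3,
                                       spurious_edges = 12)) {
  base_type <- match.arg(base_type)
  defaults <- list(n_participants = 10, n_lists = 14, n_emissions = 12,
                   p_emit = 0.05, spurious_edges = 0)
  group_a <- modifyList(defaults, group_a)
  group_b <- modifyList(defaults, group_b)
  for (g in list(group_a, group_b)) {
    if (g$n_participants < 1 || g$n_lists < 1 || g$n_emissions < 1)
      stop("all cohort counts must be positive")
    if (g$p_emit < 0 || g$p_emit > 1) stop("p_emit must lie in [0, 1]")
    if (g$spurious_edges < 0) stop("spurious_edges must be non-negative")
  }
  structure(list(n_nodes = n_nodes, base_type = base_type,
                 base_edges = base_edges, ws_nei = ws_nei, ws_p = ws_p,
                 group_a = group_a, group_b = group_b),
            class = "cohort_spec")
}

# internal: connected base network with generic labels
random_base_network <- function(n_nodes, n_edges, type = "random",
                                ws_nei = 2, ws_p = 0.1) {
  labels <- sprintf("item%02d", seq_len(n_nodes))
  for (try in 1:100) {
    g <- if (type == "smallworld")
      igraph::simplify(igraph::sample_smallworld(1, n_nodes, ws_nei, ws_p))
    else igraph::sample_gnm(n_nodes, n_edges)
    if (igraph::is_connected(g)) {
      g <- igraph::set_vertex_attr(g, "name", value = labels)
      return(g)
    }
  }
  stop("could not draw a connected base network; increase its connectivity")
}

# internal: add k uniformly random non-edges
add_spurious_edges <- function(net, k) {
  if (k == 0) return(net)
  nodes <- igraph::V(net)$name
  G <- network_adjacency(net)
  up <- which(upper.tri(G) & G == 0, arr.ind = TRUE)
  if (nrow(up) < k)
    stop("requested spurious edges exceed the available non-edges")
  pick <- up[sample.int(nrow(up), k), , drop = FALSE]
  igraph::add_edges(net, t(cbind(nodes[pick[, 1]], nodes[pick[, 2]])))
}

#' Simulate a two-group cohort of fluency corpora
#'
#' Draws one connected base network, derives each participant's true
#' network (group B gets its spurious edges, drawn independently per
#' participant), and simulates their fluency corpus by noisy censored
#' walks. The full truth record is returned alongside the corpora.
#'
#' @param spec a [cohort_spec()].
#' @param seed master seed; per-participant seeds are spawned from it so
#'   the whole cohort is reproducible.
#' @return list with `corpora` (named list of [fluency_corpus()]), and
#'   `truth` — a data frame (participant_id, group, p_emit, n_lists,
#'   n_emissions, n_true_edges) plus a named list `networks` of true
#'   networks.
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  base <- random_base_network(spec$n_nodes, spec$base_edges, spec$base_type,
                              spec$ws_nei, spec$ws_p)
  corpora <- list()
  networks <- list()
  rows <- list()
  for (gname in c("a", "b")) {
    g <- spec[[paste0("group_", gname)]]
    for (i in seq_len(g$n_participants)) {
      pid <- sprintf("%s%02d", toupper(gname), i)
      net <- add_spurious_edges(base, g$spurious_edges)
      corpora[[pid]] <- simulate_corpus(net, g$p_emit, g$n_lists,
                                        g$n_emissions, participant_id = pid)
      networks[[pid]] <- net
      rows[[pid]] <- data.frame(participant_id = pid, group = toupper(gname),
                                p_emit = g$p_emit, n_lists = g$n_lists,
                                n_emissions = g$n_emissions,
                                n_true_edges = igraph::ecount(net),
                                stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  list(corpora = corpora, truth = truth, networks = networks, base = base)
}
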