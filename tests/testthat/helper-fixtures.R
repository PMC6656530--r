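# Shared fixtures and independent oracles used across the suite.

path_net <- function(labels = c("a", "b", "c")) {
  semantic_network(cbind(labels[-length(labels)], labels[-1]))
}

complete_net <- function(n, labels = letters[seq_len(n)]) {
  semantic_network(t(utils::combn(labels, 2)))
}

star_net <- function(k = 3) {
  semantic_network(cbind("hub", paste0("leaf", seq_len(k))))
}

# connected Erdos-Renyi G(n, m) fixture
random_connected_net <- function(n, m, seed) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnm(n, m)
    if (igraph::is_connected(g)) break
  }
  igraph::set_vertex_attr(g, "name", value = paste0("n", seq_len(n)))
}

toy_corpus <- function(lists, pid = "p1") {
  fluency_corpus(pid, lapply(seq_along(lists), function(i)
    fluency_list(pid, paste0("l", i), lists[[i]])))
}

# ---- independent brute-force network-measure oracle (BFS + triangle count)

bfs_distances <- function(A, from) {
  n <- nrow(A)
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  frontier <- from
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(A[v, ] == 1 & is.na(dist))
      dist[nb] <- d
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  dist
}

brute_measures <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  m <- sum(A) / 2
  # largest component via BFS
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (is.na(comp[v])) {
      cid <- cid + 1L
      comp[!is.na(bfs_distances(A, v))] <- cid
    }
  }
  giant <- which(comp == which.max(tabulate(comp)))
  D <- NA_real_; L <- NA_real_
  if (length(giant) >= 2) {
    dmat <- sapply(giant, function(v) bfs_distances(A, v)[giant])
    D <- max(dmat)
    L <- mean(dmat[upper.tri(dmat)])
  }
  triangles <- sum(diag(A %*% A %*% A)) / 6
  triplets <- sum(deg * (deg - 1) / 2)
  list(n_nodes = n, n_edges = m,
       density = if (n >= 2) m / (n * (n - 1) / 2) else NA_real_,
       mean_degree = mean(deg), median_degree = median(deg),
       diameter = D, aspl = L,
       clustering = if (triplets > 0) 3 * triangles / triplets else NA_real_)
}

# all labelled graphs on n nodes as adjacency matrices
enumerate_graphs <- function(n, labels = paste0("v", seq_len(n))) {
  np <- n * (n - 1) / 2
  lapply(seq_len(2^np) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(np)]
    A <- matrix(0, n, n, dimnames = list(labels, labels))
    A[upper.tri(A)] <- bits
    A + t(A)
  })
}

adjacency_to_net <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# printed averaged confusion counts of the three diagnostic models
# (hits, misses, false alarms, correct rejections)
published_confusion <- list(
  baseline = c(36.02, 5.02, 4.49, 80.49),
  stepwise = c(36.67, 4.37, 4.51, 80.47),
  maximal  = c(38.11, 2.93, 2.00, 82.98))
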