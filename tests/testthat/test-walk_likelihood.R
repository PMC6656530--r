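test_that("transition matrix rows are degree-normalized and isolated rows flagged", {
  A <- build_transition_matrix(path_net())
  expect_equal(A["b", c("a", "c")], c(a = 0.5, c = 0.5))
  A4 <- build_transition_matrix(complete_net(4))
  expect_true(all(abs(A4[row(A4) != col(A4)] - 1 / 3) < 1e-12))
  set.seed(3)
  net <- random_connected_net(8, 10, seed = 3)
  net <- igraph::add_vertices(net, 1, name = "iso")
  A8 <- build_transition_matrix(net)
  expect_equal(unname(rowSums(A8)[!attr(A8, "isolated")]),
               rep(1, 8), tolerance = 1e-12)
  expect_true(attr(A8, "isolated")[["iso"]])
})

test_that("initial item probability is the stationary distribution", {
  expect_equal(initial_item_prob(star_net(3), "hub"), 0.5)
  expect_equal(initial_item_prob(complete_net(5), "a"), 1 / 5)
  expect_equal(initial_item_prob(path_net(), "b"), 0.5)
  net <- path_net()
  probs <- vapply(igraph::V(net)$name, initial_item_prob, numeric(1), net = net)
  expect_equal(sum(probs), 1)
  expect_error(initial_item_prob(net, "zebra"), "not a node")
})

test_that("transition probabilities match closed forms", {
  e <- semantic_network(rbind(c("a", "b")))
  for (p in c(0, 0.3, 1))
    expect_equal(transition_prob("a", "b", e, p), 1)
  net <- path_net(c("b", "a", "c"))
  # deterministic censoring: the walk can only be absorbed at c
  expect_equal(transition_prob(c("b", "a"), "c", net, 0), 1)
  # renewal series at p_emit = 0.5 (cycle: a->b emits 1/4, a->b->a emits 1/8,
  # a->c emits 1/2, renewal 1/8)
  expect_equal(transition_prob(c("b", "a"), "b", net, 0.5), 2 / 7)
  expect_equal(transition_prob(c("b", "a"), "c", net, 0.5), 4 / 7)
  expect_equal(transition_prob(c("b", "a"), "a", net, 0.5), 1 / 7)
  expect_error(transition_prob(c("b", "a"), "c", net, 1.2), "p_emit")
})

test_that("p_emit = 0 forbids perseverations; p_emit = 1 is the uncensored walk", {
  set.seed(7)
  net <- random_connected_net(6, 9, seed = 7)
  nodes <- igraph::V(net)$name
  prefix <- c(nodes[1], nodes[which(network_adjacency(net)[1, ] == 1)[1]])
  for (x in unique(prefix))
    expect_equal(transition_prob(prefix, x, net, 0), 0)
  # at p_emit = 1 the next-emission distribution equals the walk's own row of A
  A <- build_transition_matrix(net)
  d <- next_emission_distribution(prefix, net, 1)
  expect_equal(d[nodes], A[prefix[2], nodes], tolerance = 1e-12)
})

test_that("per-transition distributions are complete over covering prefixes, substochastic otherwise", {
  for (seed in 1:4) {
    net <- random_connected_net(5, 7, seed = seed)
    nodes <- igraph::V(net)$name
    set.seed(seed)
    full <- unique(random_walk(net, nodes[1], 60))
    expect_setequal(full, nodes)  # prefix covering all nodes
    for (p in c(0.3, 0.7, 1)) {
      expect_equal(sum(next_emission_distribution(full, net, p)), 1,
                   tolerance = 1e-9)
      expect_lt(sum(next_emission_distribution(full[1:2], net, p)), 1 + 1e-9)
    }
  }
})

test_that("list log-likelihood composes the stationary start with transitions", {
  e <- semantic_network(rbind(c("a", "b")))
  expect_equal(list_log_likelihood(c("a", "b"), e, 0.4), log(0.5))
  expect_identical(list_log_likelihood(c("a", "b", "a"), e, 0), -Inf)
  expect_error(list_log_likelihood(character(0), e, 0.5), "empty")
  # agreement between the R transition-prob composition and the compiled path
  for (seed in 1:3) {
    net <- random_connected_net(6, 9, seed = seed)
    set.seed(seed + 100)
    items <- simulate_list(net, 0.5, 5)$items
    manual <- log(initial_item_prob(net, items[1]))
    for (n in 2:length(items))
      manual <- manual + log(transition_prob(items[1:(n - 1)], items[n], net, 0.5))
    expect_equal(list_log_likelihood(items, net, 0.5), manual, tolerance = 1e-10)
  }
})

test_that("corpus log-likelihood is an order-invariant sum over lists", {
  net <- random_connected_net(6, 9, seed = 12)
  set.seed(2)
  l1 <- simulate_list(net, 0.3, 4)$items
  l2 <- simulate_list(net, 0.3, 5)$items
  cp <- toy_corpus(list(l1, l2))
  expect_equal(corpus_log_likelihood(cp, net, 0.3),
               list_log_likelihood(l1, net, 0.3) +
                 list_log_likelihood(l2, net, 0.3))
  expect_equal(corpus_log_likelihood(toy_corpus(list(l2, l1)), net, 0.3),
               corpus_log_likelihood(cp, net, 0.3))
  expect_equal(corpus_log_likelihood(toy_corpus(list(l1, l1)), net, 0.3),
               2 * list_log_likelihood(l1, net, 0.3))
  expect_equal(corpus_log_likelihood(toy_corpus(list(l1)), net, 0.3),
               list_log_likelihood(l1, net, 0.3))
})

test_that("likelihood is invariant under bijective relabelling", {
  net <- random_connected_net(6, 8, seed = 21)
  set.seed(5)
  items <- simulate_list(net, 0.4, 6)$items
  perm <- setNames(paste0("x", 1:6), igraph::V(net)$name)
  el <- igraph::as_edgelist(net)
  net2 <- semantic_network(cbind(perm[el[, 1]], perm[el[, 2]]))
  expect_equal(list_log_likelihood(unname(perm[items]), net2, 0.4),
               list_log_likelihood(items, net, 0.4))
})

test_that("a list visiting an isolated node has zero likelihood", {
  net <- igraph::add_vertices(path_net(), 1, name = "iso")
  expect_identical(list_log_likelihood(c("a", "iso"), net, 0.5), -Inf)
  expect_identical(list_log_likelihood("iso", net, 0.5), -Inf)
})
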