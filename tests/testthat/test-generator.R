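test_that("walks on a single edge are forced and seeded walks reproduce", {
  e <- semantic_network(rbind(c("a", "b")))
  expect_equal(random_walk(e, "a", 3), c("a", "b", "a", "b"))
  net <- random_connected_net(7, 10, seed = 2)
  set.seed(123); w1 <- random_walk(net, "stationary", 20)
  set.seed(123); w2 <- random_walk(net, "stationary", 20)
  expect_equal(w1, w2)
  iso <- igraph::add_vertices(net, 1, name = "iso")
  expect_error(random_walk(iso, "iso", 5), "isolated")
})

test_that("long-run visit frequencies match the stationary distribution", {
  net <- path_net()
  set.seed(4)
  walk <- random_walk(net, "stationary", 1e5)
  freq <- table(factor(walk, levels = c("a", "b", "c"))) / length(walk)
  expected <- c(a = 0.25, b = 0.5, c = 0.25)
  se <- sqrt(expected * (1 - expected) / length(walk))
  # serial dependence inflates the variance; 3 iid s.e. times a slack factor
  expect_true(all(abs(freq - expected) < 3 * 3 * se))
})

test_that("censoring emits first visits always and revisits with probability p_emit", {
  walk <- c("dog", "cat", "hamster", "cat", "lion")
  expect_equal(censor_walk(walk, 0), c("dog", "cat", "hamster", "lion"))
  expect_equal(censor_walk(walk, 1), walk)
  norep <- c("dog", "cat", "lion")
  for (p in c(0, 0.5, 1)) expect_equal(censor_walk(norep, p), norep)
  set.seed(8)
  emitted <- mean(replicate(2000, length(censor_walk(walk, 0.3)) == 5))
  expect_lt(abs(emitted - 0.3), 0.05)  # one revisit, emitted w.p. 0.3
})

test_that("simulated lists emit the requested number of items", {
  e <- semantic_network(rbind(c("a", "b")))
  set.seed(10)
  firsts <- replicate(400, simulate_list(e, 0, 2)$items[1])
  expect_true(all(replicate(20, length(simulate_list(e, 0, 2)$items)) == 2))
  expect_gt(mean(firsts == "a"), 0.4)  # each start ~ probability 0.5
  expect_lt(mean(firsts == "a"), 0.6)
  expect_error(simulate_list(e, 0, 5, max_steps = 1e4), "max_steps")
  set.seed(3); l1 <- simulate_list(e, 0.5, 6)
  set.seed(3); l2 <- simulate_list(e, 0.5, 6)
  expect_equal(l1, l2)
})

test_that("perseveration rates are zero without noise and increase with p_emit", {
  net <- random_connected_net(6, 9, seed = 55)
  set.seed(55)
  cp0 <- simulate_corpus(net, 0, n_lists = 50, n_emissions = 5)
  expect_equal(perseveration_rate(cp0), 0)
  rates <- vapply(c(0.1, 0.3, 0.5), function(p) {
    sims <- fluencynet:::cpp_simulate_lists(network_adjacency(net), p, 8L,
                                            10000L, 1e6)
    mean(apply(sims, 1, function(r) sum(duplicated(r)) / length(r)))
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("cohort simulation adds exactly the requested spurious edges", {
  spec <- cohort_spec(n_nodes = 30, base_edges = 45,
                      group_a = list(n_participants = 2, n_lists = 2,
                                     n_emissions = 5, p_emit = 0.1),
                      group_b = list(n_participants = 2, n_lists = 2,
                                     n_emissions = 5, p_emit = 0.1,
                                     spurious_edges = 20))
  sim <- simulate_cohort(spec, seed = 6)
  base_edges <- igraph::ecount(sim$base)
  expect_true(all(sim$truth$n_true_edges[sim$truth$group == "A"] == base_edges))
  expect_true(all(sim$truth$n_true_edges[sim$truth$group == "B"] == base_edges + 20))
  expect_error(cohort_spec(group_a = list(n_lists = 0)), "positive")
  expect_error(
    simulate_cohort(cohort_spec(n_nodes = 5, base_edges = 6,
      group_b = list(spurious_edges = 10)), seed = 1),
    "exceed")
})

test_that("with equal groups the two generating processes coincide", {
  spec <- cohort_spec(n_nodes = 10, base_edges = 14,
                      group_a = list(n_participants = 2, n_lists = 2,
                                     n_emissions = 4, p_emit = 0.2),
                      group_b = list(n_participants = 2, n_lists = 2,
                                     n_emissions = 4, p_emit = 0.2,
                                     spurious_edges = 0))
  sim <- simulate_cohort(spec, seed = 20)
  for (pid in names(sim$networks))
    expect_equal(network_adjacency(sim$networks[[pid]]),
                 network_adjacency(sim$base))
})

test_that("cohort simulation is deterministic under the master seed", {
  spec <- cohort_spec(n_nodes = 8, base_edges = 10,
                      group_a = list(n_participants = 2, n_lists = 2, n_emissions = 4),
                      group_b = list(n_participants = 2, n_lists = 2, n_emissions = 4))
  s1 <- simulate_cohort(spec, seed = 99)
  s2 <- simulate_cohort(spec, seed = 99)
  expect_equal(s1$truth, s2$truth)
  expect_equal(lapply(s1$corpora, `[[`, "lists"),
               lapply(s2$corpora, `[[`, "lists"))
})
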