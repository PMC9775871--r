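triangle_weights <- function(ab, ac, bc) {
  w <- matrix(c(1, ab, ac,
                ab, 1, bc,
                ac, bc, 1), 3, dimnames = list(c("a", "b", "c"),
                                               c("a", "b", "c")))
  w
}

test_that("edge policies keep exactly the intended pairs", {
  w <- triangle_weights(0.9, -0.2, 0.5)
  all_net <- build_network(w)
  expect_equal(igraph::ecount(all_net$graph), 3)
  pos <- build_network(w, policy = "positive")
  expect_equal(igraph::ecount(pos$graph), 2)
  expect_false(any(tidy(pos)$weight < 0))
  # node count preserved under any policy, weights carried bit-exact
  expect_equal(length(pos$word_labels), 3)
  expect_setequal(tidy(all_net)$weight, c(0.9, -0.2, 0.5))
})

test_that("threshold policy count matches brute-force pair counting", {
  withr::local_seed(7)
  for (r in 1:10) {
    n <- sample(4:8, 1)
    w <- matrix(runif(n * n, -1, 1), n)
    w <- (w + t(w)) / 2
    diag(w) <- 1
    dimnames(w) <- list(letters[1:n], letters[1:n])
    tau <- runif(1, -0.5, 0.5)
    net <- suppressWarnings(build_network(w, policy = "threshold", tau = tau))
    expect_equal(igraph::ecount(net$graph), sum(w[upper.tri(w)] > tau))
  }
})

test_that("three-node spanning tree keeps the two strongest similarities", {
  net <- build_network(triangle_weights(0.9, 0.2, 0.5))
  tree <- spanning_tree(net)
  expect_true(tree$is_tree)
  expect_equal(sort(tidy(tree)$weight), c(0.5, 0.9))
  expect_equal(sum(tidy(tree)$weight), 1.4)
  # min-distance objective on the same similarity weights picks the weakest
  anti <- spanning_tree(net, objective = "min_distance")
  expect_equal(sum(tidy(anti)$weight), 0.2 + 0.5)
})

test_that("spanning trees have n - 1 edges and no cycles", {
  withr::local_seed(17)
  for (r in 1:10) {
    g <- rand_connected_graph(sample(5:9, 1), 0.5, weighted = TRUE)
    tree <- spanning_tree(g$network)
    n <- nrow(g$adj)
    expect_equal(igraph::ecount(tree$graph), n - 1)
    expect_true(igraph::is_connected(tree$graph))
    expect_true(tree$is_tree)
  }
})

test_that("maximum-similarity tree total matches exhaustive enumeration", {
  withr::local_seed(23)
  checked <- 0
  while (checked < 15) {
    g <- rand_connected_graph(6, 0.6, weighted = TRUE)
    el <- igraph::as_edgelist(g$network$graph, names = FALSE)
    edges <- data.frame(a = el[, 1], b = el[, 2],
                        w = igraph::E(g$network$graph)$weight)
    oracle <- oracle_max_spanning_total(edges, 6)
    if (is.na(oracle)) next
    tree <- spanning_tree(g$network)
    expect_equal(sum(tidy(tree)$weight), oracle, tolerance = 1e-12)
    # igraph's MST on the 1 - w distance is an independent cross-check
    ig <- igraph::mst(g$network$graph,
                      weights = 1 - igraph::E(g$network$graph)$weight)
    expect_equal(sum(tidy(tree)$weight), sum(igraph::E(ig)$weight),
                 tolerance = 1e-12)
    checked <- checked + 1
  }
})

test_that("max-similarity and min-distance on 1 - r agree for distinct weights", {
  withr::local_seed(29)
  g <- rand_connected_graph(8, 0.6, weighted = TRUE)
  t1 <- spanning_tree(g$network, objective = "max_similarity")
  dist_g <- g$network
  igraph::E(dist_g$graph)$weight <- 1 - igraph::E(g$network$graph)$weight
  dist_g$weight_interpretation <- "distance"
  t2 <- spanning_tree(dist_g, objective = "min_distance")
  e1 <- tidy(t1)[c("word_a", "word_b")]
  e2 <- tidy(t2)[c("word_a", "word_b")]
  expect_equal(e1[order(e1$word_a, e1$word_b), ],
               e2[order(e2$word_a, e2$word_b), ], ignore_attr = TRUE)
})

test_that("disconnected input yields a flagged spanning forest", {
  w <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  w["a", "b"] <- w["b", "a"] <- 0.8
  w["c", "d"] <- w["d", "c"] <- 0.6
  diag(w) <- 1
  net <- build_network(w, policy = "positive")
  expect_warning(forest <- spanning_tree(net), "disconnected")
  expect_false(forest$is_tree)
  expect_equal(igraph::ecount(forest$graph), 2)
})

test_that("GraphML and edge-list exports round-trip labels and weights", {
  d <- simulate_fluency(fluency_sim_spec(n_participants = 12, seed = 6))
  net <- build_network(word_correlations(d))
  gpath <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gpath)
  back <- read_network_graphml(gpath)
  expect_setequal(back$word_labels, net$word_labels)
  orig <- tidy(net); rt <- tidy(back)
  key <- function(e) paste(pmin(e$word_a, e$word_b), pmax(e$word_a, e$word_b))
  expect_equal(rt$weight[match(key(orig), key(rt))], orig$weight,
               tolerance = 1e-6)
  epath <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, epath)
  tab <- readr::read_tsv(epath, show_col_types = FALSE)
  expect_equal(nrow(tab), igraph::ecount(net$graph))
  expect_equal(tab$weight[match(key(orig), paste(pmin(tab$node_a, tab$node_b),
                                                 pmax(tab$node_a, tab$node_b)))],
               orig$weight, tolerance = 1e-5)
})
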