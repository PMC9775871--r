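# Independent brute-force oracles.  Everything here works from a plain
# adjacency / weight matrix and first principles (triple enumeration,
# Floyd-Warshall, subset enumeration, recursive partition generation) and
# shares no code path with the package implementations it checks.

# mean Watts-Strogatz local clustering; degree < 2 contributes 0
oracle_cc <- function(adj) {
  n <- nrow(adj)
  local <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] > 0) links <- links + 1
      }
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
  mean(local)
}

# all-pairs shortest path mean via Floyd-Warshall (unit edge lengths)
oracle_aspl <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  mean(d[upper.tri(d)])
}

# maximum-total-weight spanning tree by enumerating all (n-1)-edge subsets;
# returns NA if the subset count exceeds `cap`
oracle_max_spanning_total <- function(edges, n, cap = 20000) {
  m <- nrow(edges)
  if (n < 2 || m < n - 1 || choose(m, n - 1) > cap) return(NA_real_)
  spanning <- function(sel) {
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i] <- parent[parent[i]]
      i
    }
    for (e in sel) {
      ra <- find(edges$a[e]); rb <- find(edges$b[e])
      if (ra == rb) return(FALSE)  # cycle => not a tree
      parent[ra] <- rb
    }
    TRUE
  }
  best <- -Inf
  for (sel in asplit(utils::combn(m, n - 1), 2)) {
    if (spanning(sel)) best <- max(best, sum(edges$w[sel]))
  }
  if (is.finite(best)) best else NA_real_
}

# modularity from the definition, on a weight matrix
oracle_modularity <- function(wmat, membership) {
  m <- sum(wmat[upper.tri(wmat)])
  if (m == 0) return(0)
  deg <- rowSums(wmat)
  q <- 0
  for (cm in unique(membership)) {
    idx <- membership == cm
    e_c <- sum(wmat[idx, idx][upper.tri(wmat[idx, idx, drop = FALSE])])
    q <- q + e_c / m - (sum(deg[idx]) / (2 * m))^2
  }
  q
}

# every membership vector of n elements (grown one element at a time,
# breadth-first over existing blocks -- deliberately unlike the package's
# restricted-growth recursion)
oracle_partitions <- function(n) {
  parts <- list(1L)
  if (n == 1) return(parts)
  for (el in 2:n) {
    parts <- unlist(lapply(parts, function(p) {
      k <- max(p)
      lapply(seq_len(k + 1L), function(blk) c(p, blk))
    }), recursive = FALSE)
  }
  parts
}

oracle_best_modularity <- function(wmat) {
  best <- -Inf
  for (p in oracle_partitions(nrow(wmat))) {
    best <- max(best, oracle_modularity(wmat, p))
  }
  best
}

# random undirected test graph as an adjacency matrix + lexical_network
rand_test_graph <- function(n, p, weighted = FALSE) {
  adj <- matrix(0, n, n)
  up <- which(upper.tri(adj))
  on <- up[runif(length(up)) < p]
  adj[on] <- if (weighted) runif(length(on), 0.1, 1) else 1
  adj <- adj + t(adj)
  dimnames(adj) <- list(letters[seq_len(n)], letters[seq_len(n)])
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = if (weighted) TRUE else NULL)
  list(adj = adj, network = new_lexical_network(g))
}

# keep drawing until the graph is connected
rand_connected_graph <- function(n, p, weighted = FALSE) {
  repeat {
    g <- rand_test_graph(n, p, weighted)
    if (igraph::is_connected(g$network$graph)) return(g)
  }
}
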