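#' Clustering coefficient of a network
#'
#' Mean local clustering over all nodes.  `"unweighted"` is the
#' Watts-Strogatz local clustering coefficient (closed triples around each
#' node); `"weighted"` is Barrat's weighted local clustering, which reduces
#' to the unweighted value when all weights are equal.  Nodes of degree < 2
#' contribute 0 (a stated convention: it changes the mean relative to
#' excluding them).
#'
#' @param network A `lexical_network` or igraph graph with >= 3 nodes.
#' @param mode `"unweighted"` or `"weighted"` (Barrat; requires nonnegative
#'   weights).
#' @return A single value in \[0, 1\].
#' @export
#' @examples
#' clustering_coefficient(er_random_graph(10, 1, seed = 1))  # complete: 1
clustering_coefficient <- function(network, mode = c("unweighted", "weighted")) {
  mode <- match.arg(mode)
  g <- as_igraph(network)
  if (igraph::vcount(g) < 3L) {
    stop_bilexnet("Clustering coefficient is undefined for fewer than 3 nodes.",
                  "undefined_value")
  }
  if (mode == "weighted") {
    w <- igraph::E(g)$weight %||% rep(1, igraph::ecount(g))
    if (any(w < 0)) {
      stop_bilexnet(
        "Barrat weighted clustering requires nonnegative weights; use mode = \"unweighted\", an edge policy excluding negative correlations, or transform the weights.",
        "negative_weights")
    }
    local <- igraph::transitivity(g, type = "barrat", isolates = "zero")
  } else {
    local <- igraph::transitivity(g, type = "local", isolates = "zero",
                                  weights = NA)
  }
  local[is.na(local)] <- 0
  mean(local)
}

#' Average shortest path length
#'
#' Mean shortest-path length over all unordered node pairs.  `"hops"` treats
#' every edge as length 1; `"weighted"` uses edge distances — for similarity
#' weights the distance transform 1 - w is applied, for distance weights the
#' weights are used as-is.  A disconnected graph is reduced to its largest
#' component with a warning.
#'
#' @param network A `lexical_network` or igraph graph.
#' @param mode `"hops"` or `"weighted"`.
#' @return Mean path length (>= 1 in hops mode on a connected graph with
#'   >= 2 nodes).
#' @export
#' @examples
#' average_shortest_path_length(er_random_graph(5, 1, seed = 1))  # K5: 1
average_shortest_path_length <- function(network, mode = c("hops", "weighted")) {
  mode <- match.arg(mode)
  g <- as_igraph(network)
  comps <- igraph::components(g)
  if (comps$no > 1L) {
    rlang::warn(sprintf(
      "Network is disconnected (%d components); ASPL computed on the largest component.",
      comps$no))
    biggest <- which.max(comps$csize)
    g <- igraph::induced_subgraph(g, which(comps$membership == biggest))
  }
  if (igraph::vcount(g) < 2L) {
    stop_bilexnet("ASPL is undefined on a singleton graph.", "undefined_value")
  }
  weights <- if (mode == "hops") {
    NA
  } else {
    w <- igraph::E(g)$weight %||% rep(1, igraph::ecount(g))
    interp <- if (inherits(network, "lexical_network"))
      network$weight_interpretation else "distance"
    d <- if (interp == "similarity") 1 - w else w
    if (any(d < 0)) {
      stop_bilexnet("Weighted ASPL needs nonnegative distances.", "negative_weights")
    }
    d
  }
  d <- igraph::distances(g, weights = weights)
  mean(d[upper.tri(d)])
}

#' Small-world index
#'
#' `S = (cc / ccran) / (aspl / asplran)`: the clustering coefficient and
#' average shortest path length of an empirical network, each normalised by
#' the mean of the same statistic over size-matched random networks.  A
#' network is classified small-world when S > 1 — clustering well above the
#' random baseline without a correspondingly longer path length.
#'
#' The index is scale-invariant: multiplying `cc` and `ccran` (or `aspl` and
#' `asplran`) by a common positive factor leaves S unchanged.
#'
#' @param cc,ccran Empirical and random-baseline clustering coefficients
#'   (> 0).
#' @param aspl,asplran Empirical and random-baseline average shortest path
#'   lengths (> 0).
#' @return The small-world index (vectorised over its arguments).
#' @export
#' @examples
#' small_world_index(cc = 0.979, ccran = 0.951, aspl = 1.024, asplran = 1.355)
small_world_index <- function(cc, ccran, aspl, asplran) {
  vals <- cbind(cc = cc, ccran = ccran, aspl = aspl, asplran = asplran)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_bilexnet("All of cc, ccran, aspl, asplran must be finite and > 0.",
                  "validation")
  }
  as.numeric((cc / ccran) / (aspl / asplran))
}

#' Modularity of a community assignment
#'
#' Computes Newman-Girvan modularity directly from its definition,
#' `Q = sum_c (e_c / m - (d_c / 2m)^2)`, where `m` is the total edge weight,
#' `e_c` the within-community weight, and `d_c` the total (weighted) degree
#' of community `c`.  With unit weights this is the unweighted modularity.
#'
#' @param network A `lexical_network` or igraph graph.
#' @param membership Community assignment: a vector in vertex order, or
#'   named by vertex, or a `community_partition`.
#' @return Modularity Q in \[-0.5, 1\]; 0 for an edgeless graph.
#' @export
#' @examples
#' g <- er_random_graph(6, 1, seed = 1)
#' modularity_score(g, rep(1:2, each = 3))
modularity_score <- function(network, membership) {
  g <- as_igraph(network)
  if (inherits(membership, "community_partition")) {
    membership <- setNames(membership$partition$community,
                           membership$partition$word)
  }
  if (!is.null(names(membership))) {
    membership <- membership[igraph::V(g)$name]
    if (anyNA(membership)) {
      stop_bilexnet("`membership` names do not cover all vertices.", "validation")
    }
  }
  if (length(membership) != igraph::vcount(g)) {
    stop_bilexnet("`membership` must assign every node exactly once.", "validation")
  }
  membership <- as.integer(factor(membership))
  if (igraph::ecount(g) == 0L) {
    return(0)
  }
  w <- igraph::E(g)$weight %||% rep(1, igraph::ecount(g))
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  m <- sum(w)
  within <- membership[ends[, 1L]] == membership[ends[, 2L]]
  e_c <- vapply(seq_len(max(membership)), function(cm) {
    sum(w[within & membership[ends[, 1L]] == cm])
  }, numeric(1))
  deg <- rep(0, igraph::vcount(g))
  for (k in 1:2) {
    agg <- tapply(w, ends[, k], sum)
    deg[as.integer(names(agg))] <- deg[as.integer(names(agg))] + agg
  }
  d_c <- tapply(deg, membership, sum)
  sum(e_c / m - (d_c / (2 * m))^2)
}

#' Network metric summary
#'
#' One-row tibble of the standard lexical-network statistics: node count,
#' clustering coefficient, average shortest path length, modularity of the
#' detected community partition and, when a null ensemble is supplied, the
#' null baselines and the small-world index formed from them.
#'
#' The default modes (weighted Barrat CC, hop ASPL) are the ones that keep a
#' near-complete correlation network informative: on such a graph the hop
#' ASPL is close to 1 while the weighted CC still reflects the correlation
#' structure.  If the network carries negative weights, weighted CC is
#' undefined and the function falls back to unweighted CC with a warning;
#' the `cc_mode` column always records the mode actually used.
#'
#' @param network A `lexical_network` or igraph graph.
#' @param null Optional `null_ensemble` providing `ccran` / `asplran`.
#' @param cc_mode,aspl_mode Metric modes, see [clustering_coefficient()] and
#'   [average_shortest_path_length()].
#' @param community_seed Seed for community detection.
#' @return A one-row tibble with columns `n`, `cc`, `aspl`, `q`,
#'   `n_communities`, `ccran`, `asplran`, `s`, `cc_mode`, `aspl_mode`.
#' @export
network_metrics <- function(network, null = NULL,
                            cc_mode = c("weighted", "unweighted"),
                            aspl_mode = c("hops", "weighted"),
                            community_seed = 1L) {
  cc_mode <- match.arg(cc_mode)
  aspl_mode <- match.arg(aspl_mode)
  g <- as_igraph(network)
  cc <- tryCatch(
    clustering_coefficient(network, mode = cc_mode),
    bilexnet_negative_weights = function(cnd) {
      rlang::warn("Negative weights present: falling back to unweighted clustering coefficient.")
      cc_mode <<- "unweighted"
      clustering_coefficient(network, mode = "unweighted")
    })
  aspl <- average_shortest_path_length(network, mode = aspl_mode)
  part <- detect_communities(network, seed = community_seed)
  ccran <- asplran <- s <- NA_real_
  if (!is.null(null)) {
    sums <- glance(null)
    ccran <- sums$cc_mean
    asplran <- sums$aspl_mean
    s <- small_world_index(cc, ccran, aspl, asplran)
  }
  tibble::tibble(
    n = igraph::vcount(g),
    cc = cc, aspl = aspl,
    q = part$q, n_communities = part$n_communities,
    ccran = ccran, asplran = asplran, s = s,
    cc_mode = cc_mode, aspl_mode = aspl_mode
  )
}
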