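#' Detect communities in a lexical network
#'
#' Partitions the nodes to maximise modularity.  The default method is
#' multilevel (Louvain) modularity optimisation, made reproducible by a
#' fixed seed; `method = "exact"` enumerates every set partition (feasible
#' up to 10 nodes) and returns a global optimum.  Modularity maximisation is
#' defined for nonnegative weights, so negative-weight edges (possible on
#' correlation networks under the `"all"` edge policy) are dropped before
#' detection, with a message.  An edgeless graph yields the trivial
#' partition (every node its own community) with Q = 0.
#'
#' The reported `q` is always recomputed from the returned assignment with
#' [modularity_score()], never copied from the optimiser.
#'
#' @param network A `lexical_network` or igraph graph.
#' @param method `"louvain"` or `"exact"` (exhaustive, n <= 10).
#' @param seed Integer seed for the heuristic.
#' @return A `community_partition`: list with `partition` (tibble `word`,
#'   `community`), `q`, `n_communities`, `method`.
#' @export
#' @examples
#' g <- igraph::make_graph(~ a-b, b-c, a-c, d-e, e-f, d-f)
#' detect_communities(g)$q  # two triangles: 0.5
detect_communities <- function(network, method = c("louvain", "exact"),
                               seed = 1L) {
  method <- match.arg(method)
  g <- as_igraph(network)
  labels <- igraph::V(g)$name
  if (is.null(labels)) {
    labels <- paste0("w", seq_len(igraph::vcount(g)))
    igraph::V(g)$name <- labels
  }
  w <- igraph::E(g)$weight %||% rep(1, igraph::ecount(g))
  if (any(w < 0)) {
    rlang::inform(sprintf(
      "Dropping %d negative-weight edge(s) before modularity maximisation.",
      sum(w < 0)))
    g <- igraph::delete_edges(g, which(w < 0))
  }
  if (igraph::ecount(g) == 0L) {
    membership <- seq_along(labels)
  } else if (method == "louvain") {
    cl <- withr::with_seed(seed, igraph::cluster_louvain(g))
    membership <- igraph::membership(cl)
  } else {
    n <- igraph::vcount(g)
    if (n > 10L) {
      stop_bilexnet("Exact community search is limited to networks of <= 10 nodes.",
                    "validation")
    }
    best <- NULL
    best_q <- -Inf
    for (p in set_partitions(n)) {
      q <- modularity_score(g, p)
      if (q > best_q + 1e-12) {
        best_q <- q
        best <- p
      }
    }
    membership <- best
  }
  membership <- as.integer(factor(membership, levels = unique(membership)))
  q <- modularity_score(g, membership)
  structure(
    list(
      partition = tibble::tibble(word = labels, community = membership),
      q = q,
      n_communities = length(unique(membership)),
      method = if (igraph::ecount(g) == 0L) "trivial" else method
    ),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities over %d nodes, Q = %.4f (%s)\n",
              x$n_communities, nrow(x$partition), x$q, x$method))
  invisible(x)
}

#' @describeIn detect_communities Node-level tibble (`word`, `community`).
#' @param x A `community_partition`.
#' @param ... Unused.
#' @method tidy community_partition
#' @export
tidy.community_partition <- function(x, ...) {
  x$partition
}

#' @describeIn detect_communities One-row summary (`q`, `n_communities`,
#'   `method`).
#' @method glance community_partition
#' @export
glance.community_partition <- function(x, ...) {
  tibble::tibble(q = x$q, n_communities = x$n_communities, method = x$method)
}

# all set partitions of n elements as integer membership vectors
# (restricted-growth strings); Bell(10) = 115975
set_partitions <- function(n) {
  out <- vector("list", 0L)
  recurse <- function(prefix, k) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (v in seq_len(k + 1L)) {
      recurse(c(prefix, v), max(k, v))
    }
  }
  recurse(integer(0), 0L)
  out
}
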