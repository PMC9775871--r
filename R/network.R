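#' Lexical networks
#'
#' A `lexical_network` is an undirected weighted graph over word nodes:
#' an igraph graph plus flags recording whether it is a spanning tree and
#' whether edge weights are similarities (correlations) or distances.
#'
#' @param graph An undirected igraph graph with named vertices and
#'   (optionally) an edge `weight` attribute; missing weights default to 1.
#' @param is_tree Logical: is this a spanning tree/forest backbone?
#' @param weight_interpretation `"similarity"` or `"distance"`.
#' @return An object of class `lexical_network`.
#' @keywords internal
#' @export
new_lexical_network <- function(graph, is_tree = FALSE,
                                weight_interpretation = c("similarity", "distance")) {
  weight_interpretation <- match.arg(weight_interpretation)
  if (!igraph::is_igraph(graph) || igraph::is_directed(graph)) {
    stop_bilexnet("`graph` must be an undirected igraph graph.", "validation")
  }
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- paste0("w", seq_len(igraph::vcount(graph)))
  }
  if (igraph::ecount(graph) > 0L && is.null(igraph::E(graph)$weight)) {
    igraph::E(graph)$weight <- 1
  }
  structure(
    list(graph = graph,
         word_labels = igraph::V(graph)$name,
         is_tree = isTRUE(is_tree),
         weight_interpretation = weight_interpretation),
    class = "lexical_network"
  )
}

# coerce lexical_network / igraph to igraph
as_igraph <- function(x) {
  if (inherits(x, "lexical_network")) x$graph
  else if (igraph::is_igraph(x)) x
  else stop_bilexnet("Expected a lexical_network or igraph graph.", "validation")
}

#' @export
print.lexical_network <- function(x, ...) {
  cat(sprintf("<lexical_network> %d nodes, %d edges (%s weights%s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$weight_interpretation, if (x$is_tree) ", spanning tree" else ""))
  invisible(x)
}

#' @describeIn build_network Edge tibble: `word_a`, `word_b`, `weight`.
#' @param x A `lexical_network`.
#' @param ... Unused.
#' @method tidy lexical_network
#' @export
tidy.lexical_network <- function(x, ...) {
  g <- x$graph
  if (igraph::ecount(g) == 0L) {
    return(tibble::tibble(word_a = character(), word_b = character(),
                          weight = numeric()))
  }
  ends <- igraph::as_edgelist(g)
  tibble::tibble(word_a = ends[, 1L], word_b = ends[, 2L],
                 weight = igraph::E(g)$weight)
}

#' Build a weighted lexical network from a correlation matrix
#'
#' Nodes are words (node count is preserved whatever the edge policy does);
#' edges carry the pairwise correlations as weights.  The default policy
#' keeps every finite off-diagonal weight, i.e. a near-complete graph;
#' `"positive"` keeps only positive correlations; `"threshold"` keeps weights
#' strictly greater than `tau`.
#'
#' @param weights A `weight_matrix` from [word_correlations()], or a
#'   symmetric numeric matrix with dimnames.
#' @param policy Edge-inclusion policy: `"all"`, `"positive"`, `"threshold"`.
#' @param tau Threshold used when `policy = "threshold"`.
#' @return A `lexical_network` with similarity weights.
#' @export
#' @examples
#' w <- matrix(c(1, .8, -.2, .8, 1, .5, -.2, .5, 1), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' build_network(w, policy = "positive")
build_network <- function(weights, policy = c("all", "positive", "threshold"),
                          tau = NULL) {
  policy <- match.arg(policy)
  w <- if (inherits(weights, "weight_matrix")) weights$weights else weights
  if (!is.matrix(w) || nrow(w) != ncol(w) || is.null(colnames(w))) {
    stop_bilexnet("`weights` must be a square matrix with dimnames.", "validation")
  }
  if (policy == "threshold") {
    tau <- check_number(tau, "tau")
  }
  labels <- colnames(w)
  idx <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[idx]
  keep <- is.finite(wt)
  keep <- keep & switch(policy,
    all = TRUE,
    positive = wt > 0,
    threshold = wt > tau
  )
  edges <- data.frame(from = labels[idx[keep, 1L]],
                      to = labels[idx[keep, 2L]],
                      weight = wt[keep])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = labels))
  if (nrow(edges) == 0L) {
    rlang::warn("Edge policy retained no edges; returning an edgeless network.")
  }
  new_lexical_network(g, weight_interpretation = "similarity")
}

#' Spanning-tree backbone of a lexical network
#'
#' Extracts the spanning tree that either maximises total similarity weight
#' (default; for correlation weights this equals minimising total 1 - r
#' distance) or minimises total weight under a distance interpretation.
#' Kruskal's algorithm with deterministic tie-breaking: ties in the edge key
#' are broken by lexicographic node-pair order.  Disconnected input yields a
#' per-component spanning forest with a warning, and the result is flagged
#' `is_tree` only when the input was connected.
#'
#' @param network A `lexical_network` (or igraph graph).
#' @param objective `"max_similarity"` or `"min_distance"` (applied to the
#'   stored edge weights).
#' @return A `lexical_network` over the same nodes with n - 1 edges per
#'   connected component, weights copied from the input.
#' @export
spanning_tree <- function(network, objective = c("max_similarity", "min_distance")) {
  objective <- match.arg(objective)
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  labels <- igraph::V(g)$name
  edges <- tidy(new_lexical_network(g))
  comps <- igraph::components(g)
  if (comps$no > 1L) {
    rlang::warn(sprintf(
      "Network is disconnected (%d components); returning a spanning forest.",
      comps$no))
  }
  if (nrow(edges) > 0L) {
    a <- pmin(edges$word_a, edges$word_b)
    b <- pmax(edges$word_a, edges$word_b)
    key <- if (objective == "max_similarity") -edges$weight else edges$weight
    ord <- order(key, a, b)
    # union-find over vertex labels
    parent <- seq_len(n)
    names(parent) <- labels
    find <- function(i) {
      while (parent[i] != i) {
        parent[i] <<- parent[parent[i]]
        i <- parent[i]
      }
      i
    }
    keep <- logical(nrow(edges))
    for (e in ord) {
      ra <- find(match(a[e], labels))
      rb <- find(match(b[e], labels))
      if (ra != rb) {
        parent[ra] <- rb
        keep[e] <- TRUE
      }
    }
    edges <- edges[keep, , drop = FALSE]
  }
  tg <- igraph::graph_from_data_frame(
    data.frame(from = edges$word_a, to = edges$word_b, weight = edges$weight),
    directed = FALSE, vertices = data.frame(name = labels))
  out <- new_lexical_network(tg, is_tree = comps$no == 1L,
                             weight_interpretation =
                               if (inherits(network, "lexical_network"))
                                 network$weight_interpretation else "similarity")
  out
}

#' Export and import lexical networks
#'
#' `write_network_graphml()` writes GraphML with the edge `weight` attribute
#' (and any node attributes, e.g. a `community` id).
#' `write_edge_list()` writes a TSV of `node_a`, `node_b`, `weight` with
#' weights to 6 decimal places.  `read_network_graphml()` reads GraphML back
#' into a `lexical_network`.
#'
#' @param network A `lexical_network`.
#' @param path Output file path.
#' @return The path, invisibly (readers return a `lexical_network`).
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  new_lexical_network(igraph::as_undirected(g, mode = "collapse"))
}

#' @rdname write_network_graphml
#' @export
write_edge_list <- function(network, path) {
  edges <- tidy(network)
  out <- data.frame(node_a = edges$word_a, node_b = edges$word_b,
                    weight = formatC(edges$weight, digits = 6L, format = "f"))
  readr::write_tsv(out, path)
  invisible(path)
}
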