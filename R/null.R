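#' Erdos-Renyi random lexical network
#'
#' G(n, p): each of the n(n-1)/2 unordered node pairs is an edge
#' independently with probability p.  Edges carry unit weights — the null
#' model is defined on node count and edge probability only.
#'
#' @param n Number of nodes (>= 2).
#' @param p Edge probability in \[0, 1\].
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return A `lexical_network` with unit weights.
#' @export
#' @examples
#' er_random_graph(5, 1, seed = 1)  # complete graph K5
er_random_graph <- function(n, p, seed = NULL) {
  n <- check_count(n, "n", min = 2L)
  p <- check_prob(p, "p")
  g <- with_seed_or_current(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- sprintf("v%03d", seq_len(n))
  if (igraph::ecount(g) > 0L) {
    igraph::E(g)$weight <- 1
  }
  new_lexical_network(g)
}

#' Erdos-Renyi null ensemble
#'
#' Generates `reps` G(n, p) graphs and records, per replicate, the
#' unweighted clustering coefficient, the hop average shortest path length
#' (largest component, `NA` if that component is a singleton), the
#' modularity of the Louvain partition, and the edge count.  These are the
#' baselines against which the empirical network statistics are judged: the
#' ensemble means supply `ccran` and `asplran` for the small-world index,
#' and the per-replicate vectors support significance tests.
#'
#' @param n Node count matched to the empirical network.
#' @param p Edge probability (0.5 by default).
#' @param reps Number of replicates (>= 2; 1000 by default).
#' @param seed Integer seed; the ensemble is fully reproducible.
#' @return A `null_ensemble`: list with `n`, `p`, `reps`, `seed` and
#'   `samples` (tibble `replicate`, `edges`, `cc`, `aspl`, `q`).
#' @export
#' @examples
#' ens <- null_ensemble(n = 12, p = 0.5, reps = 25, seed = 1)
#' glance(ens)
null_ensemble <- function(n, p = 0.5, reps = 1000, seed = 1L) {
  n <- check_count(n, "n", min = 2L)
  p <- check_prob(p, "p")
  reps <- check_count(reps, "reps", min = 2L)
  seed <- check_count(seed, "seed")
  samples <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(reps), function(r) {
      g <- igraph::sample_gnp(n, p)
      cc <- if (n >= 3L) {
        local <- igraph::transitivity(g, type = "local", isolates = "zero",
                                      weights = NA)
        mean(ifelse(is.na(local), 0, local))
      } else NA_real_
      comps <- igraph::components(g)
      biggest <- which.max(comps$csize)
      aspl <- if (max(comps$csize) >= 2L) {
        sub <- igraph::induced_subgraph(g, which(comps$membership == biggest))
        d <- igraph::distances(sub, weights = NA)
        mean(d[upper.tri(d)])
      } else NA_real_
      q <- if (igraph::ecount(g) == 0L) 0 else {
        igraph::modularity(igraph::cluster_louvain(g))
      }
      tibble::tibble(replicate = r, edges = igraph::ecount(g),
                     cc = cc, aspl = aspl, q = q)
    })
  })
  structure(list(n = n, p = p, reps = reps, seed = seed, samples = samples),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  s <- glance(x)
  cat(sprintf("<null_ensemble> G(n = %d, p = %g), %d replicates (seed %d)\n",
              x$n, x$p, x$reps, x$seed))
  cat(sprintf("  cc %.4f (sd %.4f), aspl %.4f (sd %.4f), q %.4f (sd %.4f)\n",
              s$cc_mean, s$cc_sd, s$aspl_mean, s$aspl_sd, s$q_mean, s$q_sd))
  invisible(x)
}

#' @describeIn null_ensemble Per-replicate metric tibble.
#' @param x A `null_ensemble`.
#' @param ... Unused.
#' @method tidy null_ensemble
#' @export
tidy.null_ensemble <- function(x, ...) {
  x$samples
}

#' @describeIn null_ensemble One-row tibble of ensemble means and SDs.
#' @method glance null_ensemble
#' @export
glance.null_ensemble <- function(x, ...) {
  s <- x$samples
  tibble::tibble(
    n = x$n, p = x$p, reps = x$reps, seed = x$seed,
    edges_mean = mean(s$edges), edges_sd = stats::sd(s$edges),
    cc_mean = mean(s$cc, na.rm = TRUE), cc_sd = stats::sd(s$cc, na.rm = TRUE),
    aspl_mean = mean(s$aspl, na.rm = TRUE),
    aspl_sd = stats::sd(s$aspl, na.rm = TRUE),
    q_mean = mean(s$q, na.rm = TRUE), q_sd = stats::sd(s$q, na.rm = TRUE)
  )
}

#' Compare an empirical network statistic to its null ensemble
#'
#' One-sample t test of the ensemble values against the empirical value
#' (df = reps - 1, two-sided), plus the z score
#' `(empirical - mean) / SD`.  The t statistic is signed
#' `(ensemble mean - empirical) / SE`, so moving the empirical value from
#' above to below the null mean flips the sign of t and z but leaves their
#' magnitudes and the p value unchanged.
#'
#' @param empirical The empirical value of the statistic (a single number,
#'   or a one-row [network_metrics()] tibble from which `metric` is taken).
#' @param ensemble A `null_ensemble`.
#' @param metric Which statistic: `"cc"`, `"aspl"` or `"q"`.
#' @return A one-row tibble: `metric`, `empirical`, `null_mean`, `null_sd`,
#'   `reps_used`, `t`, `df`, `p`, `z`, `direction`, `degenerate`.
#' @export
#' @examples
#' ens <- null_ensemble(n = 12, p = 0.5, reps = 50, seed = 1)
#' compare_to_null(0.9, ens, "cc")
compare_to_null <- function(empirical, ensemble, metric = c("cc", "aspl", "q")) {
  metric <- match.arg(metric)
  if (!inherits(ensemble, "null_ensemble")) {
    stop_bilexnet("`ensemble` must be a null_ensemble.", "validation")
  }
  if (is.data.frame(empirical)) {
    check_columns(empirical, metric, "`empirical`")
    empirical <- empirical[[metric]][1L]
  }
  empirical <- check_number(empirical, "empirical")
  vals <- ensemble$samples[[metric]]
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2L) {
    stop_bilexnet("Fewer than 2 finite ensemble values for this metric.", "validation")
  }
  mu <- mean(vals)
  sdv <- stats::sd(vals)
  degenerate <- sdv == 0
  if (degenerate) {
    t_stat <- df <- p <- z <- NA_real_
    rlang::warn("Zero ensemble SD: z and t undefined, comparison degenerate.")
  } else {
    tt <- stats::t.test(vals, mu = empirical)
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
    z <- (empirical - mu) / sdv
  }
  tibble::tibble(
    metric = metric, empirical = empirical, null_mean = mu, null_sd = sdv,
    reps_used = length(vals), t = t_stat, df = df, p = p, z = z,
    direction = if (empirical > mu) "above" else if (empirical < mu) "below" else "equal",
    degenerate = degenerate
  )
}

#' Pooled null comparison across several networks
#'
#' Pools the per-replicate deviations (ensemble value minus that network's
#' empirical value) across networks and runs a single one-sample t test of
#' the pooled deviations against zero — a single significance statement per
#' metric for a family of networks, each judged against its own size-matched
#' ensemble.
#'
#' @param empirical Numeric vector of empirical values, one per network.
#' @param ensembles List of `null_ensemble` objects, same length and order.
#' @param metric `"cc"`, `"aspl"` or `"q"`.
#' @return A one-row tibble: `metric`, `networks`, `t`, `df`, `p`,
#'   `mean_deviation`.
#' @export
pooled_null_comparison <- function(empirical, ensembles,
                                   metric = c("cc", "aspl", "q")) {
  metric <- match.arg(metric)
  if (length(empirical) != length(ensembles) || length(ensembles) < 1L) {
    stop_bilexnet("`empirical` and `ensembles` must have equal positive length.",
                  "validation")
  }
  dev <- unlist(purrr::map2(ensembles, empirical, function(e, v) {
    vals <- e$samples[[metric]]
    vals[is.finite(vals)] - v
  }))
  tt <- stats::t.test(dev, mu = 0)
  tibble::tibble(
    metric = metric, networks = length(ensembles),
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    mean_deviation = mean(dev)
  )
}
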