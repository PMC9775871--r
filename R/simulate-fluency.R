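#' Specification for a synthetic semantic-fluency dataset
#'
#' Describes a planted-cluster Bernoulli generator for semantic-fluency
#' responses.  The vocabulary is partitioned into latent semantic clusters;
#' each participant "knows" a fixed number of clusters and produces each word
#' of a known cluster with probability `p_within`, and every other word with
#' probability `p_between`.  This is the simplest generative structure under
#' which correlation-network construction, community detection and
#' small-world statistics are all exercisable.
#'
#' Defaults emulate a fluency study with around 32 participants and a 40-55
#' word vocabulary organised into a handful of semantic clusters.
#'
#' @param n_participants Number of participants (>= 2).
#' @param clusters Integer vector of words per cluster; names (optional)
#'   become cluster ids.
#' @param p_within Probability that a participant produces a word from a
#'   cluster they know.
#' @param p_between Production probability for all other words
#'   (`0 <= p_between <= p_within <= 1`).
#' @param clusters_per_participant Number of distinct clusters assigned to
#'   each participant (sampled uniformly without replacement).
#' @param language Language label attached to the dataset (e.g. `"D1"`).
#' @param category Semantic-category label (e.g. `"animal"`).
#' @param seed Integer seed; identical specs give byte-identical datasets.
#'
#' @return An object of class `fluency_sim_spec`.
#' @seealso [simulate_fluency()]
#' @export
#' @examples
#' fluency_sim_spec(n_participants = 8, clusters = c(a = 4, b = 4),
#'                  clusters_per_participant = 1, seed = 1)
fluency_sim_spec <- function(n_participants = 32,
                             clusters = c(animals_home = 9, animals_wild = 9,
                                          animals_bird = 9, animals_water = 9,
                                          animals_insect = 9),
                             p_within = 0.9,
                             p_between = 0.05,
                             clusters_per_participant = 3,
                             language = "D1",
                             category = "animal",
                             seed = 1L) {
  n_participants <- check_count(n_participants, "n_participants", min = 2L)
  if (length(clusters) < 1L || any(is.na(clusters)) || any(clusters < 1) ||
      any(clusters != floor(clusters))) {
    stop_bilexnet("`clusters` must be positive integer word counts, one per cluster.",
                  "validation")
  }
  clusters <- as.integer(clusters)
  if (is.null(names(clusters)) || anyDuplicated(names(clusters))) {
    names(clusters) <- paste0("c", seq_along(clusters))
  }
  p_within <- check_prob(p_within, "p_within")
  p_between <- check_prob(p_between, "p_between")
  if (p_between > p_within) {
    stop_bilexnet("`p_between` must not exceed `p_within`.", "validation")
  }
  clusters_per_participant <- check_count(clusters_per_participant,
                                          "clusters_per_participant", min = 1L)
  if (clusters_per_participant > length(clusters)) {
    stop_bilexnet("`clusters_per_participant` cannot exceed the number of clusters.",
                  "validation")
  }
  structure(
    list(
      n_participants = n_participants,
      clusters = clusters,
      p_within = p_within,
      p_between = p_between,
      clusters_per_participant = clusters_per_participant,
      language = language,
      category = category,
      seed = check_count(seed, "seed")
    ),
    class = "fluency_sim_spec"
  )
}

#' @export
print.fluency_sim_spec <- function(x, ...) {
  cat("<fluency_sim_spec>\n")
  cat(sprintf("  %d participants, %d words in %d clusters (%s)\n",
              x$n_participants, sum(x$clusters), length(x$clusters),
              paste(x$clusters, collapse = "+")))
  cat(sprintf("  p_within = %g, p_between = %g, %d cluster(s)/participant, seed = %d\n",
              x$p_within, x$p_between, x$clusters_per_participant, x$seed))
  invisible(x)
}

#' Simulate a semantic-fluency dataset
#'
#' Draws a participants-by-words binary incidence matrix under the
#' planted-cluster model of [fluency_sim_spec()].  Words produced by no
#' participant are retained as all-zero columns: whether to keep or drop them
#' is a downstream policy decision.
#'
#' @param spec A [fluency_sim_spec()].
#' @return A [fluency_dataset][build_incidence] with the realised
#'   cluster-membership table in `attr(, "assignments")` and the generating
#'   spec in `attr(, "sim_spec")`.
#' @export
#' @examples
#' d <- simulate_fluency(fluency_sim_spec(n_participants = 6,
#'                                        clusters = c(a = 3, b = 3),
#'                                        clusters_per_participant = 1,
#'                                        seed = 42))
#' dim(d$incidence)
simulate_fluency <- function(spec) {
  if (!inherits(spec, "fluency_sim_spec")) {
    stop_bilexnet("`spec` must be created by fluency_sim_spec().", "validation")
  }
  n <- spec$n_participants
  word_labels <- unlist(lapply(names(spec$clusters), function(cl) {
    paste0(cl, "_w", seq_len(spec$clusters[[cl]]))
  }), use.names = FALSE)
  word_cluster <- rep(names(spec$clusters), times = spec$clusters)
  m <- length(word_labels)

  sim <- withr::with_seed(spec$seed, {
    owned <- t(vapply(seq_len(n), function(i) {
      picked <- sample(names(spec$clusters), spec$clusters_per_participant)
      names(spec$clusters) %in% picked
    }, logical(length(spec$clusters))))
    colnames(owned) <- names(spec$clusters)
    prob <- matrix(spec$p_between, nrow = n, ncol = m)
    for (i in seq_len(n)) {
      prob[i, word_cluster %in% names(spec$clusters)[owned[i, ]]] <- spec$p_within
    }
    inc <- matrix(rbinom(n * m, 1L, as.vector(prob)), nrow = n, ncol = m)
    list(owned = owned, incidence = inc)
  })

  participants <- sprintf("p%02d", seq_len(n))
  dimnames(sim$incidence) <- list(participants, word_labels)
  out <- new_fluency_dataset(sim$incidence, language = spec$language,
                             category = spec$category)
  attr(out, "sim_spec") <- spec
  attr(out, "assignments") <- tibble::tibble(
    participant = rep(participants, each = spec$clusters_per_participant),
    cluster = unlist(lapply(seq_len(n), function(i) colnames(sim$owned)[sim$owned[i, ]]),
                     use.names = FALSE)
  )
  attr(out, "word_cluster") <- setNames(word_cluster, word_labels)
  out
}
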