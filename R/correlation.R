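#' Word-by-word correlation matrix of a fluency dataset
#'
#' Correlates word-production columns of the incidence matrix across
#' participants.  For binary columns the default Pearson correlation is the
#' phi coefficient.  Words produced by every participant or by none have
#' zero-variance columns and an undefined correlation; they are flagged
#' degenerate and, under the default `zero_variance = "keep"` policy, kept
#' as nodes with all their correlations set to 0 (so the word set of the
#' network still equals the produced vocabulary).  `"drop"` removes them.
#'
#' @param data A `fluency_dataset` or wide data frame (see
#'   [as_fluency_dataset()]).
#' @param method Correlation kind passed to [stats::cor()]:
#'   `"pearson"` (default; phi on binary data), `"spearman"` or `"kendall"`.
#' @param zero_variance Policy for zero-variance words: `"keep"` or `"drop"`.
#' @return A `weight_matrix`: list with `weights` (symmetric, unit diagonal,
#'   entries in \[-1, 1\]), `word_labels`, `degenerate` (named logical),
#'   `method`.
#' @export
#' @examples
#' d <- simulate_fluency(fluency_sim_spec(n_participants = 10, seed = 2))
#' w <- word_correlations(d)
#' range(w$weights)
word_correlations <- function(data,
                              method = c("pearson", "spearman", "kendall"),
                              zero_variance = c("keep", "drop")) {
  method <- match.arg(method)
  zero_variance <- match.arg(zero_variance)
  dataset <- as_fluency_dataset(data)
  inc <- dataset$incidence
  if (nrow(inc) < 2L) {
    stop_bilexnet("Correlations need at least 2 participants.", "validation")
  }
  degenerate <- apply(inc, 2L, function(col) stats::var(col) == 0)
  if (zero_variance == "drop" && any(degenerate)) {
    inc <- inc[, !degenerate, drop = FALSE]
    if (ncol(inc) < 2L) {
      stop_bilexnet("Fewer than 2 non-degenerate words left after dropping.",
                    "validation")
    }
    degenerate <- degenerate[!degenerate]
  }
  w <- suppressWarnings(stats::cor(inc, method = method))
  if (any(degenerate)) {
    w[degenerate, ] <- 0
    w[, degenerate] <- 0
  }
  diag(w) <- 1
  structure(
    list(weights = w, word_labels = colnames(w), degenerate = degenerate,
         method = method,
         language = dataset$language, category = dataset$category),
    class = "weight_matrix"
  )
}

#' @export
print.weight_matrix <- function(x, ...) {
  off <- x$weights[upper.tri(x$weights)]
  cat(sprintf("<weight_matrix> %d words, %s correlations (%d degenerate word(s))\n",
              length(x$word_labels), x$method, sum(x$degenerate)))
  cat(sprintf("  off-diagonal range [%.3f, %.3f]\n", min(off), max(off)))
  invisible(x)
}

#' @describeIn word_correlations Long tibble of unordered word pairs:
#'   `word_a`, `word_b`, `weight`, `degenerate` (TRUE if either word is).
#' @param x A `weight_matrix`.
#' @param ... Unused.
#' @method tidy weight_matrix
#' @export
tidy.weight_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$weights), arr.ind = TRUE)
  tibble::tibble(
    word_a = x$word_labels[idx[, 1L]],
    word_b = x$word_labels[idx[, 2L]],
    weight = x$weights[idx],
    degenerate = x$degenerate[idx[, 1L]] | x$degenerate[idx[, 2L]]
  )
}
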