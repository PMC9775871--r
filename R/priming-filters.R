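#' Exclude low-accuracy participants
#'
#' Removes all trials of any subject whose overall accuracy falls strictly
#' below `threshold` (default 80%); a subject at exactly the threshold is
#' retained.  The excluded subjects are reported via
#' `attr(, "exclusions")` / [exclusion_report()].
#'
#' @param trials A trial tibble (see [simulate_rt()] for the schema).
#' @param threshold Accuracy fraction below which a subject is excluded.
#' @return The filtered trial tibble, with an `exclusions` attribute: a
#'   tibble of `subject`, `n_trials`, `accuracy`, `excluded`.
#' @export
#' @examples
#' trials <- simulate_rt(rt_sim_spec(n_subjects = 6, n_items_per_cell = 5,
#'                                   accuracy = 0.85, seed = 3))
#' kept <- filter_participants(trials)
#' exclusion_report(kept)
filter_participants <- function(trials, threshold = 0.80) {
  trials <- validate_trials(trials)
  threshold <- check_prob(threshold, "threshold")
  report <- trials |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     accuracy = mean(.data$correct), .groups = "drop") |>
    dplyr::mutate(excluded = .data$accuracy < threshold)
  if (all(report$excluded)) {
    stop_bilexnet(
      sprintf("All %d subjects fall below the %.0f%% accuracy threshold.",
              nrow(report), 100 * threshold),
      "all_excluded", report = report)
  }
  out <- dplyr::filter(trials,
                       !.data$subject %in% report$subject[report$excluded])
  attr(out, "exclusions") <- report
  attr(out, "sim_spec") <- attr(trials, "sim_spec")
  out
}

#' @rdname filter_participants
#' @param x A trial tibble returned by [filter_participants()].
#' @export
exclusion_report <- function(x) {
  attr(x, "exclusions") %||%
    stop_bilexnet("No exclusion report attached; run filter_participants() first.",
                  "validation")
}

#' Preprocess reaction times: correct-only, outlier trimming, log transform
#'
#' In order: drops incorrect trials; within each trimming scope, removes in
#' a single (non-recursive) pass every trial whose RT lies more than
#' `k` standard deviations from that scope's mean; adds
#' `log_rt = ln(rt_ms)`.  A scope cell with fewer than 2 correct trials (SD
#' undefined) is left untrimmed with a warning.  Trimming is computed on the
#' millisecond scale, before the log transform.
#'
#' The default scope `"cell"` (subject x language condition x stimulus type,
#' the design cell) is the dominant convention in RT research; `"subject"`
#' and `"global"` are provided because the choice changes which trials are
#' removed.
#'
#' @param trials A trial tibble, normally already passed through
#'   [filter_participants()].
#' @param k SD multiplier for the trimming window (default 2.5).
#' @param scope Trimming scope: `"cell"`, `"subject"` or `"global"`.
#' @return The preprocessed tibble with a `log_rt` column and a `counts`
#'   attribute (tibble: `n_input`, `n_incorrect`, `n_trimmed`, `n_retained`);
#'   retained + removed always equals the input trial count.
#' @export
preprocess_rt <- function(trials, k = 2.5, scope = c("cell", "subject", "global")) {
  scope <- match.arg(scope)
  trials <- validate_trials(trials)
  k <- check_number(k, "k", min = 0)
  n_input <- nrow(trials)
  correct <- dplyr::filter(trials, .data$correct == 1L)
  n_incorrect <- n_input - nrow(correct)

  group_vars <- switch(scope,
    cell = c("subject", "language_condition", "stimulus_type"),
    subject = "subject",
    global = character(0)
  )
  grouped <- dplyr::group_by(correct, dplyr::across(dplyr::all_of(group_vars)))
  flagged <- grouped |>
    dplyr::mutate(
      .n = dplyr::n(),
      .mu = mean(.data$rt_ms),
      .sd = stats::sd(.data$rt_ms),
      .out = .data$.n >= 2L & .data$.sd > 0 &
        abs(.data$rt_ms - .data$.mu) > k * .data$.sd
    ) |>
    dplyr::ungroup()
  small <- dplyr::filter(flagged, .data$.n < 2L)
  if (nrow(small) > 0L) {
    rlang::warn(sprintf(
      "%d trimming cell(s) had < 2 correct trials; trimming skipped there.",
      dplyr::n_distinct(small[group_vars])))
  }
  out <- flagged |>
    dplyr::filter(!.data$.out) |>
    dplyr::select(-dplyr::all_of(c(".n", ".mu", ".sd", ".out"))) |>
    dplyr::mutate(log_rt = log(.data$rt_ms))
  attr(out, "counts") <- tibble::tibble(
    n_input = n_input,
    n_incorrect = n_incorrect,
    n_trimmed = nrow(correct) - nrow(out),
    n_retained = nrow(out)
  )
  attr(out, "exclusions") <- attr(trials, "exclusions")
  attr(out, "sim_spec") <- attr(trials, "sim_spec")
  out
}

#' Priming effect from condition means
#'
#' The long-term repetition-priming effect in milliseconds: mean RT to
#' unlearned items minus mean RT to learned items.  Positive values indicate
#' facilitation of previously studied (learned) items.
#'
#' @param mean_unlearned,mean_learned Mean RTs in ms (vectorised).
#' @return `mean_unlearned - mean_learned`, in ms.
#' @export
#' @examples
#' priming_effect(444.996, 427.850)
priming_effect <- function(mean_unlearned, mean_learned) {
  if (any(!is.finite(mean_unlearned)) || any(!is.finite(mean_learned))) {
    stop_bilexnet("Means must be finite.", "validation")
  }
  mean_unlearned - mean_learned
}

#' Per-condition RT means and priming effects
#'
#' @param trials A (preprocessed) trial tibble.
#' @return A tibble with one row per language condition: mean and SD of
#'   unlearned and learned RTs (ms) and the priming effect.
#' @export
priming_summary <- function(trials) {
  trials <- validate_trials(trials)
  trials |>
    dplyr::group_by(.data$language_condition, .data$stimulus_type) |>
    dplyr::summarise(mean = mean(.data$rt_ms), sd = stats::sd(.data$rt_ms),
                     n = dplyr::n(), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "stimulus_type",
                       values_from = c("mean", "sd", "n")) |>
    dplyr::mutate(priming_effect = priming_effect(.data$mean_unlearned,
                                                  .data$mean_learned))
}
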