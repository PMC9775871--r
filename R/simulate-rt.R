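#' Specification for a synthetic repetition-priming trial table
#'
#' Describes a lognormal reaction-time generator for a 2 (stimulus type:
#' learned vs unlearned) x 2 (language condition: D1-D2 vs D2-D1)
#' within-subject long-term repetition-priming design.  On the natural-log
#' scale, RT is the sum of a grand mean, Gaussian by-subject and by-item
#' random intercepts, a fixed shift `priming_beta` for learned items
#' (negative = facilitation, i.e. a positive millisecond priming effect),
#' and Gaussian residual noise; the millisecond RT is its exponential.
#' Trial correctness is drawn independently with probability `accuracy`.
#'
#' Modelling additive effects on the log scale mirrors the analysis stage,
#' which fits log-transformed RTs, so parameter recovery is well-specified.
#' Defaults emulate a cohort of 32 subjects with 20 learned and 20 unlearned
#' items per language condition and RTs around `exp(6) ~ 403` ms.
#'
#' @param n_subjects Number of subjects (>= 2: fewer would make the
#'   mixed-model fit degenerate).
#' @param n_items_per_cell Items per stimulus-type cell within each language
#'   condition (>= 2).
#' @param grand_mean_log_rt Grand mean of log RT (log-ms).
#' @param priming_beta Fixed learned-item shift on the log scale.
#' @param sd_subject,sd_item,sd_resid Standard deviations (log-ms, >= 0) of
#'   the subject effects, item effects, and residuals.
#' @param accuracy Probability a trial is answered correctly.
#' @param seed Integer seed.
#' @return An object of class `rt_sim_spec`.
#' @seealso [simulate_rt()]
#' @export
rt_sim_spec <- function(n_subjects = 32,
                        n_items_per_cell = 20,
                        grand_mean_log_rt = 6.0,
                        priming_beta = -0.12,
                        sd_subject = 0.2,
                        sd_item = 0.1,
                        sd_resid = 0.3,
                        accuracy = 0.95,
                        seed = 1L) {
  structure(
    list(
      n_subjects = check_count(n_subjects, "n_subjects", min = 2L),
      n_items_per_cell = check_count(n_items_per_cell, "n_items_per_cell", min = 2L),
      grand_mean_log_rt = check_number(grand_mean_log_rt, "grand_mean_log_rt"),
      priming_beta = check_number(priming_beta, "priming_beta"),
      sd_subject = check_number(sd_subject, "sd_subject", min = 0),
      sd_item = check_number(sd_item, "sd_item", min = 0),
      sd_resid = check_number(sd_resid, "sd_resid", min = 0),
      accuracy = check_prob(accuracy, "accuracy"),
      seed = check_count(seed, "seed")
    ),
    class = "rt_sim_spec"
  )
}

#' @export
print.rt_sim_spec <- function(x, ...) {
  cat("<rt_sim_spec>\n")
  cat(sprintf("  %d subjects, %d items/cell x 2 types x 2 conditions\n",
              x$n_subjects, x$n_items_per_cell))
  cat(sprintf("  log RT ~ %g %+g*learned, sd(subj) %g, sd(item) %g, sd(resid) %g\n",
              x$grand_mean_log_rt, x$priming_beta, x$sd_subject, x$sd_item,
              x$sd_resid))
  cat(sprintf("  accuracy %g, seed %d\n", x$accuracy, x$seed))
  invisible(x)
}

#' Simulate a repetition-priming trial table
#'
#' One test-phase trial per subject x item, items nested in
#' language condition x stimulus type.  See [rt_sim_spec()] for the
#' generative model.
#'
#' @param spec An [rt_sim_spec()].
#' @return A trial tibble with columns `subject`, `item`,
#'   `language_condition` (`"D1-D2"` / `"D2-D1"`), `stimulus_type`
#'   (`"learned"` / `"unlearned"`), `phase` (`"test"`), `rt_ms`, `correct`;
#'   the generating spec is attached as `attr(, "sim_spec")`.
#' @export
#' @examples
#' trials <- simulate_rt(rt_sim_spec(n_subjects = 4, n_items_per_cell = 3))
#' dplyr::count(trials, language_condition, stimulus_type)
simulate_rt <- function(spec) {
  if (!inherits(spec, "rt_sim_spec")) {
    stop_bilexnet("`spec` must be created by rt_sim_spec().", "validation")
  }
  subjects <- sprintf("s%02d", seq_len(spec$n_subjects))
  design <- tidyr::expand_grid(
    language_condition = c("D1-D2", "D2-D1"),
    stimulus_type = c("learned", "unlearned"),
    item_no = seq_len(spec$n_items_per_cell)
  )
  design$item <- sprintf("i_%s_%s_%02d",
                         sub("-", "", tolower(design$language_condition)),
                         substr(design$stimulus_type, 1L, 1L), design$item_no)
  trials <- tidyr::expand_grid(subject = subjects, design[c("language_condition",
                                                            "stimulus_type",
                                                            "item")])
  withr::with_seed(spec$seed, {
    subj_eff <- setNames(rnorm(spec$n_subjects, 0, spec$sd_subject), subjects)
    item_eff <- setNames(rnorm(nrow(design), 0, spec$sd_item), design$item)
    log_rt <- spec$grand_mean_log_rt +
      subj_eff[trials$subject] +
      item_eff[trials$item] +
      spec$priming_beta * (trials$stimulus_type == "learned") +
      rnorm(nrow(trials), 0, spec$sd_resid)
    trials$rt_ms <- exp(unname(log_rt))
    trials$correct <- rbinom(nrow(trials), 1L, spec$accuracy)
  })
  trials$phase <- "test"
  out <- trials[c("subject", "item", "language_condition", "stimulus_type",
                  "phase", "rt_ms", "correct")]
  attr(out, "sim_spec") <- spec
  out
}

#' Read and write trial tables as CSV
#'
#' Columns: `subject`, `item`, `language_condition`, `stimulus_type`,
#' `phase`, `rt_ms`, `correct`.  A JSON sidecar (`<path>.json`) records the
#' generating spec and seed for simulated tables.
#'
#' @param trials A trial tibble (see [simulate_rt()]).
#' @param path CSV file path.
#' @return `write_trials_csv()` returns `path` invisibly;
#'   `read_trials_csv()` returns a validated trial tibble.
#' @export
write_trials_csv <- function(trials, path) {
  validate_trials(trials)
  readr::write_csv(trials, path)
  spec <- attr(trials, "sim_spec")
  if (!is.null(spec)) {
    jsonlite::write_json(unclass(spec), paste0(path, ".json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  trials <- readr::read_csv(path, show_col_types = FALSE)
  validate_trials(trials)
}

# schema + invariant checks for trial tables
validate_trials <- function(trials) {
  if (!is.data.frame(trials)) {
    stop_bilexnet("Trials must be a data frame.", "schema")
  }
  check_columns(trials, c("subject", "item", "language_condition",
                          "stimulus_type", "rt_ms", "correct"),
                "trial table")
  if (!all(trials$language_condition %in% c("D1-D2", "D2-D1"))) {
    stop_bilexnet("`language_condition` must be \"D1-D2\" or \"D2-D1\".", "schema")
  }
  if (!all(trials$stimulus_type %in% c("learned", "unlearned"))) {
    stop_bilexnet("`stimulus_type` must be \"learned\" or \"unlearned\".", "schema")
  }
  if (!all(is.finite(trials$rt_ms)) || any(trials$rt_ms <= 0)) {
    stop_bilexnet("`rt_ms` must be finite and positive.", "schema")
  }
  if (!all(trials$correct %in% c(0L, 1L))) {
    stop_bilexnet("`correct` must be 0 or 1.", "schema")
  }
  tibble::as_tibble(trials)
}
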