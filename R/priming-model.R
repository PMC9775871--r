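#' Fit the priming mixed-effects model with backward random-structure selection
#'
#' Fits `log_rt ~ stimulus_type` for one language condition, with stimulus
#' type treatment-coded (unlearned = reference, so the coefficient is the
#' learned-item shift on the log scale: negative = facilitation = positive
#' millisecond priming effect).  The random-effects structure starts maximal
#' — correlated by-subject and by-item random intercepts and stimulus-type
#' slopes — and is simplified backwards: at each step every admissible
#' single reduction (drop an intercept-slope correlation; then a slope whose
#' correlation is gone; then an intercept whose slope is gone) is fitted by
#' maximum likelihood, and the reduction that least harms the fit is adopted
#' if a likelihood-ratio test cannot reject it at `alpha` (or, with
#' `criterion = "aic"`, if it lowers AIC).  If every random term is removed
#' the model collapses to ordinary least squares.  The selected structure is
#' refitted by REML for reporting; t and p values for mixed fits use
#' Satterthwaite degrees of freedom.
#'
#' If the maximal model fails to converge, the fit falls back down the same
#' simplification ladder until a model converges; the fallback is recorded
#' in the result.
#'
#' @param trials A preprocessed trial tibble (see [preprocess_rt()]; if
#'   `log_rt` is absent it is computed as `log(rt_ms)` with a message).
#' @param condition Language condition to analyse (`"D1-D2"` or `"D2-D1"`);
#'   may be omitted when the table contains a single condition.
#' @param criterion Backward-selection criterion: `"lrt"` (default) or
#'   `"aic"`.
#' @param alpha Significance level for the likelihood-ratio criterion.
#' @return A `priming_fit`: list with the fitted `model`, the selected
#'   `structure` (formula string), the `selection` path tibble, the `fixed`
#'   effects tibble, per-condition `means`, filtering `counts` (when
#'   present), and bookkeeping fields.  See [tidy.priming_fit()] and
#'   [glance.priming_fit()].
#' @export
#' @examples
#' \donttest{
#' trials <- simulate_rt(rt_sim_spec(n_subjects = 12, n_items_per_cell = 8,
#'                                   seed = 7))
#' fit <- fit_priming_model(preprocess_rt(filter_participants(trials)),
#'                          condition = "D1-D2")
#' tidy(fit)
#' }
fit_priming_model <- function(trials, condition = NULL,
                              criterion = c("lrt", "aic"), alpha = 0.05) {
  criterion <- match.arg(criterion)
  alpha <- check_prob(alpha, "alpha")
  trials <- validate_trials(trials)
  counts <- attr(trials, "counts")
  conditions <- unique(trials$language_condition)
  if (is.null(condition)) {
    if (length(conditions) != 1L) {
      stop_bilexnet("Several language conditions present; specify `condition`.",
                    "validation")
    }
    condition <- conditions
  }
  data <- dplyr::filter(trials, .data$language_condition == condition)
  if (nrow(data) == 0L) {
    stop_bilexnet(sprintf("No trials for condition \"%s\".", condition), "validation")
  }
  if (dplyr::n_distinct(data$subject) < 2L || dplyr::n_distinct(data$item) < 2L ||
      dplyr::n_distinct(data$stimulus_type) < 2L) {
    stop_bilexnet("Model needs >= 2 subjects, >= 2 items and both stimulus types.",
                  "validation")
  }
  if (!"log_rt" %in% names(data)) {
    rlang::inform("`log_rt` not found; computing log(rt_ms). Run preprocess_rt() to also filter and trim.")
    data$log_rt <- log(data$rt_ms)
  }
  data <- dplyr::mutate(data,
                        st_num = as.numeric(.data$stimulus_type == "learned"),
                        subject = factor(.data$subject),
                        item = factor(.data$item))

  maximal <- list(subject = c(int = TRUE, slope = TRUE, corr = TRUE),
                  item = c(int = TRUE, slope = TRUE, corr = TRUE))

  # --- maximal fit, stepping down the ladder on outright failure ----------
  state <- maximal
  current <- fit_rt_model(state, data, reml = FALSE)
  fallback <- NULL
  if (is.null(current)) {
    for (st in fallback_ladder(maximal)) {
      current <- fit_rt_model(st, data, reml = FALSE)
      if (!is.null(current)) {
        state <- st
        fallback <- structure_label(st)
        break
      }
    }
    if (is.null(current)) {
      stop_bilexnet("No random-effects structure could be fitted.", "model_failure")
    }
  }

  # --- greedy backward selection -----------------------------------------
  steps <- list()
  repeat {
    cands <- reduction_candidates(state)
    if (length(cands) == 0L) break
    fits <- lapply(cands, function(cnd) fit_rt_model(cnd$state, data, reml = FALSE))
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) break
    cands <- cands[ok]
    fits <- fits[ok]
    stat <- vapply(fits, function(f) lrt_vs(current, f), numeric(3))
    if (criterion == "lrt") {
      best <- which.max(stat["p", ])
      accept <- stat["p", best] > alpha
      record <- tibble::tibble(step = length(steps) + 1L,
                               removed = vapply(cands, `[[`, "", "label"),
                               chisq = stat["chisq", ], df = stat["df", ],
                               p = stat["p", ],
                               chosen = seq_along(cands) == best,
                               accepted = accept & seq_along(cands) == best)
    } else {
      aics <- vapply(fits, AIC, numeric(1))
      best <- which.min(aics)
      accept <- aics[best] < AIC(current)
      record <- tibble::tibble(step = length(steps) + 1L,
                               removed = vapply(cands, `[[`, "", "label"),
                               chisq = stat["chisq", ], df = stat["df", ],
                               p = aics - AIC(current),
                               chosen = seq_along(cands) == best,
                               accepted = accept & seq_along(cands) == best)
    }
    steps[[length(steps) + 1L]] <- record
    if (!accept) break
    state <- cands[[best]]$state
    current <- fits[[best]]
  }

  # --- refit selected structure by REML for reporting --------------------
  final <- fit_rt_model(state, data, reml = TRUE) %||% current
  fixed <- fixed_effects_table(final)
  structure(
    list(
      condition = condition,
      model = final,
      structure = structure_label(state),
      state = state,
      selection = if (length(steps)) dplyr::bind_rows(steps) else
        tibble::tibble(step = integer(), removed = character(),
                       chisq = numeric(), df = numeric(), p = numeric(),
                       chosen = logical(), accepted = logical()),
      fixed = fixed,
      means = priming_summary(data),
      counts = counts,
      n_trials = nrow(data),
      n_subjects = dplyr::n_distinct(data$subject),
      n_items = dplyr::n_distinct(data$item),
      criterion = criterion,
      alpha = alpha,
      fallback = fallback
    ),
    class = "priming_fit"
  )
}

# random-effects term for one grouping unit given its (int, slope, corr) flags
re_term <- function(flags, unit) {
  if (flags[["slope"]] && flags[["corr"]]) {
    sprintf("(1 + st_num | %s)", unit)
  } else if (flags[["slope"]]) {
    sprintf("(1 | %s) + (0 + st_num | %s)", unit, unit)
  } else if (flags[["int"]]) {
    sprintf("(1 | %s)", unit)
  } else {
    NULL
  }
}

structure_label <- function(state) {
  terms <- c(re_term(state$subject, "subject"), re_term(state$item, "item"))
  if (is.null(terms)) "none (ordinary least squares)" else {
    gsub("st_num", "stimulus_type", paste(terms, collapse = " + "))
  }
}

# fit one structure; NULL on outright failure (singular fits are kept)
fit_rt_model <- function(state, data, reml) {
  terms <- c(re_term(state$subject, "subject"), re_term(state$item, "item"))
  tryCatch({
    if (is.null(terms)) {
      stats::lm(log_rt ~ st_num, data = data)
    } else {
      form <- stats::as.formula(paste("log_rt ~ st_num +", paste(terms, collapse = " + ")))
      withCallingHandlers(
        lmerTest::lmer(form, data = data, REML = reml,
                       control = lme4::lmerControl(calc.derivs = FALSE,
                                                   check.conv.singular = "ignore")),
        message = function(m) invokeRestart("muffleMessage"),
        warning = function(w) invokeRestart("muffleWarning")
      )
    }
  }, error = function(e) NULL)
}

# admissible single reductions: correlations first, then slopes, then intercepts
reduction_candidates <- function(state) {
  cands <- list()
  for (unit in c("subject", "item")) {
    flags <- state[[unit]]
    if (flags[["slope"]] && flags[["corr"]]) {
      s <- state
      s[[unit]][["corr"]] <- FALSE
      cands[[length(cands) + 1L]] <-
        list(state = s, label = sprintf("correlation (%s)", unit))
    } else if (flags[["slope"]]) {
      s <- state
      s[[unit]][["slope"]] <- FALSE
      cands[[length(cands) + 1L]] <-
        list(state = s, label = sprintf("stimulus-type slope (%s)", unit))
    } else if (flags[["int"]]) {
      s <- state
      s[[unit]][["int"]] <- FALSE
      cands[[length(cands) + 1L]] <-
        list(state = s, label = sprintf("intercept (%s)", unit))
    }
  }
  cands
}

# convergence-fallback ladder: progressively simpler structures
fallback_ladder <- function(state) {
  flat <- function(sc, si, cc, ci) {
    list(subject = c(int = TRUE, slope = sc, corr = cc),
         item = c(int = TRUE, slope = si, corr = ci))
  }
  list(flat(TRUE, TRUE, FALSE, FALSE),
       flat(TRUE, FALSE, FALSE, FALSE),
       flat(FALSE, TRUE, FALSE, FALSE),
       flat(FALSE, FALSE, FALSE, FALSE),
       list(subject = c(int = TRUE, slope = FALSE, corr = FALSE),
            item = c(int = FALSE, slope = FALSE, corr = FALSE)),
       list(subject = c(int = FALSE, slope = FALSE, corr = FALSE),
            item = c(int = FALSE, slope = FALSE, corr = FALSE)))
}

# likelihood-ratio test of `reduced` nested in `full` (both ML fits); the
# boundary-of-parameter-space issue makes this conservative, which only
# favours retaining random terms
lrt_vs <- function(full, reduced) {
  ll_f <- logLik(full)
  ll_r <- logLik(reduced)
  chisq <- max(0, 2 * (as.numeric(ll_f) - as.numeric(ll_r)))
  df <- max(1, attr(ll_f, "df") - attr(ll_r, "df"))
  c(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

fixed_effects_table <- function(model) {
  if (inherits(model, "lm")) {
    cf <- summary(model)$coefficients
    tib <- tibble::tibble(term = rownames(cf), estimate = unname(cf[, 1L]),
                          se = unname(cf[, 2L]), df = model$df.residual,
                          t = unname(cf[, 3L]), p = unname(cf[, 4L]))
  } else {
    cf <- coef(summary(model))  # lmerTest: Satterthwaite df
    tib <- tibble::tibble(term = rownames(cf),
                          estimate = unname(cf[, "Estimate"]),
                          se = unname(cf[, "Std. Error"]),
                          df = unname(cf[, "df"]),
                          t = unname(cf[, "t value"]),
                          p = unname(cf[, "Pr(>|t|)"]))
  }
  tib$term <- sub("^st_num$", "stimulus_type_learned", tib$term)
  tib
}

#' @export
print.priming_fit <- function(x, ...) {
  cat(sprintf("<priming_fit> condition %s, %d trials (%d subjects, %d items)\n",
              x$condition, x$n_trials, x$n_subjects, x$n_items))
  cat("  random structure:", x$structure, "\n")
  if (!is.null(x$fallback)) {
    cat("  (maximal model did not converge; fell back to", x$fallback, ")\n")
  }
  st <- x$fixed[x$fixed$term == "stimulus_type_learned", ]
  cat(sprintf("  stimulus type (learned vs unlearned): %.4f (SE %.4f), t = %.3f, p = %.4g\n",
              st$estimate, st$se, st$t, st$p))
  cat(sprintf("  priming effect: %s ms\n",
              paste(sprintf("%.3f", x$means$priming_effect), collapse = ", ")))
  invisible(x)
}

#' Tidy and glance methods for priming fits
#'
#' `tidy()` returns the fixed-effects table (term, estimate, SE,
#' Satterthwaite df, t, p); `glance()` a one-row model summary including the
#' selected random structure and trial bookkeeping.
#'
#' @param x A `priming_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy priming_fit
#' @export
tidy.priming_fit <- function(x, ...) {
  dplyr::mutate(x$fixed, condition = x$condition, .before = 1L)
}

#' @rdname tidy.priming_fit
#' @method glance priming_fit
#' @export
glance.priming_fit <- function(x, ...) {
  tibble::tibble(
    condition = x$condition,
    structure = x$structure,
    criterion = x$criterion,
    n_trials = x$n_trials,
    n_subjects = x$n_subjects,
    n_items = x$n_items,
    logLik = as.numeric(logLik(x$model)),
    aic = AIC(x$model),
    fallback = x$fallback %||% NA_character_,
    priming_effect_ms = list(setNames(x$means$priming_effect,
                                      x$means$language_condition))
  )
}
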