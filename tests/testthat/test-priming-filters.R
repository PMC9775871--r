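# construct a trial tibble by hand
make_trials <- function(subject, rt, correct,
                        stimulus_type = "learned",
                        condition = "D1-D2") {
  tibble::tibble(
    subject = subject,
    item = paste0("i", seq_along(rt)),
    language_condition = condition,
    stimulus_type = stimulus_type,
    phase = "test",
    rt_ms = rt,
    correct = correct
  )
}

test_that("accuracy exclusion is strict-below with the boundary retained", {
  trials <- dplyr::bind_rows(
    make_trials(rep("low", 100), rep(400, 100), rep(c(1, 0), c(79, 21))),
    make_trials(rep("edge", 100), rep(400, 100), rep(c(1, 0), c(80, 20))),
    make_trials(rep("high", 100), rep(400, 100), rep(c(1, 0), c(95, 5)))
  )
  kept <- filter_participants(trials, threshold = 0.80)
  report <- exclusion_report(kept)
  expect_setequal(report$subject[report$excluded], "low")
  expect_setequal(unique(kept$subject), c("edge", "high"))
  expect_equal(nrow(kept), 200)
})

test_that("exclusion counts match a brute-force recount on a synthetic cohort", {
  withr::local_seed(91)
  acc <- runif(30, 0.70, 0.95)
  trials <- dplyr::bind_rows(lapply(seq_len(30), function(i) {
    make_trials(rep(sprintf("s%02d", i), 40), rep(400, 40),
                rbinom(40, 1, acc[i]))
  }))
  kept <- filter_participants(trials)
  report <- exclusion_report(kept)
  by_hand <- tapply(trials$correct, trials$subject, mean)
  expect_equal(sum(report$excluded), sum(by_hand < 0.80))
  expect_setequal(report$subject[report$excluded],
                  names(by_hand)[by_hand < 0.80])
})

test_that("constant RTs are never trimmed", {
  trials <- make_trials(rep("s1", 20), rep(400, 20), rep(1, 20))
  out <- preprocess_rt(trials, scope = "global")
  expect_equal(nrow(out), 20)
  expect_equal(attr(out, "counts")$n_trimmed, 0)
})

test_that("a single gross outlier is removed under global 2.5 SD trimming", {
  rt <- c(rep(400, 19), 4000)
  trials <- make_trials(rep("s1", 20), rt, rep(1, 20))
  out <- preprocess_rt(trials, k = 2.5, scope = "global")
  # arithmetic: mean 580, sd ~ 805; only the 4000 ms trial exceeds 2.5 SD
  expect_true(abs(4000 - mean(rt)) > 2.5 * sd(rt))
  expect_true(all(abs(400 - mean(rt)) <= 2.5 * sd(rt)))
  expect_equal(nrow(out), 19)
  expect_false(4000 %in% out$rt_ms)
})

test_that("incorrect trials are dropped before trimming and the log transform", {
  trials <- make_trials(rep("s1", 10), rep(403.4288, 10), rep(1, 10))
  trials$correct[3] <- 0L
  out <- preprocess_rt(trials, scope = "global")
  expect_equal(nrow(out), 9)
  counts <- attr(out, "counts")
  expect_equal(counts$n_incorrect, 1)
  expect_equal(counts$n_input, counts$n_incorrect + counts$n_trimmed +
                 counts$n_retained)
  # natural-log transform: 403.4288 ms -> 6.0000 log-ms
  expect_equal(round(out$log_rt[1], 4), 6)
})

test_that("filters are idempotent and preserve RT rank order", {
  trials <- simulate_rt(rt_sim_spec(n_subjects = 8, n_items_per_cell = 6,
                                    accuracy = 0.9, seed = 17))
  kept <- filter_participants(trials)
  expect_equal(nrow(filter_participants(kept)), nrow(kept))
  pp <- preprocess_rt(kept)
  pp2 <- suppressWarnings(preprocess_rt(pp))
  expect_equal(nrow(pp2), nrow(pp))
  expect_identical(order(pp$rt_ms), order(pp$log_rt))
})

test_that("trimming scope changes which trials are removed", {
  # one subject's RTs are uniformly slow: global trimming hits them,
  # per-subject trimming does not
  withr::local_seed(97)
  trials <- dplyr::bind_rows(
    make_trials(rep("fast", 30), rnorm(30, 400, 5), rep(1, 30)),
    make_trials(rep("slow", 30), rnorm(30, 1200, 5), rep(1, 30))
  )
  per_subject <- preprocess_rt(trials, scope = "subject")
  expect_gte(nrow(per_subject), 56)  # only within-subject outliers go
  cells <- preprocess_rt(trials, scope = "cell")
  expect_equal(nrow(cells), nrow(per_subject))  # one cell per subject here
})

test_that("published priming effects recompute from the printed means", {
  exact <- priming_effect(c(444.996, 372.725, 397.428),
                          c(427.850, 369.599, 411.796))
  expect_equal(exact, c(17.146, 3.126, -14.368), tolerance = 1e-9)
  rounded <- priming_effect(c(395.113, 342.912, 372.356),
                            c(389.677, 347.909, 375.225))
  expect_true(all(abs(rounded - c(5.435, -4.996, -2.868)) <= 0.001 + 1e-9))
  expect_equal(priming_effect(500, 500), 0)
  expect_error(priming_effect(Inf, 1), class = "bilexnet_validation")
})

test_that("priming summary satisfies its defining identity", {
  trials <- simulate_rt(rt_sim_spec(n_subjects = 6, n_items_per_cell = 5,
                                    seed = 19))
  s <- priming_summary(trials)
  expect_equal(s$priming_effect, s$mean_unlearned - s$mean_learned)
  expect_setequal(s$language_condition, c("D1-D2", "D2-D1"))
})
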