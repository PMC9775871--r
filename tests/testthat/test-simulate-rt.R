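test_that("noiseless null generator is exactly lognormal-degenerate", {
  spec <- rt_sim_spec(n_subjects = 5, n_items_per_cell = 4,
                      grand_mean_log_rt = 6, priming_beta = 0,
                      sd_subject = 0, sd_item = 0, sd_resid = 0,
                      accuracy = 1, seed = 1)
  trials <- simulate_rt(spec)
  expect_equal(nrow(trials), 5 * 4 * 2 * 2)
  expect_true(all(trials$rt_ms == exp(6)))
  s <- priming_summary(trials)
  expect_equal(s$priming_effect, c(0, 0))
  expect_true(all(trials$correct == 1L))
})

test_that("zero accuracy leads to every subject being excluded downstream", {
  trials <- simulate_rt(rt_sim_spec(n_subjects = 4, n_items_per_cell = 3,
                                    accuracy = 0, seed = 2))
  expect_error(filter_participants(trials), class = "bilexnet_all_excluded")
})

test_that("identical rt spec and seed give identical trial tables", {
  spec <- rt_sim_spec(n_subjects = 6, n_items_per_cell = 4, seed = 123)
  expect_identical(simulate_rt(spec), simulate_rt(spec))
})

test_that("learned-minus-unlearned log RT gap recovers the generating shift", {
  # raw cell-mean contrast over replicates, independent of any model fit
  gaps <- vapply(seq_len(50), function(r) {
    trials <- simulate_rt(rt_sim_spec(n_subjects = 8, n_items_per_cell = 6,
                                      priming_beta = -0.12, accuracy = 1,
                                      seed = 1000 + r))
    mean(log(trials$rt_ms[trials$stimulus_type == "learned"])) -
      mean(log(trials$rt_ms[trials$stimulus_type == "unlearned"]))
  }, numeric(1))
  expect_lt(abs(mean(gaps) - (-0.12)), 3 * sd(gaps) / sqrt(50))
})

test_that("paired comparison on the null generator rejects at the nominal rate", {
  # sd_item = 0 here deliberately: with shared items across subjects, item
  # noise does not average out over subjects and a by-subject test is no
  # longer exact (the classic fixed-language-effect fallacy the mixed model
  # exists to avoid)
  rejections <- vapply(seq_len(200), function(r) {
    trials <- simulate_rt(rt_sim_spec(n_subjects = 8, n_items_per_cell = 6,
                                      priming_beta = 0, sd_item = 0,
                                      accuracy = 1, seed = 5000 + r))
    by_subj <- tapply(log(trials$rt_ms),
                      list(trials$subject, trials$stimulus_type), mean)
    t.test(by_subj[, "learned"], by_subj[, "unlearned"],
           paired = TRUE)$p.value < 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(mean(rejections) - 0.05), 3 * se)
})

test_that("invalid rt specs are rejected", {
  expect_error(rt_sim_spec(n_subjects = 1), class = "bilexnet_validation")
  expect_error(rt_sim_spec(n_items_per_cell = 1), class = "bilexnet_validation")
  expect_error(rt_sim_spec(sd_resid = -0.1), class = "bilexnet_validation")
  expect_error(rt_sim_spec(accuracy = 1.5), class = "bilexnet_validation")
})

test_that("trial tables round-trip through CSV with their sidecar", {
  spec <- rt_sim_spec(n_subjects = 3, n_items_per_cell = 2, seed = 4)
  trials <- simulate_rt(spec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials_csv(trials, path)
  back <- read_trials_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(trials),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$seed, 4)
})
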