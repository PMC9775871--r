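test_that("zero random variance collapses the model to the two-group contrast", {
  trials <- simulate_rt(rt_sim_spec(n_subjects = 10, n_items_per_cell = 8,
                                    priming_beta = -0.12,
                                    sd_subject = 0, sd_item = 0, sd_resid = 0.3,
                                    accuracy = 1, seed = 29))
  trials$log_rt <- log(trials$rt_ms)
  fit <- fit_priming_model(trials, condition = "D1-D2")
  # with no true subject/item variance the selection should shed the slopes
  # at minimum; whatever remains, the balanced-design estimate must agree
  # with the plain difference in cell means
  expect_false(grepl("stimulus_type \\|", fit$structure))
  d <- trials[trials$language_condition == "D1-D2", ]
  two_group <- mean(d$log_rt[d$stimulus_type == "learned"]) -
    mean(d$log_rt[d$stimulus_type == "unlearned"])
  est <- fit$fixed$estimate[fit$fixed$term == "stimulus_type_learned"]
  expect_equal(est, two_group, tolerance = 1e-6)
})

test_that("sign convention: facilitation gives a negative log coefficient and a positive ms effect", {
  trials <- simulate_rt(rt_sim_spec(n_subjects = 20, n_items_per_cell = 12,
                                    priming_beta = -0.3, sd_resid = 0.1,
                                    accuracy = 1, seed = 31))
  fit <- fit_priming_model(preprocess_rt(filter_participants(trials)),
                           condition = "D2-D1")
  est <- fit$fixed$estimate[fit$fixed$term == "stimulus_type_learned"]
  expect_lt(est, 0)
  eff <- fit$means$priming_effect[fit$means$language_condition == "D2-D1"]
  expect_gt(eff, 0)
})

test_that("the selection path is recorded and the reported structure matches it", {
  trials <- simulate_rt(rt_sim_spec(n_subjects = 12, n_items_per_cell = 8,
                                    seed = 37))
  fit <- fit_priming_model(preprocess_rt(filter_participants(trials)),
                           condition = "D1-D2")
  expect_s3_class(fit$selection, "tbl_df")
  expect_gt(nrow(fit$selection), 0)
  # every accepted step must have been the chosen candidate
  expect_true(all(fit$selection$chosen[fit$selection$accepted]))
  # the final structure string parses back to the retained terms
  expect_true(fit$structure == "none (ordinary least squares)" ||
                grepl("\\| (subject|item)", fit$structure))
  expect_equal(tidy(fit)$term,
               c("(Intercept)", "stimulus_type_learned"))
  expect_equal(glance(fit)$condition, "D1-D2")
})

test_that("AIC-based selection also runs and reports a structure", {
  trials <- simulate_rt(rt_sim_spec(n_subjects = 10, n_items_per_cell = 6,
                                    seed = 41))
  fit <- fit_priming_model(preprocess_rt(filter_participants(trials)),
                           condition = "D1-D2", criterion = "aic")
  expect_s3_class(fit, "priming_fit")
  expect_true(nzchar(fit$structure))
})

test_that("model preconditions are enforced", {
  trials <- simulate_rt(rt_sim_spec(n_subjects = 6, n_items_per_cell = 4,
                                    seed = 43))
  expect_error(fit_priming_model(trials), class = "bilexnet_validation")
  only_learned <- dplyr::filter(trials, stimulus_type == "learned")
  expect_error(fit_priming_model(only_learned, condition = "D1-D2"),
               class = "bilexnet_validation")
  expect_error(fit_priming_model(trials, condition = "D3-D1"),
               class = "bilexnet_validation")
})

test_that("log_rt is derived on the fly when preprocessing was skipped", {
  trials <- simulate_rt(rt_sim_spec(n_subjects = 8, n_items_per_cell = 5,
                                    seed = 47))
  expect_message(fit <- fit_priming_model(trials, condition = "D2-D1"),
                 "log_rt")
  expect_s3_class(fit, "priming_fit")
})
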