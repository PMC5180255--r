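g <- stim_geometry()
mp <- build_manipulated_pairs(task_mapping("linear"))
kept <- mp$pairs[!mp$pairs$identical, ]

test_that("region masks cover the canvas and partition it at the midline", {
  up <- template_model("upper_field", g)$mask
  lo <- template_model("lower_field", g)$mask
  full <- template_model("full", g)$mask
  expect_equal(up + lo, full)
  expect_true(all(full == 1))
})

test_that("template predictions follow the chance rule for in-region identity", {
  # a pair differing only in its top arms
  pair_top <- list(positive = stim_config("top", "top"),
                   negative = stim_config("none", "top"),
                   pair_id = "t")
  expect_equal(template_prediction(template_model("lower_field", g),
                                   pair_top), 0.5)
  expect_equal(template_prediction(template_model("upper_field", g),
                                   pair_top), 1.0)
  expect_equal(template_prediction(template_model("full", g), pair_top), 1.0)
  # identical pair: chance under any model
  same <- list(positive = stim_config("top", "none"),
               negative = stim_config("top", "none"), pair_id = "s")
  for (kind in c("full", "upper_field", "lower_field"))
    expect_equal(template_prediction(template_model(kind, g), same), 0.5)
  # geometry mismatch is an input error
  expect_error(template_prediction(template_model("full", g), pair_top,
                                   geometry = stim_geometry(pixels_per_degree = 1)),
               "match")
})

test_that("binary half-field predictions jointly determine the full model", {
  pu <- template_predictions(template_model("upper_field", g), kept)
  pl <- template_predictions(template_model("lower_field", g), kept)
  pf <- template_predictions(template_model("full", g), kept)
  expect_equal(pf$prediction,
               ifelse(pu$prediction == 1 | pl$prediction == 1, 1, 0.5))
  # prediction matrix ids round-trip with the emitted pair table
  expect_setequal(pu$pair_id, kept$pair_id)
})

test_that("per-pair performance uses exact binomial intervals and windows", {
  log <- make_log(rep(c(TRUE, FALSE), 10))
  pp <- per_pair_performance(log, last_sessions = Inf)
  expect_equal(pp$accuracy, 0.5)
  expect_lte(pp$ci_lower, 0.5)
  expect_gte(pp$ci_upper, 0.5)
  # 20/20 correct: upper bound 1, lower bound above 0.8
  pp2 <- per_pair_performance(make_log(rep(TRUE, 20)), last_sessions = Inf)
  expect_equal(pp2$ci_upper, 1.0)
  expect_gt(pp2$ci_lower, 0.8)
  expect_equal(pp2$ci_lower,
               stats::binom.test(20, 20)$conf.int[1])
  # intervals shrink with trial count at fixed accuracy
  widths <- vapply(c(20, 80, 320), function(n) {
    p <- per_pair_performance(make_log(rep(c(TRUE, FALSE), n / 2)),
                              last_sessions = Inf)
    p$ci_upper - p$ci_lower
  }, 0)
  expect_true(all(diff(widths) < 0))
  # a pair with zero trials is reported, not dropped
  log2 <- make_log(rep(TRUE, 10))
  log2$pair_id <- "seen"
  log2$pair_id[1] <- "unseen"
  log2$correction_trial[1] <- TRUE
  pp3 <- per_pair_performance(log2, last_sessions = Inf)
  expect_true("unseen" %in% pp3$pair_id)
  expect_true(is.na(pp3$accuracy[pp3$pair_id == "unseen"]))
})

test_that("prediction-performance correlation handles perfect and degenerate cases", {
  pred <- data.frame(pair_id = letters[1:6],
                     prediction = c(0.5, 1, 0.5, 1, 0.5, 1))
  obs <- data.frame(pair_id = letters[1:6],
                    accuracy = c(0.5, 1, 0.5, 1, 0.5, 1))
  r <- prediction_performance_correlation(pred, obs)
  expect_equal(r$r, 1)
  expect_false(r$zero_variance)
  # zero variance in predictions is flagged, not an error
  flat <- data.frame(pair_id = letters[1:6], prediction = rep(1, 6))
  r2 <- prediction_performance_correlation(flat, obs)
  expect_true(r2$zero_variance)
  expect_true(is.na(r2$r))
  expect_error(prediction_performance_correlation(pred[1:2, ], obs[1:2, ]),
               "at least 3")
})

test_that("permutation p-values are calibrated against the analytic p", {
  set.seed(13)
  pred <- data.frame(pair_id = letters[1:10], prediction = runif(10))
  obs <- data.frame(pair_id = letters[1:10],
                    accuracy = pred$prediction + rnorm(10, sd = 0.3))
  r <- prediction_performance_correlation(pred, obs, n_permutations = 999,
                                          seed = 1)
  expect_true(r$p_permutation > 0 && r$p_permutation <= 1)
  expect_lt(abs(r$p_permutation - r$p), 0.1)
})

test_that("half-field reader agents correlate best with their matching model", {
  cm <- class_mean_images(task_mapping("linear"), g)
  plist <- crosslearn:::as_pair_list(kept)
  names(plist) <- vapply(plist, `[[`, "", "pair_id")
  preds <- lapply(c(upper_field = "upper_field", lower_field = "lower_field"),
                  function(kind) template_predictions(template_model(kind, g),
                                                      kept, g))
  for (kind in c("upper_field", "lower_field")) {
    mask <- template_model(kind, g)$mask
    agent <- strategy_linear_template(learning_rate = 0, template = cm$diff * mask,
                                      mask = mask)
    log <- simulate_subject(agent, task_mapping("linear"),
                            protocol_rat(max_sessions = 10), seed = 5,
                            pairs = plist)
    pp <- per_pair_performance(log, last_sessions = 10)
    obs <- data.frame(pair_id = pp$pair_id, accuracy = pp$accuracy)
    r_match <- prediction_performance_correlation(preds[[kind]], obs)$r
    other <- setdiff(c("upper_field", "lower_field"), kind)
    r_other <- prediction_performance_correlation(preds[[other]], obs)$r
    expect_gt(r_match, 0)
    expect_gt(r_match, r_other)
  }
})

test_that("transfer analysis reports the staged sign pattern and flags degeneracy", {
  # oracle: perfect on both pairs, correlation undefined by zero variance
  log <- simulate_staged_subject(strategy_oracle(), task_mapping("nonlinear"),
                                 protocol_rat(), seed = 1,
                                 stage_caps = c(4, 6, 2))
  tr <- transfer_analysis(log)
  expect_equal(tr$first_session$accuracy, c(1, 1))
  # perfect performance leaves the across-session correlation undefined
  # (zero variance or too few remaining sessions), flagged rather than 0
  expect_true(is.na(tr$correlation$r))
  # logs without the staged structure are rejected
  expect_error(transfer_analysis(make_log(rep(TRUE, 10))), "second_pair")
})

test_that("a carried-over linear rule helps the old pair and hurts the new pair", {
  log <- simulate_staged_subject(strategy_linear_template(),
                                 task_mapping("nonlinear"), protocol_rat(),
                                 seed = 2)
  tr <- transfer_analysis(log)
  expect_gt(tr$first_session$accuracy[tr$first_session$pair == "old"], 0.5)
  expect_lt(tr$first_session$accuracy[tr$first_session$pair == "new"], 0.5)
  # in the linear staging the same rule transfers positively to both pairs
  log2 <- simulate_staged_subject(strategy_linear_template(),
                                  task_mapping("linear"), protocol_rat(),
                                  seed = 2)
  tr2 <- transfer_analysis(log2)
  expect_true(all(tr2$first_session$accuracy > 0.5))
})
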