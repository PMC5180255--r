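test_that("backward curves align subjects at the criterion point", {
  # constructed subject: 40 trials, errors early, last 25 all correct;
  # human criterion lands at trial 35 (first window with mean > 0.8)
  correct <- c(rep(c(TRUE, FALSE), 10), rep(TRUE, 20))
  log <- make_log(correct)
  cr <- apply_criterion(log, protocol_human())
  curve <- backward_curve(list(log), protocol_human())
  expect_equal(nrow(curve), 20)
  expect_equal(curve$x, 1:20)
  expect_equal(curve$y, as.numeric(correct[(cr$point - 19):cr$point]))
  expect_equal(curve$se, rep(0, 20))  # single subject: se 0 by convention
  expect_equal(attr(curve, "n_subjects"), 1)
})

test_that("oracle cohorts give a flat perfect curve", {
  logs <- simulate_cohort(3, strategy_oracle(), task_mapping("nonlinear"),
                          protocol_human(), base_seed = 1)
  curve <- backward_curve(logs, protocol_human())
  expect_equal(curve$y, rep(1, 20))
  expect_equal(curve$se, rep(0, 20))
  expect_equal(attr(curve, "n_subjects"), 3)
})

test_that("subjects without criterion are excluded with a warning, all-excluded errors", {
  good <- make_log(rep(TRUE, 30), subject = "s1")
  bad <- make_log(rep(c(TRUE, FALSE), 20), subject = "s2")
  expect_warning(curve <- backward_curve(list(good, bad), protocol_human()),
                 "1 subject")
  expect_equal(attr(curve, "n_subjects"), 1)
  expect_equal(attr(curve, "n_excluded"), 1)
  expect_error(suppressWarnings(backward_curve(list(bad), protocol_human())),
               "empty")
})

test_that("noiseless logistic curves are recovered to high precision", {
  # a rat-style 9-session window with a mid-window rise
  curve <- simulate_logistic_cohort(0.68, 0.68, 6.65, noiseless = TRUE,
                                    n_points = 9)
  fit <- fit_logistic(curve, species = "rat")
  expect_true(fit$converged)
  expect_lt(max(abs(fit$par - c(0.68, 0.68, 6.65))), 1e-3)
  expect_lt(fit$sse, 1e-10)
  # human-style 20-point windows
  for (tri in list(c(0.89, 0.12, 20), c(0.54, 0.27, 2.68))) {
    cv <- simulate_logistic_cohort(tri[1], tri[2], tri[3], noiseless = TRUE,
                                   n_points = 20)
    f <- fit_logistic(cv, species = "human")
    expect_lt(max(abs(f$par - tri)), 1e-3)
    expect_lt(f$sse, 1e-10)
  }
})

test_that("the optimum is robust to perturbed start values within bounds", {
  curve <- simulate_logistic_cohort(0.68, 0.68, 6.65, noiseless = TRUE,
                                    n_points = 9)
  ref <- fit_logistic(curve, species = "rat")$par
  defs <- logistic_fit_defaults("rat")
  set.seed(11)
  for (i in 1:8) {
    st <- defs$start + stats::runif(3, -0.2, 0.2) * c(1, 1, 4)
    st <- pmin(pmax(st, defs$lower), defs$upper)
    f <- fit_logistic(curve, start = st, species = "rat")
    expect_lt(max(abs(f$par - ref)), 1e-3)
  }
})

test_that("a constant curve at baseline drives the asymptote to its lower bound", {
  fit <- fit_logistic(data.frame(x = 1:9, y = rep(0.55, 9)), species = "rat")
  expect_lt(fit$par["L"], 1e-6)
  expect_lt(fit$sse, 1e-12)
})

test_that("fitted parameters always respect the declared bounds", {
  set.seed(21)
  for (i in 1:10) {
    cv <- simulate_logistic_cohort(runif(1, 0.3, 0.9), runif(1, 0.1, 0.8),
                                   runif(1, 2, 8), n_subjects = 10,
                                   n_points = 9, trials_per_point = 30,
                                   seed = i)
    f <- fit_logistic(cv, species = "rat")
    expect_true(all(f$par >= f$lower - 1e-12))
    expect_true(all(f$par <= f$upper + 1e-12))
  }
})

test_that("linear fits recover exact lines and flat data", {
  f <- fit_linear(data.frame(x = 1:9, y = rep(0.5, 9)))
  expect_equal(f$slope, 0)
  expect_equal(f$intercept, 0.5)
  f <- fit_linear(data.frame(x = 1:20, y = 0.01 * (1:20) + 0.5))
  expect_equal(f$slope, 0.01, tolerance = 1e-12)
  expect_lt(f$sse, 1e-20)
})

test_that("a chance-level simulated rat cohort has a near-zero linear slope", {
  logs <- simulate_cohort(5, strategy_random(), task_mapping("nonlinear"),
                          protocol_rat(max_sessions = 9), base_seed = 31)
  curve <- backward_curve(logs, protocol_rat(), align = "end")
  f <- fit_linear(curve)
  # slope standard error from the regression itself
  se <- summary(stats::lm(y ~ x, data = curve))$coefficients["x", "Std. Error"]
  expect_lt(abs(f$slope), 3 * se)
})

test_that("model choice follows the data-generating process", {
  logistic_cv <- simulate_logistic_cohort(0.7, 0.5, 5, n_subjects = 30,
                                          n_points = 9,
                                          trials_per_point = 60, seed = 3)
  f_log <- fit_logistic(logistic_cv, species = "rat")
  f_lin <- fit_linear(logistic_cv)
  expect_lt(f_log$sse, f_lin$sse)
  # data below the logistic model's floor: the line must win
  drift <- data.frame(x = 1:20, y = 0.35 + 0.005 * (1:20))
  expect_lt(fit_linear(drift)$sse, fit_logistic(drift, species = "human")$sse)
})

test_that("the fit report orders fast and slow learners correctly", {
  fast <- simulate_logistic_cohort(0.7, 0.6, 3, n_subjects = 30,
                                   n_points = 20, trials_per_point = 60,
                                   seed = 5)
  slow <- simulate_logistic_cohort(0.7, 0.2, 12, n_subjects = 30,
                                   n_points = 20, trials_per_point = 60,
                                   seed = 6)
  rep_ <- model_selection_report(list(fast = fast, slow = slow),
                                 species = "human")
  expect_equal(rep_$model, c("logistic", "logistic"))
  expect_gt(rep_$k[1], rep_$k[2])
  expect_lt(rep_$x0[1], rep_$x0[2])
  # empty input and linear fallback
  expect_equal(nrow(model_selection_report(list())), 0)
  flat <- data.frame(x = 1:9, y = rep(0.5, 9))
  rep2 <- model_selection_report(list(chance = flat), species = "rat",
                                 linear_for = "chance")
  expect_equal(rep2$model, "linear")
  expect_false(is.na(rep2$slope))
})

test_that("Monte-Carlo cohorts track the generating curve within sampling error", {
  L <- 0.6; k <- 0.4; x0 <- 8
  cv <- simulate_logistic_cohort(L, k, x0, n_subjects = 30, n_points = 20,
                                 trials_per_point = 60, seed = 9)
  p <- logistic_growth(cv$x, L, k, x0)
  expect_true(all(abs(cv$y - p) <= 3 * pmax(cv$se, 1e-3)))
})
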