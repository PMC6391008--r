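test_that("constrained/unconstrained transforms round-trip exactly", {
  for (model in c("rl", "ddmrl")) {
    spec <- twostepr:::param_spec(model, "full")
    set.seed(21)
    for (i in 1:20) {
      theta <- twostepr:::draw_params(model)[spec$free]
      back <- twostepr:::from_unconstrained(
        twostepr:::to_unconstrained(theta, spec), spec)
      expect_equal(back, theta, tolerance = 1e-12)
    }
  }
})

test_that("tied variants expand to the full canonical parameter vector", {
  spec5 <- twostepr:::param_spec("rl", "tied")
  full <- twostepr:::expand_params(
    c(alpha1 = 0.3, beta1 = 4, lambda = 0.5, w = 0.7, p = 0.1), spec5)
  expect_equal(full[["alpha2"]], 0.3)
  expect_equal(full[["beta2"]], 4)
  spec8 <- twostepr:::param_spec("ddmrl", "tied")
  full8 <- twostepr:::expand_params(
    c(alpha1 = 0.3, alpha2 = 0.6, lambda = 0.5, w = 0.7, p = 0.1,
      b1 = 5, a1 = 2, tau1 = 0.3), spec8)
  expect_equal(unname(full8[c("b2", "a2", "tau2")]), c(5, 2, 0.3))
})

test_that("individual fit is deterministic and dominates the truth", {
  truth <- rl_params(alpha1 = 0.6, beta1 = 5, lambda = 0.5, w = 0.8, p = 0.2)
  d <- simulate_twostep(truth, task_config(n_trials = 300), seed = 22)
  opts <- fit_options(n_restarts = 8, seed = 7)
  f1 <- twostep_fit(d, model = "rl", opts = opts)
  f2 <- twostep_fit(d, model = "rl", opts = opts)
  expect_identical(coef(f1), coef(f2))
  expect_gte(f1$loglik[1], twostep_loglik(truth, d)) # MLE dominance
  expect_s3_class(f1, "twostep_fit")
  expect_equal(nrow(coef(f1)), 1)
})

test_that("refitting from the truth as a start recovers w on long sessions", {
  set.seed(23)
  for (w_true in c(0.05, 0.95)) {
    truth <- rl_params(alpha1 = 0.6, beta1 = 8, lambda = 0.5, w = w_true,
                       p = 0.1)
    d <- simulate_twostep(truth, task_config(n_trials = 1000), seed = 23 +
                            round(100 * w_true))
    f <- twostep_fit(d, model = "rl",
                     opts = fit_options(n_restarts = 3, seed = 1,
                                        init = unclass(truth)))
    expect_lt(abs(coef(f)[1, "w"] - w_true), 0.15)
  }
})

test_that("fitted-model methods print, summarize and simulate", {
  truth <- canonical_ddm()
  d <- simulate_twostep(truth, task_config(n_trials = 120), n_subjects = 2,
                        seed = 24)
  f <- twostep_fit(d, model = "ddmrl",
                   opts = fit_options(n_restarts = 2, maxit = 150, seed = 2))
  expect_output(print(f), "DDMRL model")
  expect_output(summary(f), "Parameter estimates")
  expect_s3_class(logLik(f), "logLik")
  sim <- simulate(f, seed = 3)
  expect_equal(sort(unique(sim$subject_id)), sort(unique(d$subject_id)))
  expect_equal(nrow(sim), nrow(d))
})

test_that("hierarchical EM shrinks a homogeneous population to the truth", {
  truth <- rl_params(alpha1 = 0.6, beta1 = 6, lambda = 0.5, w = 0.7, p = 0.1)
  d <- simulate_twostep(truth, task_config(n_trials = 250), n_subjects = 8,
                        seed = 25)
  h <- suppressWarnings(
    twostep_fit(d, model = "rl", hierarchical = TRUE,
                opts = fit_options(n_restarts = 2, maxit = 200, seed = 3,
                                   em_maxit = 12)))
  expect_s3_class(h, "twostep_hfit")
  # identical generating parameters: individual estimates cluster at truth
  expect_lt(abs(mean(coef(h)[, "w"]) - 0.7), 0.12)
  expect_lt(sd(coef(h)[, "w"]), 0.12)
  # shrinkage: hierarchical w spread no larger than individual-fit spread
  f <- twostep_fit(d, model = "rl",
                   opts = fit_options(n_restarts = 3, seed = 3))
  expect_lte(var(coef(h)[, "w"]), var(coef(f)[, "w"]) + 1e-8)
})

test_that("a flat prior makes the MAP coincide with the MLE", {
  set.seed(26)
  ses <- random_session(60)
  spec <- twostepr:::param_spec("rl", "full")
  nll <- twostepr:::neg_loglik_factory(ses, "rl", spec)
  eta <- twostepr:::to_unconstrained(
    c(alpha1 = 0.4, alpha2 = 0.5, beta1 = 3, beta2 = 3, lambda = 0.5,
      w = 0.5, p = 0.1), spec)
  pen <- twostepr:::penalty_gauss(eta, mu = rep(0, 7), sigma2 = rep(Inf, 7))
  expect_identical(pen, 0)
})

test_that("integrated BIC prefers the generating variant", {
  # stage-heterogeneous cohort: the 7-parameter model should win
  truth <- rl_params(alpha1 = 0.15, alpha2 = 0.9, beta1 = 2, beta2 = 8,
                     lambda = 0.5, w = 0.6, p = 0.1)
  d <- simulate_twostep(truth, task_config(n_trials = 250), n_subjects = 10,
                        seed = 27)
  opts <- fit_options(n_restarts = 2, maxit = 200, seed = 4, em_maxit = 8)
  h7 <- suppressWarnings(twostep_fit(d, "rl", "full", TRUE, opts))
  h5 <- suppressWarnings(twostep_fit(d, "rl", "tied", TRUE, opts))
  expect_lt(suppressWarnings(bic_int(h7)), suppressWarnings(bic_int(h5)))
  # tied-parameter cohort: the 5-parameter model wins or ties within 10
  truth_t <- rl_params(alpha1 = 0.6, beta1 = 5, lambda = 0.5, w = 0.6,
                       p = 0.1)
  dt <- simulate_twostep(truth_t, task_config(n_trials = 250),
                         n_subjects = 10, seed = 28)
  g7 <- suppressWarnings(twostep_fit(dt, "rl", "full", TRUE, opts))
  g5 <- suppressWarnings(twostep_fit(dt, "rl", "tied", TRUE, opts))
  expect_lt(suppressWarnings(bic_int(g5)), suppressWarnings(bic_int(g7)) + 10)
  # the penalty term alone is monotone in the number of parameters
  n_obs <- 2 * sum(d[d$subject_id == d$subject_id[1], "trial"] > 0) * 10
  expect_gt(2 * 7 * log(n_obs), 2 * 5 * log(n_obs))
})
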