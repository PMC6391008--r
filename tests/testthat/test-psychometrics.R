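test_that("Spearman-Brown correction is exact and monotone", {
  expect_equal(spearman_brown(0.5), 2 / 3)
  expect_equal(spearman_brown(1), 1)
  expect_equal(spearman_brown(0), 0)
  r <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(spearman_brown(r)) > 0))
})

test_that("split-half reliability spans its limiting cases", {
  set.seed(41)
  # identical halves by construction: duplicate each trial so the odd and
  # even halves contain the same behaviour
  base <- random_session(60, blocks = 1, with_rt = TRUE)
  dup <- lapply(sprintf("P%02d", 1:6), function(id) {
    b <- random_session(60, blocks = 1, with_rt = TRUE)
    twice <- b[rep(seq_len(60), each = 2), ]
    twice$trial <- seq_len(120)
    twice$subject_id <- id
    twice
  })
  dup <- do.call(rbind, dup)
  rep_dup <- split_half(dup, "mb2")
  expect_equal(rep_dup$r_raw, 1, tolerance = 1e-10)
  expect_equal(rep_dup$r_corrected, 1, tolerance = 1e-10)
  # independent noise between halves: corrected r near 0 across subjects
  many <- do.call(rbind, lapply(sprintf("Q%03d", 1:120), function(id) {
    s <- random_session(40, blocks = 1, with_rt = TRUE)
    s$subject_id <- id
    s
  }))
  rep_null <- split_half(many, "mb2")
  expect_lt(abs(rep_null$r_raw), 0.25)
  expect_error(split_half(many[many$subject_id %in% c("Q001", "Q002"), ],
                          "mb2"), ">= 3 sessions")
})

test_that("reliability at the full grid point reproduces split_half", {
  set.seed(42)
  d <- simulate_twostep(canonical_ddm(), task_config(n_trials = 60),
                        n_subjects = 8, seed = 42)
  curve <- reliability_curve(d, "mb2", trial_grid = c(40, 60))
  full <- split_half(d, "mb2")
  expect_equal(curve$r_corrected[curve$trials == 60], full$r_corrected)
  expect_error(reliability_curve(d, "mb2", trial_grid = 100), "exceeds")
})

test_that("temporal stability handles trivial and partial cases", {
  x <- c(0.1, 0.4, 0.2, 0.8, 0.6)
  expect_equal(temporal_stability(x, x)$estimate, 1)
  expect_warning(out <- temporal_stability(rep(0.3, 5), x), "constant")
  expect_true(is.na(out$estimate))
  expect_error(temporal_stability(x[1:2], x[1:2]), ">= 3")
  # partial correlation against the direct rank-residual formula
  set.seed(43)
  z <- rnorm(30)
  a <- z + rnorm(30)
  b <- z + rnorm(30)
  got <- temporal_stability(a, b, "partial", covariate = z)$estimate
  rx <- residuals(lm(rank(a) ~ rank(z)))
  ry <- residuals(lm(rank(b) ~ rank(z)))
  expect_equal(got, cor(rx, ry), tolerance = 1e-12)
  # and the plain rank correlation matches cor()
  expect_equal(temporal_stability(a, b, "spearman")$estimate,
               cor(a, b, method = "spearman"))
})

test_that("MANOVA chi-square has the right shape and null calibration", {
  set.seed(44)
  a <- matrix(rnorm(60), ncol = 2)
  out <- manova_chi2(a, a + 0) # identical groups
  expect_equal(out$df, 2)
  expect_equal(out$chi2, 0, tolerance = 1e-10)
  expect_equal(out$lambda, 1, tolerance = 1e-10)
  # agreement with stats::manova's Wilks lambda on random groups
  b <- matrix(rnorm(60, 0.4), ncol = 2)
  ours <- manova_chi2(a, b)
  g <- factor(rep(1:2, each = 30))
  fit <- summary(stats::manova(rbind(a, b) ~ g), test = "Wilks")
  expect_equal(ours$lambda, fit$stats[1, "Wilks"], tolerance = 1e-10)
  # type-I error calibration over replicates
  reject <- vapply(1:2000, function(i) {
    x <- matrix(rnorm(50 * 2), ncol = 2)
    y <- matrix(rnorm(50 * 2), ncol = 2)
    manova_chi2(x, y)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(reject) - 0.05), 0.015)
  expect_error(manova_chi2(a[, 1, drop = FALSE], a), "two dependent")
})

test_that("power analysis reaches its separation limit", {
  # groups ~10 SD apart with per-agent nuisance: every study detects it
  p_sep <- power_analysis(means = c(0.05, 0.95), w_sd = 0.09,
                          n_per_group = 25, n_trials = 150,
                          n_iterations = 15, nuisance = "agent", seed = 45)
  expect_gt(p_sep$power, 0.9)
  expect_s3_class(p_sep, "power_result")
  expect_output(print(p_sep), "significant")
})

test_that("degenerate recovery preserves ranks when started from the truth", {
  # widely separated w values, long sessions, truth supplied as the start:
  # the polished estimates stay in the truth's neighbourhood and the rank
  # correlation is perfect
  w_true <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  pars <- t(vapply(w_true, function(w)
    rl_params(alpha1 = 0.5, beta1 = 6, lambda = 0.5, w = w, p = 0.1),
    numeric(7)))
  d <- simulate_twostep(pars, task_config(n_trials = 800), seed = 46)
  sessions <- twostepr:::split_sessions(d)
  spec <- twostepr:::param_spec("rl", "full")
  ranges <- twostepr:::resolve_ranges(NULL, "rl", spec)
  rec <- t(vapply(seq_along(sessions), function(i) {
    opts <- fit_options(n_restarts = 1, maxit = 400, seed = i,
                        init = pars[i, ])
    twostepr:::fit_one(sessions[[i]], "rl", spec, ranges, opts)$theta
  }, numeric(7)))
  expect_lt(max(abs(rec[, "w"] - w_true)), 0.12)
  expect_equal(cor(w_true, rec[, "w"], method = "spearman"), 1)
})
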