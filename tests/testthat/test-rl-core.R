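test_that("single-trial value updates follow the SARSA(lambda) arithmetic", {
  # alpha2 = 0.5, Q(a2) = 0, r = 1  ->  Q(a2)' = 0.5
  ses2 <- make_session(c(1, 1), c(2, 2), c(1, 1), c(1, 1))
  tr2 <- twostep_trajectory(c(alpha1 = 0, alpha2 = 0.5, lambda = 0, w = 0,
                              p = 0), ses2)
  expect_equal(tr2$q2[2, 1], 0.5)

  # alpha1 = .5, lambda = .5: the first trial primes Q2(bandit 1) to 0.2
  # (one alpha2 = .2 update of reward 1 from zero); the second trial then
  # updates Q1 by .5 * .2 + .5 * .5 * (1 - .2) = 0.3
  par <- c(alpha1 = 0.5, alpha2 = 0.2, lambda = 0.5, w = 0, p = 0)
  ses3 <- make_session(c(2, 1, 1), c(2, 2, 2), c(1, 1, 1), c(1, 1, 1))
  tr3 <- twostep_trajectory(par, ses3)
  expect_equal(tr3$q2[2, 1], 0.2)
  expect_equal(tr3$qmf1[3, 1], 0.3)
  # and the stage-2 update of the same trial: 0.2 + 0.2 * (1 - 0.2)
  expect_equal(tr3$q2[3, 1], 0.36)

  # no learning: trajectory constant at zero
  set.seed(1)
  ses <- random_session(40)
  tr0 <- twostep_trajectory(c(alpha1 = 0, alpha2 = 0, lambda = 0.5, w = 0.3,
                              p = 0), ses)
  expect_true(all(tr0$qmf1 == 0) && all(tr0$q2 == 0))
})

test_that("model-based values weight state maxima by transition probability", {
  # maxima (1, 0) with p_common = .7 -> Q_MB(action 1) = .7
  ses <- make_session(c(1, 1), c(2, 2), c(1, 1), c(1, 1))
  tr <- twostep_trajectory(c(alpha1 = 0, alpha2 = 1, lambda = 0, w = 1, p = 0),
                           ses)
  # after trial 1: Q2 = (1,0,0,0), so trial-2 MB values are (.7, .3)
  expect_equal(tr$qmb[2, ], c(0.7, 0.3))
  # degenerate symmetry: all equal values give equal MB values
  expect_equal(tr$qmb[1, ], c(0, 0))
})

test_that("net values blend MF and MB components and add perseveration", {
  set.seed(2)
  ses <- random_session(30)
  par <- c(alpha1 = 0.4, alpha2 = 0.6, lambda = 0.3, w = 0, p = 0)
  tr <- twostep_trajectory(par, ses)
  expect_equal(tr$qnet, tr$qmf1) # w = 0, p = 0: pure model-free
  par["w"] <- 1
  tr <- twostep_trajectory(par, ses)
  expect_equal(tr$qnet, tr$qmb) # w = 1: pure model-based
  # direct arithmetic: Qnet = .5*(.2,.4) + .5*(.8,0) + p*Stay(action 1)
  expect_equal(0.5 * c(0.2, 0.4) + 0.5 * c(0.8, 0) + 0.1 * c(1, 0),
               c(0.6, 0.2))
})

test_that("uniform softmax gives 2n log(1/2) and probabilities normalize", {
  set.seed(3)
  ses <- random_session(25)
  p0 <- rl_params(alpha1 = 0.5, beta1 = 0, lambda = 0.5, w = 0.5, p = 0.3)
  expect_equal(twostep_loglik(p0, ses), 2 * 25 * log(0.5))
  # normalization: P(observed) + P(flipped) = 1 at stage 1
  p <- rl_params(alpha1 = 0.5, beta1 = 3, lambda = 0.5, w = 0.5, p = 0.1)
  flipped <- ses
  flipped$choice1 <- 3L - ses$choice1
  flipped$transition <- ifelse((flipped$choice1 == 1) == (flipped$state2 == 2),
                               "common", "rare")
  ll_obs <- twostep_loglik(p, ses, by_trial = TRUE)
  ll_flip <- twostep_loglik(p, flipped, by_trial = TRUE)
  # stage-2 contribution identical in both (same stage-2 choices), so
  # comparing at trial 1 (all values zero => stage-2 prob = 1/2) isolates
  # stage-1 normalization
  expect_equal(exp(ll_obs[1] - log(0.5)) + exp(ll_flip[1] - log(0.5)), 1)
})

test_that("compiled recursion matches the R oracle to machine precision", {
  par <- c(alpha1 = 0.5, alpha2 = 0.5, beta1 = 2, beta2 = 2, lambda = 0.5,
           w = 0.5, p = 0.1)
  # hand-specified 3-trial session
  ses3 <- make_session(choice1 = c(1, 1, 2), state2 = c(2, 3, 3),
                       choice2 = c(1, 2, 1), reward = c(1, 0, 1))
  o <- oracle_rl(par, ses3)
  expect_equal(twostep_loglik(par, ses3, model = "rl"), sum(o$loglik),
               tolerance = 1e-12)
  # random 50-trial sessions, multiple parameter draws
  set.seed(4)
  for (i in 1:5) {
    ses <- random_session(50)
    par_i <- c(alpha1 = runif(1), alpha2 = runif(1), beta1 = runif(1, 0, 8),
               beta2 = runif(1, 0, 8), lambda = runif(1), w = runif(1),
               p = runif(1, -0.3, 0.5))
    o <- oracle_rl(par_i, ses)
    tr <- twostep_trajectory(par_i, ses)
    expect_equal(tr$qmf1, o$qmf1, tolerance = 1e-12)
    expect_equal(tr$q2, o$q2, tolerance = 1e-12)
    expect_equal(tr$qnet, o$qnet, tolerance = 1e-12)
    expect_equal(twostep_loglik(par_i, ses, model = "rl",
                                by_trial = TRUE),
                 o$loglik, tolerance = 1e-12)
  }
})

test_that("trial order matters for the likelihood (value recursion)", {
  set.seed(5)
  ses <- random_session(40, blocks = 1)
  p <- rl_params(alpha1 = 0.6, beta1 = 4, lambda = 0.5, w = 0.5, p = 0.1)
  ll <- twostep_loglik(p, ses)
  perm <- ses[c(2:40, 1), ]
  perm$trial <- 1:40
  expect_false(isTRUE(all.equal(ll, twostep_loglik(p, perm))))
})

test_that("likelihood rejects bad input", {
  p <- rl_params(alpha1 = 0.5, beta1 = 5, lambda = 0.5, w = 0.5, p = 0)
  expect_error(twostep_loglik(p, random_session(10)[0, ]), "empty")
  bad <- unclass(p)
  bad["beta1"] <- NaN
  expect_error(twostep_loglik(bad, random_session(10), model = "rl"),
               "non-finite")
})
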