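# Pure-R reference implementations used as independent oracles for the
# compiled value recursion and likelihoods.

# step-through of the hybrid learner: SARSA(lambda) updates, transition-
# weighted model-based values, w-blend + perseveration, softmax likelihood
oracle_rl <- function(par, ses, p_common = 0.7) {
  n <- nrow(ses)
  q1 <- c(0, 0)
  q2 <- rep(0, 4)
  qmf1 <- matrix(0, n, 2); q2m <- matrix(0, n, 4)
  qmb <- matrix(0, n, 2); qnet <- matrix(0, n, 2)
  ll <- numeric(n)
  prev <- 0L; prev_block <- NA
  for (t in seq_len(n)) {
    if (is.na(prev_block) || ses$block[t] != prev_block) prev <- 0L
    prev_block <- ses$block[t]
    m <- c(max(q2[1:2]), max(q2[3:4]))
    mb <- c(p_common * m[1] + (1 - p_common) * m[2],
            (1 - p_common) * m[1] + p_common * m[2])
    net <- (1 - par[["w"]]) * q1 + par[["w"]] * mb
    if (prev > 0) net[prev] <- net[prev] + par[["p"]]
    qmf1[t, ] <- q1; q2m[t, ] <- q2; qmb[t, ] <- mb; qnet[t, ] <- net
    a1 <- ses$choice1[t]
    p1 <- exp(par[["beta1"]] * net) / sum(exp(par[["beta1"]] * net))
    bandit <- (ses$state2[t] - 2) * 2 + ses$choice2[t]
    pair <- if (ses$state2[t] == 2) 1:2 else 3:4
    p2 <- exp(par[["beta2"]] * q2[pair]) / sum(exp(par[["beta2"]] * q2[pair]))
    ll[t] <- log(p1[a1]) + log(p2[ses$choice2[t]])
    pe2 <- ses$reward[t] - q2[bandit]
    q1[a1] <- q1[a1] + par[["alpha1"]] * (q2[bandit] - q1[a1]) +
      par[["alpha1"]] * par[["lambda"]] * pe2
    q2[bandit] <- q2[bandit] + par[["alpha2"]] * pe2
    prev <- a1
  }
  list(qmf1 = qmf1, q2 = q2m, qmb = qmb, qnet = qnet, loglik = ll)
}

# a hand-specifiable session table
make_session <- function(choice1, state2, choice2, reward, rt1 = NA,
                         rt2 = NA, block = 1) {
  n <- length(choice1)
  data.frame(subject_id = "S001", timepoint = "t1",
             block = rep_len(block, n), trial = seq_len(n),
             choice1 = choice1,
             transition = ifelse((choice1 == 1) == (state2 == 2),
                                 "common", "rare"),
             state2 = state2, choice2 = choice2, reward = reward,
             rt1_s = rep_len(rt1, n), rt2_s = rep_len(rt2, n),
             stringsAsFactors = FALSE)
}

# random but valid session of n trials (uniform behaviour)
random_session <- function(n, blocks = 2, with_rt = FALSE) {
  choice1 <- sample(1:2, n, replace = TRUE)
  state2 <- sample(2:3, n, replace = TRUE)
  make_session(choice1, state2, sample(1:2, n, replace = TRUE),
               sample(0:1, n, replace = TRUE),
               rt1 = if (with_rt) runif(n, 0.4, 1.5) else NA,
               rt2 = if (with_rt) runif(n, 0.4, 1.5) else NA,
               block = rep(seq_len(blocks), each = ceiling(n / blocks),
                           length.out = n))
}

canonical_ddm <- function(w = 0.7) {
  ddmrl_params(alpha1 = 0.5, lambda = 0.6, w = w, p = 0.1, b1 = 5, a1 = 2,
               tau1 = 0.3)
}
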