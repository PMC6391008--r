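#' Log-likelihood of a session under the hybrid RL or DDM-RL model
#'
#' Rolls the hybrid model-based/model-free value recursion through the
#' observed trials and accumulates per-trial log-probabilities: softmax
#' choice probabilities at both stages for [rl_params()], or Wiener
#' first-passage densities of the observed (choice, RT) pairs for
#' [ddmrl_params()] (drift = `b *` Q-value difference towards the chosen
#' option, decision time = RT minus non-decision time). First-stage values
#' blend model-free and model-based components by `w` and add the
#' perseveration bonus; second-stage values are the model-free values within
#' the visited state.
#'
#' @param params an [rl_params()] or [ddmrl_params()] object (or full-length
#'   named numeric vector in canonical order together with `model`).
#' @param data a trial table for a single session (one subject, one
#'   timepoint), as produced by [simulate_twostep()] or [read_trials()].
#' @param model `"rl"` or `"ddmrl"`; inferred from `params` when classed.
#' @param by_trial return the vector of per-trial log-likelihood
#'   contributions instead of their sum.
#' @param floor_density Wiener densities are floored at this value (so
#'   observed RTs at or below the non-decision time yield a large finite
#'   penalty rather than `-Inf`).
#' @param eps series truncation tolerance for the Wiener density.
#' @return The session log-likelihood (scalar), or a per-trial vector.
#' @examples
#' p <- rl_params(0.5, 5, 0.6, 0.7, 0.1)
#' d <- simulate_twostep(p, task_config(n_trials = 50), seed = 1)
#' twostep_loglik(p, d)
#' @export
twostep_loglik <- function(params, data, model = NULL, by_trial = FALSE,
                           floor_density = 1e-10, eps = 1e-8) {
  if (is.null(model)) {
    model <- if (inherits(params, "rl_params")) "rl"
    else if (inherits(params, "ddmrl_params")) "ddmrl"
    else stop("supply `model` for an unclassed parameter vector")
  }
  check_finite(unclass(params))
  ses <- session_vectors(data, need_rt = (model == "ddmrl"))
  par <- unname(unclass(params))
  if (model == "rl") {
    if (length(par) != 7) stop("RL model needs 7 parameters")
    ll <- loglik_rl_cpp(par, ses$choice1, ses$state2, ses$choice2, ses$reward,
                        ses$block, ses$p_common, by_trial)
  } else {
    if (length(par) != 11) stop("DDM-RL model needs 11 parameters")
    ll <- loglik_ddmrl_cpp(par, ses$choice1, ses$state2, ses$choice2,
                           ses$reward, ses$rt1, ses$rt2, ses$block,
                           ses$p_common, eps, floor_density, by_trial)
  }
  if (by_trial) ll else ll[[1]]
}

#' Latent value trajectories for an observed session
#'
#' Replays the value recursion over a session and returns, per trial, the
#' pre-decision values entering the choice rule: model-free first-stage
#' values, the four second-stage bandit values, model-based first-stage
#' values (transition-weighted maxima of the visited-state values), net
#' first-stage values (the `w`-blend plus perseveration), and the previous
#' first-stage choice (0 on each block's first trial).
#'
#' @param params an [rl_params()] or [ddmrl_params()] object, or a named
#'   vector containing `alpha1`, `alpha2`, `lambda`, `w`, `p`.
#' @param data single-session trial table.
#' @param p_common transition probability used for the model-based values.
#' @return A list of matrices `qmf1` (n x 2), `q2` (n x 4), `qmb` (n x 2),
#'   `qnet` (n x 2) and the integer vector `stay_prev`.
#' @export
twostep_trajectory <- function(params, data, p_common = 0.7) {
  par <- unclass(params)
  need <- c("alpha1", "alpha2", "lambda", "w", "p")
  if (!all(need %in% names(par))) stop("params must name ", paste(need, collapse = ", "))
  ses <- session_vectors(data, need_rt = FALSE)
  latent_cpp(unname(par[need]), ses$choice1, ses$state2, ses$choice2,
             ses$reward, ses$block, p_common)
}

# validate a single-session trial table and unpack it to plain vectors
session_vectors <- function(data, need_rt = FALSE, p_common = 0.7) {
  need <- c("block", "trial", "choice1", "transition", "state2", "choice2",
            "reward")
  if (!all(need %in% names(data)))
    stop("session is missing column(s): ",
         paste(setdiff(need, names(data)), collapse = ", "))
  if (nrow(data) == 0) stop("empty session")
  if ("subject_id" %in% names(data) &&
      length(unique(data$subject_id)) > 1)
    stop("expected a single subject's session")
  if (!all(data$choice1 %in% c(1, 2)) || !all(data$choice2 %in% c(1, 2)) ||
      !all(data$state2 %in% c(2, 3)) || !all(data$reward %in% c(0, 1)))
    stop("invalid codes in session columns")
  if (need_rt) {
    if (!all(c("rt1_s", "rt2_s") %in% names(data)) ||
        anyNA(data$rt1_s) || anyNA(data$rt2_s))
      stop("DDM-RL likelihood requires complete rt1_s and rt2_s")
  }
  list(choice1 = as.integer(data$choice1), state2 = as.integer(data$state2),
       choice2 = as.integer(data$choice2), reward = as.integer(data$reward),
       block = as.integer(data$block),
       rt1 = if ("rt1_s" %in% names(data)) as.numeric(data$rt1_s) else NULL,
       rt2 = if ("rt2_s" %in% names(data)) as.numeric(data$rt2_s) else NULL,
       p_common = p_common)
}

# split a trial table into single sessions (subject x timepoint), keeping
# a stable order
split_sessions <- function(data) {
  key <- interaction(data$subject_id, data$timepoint, drop = TRUE,
                     lex.order = TRUE)
  split(data, key)
}
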