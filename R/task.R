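#' Two-stage task configuration
#'
#' Describes the generative environment of the two-stage decision task: a
#' first-stage choice between two options leads, with fixed probability
#' `p_common` (conventionally 0.7), to one of two second-stage states, each
#' offering two bandits whose binary-reward probabilities follow independent
#' Gaussian random walks reflected at `walk_bounds`. The frequent destination
#' of first-stage action 1 is state 2 (action 2 leads commonly to state 3).
#'
#' @param n_trials number of trials per session (>= 2). The canonical session
#'   lengths are 121 (baseline) and 201 (follow-up).
#' @param p_common probability of the common transition, in (0.5, 1\].
#' @param n_blocks number of blocks; a break splits the session evenly and
#'   resets the perseveration indicator on each block's first trial.
#' @param walk_sd standard deviation of the Gaussian step of each reward
#'   probability walk.
#' @param walk_bounds length-2 vector: reflecting lower/upper bounds of the
#'   walks, within \[0, 1\].
#' @param deadline optional response deadline in seconds; when set, simulated
#'   stages that exceed it are resampled. `NULL` (the default) imposes none.
#' @return An object of class `task_config`.
#' @examples
#' task_config(n_trials = 201)
#' @export
task_config <- function(n_trials = 201, p_common = 0.7, n_blocks = 2,
                        walk_sd = 0.025, walk_bounds = c(0.25, 0.75),
                        deadline = NULL) {
  if (!is.numeric(n_trials) || n_trials < 2) stop("n_trials must be >= 2")
  if (!(p_common > 0.5 && p_common <= 1)) stop("p_common must be in (0.5, 1]")
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  if (length(walk_bounds) != 2 || walk_bounds[1] < 0 || walk_bounds[2] > 1 ||
      walk_bounds[1] >= walk_bounds[2])
    stop("walk_bounds must satisfy 0 <= low < high <= 1")
  if (walk_sd < 0) stop("walk_sd must be >= 0")
  if (!is.null(deadline) && deadline <= 0) stop("deadline must be > 0")
  structure(list(n_trials = as.integer(n_trials), p_common = p_common,
                 n_blocks = as.integer(n_blocks), walk_sd = walk_sd,
                 walk_bounds = walk_bounds, deadline = deadline),
            class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf(paste0("Two-stage task: %d trials, %d block(s), ",
                     "P(common) = %.2f\n"),
              x$n_trials, x$n_blocks, x$p_common))
  cat(sprintf("Reward walks: Gaussian steps sd %.3f reflected at [%.2f, %.2f]\n",
              x$walk_sd, x$walk_bounds[1], x$walk_bounds[2]))
  if (!is.null(x$deadline))
    cat(sprintf("Response deadline: %.2f s (timed-out stages resampled)\n",
                x$deadline))
  invisible(x)
}

# block index per trial, breaks at (approximately) even boundaries
block_index <- function(n_trials, n_blocks) {
  rep(seq_len(n_blocks), each = ceiling(n_trials / n_blocks),
      length.out = n_trials)
}

#' Reward-probability random walks
#'
#' Generates the four bandits' reward-probability trajectories: independent
#' Gaussian random walks (step sd `config$walk_sd`) reflected at
#' `config$walk_bounds`, initialized uniformly within the bounds.
#'
#' @param config a [task_config()].
#' @param seed optional integer seed.
#' @return An `n_trials` x 4 matrix of reward probabilities.
#' @examples
#' w <- reward_walks(task_config(n_trials = 50), seed = 1)
#' range(w) # within walk_bounds
#' @export
reward_walks <- function(config = task_config(), seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  if (!is.null(seed)) set.seed(seed)
  probs <- reward_walks_cpp(config$n_trials, config$walk_sd,
                            config$walk_bounds[1], config$walk_bounds[2])
  colnames(probs) <- paste0("bandit", 1:4)
  probs
}

#' Sample second-stage states for first-stage choices
#'
#' @param choice1 vector of first-stage actions (1 or 2).
#' @param config a [task_config()].
#' @return Integer vector of second-stage states (2 or 3).
#' @examples
#' table(sample_transition(rep(1, 1000), task_config()))
#' @export
sample_transition <- function(choice1, config = task_config()) {
  stopifnot(inherits(config, "task_config"))
  if (!all(choice1 %in% c(1, 2))) stop("choice1 must be 1 or 2")
  common <- runif(length(choice1)) < config$p_common
  ifelse((choice1 == 1) == common, 2L, 3L)
}

#' Simulate agents performing the two-stage task
#'
#' Closed-loop simulation: values are learned trial by trial via the hybrid
#' model-based/model-free recursion, first- and second-stage choices are
#' emitted by a softmax (for [rl_params()]) or by a sampled Wiener diffusion
#' first passage (for [ddmrl_params()], which also yields reaction times),
#' and rewards are Bernoulli draws from the bandits' random-walk
#' probabilities. Each subject gets independent reward walks unless `walks`
#' is supplied.
#'
#' @param params an [rl_params()] or [ddmrl_params()] object, or a matrix
#'   with one row per subject (columns in the canonical parameter order).
#' @param config a [task_config()].
#' @param n_subjects number of subjects (ignored when `params` is a matrix).
#' @param timepoint session label, e.g. `"baseline"`.
#' @param subject_ids optional character vector of subject identifiers.
#' @param seed optional integer seed; the simulation is reproducible from it.
#' @param walks optional `n_trials` x 4 matrix of reward probabilities shared
#'   by all subjects.
#' @return A data frame in the trial-table schema: `subject_id`, `timepoint`,
#'   `block`, `trial`, `choice1`, `transition` (`"common"`/`"rare"`),
#'   `state2`, `choice2`, `reward`, `rt1_s`, `rt2_s` (RTs are `NA` for the
#'   choice-only RL model).
#' @examples
#' d <- simulate_twostep(rl_params(0.5, 5, 0.6, 0.7, 0.1),
#'                       task_config(n_trials = 50), n_subjects = 2, seed = 1)
#' head(d)
#' @export
simulate_twostep <- function(params, config = task_config(), n_subjects = 1,
                             timepoint = "t1", subject_ids = NULL,
                             seed = NULL, walks = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pm <- params_matrix(params, n_subjects)
  n_subjects <- nrow(pm$par)
  if (is.null(subject_ids))
    subject_ids <- sprintf("S%03d", seq_len(n_subjects))
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    wk <- if (is.null(walks)) reward_walks(config) else walks
    ses <- simulate_session(pm$par[i, ], pm$model, config, wk)
    ses$data$subject_id <- subject_ids[i]
    ses$data$timepoint <- timepoint
    out[[i]] <- ses$data
  }
  df <- do.call(rbind, out)
  df[c("subject_id", "timepoint", "block", "trial", "choice1", "transition",
       "state2", "choice2", "reward", "rt1_s", "rt2_s")]
}

# one session; par is a full canonical vector, model "rl" or "ddmrl".
# Returns list(data, q2) with q2 the pre-trial second-stage values when
# keep_latent is TRUE (used by the w-sweep mechanism analysis).
simulate_session <- function(par, model, config = task_config(),
                             walks = NULL, keep_latent = FALSE) {
  if (is.null(walks)) walks <- reward_walks(config)
  stopifnot(nrow(walks) == config$n_trials)
  blocks <- block_index(config$n_trials, config$n_blocks)
  deadline <- if (is.null(config$deadline)) 0 else config$deadline
  sim <- sim_session_cpp(ifelse(model == "rl", 0L, 1L), unname(par), walks,
                         config$p_common, blocks, keep_latent, deadline)
  data <- data.frame(
    subject_id = "S001", timepoint = "t1", block = blocks,
    trial = seq_len(config$n_trials), choice1 = sim$choice1,
    transition = ifelse(sim$transition == 1L, "common", "rare"),
    state2 = sim$state2, choice2 = sim$choice2, reward = sim$reward,
    rt1_s = sim$rt1, rt2_s = sim$rt2, stringsAsFactors = FALSE)
  list(data = data, q2 = if (keep_latent) sim$q2 else NULL)
}

# normalize `params` to a matrix with full canonical columns + model string
params_matrix <- function(params, n_subjects) {
  if (inherits(params, "rl_params") || inherits(params, "ddmrl_params")) {
    model <- if (inherits(params, "rl_params")) "rl" else "ddmrl"
    par <- matrix(rep(unclass(params), n_subjects), nrow = n_subjects,
                  byrow = TRUE, dimnames = list(NULL, names(params)))
  } else if (is.matrix(params)) {
    model <- if (ncol(params) == 7) "rl" else if (ncol(params) == 11) "ddmrl"
      else stop("parameter matrix must have 7 (RL) or 11 (DDM-RL) columns")
    par <- params
    spec <- param_spec(model, "full")
    if (is.null(colnames(par))) colnames(par) <- spec$all
    par <- par[, spec$all, drop = FALSE]
  } else stop("params must be rl_params, ddmrl_params, or a matrix")
  list(par = par, model = model)
}
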