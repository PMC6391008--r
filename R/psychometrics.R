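#' Spearman-Brown correction
#'
#' Steps a split-half correlation up to the reliability of the full-length
#' test: `2 r / (1 + r)`.
#'
#' @param r Pearson correlation between the two halves.
#' @return Corrected reliability.
#' @export
spearman_brown <- function(r) 2 * r / (1 + r)

#' Split-half reliability of a model-basedness score
#'
#' Splits every session into odd and even trials, computes the score on each
#' half, and correlates the half-scores across sessions (subject x
#' timepoint). For the choice score the halves are defined by the parity of
#' the *outcome* trial (the trial whose stay decision is scored); the
#' conditioning trial's transition/reward coding is retained regardless of
#' its own parity. For the RT score the halves are the trials whose RT is
#' measured.
#'
#' @param data multi-subject trial table.
#' @param score `"mb1"` (choice) or `"mb2"` (RT).
#' @param correct apply the [spearman_brown()] correction.
#' @return An object of class `reliability_report`: score name, raw and
#'   corrected correlations, number of sessions used (undefined half-scores
#'   are dropped pairwise and counted), and the trial count.
#' @examples
#' p <- ddmrl_params(alpha1 = 0.5, lambda = 0.6, w = 0.8, p = 0.1,
#'                   b1 = 5, a1 = 2, tau1 = 0.3)
#' d <- simulate_twostep(p, task_config(n_trials = 100), n_subjects = 8, seed = 1)
#' split_half(d, "mb2")
#' @export
split_half <- function(data, score = c("mb1", "mb2"), correct = TRUE) {
  score <- match.arg(score)
  sessions <- split_sessions(data)
  halves <- vapply(sessions, function(ses)
    c(half_score(ses, score, 1), half_score(ses, score, 0)), numeric(2))
  ok <- complete.cases(t(halves))
  if (sum(ok) < 3) stop("need >= 3 sessions with defined half-scores")
  r <- cor(halves[1, ok], halves[2, ok])
  structure(list(score = score, r_raw = r,
                 r_corrected = if (correct) spearman_brown(r) else NA_real_,
                 n_sessions = sum(ok), n_dropped = sum(!ok),
                 n_trials = max(vapply(sessions, nrow, integer(1)))),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("Split-half reliability of %s (%d trials, %d sessions%s)\n",
              toupper(x$score), x$n_trials, x$n_sessions,
              if (x$n_dropped) sprintf(", %d dropped", x$n_dropped) else ""))
  cat(sprintf("  odd/even r = %.3f", x$r_raw))
  if (!is.na(x$r_corrected))
    cat(sprintf(", Spearman-Brown corrected = %.3f", x$r_corrected))
  cat("\n")
  invisible(x)
}

# score on the odd (parity 1) or even (parity 0) half of one session
half_score <- function(ses, score, parity) {
  if (score == "mb1") {
    pr <- stay_pairs(ses)
    pr <- pr[pr$outcome_trial %% 2 == parity, ]
    cells <- vapply(list(c("common", 1), c("rare", 1), c("common", 0),
                         c("rare", 0)), function(cl) {
      sel <- pr$transition == cl[1] & pr$reward == as.integer(cl[2])
      if (!any(sel)) NA_real_ else mean(pr$stay[sel])
    }, numeric(1))
    (cells[1] - cells[2]) - (cells[3] - cells[4])
  } else {
    mb2_rt(ses[ses$trial %% 2 == parity, ])
  }
}

#' Reliability as a function of task length
#'
#' Recomputes [split_half()] on sessions truncated to their first `k` trials
#' for each `k` in `trial_grid`.
#'
#' @inheritParams split_half
#' @param trial_grid integer vector of trial counts (defaults to every trial
#'   from 20 to the shortest session).
#' @return Data frame with columns `trials`, `r_raw`, `r_corrected`,
#'   `n_sessions`; class `reliability_curve`.
#' @export
reliability_curve <- function(data, score = c("mb1", "mb2"),
                              trial_grid = NULL) {
  score <- match.arg(score)
  n_min <- min(vapply(split_sessions(data), nrow, integer(1)))
  if (is.null(trial_grid)) trial_grid <- seq(20L, n_min)
  if (any(trial_grid > n_min)) stop("trial_grid exceeds session length")
  rows <- lapply(trial_grid, function(k) {
    sub <- data[data$trial <= k, ]
    rep_k <- tryCatch(split_half(sub, score), error = function(e) NULL)
    data.frame(trials = k,
               r_raw = if (is.null(rep_k)) NA_real_ else rep_k$r_raw,
               r_corrected = if (is.null(rep_k)) NA_real_
                             else rep_k$r_corrected,
               n_sessions = if (is.null(rep_k)) 0L else rep_k$n_sessions)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("reliability_curve", "data.frame")
  out
}

#' @export
plot.reliability_curve <- function(x, ...) {
  plot(x$trials, x$r_corrected, type = "l", xlab = "trials in analysis",
       ylab = "split-half reliability (Spearman-Brown)", ylim = c(0, 1), ...)
  graphics::abline(h = 0.7, lty = 2)
  invisible(x)
}

#' Temporal stability between two testing sessions
#'
#' Correlates a subject-level score across two timepoints, with a normal
#' approximation confidence interval. The partial method residualizes both
#' vectors on a covariate's ranks before correlating (Spearman partial
#' correlation).
#'
#' @param x,y paired score vectors (one element per subject).
#' @param method correlation type.
#' @param covariate covariate vector for `method = "partial"`.
#' @param conf confidence level.
#' @return List with `estimate`, `conf_int`, `method`, `n`.
#' @export
temporal_stability <- function(x, y, method = c("pearson", "spearman",
                                                "partial"),
                               covariate = NULL, conf = 0.95) {
  method <- match.arg(method)
  ok <- complete.cases(x, y, if (is.null(covariate)) rep(0, length(x))
                             else covariate)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant score vector; correlation undefined")
    return(list(estimate = NA_real_, conf_int = c(NA_real_, NA_real_),
                method = method, n = n))
  }
  nz <- 0L
  if (method == "pearson") {
    est <- cor(x, y)
  } else if (method == "spearman") {
    est <- cor(x, y, method = "spearman")
  } else {
    if (is.null(covariate)) stop("partial correlation needs a covariate")
    z <- rank(covariate[ok])
    rx <- residuals(lm(rank(x) ~ z))
    ry <- residuals(lm(rank(y) ~ z))
    est <- cor(rx, ry)
    nz <- 1L
  }
  # Fisher z interval (1.06 variance inflation for rank-based estimates)
  infl <- if (method == "pearson") 1 else 1.06
  se <- sqrt(infl / (n - 3 - nz))
  zc <- qnorm(1 - (1 - conf) / 2)
  ci <- tanh(atanh(est) + c(-1, 1) * zc * se)
  list(estimate = est, conf_int = ci, method = method, n = n)
}

#' Parameter recovery study
#'
#' Draws agents' parameters uniformly from `ranges`, simulates each agent's
#' session, refits the generating model by individual maximum likelihood
#' (with the sampling ranges as optimizer box constraints), and reports the
#' Spearman correlation between true and recovered values per parameter.
#'
#' @param model `"rl"` or `"ddmrl"` (full variants: 7 and 11 parameters).
#' @param n_agents number of simulated agents.
#' @param n_trials session length.
#' @param ranges named list of sampling ranges; defaults to
#'   [default_ranges()].
#' @param config [task_config()] template (its `n_trials` is overridden).
#' @param opts [fit_options()] for the refits.
#' @param seed integer seed for the whole study.
#' @return Object of class `recovery_report`: `correlations` (named Spearman
#'   rho per parameter), `truth` and `recovered` matrices, `n_failed`.
#' @export
parameter_recovery <- function(model = c("rl", "ddmrl"), n_agents = 100,
                               n_trials = 200, ranges = NULL,
                               config = task_config(), opts = fit_options(),
                               seed = 1) {
  model <- match.arg(model)
  if (is.null(ranges)) ranges <- default_ranges(model)
  set.seed(seed)
  cfg <- task_config(n_trials = n_trials, p_common = config$p_common,
                     n_blocks = config$n_blocks, walk_sd = config$walk_sd,
                     walk_bounds = config$walk_bounds)
  spec <- param_spec(model, "full")
  truth <- t(vapply(seq_len(n_agents), function(i) draw_params(model, ranges),
                    numeric(length(spec$all))))
  data <- simulate_twostep(truth, cfg,
                           subject_ids = sprintf("A%04d", seq_len(n_agents)))
  fit <- twostep_fit(data, model = model, variant = "full",
                     opts = modifyList(opts, list(ranges = ranges)))
  rec <- coef(fit)
  ok <- complete.cases(rec)
  rho <- vapply(spec$all, function(nm)
    cor(truth[ok, nm], rec[ok, nm], method = "spearman"), numeric(1))
  structure(list(model = model, n_agents = n_agents, n_trials = n_trials,
                 correlations = rho, truth = truth, recovered = rec,
                 n_failed = sum(!ok)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery, %s model: %d agents, %d trials%s\n",
              toupper(x$model), x$n_agents, x$n_trials,
              if (x$n_failed) sprintf(" (%d fits failed)", x$n_failed) else ""))
  cat("Spearman r(true, recovered):\n")
  print(round(x$correlations, 3))
  invisible(x)
}

#' @export
plot.recovery_report <- function(x, parameter = "w", ...) {
  ok <- complete.cases(x$recovered)
  plot(x$truth[ok, parameter], x$recovered[ok, parameter],
       xlab = paste("true", parameter), ylab = paste("recovered", parameter),
       ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Mechanism sweep over the model-based weight
#'
#' Simulates DDM-RL experiments at each value of `w_grid` (other parameters
#' drawn uniformly from `ranges` per experiment) and summarizes, per level:
#' mean MB-I and MB-II scores (plus their standardized-across-levels
#' versions), mean within-state Q-value spread (max - min of the visited
#' state's two bandit values) after common and after rare transitions, the
#' spread of the "best" state (the state holding the globally maximal
#' second-stage Q-value) and of the other ("worst") state, and the
#' probability of entering the best state through a common transition.
#'
#' @param w_grid model-based weights to sweep.
#' @param n_experiments simulated experiments per level.
#' @param n_trials trials per experiment.
#' @param ranges nuisance-parameter sampling ranges (defaults to
#'   [default_ranges()] for the DDM-RL model).
#' @param config [task_config()] template for the environment.
#' @param seed integer seed.
#' @return Object of class `w_sweep`: `by_w` data frame and overall
#'   `dq_best` / `dq_worst` means pooled over all simulations.
#' @export
w_sweep <- function(w_grid = seq(0, 1, by = 0.1), n_experiments = 200,
                    n_trials = 5000, ranges = NULL, config = task_config(),
                    seed = 1) {
  if (is.null(ranges)) ranges <- default_ranges("ddmrl")
  set.seed(seed)
  cfg <- task_config(n_trials = n_trials, p_common = config$p_common,
                     n_blocks = 1, walk_sd = config$walk_sd,
                     walk_bounds = config$walk_bounds)
  acc <- expand.grid(w = w_grid, exp = seq_len(n_experiments))
  res <- matrix(NA_real_, nrow(acc), 6,
                dimnames = list(NULL, c("mb1", "mb2", "dq_common", "dq_rare",
                                        "dq_best", "dq_worst")))
  p_best_common <- numeric(nrow(acc))
  for (i in seq_len(nrow(acc))) {
    par <- draw_params("ddmrl", ranges)
    par["w"] <- acc$w[i]
    sim <- simulate_session(par, "ddmrl", cfg, keep_latent = TRUE)
    q2 <- sim$q2
    d <- sim$data
    spread2 <- pmax(q2[, 1], q2[, 2]) - pmin(q2[, 1], q2[, 2])
    spread3 <- pmax(q2[, 3], q2[, 4]) - pmin(q2[, 3], q2[, 4])
    visited <- ifelse(d$state2 == 2, spread2, spread3)
    best_is_2 <- pmax(q2[, 1], q2[, 2]) >= pmax(q2[, 3], q2[, 4])
    res[i, ] <- c(mb1_choice(d), mb2_rt(d),
                  mean(visited[d$transition == "common"]),
                  mean(visited[d$transition == "rare"]),
                  mean(ifelse(best_is_2, spread2, spread3)),
                  mean(ifelse(best_is_2, spread3, spread2)))
    p_best_common[i] <- mean((d$state2 == ifelse(best_is_2, 2, 3)) &
                               d$transition == "common")
  }
  by_w <- aggregate(cbind(res, p_best_common = p_best_common),
                    by = list(w = acc$w), FUN = mean, na.rm = TRUE)
  by_w$mb1_std <- as.numeric(scale(by_w$mb1))
  by_w$mb2_std <- as.numeric(scale(by_w$mb2))
  structure(list(by_w = by_w, dq_best = mean(res[, "dq_best"]),
                 dq_worst = mean(res[, "dq_worst"]),
                 n_experiments = n_experiments, n_trials = n_trials),
            class = "w_sweep")
}

#' @export
print.w_sweep <- function(x, ...) {
  cat(sprintf("w-sweep: %d experiments x %d trials per level\n",
              x$n_experiments, x$n_trials))
  print(round(x$by_w, 3))
  cat(sprintf("Mean within-state Q spread: best state %.3f, worst state %.3f\n",
              x$dq_best, x$dq_worst))
  invisible(x)
}

#' Two-group MANOVA chi-square on a pair of scores
#'
#' One-way two-group MANOVA on two dependent variables via Wilks' lambda
#' with Bartlett's chi-square approximation:
#' `chi2 = -(N - 1 - (p + g)/2) * log(Lambda)`, `df = p * (g - 1) = 2`.
#'
#' @param group_a,group_b matrices/data frames with two columns (one row per
#'   subject).
#' @return List `chi2`, `df`, `p_value`, `lambda`.
#' @export
manova_chi2 <- function(group_a, group_b) {
  a <- as.matrix(group_a); b <- as.matrix(group_b)
  if (ncol(a) != 2 || ncol(b) != 2) stop("expected two dependent variables")
  if (nrow(a) < 3 || nrow(b) < 3) stop("need >= 3 subjects per group")
  all <- rbind(a, b)
  tot <- crossprod(scale(all, scale = FALSE))
  wi <- crossprod(scale(a, scale = FALSE)) + crossprod(scale(b, scale = FALSE))
  if (abs(det(wi)) < 1e-300) stop("singular within-group covariance")
  lambda <- det(wi) / det(tot)
  n <- nrow(all)
  chi2 <- -(n - 1 - (2 + 2) / 2) * log(lambda)
  list(chi2 = chi2, df = 2, p_value = pchisq(chi2, 2, lower.tail = FALSE),
       lambda = lambda)
}

#' Simulation-based power analysis for group comparisons
#'
#' Estimates the power of a two-group MANOVA on the pair (MB-I, MB-II) to
#' detect a group difference in the model-based weight. Per iteration, each
#' group's `w` values are drawn from a Gaussian (sd `w_sd`) truncated to
#' \[0, 1\] around its group mean, every agent's remaining DDM-RL parameters
#' are drawn uniformly from `ranges`, a session is simulated per agent, both
#' scores are computed, and the MANOVA chi-square is tested at `alpha`.
#' Power is the fraction of significant iterations.
#'
#' @param effect `"small"` (group means .49/.51, Cohen's d = .2),
#'   `"medium"` (.475/.525, d = .5), `"large"` (.46/.54, d = .8) or
#'   `"null"` (.5/.5); alternatively supply `means` directly.
#' @param n_per_group agents per group.
#' @param n_trials trials per agent.
#' @param n_iterations simulated studies.
#' @param means optional length-2 vector of group w-means overriding
#'   `effect`.
#' @param w_sd standard deviation of the w distribution.
#' @param alpha significance level.
#' @param ranges nuisance-parameter ranges (defaults to
#'   [default_ranges()] for the DDM-RL model).
#' @param nuisance whether the non-w parameters are drawn once per simulated
#'   experiment (shared by every agent in that iteration, mirroring the
#'   sweep convention of [w_sweep()]; the default) or independently per
#'   agent.
#' @param config [task_config()] template for the environment.
#' @param seed integer seed.
#' @return Object of class `power_result`: `power` (proportion), binomial
#'   95% `conf_int`, `n_failed` iterations excluded, and the settings.
#' @export
power_analysis <- function(effect = c("small", "medium", "large", "null"),
                           n_per_group = 30, n_trials = 200,
                           n_iterations = 1000, means = NULL, w_sd = 0.1,
                           alpha = 0.05, ranges = NULL,
                           nuisance = c("experiment", "agent"),
                           config = task_config(), seed = 1) {
  nuisance <- match.arg(nuisance)
  if (is.null(means)) {
    effect <- match.arg(effect)
    means <- switch(effect, small = c(0.49, 0.51), medium = c(0.475, 0.525),
                    large = c(0.46, 0.54), null = c(0.5, 0.5))
  } else effect <- "custom"
  stopifnot(all(means >= 0 & means <= 1), w_sd > 0)
  if (is.null(ranges)) ranges <- default_ranges("ddmrl")
  set.seed(seed)
  cfg <- task_config(n_trials = n_trials, p_common = config$p_common,
                     n_blocks = config$n_blocks, walk_sd = config$walk_sd,
                     walk_bounds = config$walk_bounds)
  blocks <- block_index(cfg$n_trials, cfg$n_blocks)
  spec_all <- param_spec("ddmrl", "full")$all
  sig <- logical(n_iterations)
  failed <- logical(n_iterations)
  for (it in seq_len(n_iterations)) {
    shared <- draw_params("ddmrl", ranges)
    sc <- lapply(means, function(mu) {
      par <- if (nuisance == "experiment")
        matrix(shared, n_per_group, length(spec_all), byrow = TRUE,
               dimnames = list(NULL, spec_all))
      else
        t(vapply(seq_len(n_per_group),
                 function(i) draw_params("ddmrl", ranges),
                 numeric(length(spec_all))))
      par[, "w"] <- rtruncnorm(n_per_group, mu, w_sd, 0, 1)
      s <- sim_cohort_scores_cpp(par, cfg$n_trials, cfg$p_common,
                                 cfg$walk_sd, cfg$walk_bounds[1],
                                 cfg$walk_bounds[2], blocks, 0)
      s[complete.cases(s), , drop = FALSE]
    })
    test <- tryCatch(manova_chi2(sc[[1]], sc[[2]]), error = function(e) NULL)
    if (is.null(test)) failed[it] <- TRUE
    else sig[it] <- test$p_value < alpha
  }
  n_ok <- sum(!failed)
  pw <- mean(sig[!failed])
  se <- sqrt(pw * (1 - pw) / n_ok)
  structure(list(power = pw, conf_int = pmin(pmax(pw + c(-1, 1) * 1.96 * se,
                                                  0), 1),
                 n_failed = sum(failed), effect = effect, means = means,
                 w_sd = w_sd, n_per_group = n_per_group, n_trials = n_trials,
                 n_iterations = n_iterations, alpha = alpha),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(paste0("Power (%s effect: w-means %.3f/%.3f, sd %.2f), ",
                     "%d/group, %d trials, %d iterations:\n"),
              x$effect, x$means[1], x$means[2], x$w_sd, x$n_per_group,
              x$n_trials, x$n_iterations))
  cat(sprintf("  %.1f%% significant at alpha = %.2f (95%% CI %.1f-%.1f%%)%s\n",
              100 * x$power, x$alpha, 100 * x$conf_int[1],
              100 * x$conf_int[2],
              if (x$n_failed) sprintf("; %d failed", x$n_failed) else ""))
  invisible(x)
}

# Gaussian truncated to [lo, hi] by rejection (cheap at sd 0.1 around 0.5)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}
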