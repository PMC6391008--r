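#' Fitting options
#'
#' @param n_restarts number of random multistart points per session.
#' @param maxit optimizer iteration budget per start.
#' @param seed integer seed making the fit deterministic.
#' @param ranges optional named list of `c(lower, upper)` box constraints and
#'   start ranges per parameter; defaults to [default_ranges()] for the model.
#' @param init optional named vector of free parameters (natural scale) used
#'   as an additional deterministic start point.
#' @param em_maxit maximum EM iterations for hierarchical fits.
#' @param em_tol relative-change convergence tolerance on the total
#'   approximate evidence.
#' @param var_floor floor on prior variances in the EM M-step.
#' @return A list of options for [twostep_fit()].
#' @export
fit_options <- function(n_restarts = 8, maxit = 500, seed = 1, ranges = NULL,
                        init = NULL, em_maxit = 200, em_tol = 1e-4,
                        var_floor = 1e-6) {
  stopifnot(n_restarts >= 1, maxit >= 1)
  list(n_restarts = n_restarts, maxit = maxit, seed = seed, ranges = ranges,
       init = init, em_maxit = em_maxit, em_tol = em_tol,
       var_floor = var_floor)
}

#' Fit the hybrid RL or DDM-RL model to two-stage task data
#'
#' Maximum-likelihood estimation per subject-by-timepoint session via
#' multistart quasi-Newton optimization in unconstrained (logit/log)
#' parameter space, or hierarchical estimation via expectation-maximization
#' with a Laplace approximation, where each parameter has a Gaussian
#' population distribution (in transformed space) whose mean and variance
#' are estimated alongside the subject-level parameters.
#'
#' @param data trial table (one or more subjects/timepoints).
#' @param model `"rl"` (choice-only softmax) or `"ddmrl"` (joint choice+RT).
#' @param variant `"full"` for stage-specific parameters (7 for RL, 11 for
#'   DDM-RL) or `"tied"` for the reduced set (5 and 8) sharing parameters
#'   across stages.
#' @param hierarchical fit with Gaussian group priors (needs >= 2 sessions).
#' @param opts a [fit_options()] list.
#' @return An object of class `twostep_fit` (and `twostep_hfit` if
#'   hierarchical): estimates per session, log-likelihoods, convergence
#'   flags, and for hierarchical fits the group prior and per-session
#'   Laplace evidence. Methods: `print`, `summary`, `coef`, `logLik`,
#'   [simulate.twostep_fit()].
#' @examples
#' p <- rl_params(0.5, 5, 0.6, 0.7, 0.2)
#' d <- simulate_twostep(p, task_config(n_trials = 150), n_subjects = 2, seed = 1)
#' f <- twostep_fit(d, model = "rl", opts = fit_options(n_restarts = 3))
#' coef(f)
#' @export
twostep_fit <- function(data, model = c("rl", "ddmrl"),
                        variant = c("full", "tied"), hierarchical = FALSE,
                        opts = fit_options()) {
  model <- match.arg(model)
  variant <- match.arg(variant)
  spec <- param_spec(model, variant)
  ranges <- resolve_ranges(opts$ranges, model, spec)
  sessions <- split_sessions(data)
  if (hierarchical && length(sessions) < 2)
    stop("hierarchical fitting needs >= 2 sessions")
  set.seed(opts$seed)
  if (hierarchical) {
    fit_em(sessions, model, spec, ranges, opts)
  } else {
    res <- lapply(sessions, function(ses)
      fit_one(ses, model, spec, ranges, opts))
    build_fit(res, sessions, model, spec, opts, hierarchical = FALSE)
  }
}

# box constraints / start ranges for the free parameters, from user-supplied
# or default sampling ranges, clipped away from transform singularities
resolve_ranges <- function(ranges, model, spec) {
  base <- default_ranges(model)
  if (!is.null(ranges)) base <- modifyList(base, ranges)
  base <- base[spec$free]
  for (nm in spec$free) {
    r <- base[[nm]]
    if (spec$transform[nm] == "logit") r <- pmin(pmax(r, 1e-6), 1 - 1e-6)
    if (spec$transform[nm] == "log") r[1] <- max(r[1], 1e-6)
    base[[nm]] <- r
  }
  base
}

range_mat <- function(ranges, spec) {
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  cbind(lower = to_unconstrained(lo, spec), upper = to_unconstrained(hi, spec))
}

neg_loglik_factory <- function(ses, model, spec) {
  vec <- session_vectors(ses, need_rt = (model == "ddmrl"))
  function(eta) {
    theta <- setNames(from_unconstrained(eta, spec), spec$free)
    full <- expand_params(theta, spec)
    ll <- if (model == "rl")
      loglik_rl_cpp(unname(full), vec$choice1, vec$state2, vec$choice2,
                    vec$reward, vec$block, vec$p_common, FALSE)[[1]]
    else
      loglik_ddmrl_cpp(unname(full), vec$choice1, vec$state2, vec$choice2,
                       vec$reward, vec$rt1, vec$rt2, vec$block, vec$p_common,
                       1e-8, 1e-10, FALSE)[[1]]
    if (!is.finite(ll)) 1e10 else -ll
  }
}

# multistart MLE for one session; returns estimates on the natural scale
fit_one <- function(ses, model, spec, ranges, opts) {
  nll <- neg_loglik_factory(ses, model, spec)
  bounds <- range_mat(ranges, spec)
  d <- length(spec$free)
  best <- NULL
  restarts <- matrix(runif(opts$n_restarts * d), ncol = d)
  starts <- lapply(seq_len(opts$n_restarts), function(k)
    bounds[, 1] + restarts[k, ] * (bounds[, 2] - bounds[, 1]))
  if (!is.null(opts$init)) {
    eta_init <- to_unconstrained(opts$init[spec$free], spec)
    starts <- c(list(pmin(pmax(eta_init, bounds[, 1]), bounds[, 2])), starts)
  }
  for (eta0 in starts) {
    sol <- tryCatch(
      nlminb(eta0, nll, lower = bounds[, 1], upper = bounds[, 2],
             control = list(iter.max = opts$maxit, eval.max = opts$maxit * 2)),
      error = function(e) NULL)
    if (is.null(sol) || !is.finite(sol$objective)) next
    if (is.null(best) || sol$objective < best$objective) best <- sol
  }
  if (is.null(best))
    return(list(theta = setNames(rep(NA_real_, d), spec$free),
                loglik = NA_real_, converged = FALSE, n_eval = 0L))
  theta <- setNames(from_unconstrained(best$par, spec), spec$free)
  list(theta = theta, loglik = -best$objective,
       converged = best$convergence == 0,
       n_eval = sum(best$evaluations), eta = best$par)
}

build_fit <- function(res, sessions, model, spec, opts, hierarchical,
                      extra = list()) {
  meta <- do.call(rbind, lapply(sessions, function(s)
    data.frame(subject_id = s$subject_id[1], timepoint = s$timepoint[1],
               n_trials = nrow(s), stringsAsFactors = FALSE)))
  est <- do.call(rbind, lapply(res, function(r) r$theta))
  rownames(est) <- NULL
  out <- c(list(model = model, variant = spec$variant, spec = spec,
                sessions = meta, estimates = est,
                loglik = vapply(res, function(r) r$loglik, numeric(1)),
                converged = vapply(res, function(r) isTRUE(r$converged),
                                   logical(1)),
                hierarchical = hierarchical, opts = opts),
           extra)
  rownames(out$sessions) <- NULL
  names(out$loglik) <- NULL
  class(out) <- if (hierarchical) c("twostep_hfit", "twostep_fit")
                else "twostep_fit"
  out
}

#' @export
print.twostep_fit <- function(x, ...) {
  cat(sprintf("%s model (%s variant, %d free parameters), %s fit\n",
              toupper(x$model), x$variant, length(x$spec$free),
              if (x$hierarchical) "hierarchical EM" else "individual ML"))
  cat(sprintf("%d session(s); total log-likelihood %.2f\n",
              nrow(x$sessions), sum(x$loglik)))
  if (!all(x$converged))
    cat(sprintf("note: %d session fit(s) did not converge\n",
                sum(!x$converged)))
  if (x$hierarchical)
    cat(sprintf("BIC_int = %.1f\n", x$bic_int))
  invisible(x)
}

#' @export
summary.twostep_fit <- function(object, ...) {
  est <- coef(object)
  s <- apply(est, 2, function(v)
    c(mean = mean(v, na.rm = TRUE), sd = sd(v, na.rm = TRUE),
      min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE)))
  print(object)
  cat("\nParameter estimates across sessions:\n")
  print(round(t(s), 4))
  invisible(t(s))
}

#' @export
coef.twostep_fit <- function(object, ...) object$estimates

#' @export
logLik.twostep_fit <- function(object, ...) {
  val <- sum(object$loglik)
  attr(val, "df") <- length(object$spec$free) * nrow(object$sessions)
  attr(val, "nobs") <- 2L * sum(object$sessions$n_trials)
  class(val) <- "logLik"
  val
}

#' Simulate new sessions from a fitted model
#'
#' Posterior-predictive style simulation: each fitted session's parameter
#' estimates drive a fresh closed-loop simulation with the same number of
#' trials (fresh reward walks).
#'
#' @param object a [twostep_fit()] result.
#' @param nsim number of replicate cohorts.
#' @param seed optional integer seed.
#' @param config optional [task_config()] overriding trial counts.
#' @param ... unused.
#' @return A trial table (one `timepoint` suffix per replicate if
#'   `nsim > 1`).
#' @export
simulate.twostep_fit <- function(object, nsim = 1, seed = NULL,
                                 config = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  spec <- object$spec
  out <- list()
  for (r in seq_len(nsim)) {
    sims <- lapply(seq_len(nrow(object$estimates)), function(i) {
      theta <- object$estimates[i, ]
      if (anyNA(theta)) return(NULL)
      full <- expand_params(setNames(theta, spec$free), spec)
      cfg <- if (is.null(config))
        task_config(n_trials = object$sessions$n_trials[i]) else config
      ses <- simulate_session(full, object$model, cfg)$data
      ses$subject_id <- object$sessions$subject_id[i]
      ses$timepoint <- paste0(object$sessions$timepoint[i],
                              if (nsim > 1) paste0(".sim", r) else "")
      ses
    })
    out[[r]] <- do.call(rbind, sims)
  }
  do.call(rbind, out)
}
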