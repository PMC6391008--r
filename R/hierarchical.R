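# Hierarchical expectation-maximization with Laplace approximation.
#
# Subject-level parameters are independent Gaussian random effects in
# unconstrained (logit/log) space. The E-step finds each session's MAP under
# the current prior and a Laplace (inverse-Hessian) covariance; the M-step
# updates prior means/variances by the standard moment rule
#   mu  = mean(theta_i)
#   var = mean(theta_i^2 + V_i) - mu^2   (floored)
# Convergence: relative change in the summed Laplace evidence < em_tol.

fit_em <- function(sessions, model, spec, ranges, opts) {
  d <- length(spec$free)
  n <- length(sessions)
  nlls <- lapply(sessions, neg_loglik_factory, model = model, spec = spec)
  bounds <- range_mat(ranges, spec)

  # initialize from quick individual fits
  init <- lapply(sessions, function(ses)
    fit_one(ses, model, spec, ranges,
            modifyList(opts, list(n_restarts = max(3, opts$n_restarts %/% 2)))))
  eta <- do.call(rbind, lapply(init, function(r)
    if (is.null(r$eta)) rowMeans(bounds) else r$eta))
  mu <- colMeans(eta)
  sigma2 <- pmax(apply(eta, 2, var), opts$var_floor)

  evid <- rep(NA_real_, n)
  V <- matrix(sigma2, n, d, byrow = TRUE)
  total_prev <- -Inf
  iter <- 0L
  converged <- FALSE
  hess_fallbacks <- 0L
  repeat {
    iter <- iter + 1L
    # E-step: per-session MAP + Laplace variance
    for (i in seq_len(n)) {
      nll <- nlls[[i]]
      npost <- function(e) nll(e) + penalty_gauss(e, mu, sigma2)
      sol <- tryCatch(
        nlminb(eta[i, ], npost,
               control = list(iter.max = opts$maxit,
                              eval.max = opts$maxit * 2)),
        error = function(e) NULL)
      if (!is.null(sol) && is.finite(sol$objective)) eta[i, ] <- sol$par
      H <- tryCatch(optimHess(eta[i, ], npost), error = function(e) NULL)
      ld <- NA_real_
      if (!is.null(H)) {
        ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                       error = function(e) NULL)
        if (!is.null(ev) && all(ev > 0)) {
          V[i, ] <- pmax(diag(solve(H)), 0)
          ld <- sum(log(ev))
        }
      }
      if (is.na(ld)) { # singular Hessian: fall back to the prior variance
        hess_fallbacks <- hess_fallbacks + 1L
        V[i, ] <- sigma2
        ld <- sum(log(1 / sigma2))
      }
      evid[i] <- -npost(eta[i, ]) + 0.5 * d * log(2 * pi) - 0.5 * ld
    }
    # M-step
    mu <- colMeans(eta)
    sigma2 <- pmax(colMeans(eta^2 + V) - mu^2, opts$var_floor)
    total <- sum(evid)
    if (is.finite(total_prev) &&
        abs(total - total_prev) < opts$em_tol * (abs(total_prev) + 1e-8)) {
      converged <- TRUE
      break
    }
    if (iter >= opts$em_maxit) break
    total_prev <- total
  }

  res <- lapply(seq_len(n), function(i) {
    theta <- setNames(from_unconstrained(eta[i, ], spec), spec$free)
    list(theta = theta, loglik = -nlls[[i]](eta[i, ]), converged = converged,
         eta = eta[i, ])
  })
  prior <- data.frame(parameter = spec$free, mean = mu, sd = sqrt(sigma2),
                      row.names = NULL)
  n_obs <- 2L * sum(vapply(sessions, nrow, integer(1)))
  bic <- -2 * sum(evid) + (2 * d) * log(n_obs)
  fit <- build_fit(res, sessions, model, spec, opts, hierarchical = TRUE,
                   extra = list(prior = prior, evidence = unname(evid),
                                bic_int = bic, em_iterations = iter,
                                em_converged = converged,
                                hessian_fallbacks = hess_fallbacks,
                                n_obs = n_obs))
  if (!converged)
    warning("EM did not converge within em_maxit iterations")
  fit
}

# negative Gaussian log-prior; infinite variances give a flat prior
penalty_gauss <- function(eta, mu, sigma2) {
  fin <- is.finite(sigma2)
  if (!any(fin)) return(0)
  0.5 * sum((eta[fin] - mu[fin])^2 / sigma2[fin] +
              log(2 * pi * sigma2[fin]))
}

#' Integrated BIC of a hierarchical fit
#'
#' Group-level Bayesian information criterion using the Laplace-approximated
#' per-session log marginal likelihoods from [twostep_fit()] with
#' `hierarchical = TRUE`:
#' `-2 * sum(evidence) + n_hyper * log(n_observations)`, where the
#' hyperparameters are the prior mean and variance of each free parameter
#' and an observation is one stage of one trial. Lower is better; a
#' difference of 10 or more is conventionally strong evidence.
#'
#' @param fit a hierarchical `twostep_fit` object.
#' @return The integrated BIC (scalar). A warning is attached if the EM did
#'   not converge.
#' @export
bic_int <- function(fit) {
  if (!inherits(fit, "twostep_hfit"))
    stop("bic_int requires a hierarchical fit")
  if (!isTRUE(fit$em_converged))
    warning("EM had not converged; BIC_int may be unreliable")
  fit$bic_int
}
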