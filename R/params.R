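#' Parameters of the hybrid RL choice model
#'
#' Constructs a validated parameter set for the hybrid model-based/model-free
#' reinforcement-learning model of the two-stage task. The full variant has
#' seven free parameters (stage-specific learning rates and inverse
#' temperatures); the tied five-parameter variant shares a single learning
#' rate and a single inverse temperature across stages, which is obtained by
#' omitting `alpha2` and `beta2`.
#'
#' @param alpha1 first-stage learning rate, in \[0, 1\].
#' @param beta1 first-stage softmax inverse temperature, non-negative.
#' @param lambda eligibility trace, in \[0, 1\]: how strongly the second-stage
#'   reward prediction error propagates to the first-stage value.
#' @param w model-based weight, in \[0, 1\] (0 = purely model-free,
#'   1 = purely model-based).
#' @param p perseveration: additive value bonus for repeating the previous
#'   first-stage choice.
#' @param alpha2 second-stage learning rate; defaults to `alpha1` (tied).
#' @param beta2 second-stage inverse temperature; defaults to `beta1` (tied).
#' @return An object of class `rl_params`: a named numeric vector in the
#'   canonical order `alpha1, alpha2, beta1, beta2, lambda, w, p`.
#' @examples
#' rl_params(alpha1 = 0.4, beta1 = 5, lambda = 0.6, w = 0.7, p = 0.1)
#' @export
rl_params <- function(alpha1, beta1, lambda, w, p,
                      alpha2 = alpha1, beta2 = beta1) {
  par <- c(alpha1 = alpha1, alpha2 = alpha2, beta1 = beta1, beta2 = beta2,
           lambda = lambda, w = w, p = p)
  check_unit(par[c("alpha1", "alpha2", "lambda", "w")])
  check_nonneg(par[c("beta1", "beta2")])
  check_finite(par)
  structure(par, class = "rl_params")
}

#' Parameters of the joint choice and reaction-time (DDM-RL) model
#'
#' Constructs a validated parameter set for the model in which the hybrid
#' learner's value differences drive a Wiener diffusion process: the trial
#' drift rate is `b * (Q(chosen) - Q(unchosen))`, evidence diffuses with unit
#' noise between boundaries separated by `a` starting midway, and the
#' reaction time is the first-passage time plus the non-decision time `tau`.
#' The full variant has eleven parameters (stage-specific `b`, `a`, `tau`);
#' the tied eight-parameter variant shares one diffusion parameter set
#' across stages, obtained by omitting `b2`, `a2`, `tau2`.
#'
#' @inheritParams rl_params
#' @param b1,b2 drift scaling per stage (maps Q-value differences to drift).
#' @param a1,a2 boundary separation per stage, positive.
#' @param tau1,tau2 non-decision time per stage, seconds, non-negative.
#' @return An object of class `ddmrl_params`: a named numeric vector in the
#'   canonical order `alpha1, alpha2, lambda, w, p, b1, a1, tau1, b2, a2, tau2`.
#' @examples
#' ddmrl_params(alpha1 = 0.4, lambda = 0.6, w = 0.7, p = 0.1,
#'              b1 = 4, a1 = 2, tau1 = 0.3)
#' @export
ddmrl_params <- function(alpha1, lambda, w, p, b1, a1, tau1,
                         alpha2 = alpha1, b2 = b1, a2 = a1, tau2 = tau1) {
  par <- c(alpha1 = alpha1, alpha2 = alpha2, lambda = lambda, w = w, p = p,
           b1 = b1, a1 = a1, tau1 = tau1, b2 = b2, a2 = a2, tau2 = tau2)
  check_unit(par[c("alpha1", "alpha2", "lambda", "w")])
  check_finite(par)
  if (any(par[c("a1", "a2")] <= 0)) stop("boundary separation must be > 0")
  if (any(par[c("tau1", "tau2")] < 0)) stop("non-decision time must be >= 0")
  structure(par, class = "ddmrl_params")
}

check_unit <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("parameter(s) ", paste(names(x)[!is.finite(x) | x < 0 | x > 1],
                                collapse = ", "), " must lie in [0, 1]")
  invisible(x)
}
check_nonneg <- function(x) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("parameter(s) ", paste(names(x)[!is.finite(x) | x < 0],
                                collapse = ", "), " must be >= 0")
  invisible(x)
}
check_finite <- function(x) {
  if (any(!is.finite(x)))
    stop("non-finite parameter(s): ",
         paste(names(x)[!is.finite(x)], collapse = ", "))
  invisible(x)
}

# Free-parameter layout per model/variant: names in canonical vector order,
# which entries are free, and the unconstrained transform for each.
param_spec <- function(model = c("rl", "ddmrl"), variant = c("full", "tied")) {
  model <- match.arg(model)
  variant <- match.arg(variant)
  if (model == "rl") {
    all <- c("alpha1", "alpha2", "beta1", "beta2", "lambda", "w", "p")
    free <- if (variant == "full") all else c("alpha1", "beta1", "lambda", "w", "p")
    tied <- if (variant == "full") NULL else c(alpha2 = "alpha1", beta2 = "beta1")
    trans <- c(alpha1 = "logit", alpha2 = "logit", beta1 = "log", beta2 = "log",
               lambda = "logit", w = "logit", p = "identity")
  } else {
    all <- c("alpha1", "alpha2", "lambda", "w", "p",
             "b1", "a1", "tau1", "b2", "a2", "tau2")
    free <- if (variant == "full") all else
      c("alpha1", "alpha2", "lambda", "w", "p", "b1", "a1", "tau1")
    tied <- if (variant == "full") NULL else
      c(b2 = "b1", a2 = "a1", tau2 = "tau1")
    trans <- c(alpha1 = "logit", alpha2 = "logit", lambda = "logit",
               w = "logit", p = "identity", b1 = "log", a1 = "log",
               tau1 = "log", b2 = "log", a2 = "log", tau2 = "log")
  }
  list(model = model, variant = variant, all = all, free = free, tied = tied,
       transform = trans[free])
}

# expand a free-parameter vector (named, canonical order of spec$free) to the
# full canonical vector the C++ code expects
expand_params <- function(theta, spec) {
  full <- setNames(numeric(length(spec$all)), spec$all)
  full[spec$free] <- theta[spec$free]
  for (nm in names(spec$tied)) full[nm] <- full[spec$tied[nm]]
  full
}

# constrained <-> unconstrained maps; exact round trip is tested
to_unconstrained <- function(theta, spec) {
  tr <- spec$transform
  out <- theta
  lg <- tr == "logit"
  out[lg] <- stats::qlogis(pmin(pmax(theta[lg], 1e-12), 1 - 1e-12))
  lo <- tr == "log"
  out[lo] <- log(pmax(theta[lo], 1e-300))
  out
}
from_unconstrained <- function(eta, spec) {
  tr <- spec$transform
  out <- eta
  lg <- tr == "logit"
  out[lg] <- stats::plogis(eta[lg])
  lo <- tr == "log"
  out[lo] <- exp(eta[lo])
  out
}

# default sampling ranges for simulation studies (uniform draws) and as
# optimizer box constraints in recovery analyses
default_ranges <- function(model = c("rl", "ddmrl")) {
  model <- match.arg(model)
  if (model == "rl") {
    list(alpha1 = c(0, 1), alpha2 = c(0, 1), beta1 = c(1, 8), beta2 = c(1, 8),
         lambda = c(0, 1), w = c(0, 1), p = c(0, 0.5))
  } else {
    list(alpha1 = c(0, 1), alpha2 = c(0, 1), lambda = c(0, 1), w = c(0, 1),
         p = c(0, 0.5), b1 = c(1, 10), a1 = c(1, 3), tau1 = c(0.01, 0.5),
         b2 = c(1, 10), a2 = c(1, 3), tau2 = c(0.01, 0.5))
  }
}

# draw one full parameter vector uniformly from ranges (list name -> c(lo, hi))
draw_params <- function(model, ranges = default_ranges(model)) {
  spec <- param_spec(model, "full")
  th <- vapply(spec$all, function(nm) {
    r <- ranges[[nm]]
    runif(1, r[1], r[2])
  }, numeric(1))
  setNames(th, spec$all)
}

#' @export
print.rl_params <- function(x, ...) {
  cat("Hybrid RL model parameters:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' @export
print.ddmrl_params <- function(x, ...) {
  cat("DDM-RL model parameters:\n")
  print(round(unclass(x), 4))
  invisible(x)
}
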