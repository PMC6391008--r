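#' Wiener first-passage-time density
#'
#' Density of the first passage time of a Wiener diffusion with unit noise,
#' drift `drift` (positive towards the upper boundary), boundary separation
#' `a` and relative starting point `start` (fraction of `a`; the two-stage
#' decision model fixes it at 0.5, i.e. no prior bias). The density is
#' evaluated by the standard infinite-series expansions, switching between
#' the small-time and large-time forms by the number-of-terms criterion, with
#' absolute truncation tolerance `eps`.
#'
#' @param t decision time(s), > 0 (seconds).
#' @param a boundary separation, > 0.
#' @param drift drift rate towards the upper boundary.
#' @param boundary which absorption the density refers to.
#' @param start relative starting point in (0, 1).
#' @param eps series truncation tolerance.
#' @return Vector of densities (>= 0).
#' @examples
#' # symmetric absorption: each boundary captures half the mass at zero drift
#' integrate(dwfpt, 0, Inf, a = 2, drift = 0)$value
#' @export
dwfpt <- function(t, a, drift, boundary = c("upper", "lower"), start = 0.5,
                  eps = 1e-8) {
  boundary <- match.arg(boundary)
  if (a <= 0) stop("a must be > 0")
  if (start <= 0 || start >= 1) stop("start must be in (0, 1)")
  if (any(t <= 0, na.rm = TRUE)) stop("t must be > 0")
  wfpt_density_cpp(t, a, drift, start, boundary == "upper", eps)
}

#' Probability of absorption at the upper boundary
#'
#' Closed form for the symmetric start used by the decision model:
#' `1 / (1 + exp(-a * drift))`.
#'
#' @inheritParams dwfpt
#' @return Probability that the diffusion is absorbed at the upper boundary.
#' @export
wfpt_p_upper <- function(a, drift) {
  if (a <= 0) stop("a must be > 0")
  wfpt_p_upper_cpp(a, drift)
}

#' Sample Wiener first passages
#'
#' Draws (boundary, decision time) pairs from the two-boundary Wiener
#' diffusion with symmetric start. The attained boundary is drawn from its
#' exact absorption probability and the decision time by numerical inversion
#' of the conditional first-passage distribution (with a symmetric start the
#' decision time is independent of the attained boundary), so samples follow
#' the analytic density [dwfpt()] without discretization error.
#'
#' @param n number of draws.
#' @inheritParams dwfpt
#' @return A data frame with columns `boundary` (`"upper"`/`"lower"`) and
#'   `time` (decision time, seconds; non-decision time not included).
#' @examples
#' set.seed(1)
#' s <- rwfpt(1000, a = 2, drift = 1)
#' mean(s$boundary == "upper")
#' @export
rwfpt <- function(n, a, drift) {
  if (a <= 0) stop("a must be > 0")
  s <- wfpt_sample_cpp(n, a, drift)
  data.frame(boundary = ifelse(s$upper == 1L, "upper", "lower"),
             time = s$time, stringsAsFactors = FALSE)
}

#' Euler-Maruyama first-passage sampler
#'
#' Brute-force discrete-time simulation of the same diffusion (step size
#' `dt`). Slow and biased by the time discretization; kept as an independent
#' oracle against which the analytic density and the exact sampler are
#' validated.
#'
#' @inheritParams rwfpt
#' @param dt Euler step size in seconds.
#' @return As [rwfpt()].
#' @export
rwfpt_euler <- function(n, a, drift, dt = 1e-4) {
  if (a <= 0 || dt <= 0) stop("a and dt must be > 0")
  s <- wfpt_sample_euler_cpp(n, a, drift, dt)
  data.frame(boundary = ifelse(s$upper == 1L, "upper", "lower"),
             time = s$time, stringsAsFactors = FALSE)
}

# survival function of the decision time given (a, |drift|); internal,
# used to invert the CDF in tests
wfpt_cond_survival <- function(t, a, drift) {
  wfpt_cond_survival_cpp(t, a, drift)
}
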