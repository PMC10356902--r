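# Privacy accounting for DP-SGD.
#
# The guarantee tracked is (epsilon, delta)-DP of the released model: for any
# neighbouring datasets D, D' and any event S,
# Pr[M(D) in S] <= exp(epsilon) Pr[M(D') in S] + delta.
# Each DP-SGD step is a (subsampled) Gaussian mechanism with sensitivity
# max_grad_norm and noise sigma * max_grad_norm.

# exact delta(eps) of a single Gaussian mechanism with noise ratio sigma
# (Balle & Wang analytic bound, sensitivity 1)
.gm_delta <- function(eps, sigma) {
  stats::pnorm(1 / (2 * sigma) - eps * sigma) -
    exp(eps) * stats::pnorm(-1 / (2 * sigma) - eps * sigma)
}

# per-step RDP of the Poisson-subsampled Gaussian mechanism at integer
# order alpha (binomial-expansion upper bound), via log-sum-exp
.subsampled_rdp <- function(alpha, q, sigma) {
  k <- 0:alpha
  logterms <- lchoose(alpha, k) + (alpha - k) * log1p(-q) + k * log(q) +
    k * (k - 1) / (2 * sigma^2)
  m <- max(logterms)
  (m + log(sum(exp(logterms - m)))) / (alpha - 1)
}

#' Privacy spent by a number of DP-SGD steps
#'
#' Converts the accumulated mechanism composition to an epsilon at the
#' configured delta. With sampling rate 1 the exact analytic
#' Gaussian-mechanism bound for the `steps`-fold composition is used; with
#' subsampling, Renyi-DP of the Poisson-subsampled Gaussian mechanism is
#' composed over integer orders 2..256 and converted with
#' eps = min_alpha (steps * rdp(alpha) + log(1/delta) / (alpha - 1)).
#'
#' @param dp A [dp_config()] with `noise_multiplier` set.
#' @param steps Number of optimizer steps taken (>= 0).
#' @param sampling_rate Expected fraction of the training set per step.
#' @return epsilon at `dp$delta`; 0 when `steps` is 0, `Inf` when the noise
#'   multiplier is 0.
#' @export
privacy_spent <- function(dp, steps, sampling_rate) {
  stopifnot(inherits(dp, "dp_config"))
  if (dp$delta <= 0 || dp$delta >= 1) stop("delta must lie in (0, 1)")
  if (steps < 0) stop("steps must be >= 0")
  if (steps == 0) return(0)
  sigma <- dp$noise_multiplier
  if (is.null(sigma)) stop("noise_multiplier not set")
  if (sigma == 0) return(Inf)
  q <- sampling_rate
  if (q <= 0 || q > 1) stop("sampling_rate must lie in (0, 1]")
  if (q == 1) {
    sig_eff <- sigma / sqrt(steps)
    if (.gm_delta(0, sig_eff) <= dp$delta) return(0)
    f <- function(e) .gm_delta(e, sig_eff) - dp$delta
    hi <- 1
    while (f(hi) > 0 && hi < 1e6) hi <- hi * 2
    return(stats::uniroot(f, c(0, hi), tol = 1e-10)$root)
  }
  alphas <- 2:256
  rdp <- vapply(alphas, .subsampled_rdp, numeric(1), q = q, sigma = sigma)
  min(steps * rdp + log(1 / dp$delta) / (alphas - 1))
}

#' Calibrate the DP-SGD noise multiplier to a privacy budget
#'
#' Finds the smallest noise multiplier for which `steps` steps at the given
#' sampling rate spend at most `target_epsilon` at `delta`.
#'
#' @param target_epsilon,delta Privacy budget.
#' @param steps Planned number of optimizer steps.
#' @param sampling_rate Expected batch fraction per step.
#' @return The calibrated noise multiplier.
#' @export
calibrate_noise <- function(target_epsilon, delta, steps, sampling_rate) {
  stopifnot(target_epsilon > 0, steps >= 1)
  eps_at <- function(sigma) {
    privacy_spent(dp_config(noise_multiplier = sigma, target_epsilon = Inf,
                            delta = delta),
                  steps, sampling_rate)
  }
  lo <- 0.2; hi <- 2
  while (eps_at(hi) > target_epsilon && hi < 1e4) hi <- hi * 2
  if (eps_at(hi) > target_epsilon) stop("cannot calibrate noise for this budget")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (eps_at(mid) > target_epsilon) lo <- mid else hi <- mid
  }
  hi
}
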