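#' Model parameters
#'
#' The dynamic model has exactly three free parameters: bound height B,
#' per-click noise variance sigma_s2 and initial mean mu0. Each neuron has an
#' accumulation-regime weight w_EA, a commitment-regime weight w_DC and a set
#' of baseline coefficients (see \code{\link{basis_config}}). The per-step
#' diffusion noise variance is fixed at dt (0.01 s) and the sensory-adaptation
#' constants are fixed, not fitted.
#'
#' @param B Bound height, latent units (> 0).
#' @param sigma_s2 Variance of the multiplicative per-click noise (>= 0).
#' @param mu0 Mean of the initial latent distribution, latent units.
#' @param w_EA,w_DC Numeric vectors, one entry per neuron: encoding weight of
#'   the latent during evidence accumulation and decision commitment.
#' @param baseline A list with one element per neuron, each a coefficient
#'   vector for the baseline design (see \code{\link{fit_baseline}}), or a
#'   numeric vector of per-neuron constant baselines (input-current units).
#' @param adaptation An \code{\link{adaptation_params}} object.
#' @param dt Time step, seconds; fixed at 0.01.
#' @param n_interior Number of interior grid bins used for inference.
#' @return A list of class \code{mmddm_params}.
#' @export
mmddm_params <- function(B = 5.5, sigma_s2 = 2, mu0 = 0,
                         w_EA = numeric(0), w_DC = numeric(0),
                         baseline = numeric(0),
                         adaptation = adaptation_params(),
                         dt = 0.01, n_interior = 99L) {
  if (B <= 0) stop("B must be positive")
  if (sigma_s2 < 0) stop("sigma_s2 must be non-negative")
  if (length(w_EA) != length(w_DC)) {
    stop("w_EA and w_DC must have one entry per neuron")
  }
  if (is.numeric(baseline) && length(baseline) > 0) {
    baseline <- as.list(baseline)
  }
  structure(list(B = B, sigma_s2 = sigma_s2, mu0 = mu0,
                 w_EA = w_EA, w_DC = w_DC, baseline = baseline,
                 adaptation = adaptation, dt = dt,
                 n_interior = as.integer(n_interior)),
            class = "mmddm_params")
}

#' Per-step input moments from adapted clicks
#'
#' Collapses the adapted click stream to per-time-step drift means and input
#' variances. In step t (covering [ (t-1) dt, t dt )), the drift is the sum of
#' right-click magnitudes minus left-click magnitudes; each click carries
#' independent multiplicative noise zeta ~ N(1, sigma_s2), so the input
#' variance of the step is sigma_s2 times the sum of squared magnitudes over
#' clicks of both sides.
#'
#' @param clicks An \code{\link{adapt_clicks}} output.
#' @param sigma_s2 Per-click noise variance.
#' @param dt Step size in seconds.
#' @param n_steps Number of steps T; clicks must fall within [0, T dt).
#' @return A list with numeric vectors \code{m} (drift) and \code{v}
#'   (variance), each of length \code{n_steps}.
#' @export
discretize_inputs <- function(clicks, sigma_s2, dt = 0.01, n_steps) {
  m <- numeric(n_steps)
  v <- numeric(n_steps)
  if (nrow(clicks) == 0L) return(list(m = m, v = v))
  step <- floor(clicks$time / dt) + 1L
  if (any(step > n_steps) || any(clicks$time < 0)) {
    stop("click outside the trial window [0, n_steps * dt)")
  }
  signed <- ifelse(clicks$side == "R", clicks$magnitude, -clicks$magnitude)
  m[seq_len(n_steps)] <- 0
  for (k in seq_along(step)) {
    m[step[k]] <- m[step[k]] + signed[k]
    v[step[k]] <- v[step[k]] + sigma_s2 * clicks$magnitude[k]^2
  }
  list(m = m, v = v)
}

#' Spike-count emission log-likelihoods over grid states
#'
#' For each grid state, sums over neurons the log Poisson probability of the
#' observed counts with rate lambda = softplus(w z + b), where w = w_EA at
#' interior states and w = w_DC at the two absorbing bound states.
#'
#' @param spike_counts Integer vector, one count per neuron, for one step.
#' @param grid A \code{\link{latent_grid}}.
#' @param w_EA,w_DC Per-neuron weights.
#' @param baseline_t Per-neuron baseline values b (input-current units) at
#'   this step.
#' @param dt Step size, seconds.
#' @return Log-likelihood vector over grid states.
#' @export
emission_loglik <- function(spike_counts, grid, w_EA, w_DC, baseline_t,
                            dt = 0.01) {
  if (any(spike_counts < 0)) stop("spike counts must be non-negative")
  S <- grid$n_interior + 2L
  out <- numeric(S)
  for (s in seq_len(S)) {
    w <- if (s == grid$i_lo || s == grid$i_hi) w_DC else w_EA
    lam <- softplus(w * grid$centers[s] + baseline_t) * dt
    out[s] <- sum(stats::dpois(spike_counts, pmax(lam, 1e-300), log = TRUE))
  }
  out
}

#' Choice emission log-likelihood over grid states
#'
#' The binary choice is the sign of z at the final step: probability 1 for
#' states whose sign matches the choice (the matching bound included),
#' probability 0 for the opposite sign, and probability 1/2 for the bin
#' centred at exactly z = 0 (tie split by symmetry).
#'
#' @param choice "L" or "R".
#' @param grid A \code{\link{latent_grid}}.
#' @return Log-likelihood vector over grid states (0, -Inf or log 1/2).
#' @export
choice_loglik <- function(choice, grid) {
  if (!choice %in% c("L", "R")) stop("choice must be \"L\" or \"R\"")
  z <- grid$centers
  p <- numeric(length(z))
  sgn <- if (choice == "R") 1 else -1
  p[sign(z) == sgn] <- 1
  p[z == 0] <- 0.5
  log(p)
}
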