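#' Discretized latent state space
#'
#' The scalar decision variable z lives on (-B, B) with two absorbing states
#' pinned at exactly -B and +B. The interior is discretized into an odd number
#' of uniform bins so that one bin is centred at z = 0; Gaussian probability
#' mass is assigned to bins by CDF differences over the bin edges, and mass
#' beyond +/-B accrues to the corresponding absorbing bound state.
#'
#' @param B Bound height (> 0), latent units.
#' @param n_interior Odd number of interior bins (>= 3).
#' @return A list of class \code{latent_grid}: \code{B}, \code{n_interior},
#'   \code{centers} (length n_interior + 2, ordered -B, interior..., +B),
#'   \code{edges} (interior bin edges, length n_interior + 1),
#'   \code{i_lo}, \code{i_hi} (indices of the -B and +B absorbing states),
#'   \code{interior} (indices of interior states) and \code{i_zero} (index of
#'   the bin centred at 0).
#' @export
latent_grid <- function(B, n_interior = 99L) {
  if (B <= 0) stop("bound height B must be positive")
  n_interior <- as.integer(n_interior)
  if (n_interior < 3L || n_interior %% 2L == 0L) {
    stop("n_interior must be an odd integer >= 3")
  }
  edges <- seq(-B, B, length.out = n_interior + 1L)
  centers_int <- (edges[-1L] + edges[-length(edges)]) / 2
  # enforce exact symmetry: the middle bin centre must be exactly 0 (the
  # choice tie rule keys on z == 0) and centres must mirror sign-wise
  half <- (n_interior - 1L) %/% 2L
  centers_int[half + 1L] <- 0
  centers_int[seq_len(half)] <- -rev(centers_int[half + 1L + seq_len(half)])
  centers <- c(-B, centers_int, B)
  structure(list(
    B = B,
    n_interior = n_interior,
    centers = centers,
    edges = edges,
    i_lo = 1L,
    i_hi = n_interior + 2L,
    interior = seq(2L, n_interior + 1L),
    i_zero = 1L + (n_interior + 1L) %/% 2L
  ), class = "latent_grid")
}

#' Integrate a Gaussian over the grid
#'
#' Returns the probability vector over all grid states (bounds included) of a
#' N(mean, var) variable: CDF differences over interior bin edges, with the
#' two tails assigned to the absorbing states.
#'
#' @param grid A \code{\link{latent_grid}}.
#' @param mean,var Gaussian mean and variance (var > 0).
#' @return Probability vector of length \code{n_interior + 2}; sums to 1.
#' @keywords internal
gaussian_bin_probs <- function(grid, mean, var) {
  s <- sqrt(var)
  cdf <- stats::pnorm(grid$edges, mean = mean, sd = s)
  p <- numeric(grid$n_interior + 2L)
  p[grid$interior] <- diff(cdf)
  p[grid$i_lo] <- cdf[1L]
  p[grid$i_hi] <- 1 - cdf[length(cdf)]
  p
}

#' Initial distribution of the decision variable
#'
#' The latent starts at N(mu0, 1), integrated over the grid; out-of-range mass
#' is assigned to the corresponding bound state.
#'
#' @param grid A \code{\link{latent_grid}}.
#' @param mu0 Initial mean, latent units.
#' @return Probability vector over grid states; sums to 1.
#' @export
initial_distribution <- function(grid, mu0) {
  gaussian_bin_probs(grid, mean = mu0, var = 1)
}

#' Single-step transition matrix of the bounded accumulator
#'
#' From each interior state z the next-step distribution is Gaussian with mean
#' z + m and variance dt + v (per-step diffusion plus per-click input noise),
#' integrated over the bins; mass beyond the bounds is absorbed. The two bound
#' states are absorbing (map to themselves with probability 1).
#'
#' @param grid A \code{\link{latent_grid}}.
#' @param m_t Drift (net adapted click input) for the step, latent units.
#' @param v_t Input variance for the step (>= 0), latent units^2.
#' @param dt Time step in seconds (diffusion variance per step).
#' @return Row-stochastic matrix, rows = source states, columns = destination.
#' @export
transition_matrix <- function(grid, m_t = 0, v_t = 0, dt = 0.01) {
  if (v_t < 0) stop("input variance must be non-negative")
  S <- grid$n_interior + 2L
  A <- matrix(0, S, S)
  A[grid$i_lo, grid$i_lo] <- 1
  A[grid$i_hi, grid$i_hi] <- 1
  for (i in grid$interior) {
    A[i, ] <- gaussian_bin_probs(grid, mean = grid$centers[i] + m_t,
                                 var = dt + v_t)
  }
  A
}

#' Overflow-safe softplus
#'
#' h(x) = log(1 + exp(x)), the firing-rate nonlinearity mapping input current
#' to rate.
#'
#' @param x Numeric vector.
#' @return softplus(x), elementwise.
#' @export
softplus <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}
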