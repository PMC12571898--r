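#' Radial-basis configuration for the decision-irrelevant baseline
#'
#' The baseline input current of each neuron has a cross-trial component (a
#' smooth function of time from the start of the session) and a within-trial
#' component built from causal kernels aligned to stimulus onset, to movement
#' onset (a window preceding it) and to the neuron's own preceding spikes.
#' Every component is a linear combination of Gaussian radial basis
#' functions; the defaults give 1 intercept + 4 + 4 + 4 + 4 = 17 coefficients
#' per neuron.
#'
#' @param n_cross,n_stim,n_move,n_spike Number of basis functions per
#'   component.
#' @param stim_span Support of the post-stimulus kernel, seconds.
#' @param move_span Length of the window preceding movement onset, seconds.
#' @param spike_span Support of the spike-history kernel, seconds.
#' @return A list of class \code{basis_config}.
#' @export
basis_config <- function(n_cross = 4L, n_stim = 4L, n_move = 4L,
                         n_spike = 4L, stim_span = 1.0, move_span = 0.4,
                         spike_span = 0.2) {
  structure(list(n_cross = n_cross, n_stim = n_stim, n_move = n_move,
                 n_spike = n_spike, stim_span = stim_span,
                 move_span = move_span, spike_span = spike_span),
            class = "basis_config")
}

n_baseline_coefs <- function(cfg) {
  1L + cfg$n_cross + cfg$n_stim + cfg$n_move + cfg$n_spike
}

# Gaussian bumps with centres spanning [lo, hi]; width tied to the spacing.
rbf_eval <- function(x, lo, hi, n) {
  if (n == 0L) return(matrix(0, length(x), 0L))
  centers <- seq(lo, hi, length.out = n)
  width <- if (n > 1L) diff(centers)[1] else (hi - lo) / 2 + 1e-9
  sapply(seq_len(n), function(j) exp(-0.5 * ((x - centers[j]) / width)^2))
}

#' Baseline design matrix of one trial
#'
#' Rows are the trial's time steps; columns are intercept, cross-trial bumps
#' (functions of the trial start time, constant within the trial), causal
#' post-stimulus bumps, pre-movement bumps (zero outside the window ending at
#' movement onset) and spike-history bumps (zero at and before each spike,
#' causal afterwards). Spike history makes the design neuron-specific.
#'
#' @param n_steps Number of time steps in the trial window.
#' @param start_time Trial start time, s from session start.
#' @param movement_onset Movement onset, s from stimulus onset.
#' @param spike_times The neuron's spike times in this trial, s.
#' @param session_span Total session duration, s (scales the cross-trial
#'   bumps).
#' @param cfg A \code{\link{basis_config}}.
#' @param dt Step size, seconds.
#' @return Matrix \code{n_steps x n_baseline_coefs(cfg)}.
#' @export
baseline_design <- function(n_steps, start_time, movement_onset,
                            spike_times, session_span, cfg = basis_config(),
                            dt = 0.01) {
  tt <- (seq_len(n_steps) - 0.5) * dt   # bin centres
  X <- matrix(1, n_steps, 1L)
  if (cfg$n_cross > 0L) {
    Xc <- rbf_eval(start_time, 0, max(session_span, 1e-6), cfg$n_cross)
    X <- cbind(X, matrix(rep(Xc, each = n_steps), n_steps))
  }
  if (cfg$n_stim > 0L) {
    # causal: supported at t >= stimulus onset (t >= 0 always holds in-trial)
    X <- cbind(X, rbf_eval(tt, 0, cfg$stim_span, cfg$n_stim))
  }
  if (cfg$n_move > 0L) {
    u <- tt - movement_onset             # <= 0 before movement
    Xm <- rbf_eval(u, -cfg$move_span, 0, cfg$n_move)
    Xm[u < -cfg$move_span | u > 0, ] <- 0
    X <- cbind(X, Xm)
  }
  if (cfg$n_spike > 0L) {
    Xs <- matrix(0, n_steps, cfg$n_spike)
    st <- spike_times[spike_times >= 0 & spike_times < n_steps * dt]
    for (s in st) {
      u <- tt - s
      keep <- u > 0 & u <= cfg$spike_span
      if (any(keep)) {
        Xs[keep, ] <- Xs[keep, , drop = FALSE] +
          rbf_eval(u[keep], 0, cfg$spike_span, cfg$n_spike)
      }
    }
    X <- cbind(X, Xs)
  }
  X
}

# Poisson negative log-likelihood with softplus inverse link, plus ridge.
softplus_pois_obj <- function(beta, X, y, dt, ridge) {
  eta <- drop(X %*% beta)
  lam <- softplus(eta)
  lam <- pmax(lam, 1e-12)
  -sum(y * log(lam * dt) - lam * dt) + ridge * sum(beta^2) / 2
}

softplus_pois_grad <- function(beta, X, y, dt, ridge) {
  eta <- drop(X %*% beta)
  lam <- pmax(softplus(eta), 1e-12)
  sig <- stats::plogis(eta)
  -drop(crossprod(X, (y / lam - dt) * sig)) + ridge * beta
}

softplus_inv <- function(y) {
  ifelse(y > 30, y, log(expm1(pmax(y, 1e-10))))
}

#' Fit the baseline model of one neuron
#'
#' Poisson regression of 0.01-s spike counts on the radial-basis design with
#' a softplus inverse link (so that fitted values live on the input-current
#' scale consumed by the spike-emission model). A small ridge penalty guards
#' against rank deficiency.
#'
#' @param spike_times List over trials of the neuron's spike times (s).
#' @param trials \code{session$trials}-style list (start/movement times).
#' @param session_span Session duration, s.
#' @param cfg A \code{\link{basis_config}}.
#' @param dt Step size, s.
#' @param ridge Ridge penalty on the coefficients.
#' @return A list of class \code{baseline_model} with \code{coef},
#'   \code{cfg}, and \code{evaluate(trial_idx)} returning the per-step
#'   baseline input of a trial.
#' @export
fit_baseline <- function(spike_times, trials, session_span,
                         cfg = basis_config(), dt = 0.01, ridge = 1e-3) {
  if (length(spike_times) != length(trials)) {
    stop("spike_times and trials must have equal length")
  }
  designs <- lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    baseline_design(trial_n_steps(tr, dt), tr$start_time, tr$movement_onset,
                    spike_times[[i]], session_span, cfg, dt)
  })
  X <- do.call(rbind, designs)
  y <- unlist(lapply(seq_along(trials), function(i) {
    Tn <- nrow(designs[[i]])
    st <- spike_times[[i]]
    st <- st[st >= 0 & st < Tn * dt]
    tabulate(floor(st / dt) + 1L, Tn)
  }))
  beta0 <- c(softplus_inv(max(mean(y) / dt, 1e-3)),
             rep(0, ncol(X) - 1L))
  fit <- stats::optim(beta0, softplus_pois_obj, softplus_pois_grad,
                      X = X, y = y, dt = dt, ridge = ridge,
                      method = "BFGS", control = list(maxit = 300))
  structure(list(coef = fit$par, cfg = cfg, dt = dt,
                 session_span = session_span,
                 convergence = fit$convergence), class = "baseline_model")
}

#' Evaluate a baseline model over a trial
#'
#' @param model A \code{\link{fit_baseline}} result (or a bare coefficient
#'   vector with attribute-free intercept-only semantics).
#' @param trial One session trial.
#' @param spike_times The neuron's spike times in the trial.
#' @param dt Step size, s.
#' @return Per-step baseline input-current vector.
#' @export
evaluate_baseline <- function(model, trial, spike_times, dt = 0.01) {
  X <- baseline_design(trial_n_steps(trial, dt), trial$start_time,
                       trial$movement_onset, spike_times,
                       model$session_span, model$cfg, dt)
  drop(X %*% model$coef)
}
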