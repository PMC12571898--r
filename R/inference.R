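#' Inference for the multi-mode drift-diffusion model
#'
#' The latent accumulator is marginalized by discretized forward filtering
#' over the grid of \code{\link{latent_grid}}; smoothed posteriors come from
#' the forward-backward recursion; all parameters are fitted jointly by
#' maximum a posteriori estimation; the neurally-inferred time of commitment
#' (nTc) is the first step at which the smoothed posterior mass of a single
#' bound state exceeds a threshold.
#'
#' @name inference
NULL

# ---- internal: per-trial precomputation ------------------------------------

# Drift and squared-magnitude click sums per step (independent of the fitted
# parameters: adaptation constants are fixed).
trial_click_moments <- function(clicks, adaptation, dt, n_steps) {
  ad <- adapt_clicks(clicks, adaptation)
  keep <- ad$time < n_steps * dt
  ad <- ad[keep, , drop = FALSE]
  m0 <- numeric(n_steps)
  c2 <- numeric(n_steps)
  if (nrow(ad)) {
    step <- pmin(floor(ad$time / dt) + 1L, n_steps)
    signed <- ifelse(ad$side == "R", ad$magnitude, -ad$magnitude)
    for (k in seq_len(nrow(ad))) {
      m0[step[k]] <- m0[step[k]] + signed[k]
      c2[step[k]] <- c2[step[k]] + ad$magnitude[k]^2
    }
  }
  list(m = m0, c2 = c2)
}

# Per-neuron baseline input matrices (N x T) for every trial.
baseline_matrices <- function(session, params) {
  N <- n_neurons(session)
  dt <- session$dt
  lapply(seq_len(n_trials(session)), function(i) {
    tr <- session$trials[[i]]
    Tn <- trial_n_steps(tr, dt)
    b <- matrix(0, N, Tn)
    for (n in seq_len(N)) {
      bn <- params$baseline[[n]]
      if (inherits(bn, "baseline_model")) {
        b[n, ] <- evaluate_baseline(bn, tr, session$spikes[[n]][[i]], dt)
      } else {
        b[n, ] <- as.numeric(bn)[1]
      }
    }
    b
  })
}

prepare_session_data <- function(session, params) {
  dt <- session$dt
  counts <- bin_spike_counts(session)
  trials <- lapply(seq_len(n_trials(session)), function(i) {
    tr <- session$trials[[i]]
    Tn <- trial_n_steps(tr, dt)
    cm <- trial_click_moments(tr$clicks, params$adaptation, dt, Tn)
    list(y = counts[[i]], m = cm$m, c2 = cm$c2, choice = tr$choice,
         n_steps = Tn)
  })
  list(trials = trials, b = baseline_matrices(session, params), dt = dt)
}

# Forward pass of one prepared trial; logem may be precomputed for reuse.
prepared_trial_fb <- function(ptrial, b, grid, sigma_s2, mu0, dt,
                              wEA, wDC, want_smooth = FALSE, logem = NULL) {
  if (is.null(logem)) {
    logem <- cpp_emission_matrix(ptrial$y, grid$centers, wEA, wDC, b, dt)
  }
  v <- sigma_s2 * ptrial$c2
  lc <- choice_loglik(ptrial$choice, grid)
  cpp_trial_fb(grid$centers, grid$edges, ptrial$m, v, dt,
               mu0 + ptrial$m[1], 1 + v[1], logem, lc, want_smooth)
}

# ---- exported single-trial operations --------------------------------------

#' Log-likelihood of one trial
#'
#' P(spikes, choice | clicks, params) by the forward recursion: initial
#' distribution (with the first-step click input folded in), per-step
#' transition x emission, and the choice likelihood at the final step. A
#' choice that annihilates all posterior mass returns \code{-Inf} (with the
#' \code{ok} flag of \code{\link{smooth_trial}} set), never \code{NaN}.
#'
#' @param trial A list with fields \code{clicks}
#'   (\code{\link{generate_click_trains}} output), \code{spike_counts}
#'   (neuron x step matrix), \code{choice} ("L"/"R") and optionally
#'   \code{baseline} (neuron x step matrix of input currents; zero if
#'   absent).
#' @param params An \code{\link{mmddm_params}}.
#' @return Scalar log-likelihood.
#' @export
trial_loglik <- function(trial, params) {
  res <- smooth_trial(trial, params, want_smooth = FALSE)
  res$loglik
}

#' Smoothed latent posterior of one trial
#'
#' Forward-backward posterior P(z_t | clicks, all spikes, choice) over the
#' discretized grid.
#'
#' @inheritParams trial_loglik
#' @param want_smooth Compute the backward pass (set \code{FALSE} for the
#'   likelihood only).
#' @return A list of class \code{latent_posterior}: \code{smoothed} and
#'   \code{filtered} (states x steps), \code{p_lo}, \code{p_hi} (per-step
#'   bound-state probabilities), \code{loglik}, \code{grid}, \code{ok}.
#' @export
smooth_trial <- function(trial, params, want_smooth = TRUE) {
  dt <- params$dt
  y <- trial$spike_counts
  if (is.null(y)) stop("trial must carry a spike_counts matrix")
  Tn <- ncol(y)
  grid <- latent_grid(params$B, params$n_interior)
  cm <- trial_click_moments(trial$clicks, params$adaptation, dt, Tn)
  b <- trial$baseline
  if (is.null(b)) b <- matrix(0, nrow(y), Tn)
  logem <- cpp_emission_matrix(y, grid$centers, params$w_EA, params$w_DC,
                               b, dt)
  v <- params$sigma_s2 * cm$c2
  lc <- choice_loglik(trial$choice, grid)
  res <- cpp_trial_fb(grid$centers, grid$edges, cm$m, v, dt,
                      params$mu0 + cm$m[1], 1 + v[1], logem, lc, want_smooth)
  post <- list(smoothed = res$smoothed, filtered = res$filtered,
               loglik = res$loglik, ok = res$ok, grid = grid)
  if (want_smooth && res$ok) {
    post$p_lo <- res$smoothed[grid$i_lo, ]
    post$p_hi <- res$smoothed[grid$i_hi, ]
  }
  structure(post, class = "latent_posterior")
}

#' Detect the neurally-inferred time of commitment (nTc)
#'
#' The nTc is the first time step at which the smoothed posterior probability
#' of a single bound state -- the larger of the two -- exceeds the threshold.
#' If the threshold is never exceeded the trial has no detected commitment.
#'
#' @param posterior A \code{\link{smooth_trial}} result.
#' @param threshold Detection threshold in (0, 1); default 0.8.
#' @return \code{NULL} if not detected, else a list with \code{step} (1-based
#'   time step), \code{side} ("L"/"R") and \code{max_bound_prob}.
#' @export
detect_ntc <- function(posterior, threshold = 0.8) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (!isTRUE(posterior$ok)) return(NULL)
  mx <- pmax(posterior$p_lo, posterior$p_hi)
  hit <- which(mx > threshold)
  if (!length(hit)) return(NULL)
  s <- hit[1L]
  list(step = s,
       side = if (posterior$p_hi[s] >= posterior$p_lo[s]) "R" else "L",
       max_bound_prob = mx[s])
}

#' Per-trial nTc table of a session
#'
#' Applies \code{\link{smooth_trial}} + \code{\link{detect_ntc}} to every
#' trial.
#'
#' @param session An \code{\link{mmddm_session}}.
#' @param params Fitted (or generative) \code{\link{mmddm_params}}.
#' @param threshold Detection threshold.
#' @return A data.frame with columns \code{trial}, \code{detected},
#'   \code{nTc_step}, \code{nTc_s}, \code{side}, \code{max_bound_prob}.
#' @export
session_ntc <- function(session, params, threshold = 0.8) {
  dat <- prepare_session_data(session, params)
  grid <- latent_grid(params$B, params$n_interior)
  out <- data.frame(trial = seq_along(dat$trials), detected = FALSE,
                    nTc_step = NA_integer_, nTc_s = NA_real_,
                    side = NA_character_, max_bound_prob = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(dat$trials)) {
    res <- prepared_trial_fb(dat$trials[[i]], dat$b[[i]], grid,
                             params$sigma_s2, params$mu0, dat$dt,
                             params$w_EA, params$w_DC, want_smooth = TRUE)
    if (!res$ok) next
    post <- list(p_lo = res$smoothed[grid$i_lo, ],
                 p_hi = res$smoothed[grid$i_hi, ], ok = TRUE)
    d <- detect_ntc(post, threshold)
    if (!is.null(d)) {
      out$detected[i] <- TRUE
      out$nTc_step[i] <- d$step
      out$nTc_s[i] <- (d$step - 0.5) * dat$dt
      out$side[i] <- d$side
      out$max_bound_prob[i] <- d$max_bound_prob
    }
  }
  out
}

# ---- MAP fitting ------------------------------------------------------------

#' Fitting configuration
#'
#' @param n_interior Interior grid bins used during fitting.
#' @param restarts Number of random restarts (best kept).
#' @param maxit L-BFGS-B iteration cap per restart.
#' @param seed Seed controlling restart jitter.
#' @param latent_prior_sd,weight_prior_sd Standard deviations of the
#'   zero-mean Gaussian priors on the unconstrained latent parameters
#'   (log B, log sigma_s2, mu0) and on the encoding weights / baseline
#'   coefficients. Set \code{use_prior = FALSE} for pure maximum likelihood.
#' @param use_prior Use the Gaussian priors (MAP) or plain ML.
#' @param tied_weights Constrain w_DC = w_EA (the single-mode accumulator
#'   used as the comparison baseline).
#' @param refine_baseline Refine the baseline coefficients jointly with all
#'   other parameters (otherwise they stay frozen at the per-neuron Poisson
#'   GLM estimates).
#' @param basis A \code{\link{basis_config}} for the baseline model; use
#'   \code{NULL} for a constant (intercept-only) baseline per neuron.
#' @param verbose Print progress.
#' @return List of class \code{fit_config}.
#' @export
fit_config <- function(n_interior = 99L, restarts = 3L, maxit = 150L,
                       seed = 1L, latent_prior_sd = 2, weight_prior_sd = 5,
                       use_prior = TRUE, tied_weights = FALSE,
                       refine_baseline = FALSE, basis = basis_config(),
                       verbose = FALSE) {
  structure(list(n_interior = as.integer(n_interior),
                 restarts = as.integer(restarts), maxit = as.integer(maxit),
                 seed = as.integer(seed), latent_prior_sd = latent_prior_sd,
                 weight_prior_sd = weight_prior_sd, use_prior = use_prior,
                 tied_weights = tied_weights,
                 refine_baseline = refine_baseline, basis = basis,
                 verbose = verbose), class = "fit_config")
}

# theta packing: [logB, log sigma_s2, mu0, wEA (N), (wDC (N) unless tied),
#                 (baseline coefs, N x K, if refined)]
unpack_theta <- function(theta, N, tied, K = 0L) {
  # clamp the unconstrained scale so line-search overshoots cannot produce
  # an infinite bound or noise variance
  B <- exp(min(max(theta[1L], -20), 20))
  sigma_s2 <- exp(min(max(theta[2L], -30), 20))
  mu0 <- theta[3L]
  wEA <- theta[3L + seq_len(N)]
  wDC <- if (tied) wEA else theta[3L + N + seq_len(N)]
  off <- 3L + N + if (tied) 0L else N
  beta <- if (K > 0L) matrix(theta[off + seq_len(N * K)], N, K) else NULL
  list(B = B, sigma_s2 = sigma_s2, mu0 = mu0, wEA = wEA, wDC = wDC,
       beta = beta)
}

#' Fit all parameters jointly by maximum a posteriori estimation
#'
#' Maximizes the sum over trials of \code{\link{trial_loglik}} plus the log
#' prior over the three latent parameters and all per-neuron parameters.
#' Positivity of B and sigma_s2 is enforced by optimizing log B and
#' log sigma_s2. Baseline coefficients are initialized from a per-neuron
#' Poisson GLM and, by default, held there (set
#' \code{refine_baseline = TRUE} in the config to refine them jointly).
#' Gradients for the per-neuron parameters are exact (Fisher's identity over
#' the smoothed posterior); the three latent parameters use central finite
#' differences.
#'
#' @param session An \code{\link{mmddm_session}}.
#' @param config A \code{\link{fit_config}}.
#' @param init Optional \code{\link{mmddm_params}} used as the starting
#'   point of the first restart.
#' @return A list of class \code{mmddm_fit}: \code{params} (point estimate),
#'   \code{logpost} (value at the optimum), \code{trace} (objective trace),
#'   \code{convergence}, \code{restart_values}, \code{config}.
#' @export
fit_map <- function(session, config = fit_config(), init = NULL) {
  N <- n_neurons(session)
  if (N < 1L) stop("session must contain at least one neuron")
  dt <- session$dt
  set.seed(config$seed)

  # --- baseline initialization (per-neuron Poisson GLM) ---
  span <- max(vapply(session$trials, `[[`, numeric(1), "start_time")) + 5
  if (is.null(config$basis)) {
    counts <- bin_spike_counts(session)
    tot <- Reduce(`+`, lapply(counts, function(y) rowSums(y)))
    nstep <- sum(vapply(session$trials, trial_n_steps, integer(1), dt))
    rate <- tot / (nstep * dt)
    baselines <- as.list(softplus_inv(pmax(rate, 1e-3)))
    K <- 0L
    designs <- NULL
  } else {
    baselines <- lapply(seq_len(N), function(n) {
      fit_baseline(session$spikes[[n]], session$trials, span,
                   config$basis, dt)
    })
    if (config$refine_baseline) {
      K <- n_baseline_coefs(config$basis)
      # spike-history columns are neuron-specific; cache one design per
      # neuron per trial only when refining jointly
      designs <- lapply(seq_len(n_trials(session)), function(i) {
        tr <- session$trials[[i]]
        Tn <- trial_n_steps(tr, dt)
        lapply(seq_len(N), function(n) {
          baseline_design(Tn, tr$start_time, tr$movement_onset,
                          session$spikes[[n]][[i]], span, config$basis, dt)
        })
      })
    } else {
      K <- 0L
      designs <- NULL
    }
  }

  params0 <- mmddm_params(B = 5.5, sigma_s2 = 2, mu0 = 0,
                          w_EA = rep(0, N), w_DC = rep(0, N),
                          baseline = baselines,
                          dt = dt, n_interior = config$n_interior)
  dat <- prepare_session_data(session, params0)
  tied <- isTRUE(config$tied_weights)
  n_w <- if (tied) N else 2L * N
  n_par <- 3L + n_w + N * K

  prior_sd <- c(rep(config$latent_prior_sd, 3L),
                rep(config$weight_prior_sd, n_w + N * K))

  # neuron x trial designs flattened for the refined-baseline branch
  beta0 <- if (K > 0L) {
    t(vapply(baselines, function(bm) bm$coef, numeric(K)))
  } else NULL

  obj_env <- new.env()
  obj_env$trace <- numeric(0)

  negpost <- function(theta) {
    p <- unpack_theta(theta, N, tied, K)
    grid <- latent_grid(p$B, config$n_interior)
    ll <- 0
    for (i in seq_along(dat$trials)) {
      b <- if (K > 0L) {
        do.call(rbind, lapply(seq_len(N), function(n) {
          drop(designs[[i]][[n]] %*% p$beta[n, ])
        }))
      } else dat$b[[i]]
      res <- prepared_trial_fb(dat$trials[[i]], b, grid, p$sigma_s2,
                               p$mu0, dat$dt, p$wEA, p$wDC)
      if (!is.finite(res$loglik)) return(1e10)
      ll <- ll + res$loglik
    }
    val <- -ll
    if (config$use_prior) val <- val + sum(theta^2 / (2 * prior_sd^2))
    obj_env$trace <- c(obj_env$trace, -val)
    val
  }

  negpost_grad <- function(theta) {
    p <- unpack_theta(theta, N, tied, K)
    grid <- latent_grid(p$B, config$n_interior)
    gEA <- numeric(N); gDC <- numeric(N)
    gBeta <- if (K > 0L) matrix(0, N, K) else NULL
    logem_cache <- vector("list", length(dat$trials))
    b_cache <- vector("list", length(dat$trials))
    ll <- 0
    for (i in seq_along(dat$trials)) {
      b <- if (K > 0L) {
        do.call(rbind, lapply(seq_len(N), function(n) {
          drop(designs[[i]][[n]] %*% p$beta[n, ])
        }))
      } else dat$b[[i]]
      b_cache[[i]] <- b
      logem_cache[[i]] <- cpp_emission_matrix(dat$trials[[i]]$y,
                                              grid$centers, p$wEA, p$wDC,
                                              b, dat$dt)
      res <- prepared_trial_fb(dat$trials[[i]], b, grid, p$sigma_s2,
                               p$mu0, dat$dt, p$wEA, p$wDC,
                               want_smooth = TRUE,
                               logem = logem_cache[[i]])
      if (!is.finite(res$loglik)) return(rep(0, n_par))
      ll <- ll + res$loglik
      eg <- cpp_emission_grad(dat$trials[[i]]$y, grid$centers, p$wEA,
                              p$wDC, b, dat$dt, res$smoothed)
      gEA <- gEA + eg$gwEA
      gDC <- gDC + eg$gwDC
      if (K > 0L) {
        for (n in seq_len(N)) {
          gBeta[n, ] <- gBeta[n, ] + drop(eg$gb[n, ] %*% designs[[i]][[n]])
        }
      }
    }
    # latent parameters: central finite differences on the unconstrained
    # scale; sigma_s2 and mu0 leave the grid (hence emissions) unchanged
    h <- 1e-4
    fd_ll <- function(th) {
      q <- unpack_theta(th, N, tied, K)
      g2 <- latent_grid(q$B, config$n_interior)
      same_grid <- isTRUE(all.equal(q$B, p$B))
      s <- 0
      for (i in seq_along(dat$trials)) {
        s <- s + prepared_trial_fb(
          dat$trials[[i]], b_cache[[i]], g2, q$sigma_s2, q$mu0, dat$dt,
          q$wEA, q$wDC,
          logem = if (same_grid) logem_cache[[i]] else NULL)$loglik
      }
      s
    }
    gl <- numeric(3L)
    for (j in 1:3) {
      tp <- theta; tm <- theta
      tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
      gl[j] <- (fd_ll(tp) - fd_ll(tm)) / (2 * h)
    }
    gl[!is.finite(gl)] <- 0
    gw <- if (tied) gEA + gDC else c(gEA, gDC)
    grad_ll <- c(gl, gw, if (K > 0L) as.numeric(gBeta))
    g <- -grad_ll
    if (config$use_prior) g <- g + theta / prior_sd^2
    g
  }

  # data-driven weight initialization: regress per-step spike rates on the
  # cumulative adapted-evidence path (a noise-free latent proxy), rescaled
  # by the local slope of the softplus at the neuron's baseline
  w0 <- local({
    num <- numeric(N); den <- 0
    mean_rate <- numeric(N); nsteps <- 0
    for (i in seq_along(dat$trials)) {
      mean_rate <- mean_rate + rowSums(dat$trials[[i]]$y)
      nsteps <- nsteps + dat$trials[[i]]$n_steps
    }
    mean_rate <- mean_rate / (nsteps * dt)
    for (i in seq_along(dat$trials)) {
      zhat <- pmin(pmax(cumsum(dat$trials[[i]]$m), -4), 4)
      num <- num + (dat$trials[[i]]$y / dt - mean_rate) %*% zhat
      den <- den + sum(zhat^2)
    }
    slope <- stats::plogis(softplus_inv(pmax(mean_rate, 0.5)))
    drop(num) / den / slope
  })

  theta_init <- function(r) {
    if (r == 1L && !is.null(init)) {
      th <- c(log(init$B), log(max(init$sigma_s2, 1e-6)), init$mu0,
              init$w_EA, if (!tied) init$w_DC)
      if (K > 0L) th <- c(th, as.numeric(beta0))
      return(th)
    }
    jitter <- if (r <= 1L + is.null(init)) 0 else 0.3
    th <- c(log(4), log(0.5), 0,
            rep(w0, if (tied) 1L else 2L) + stats::rnorm(n_w, 0, jitter))
    if (K > 0L) th <- c(th, as.numeric(beta0 + stats::rnorm(N * K, 0,
                                                            0.1 * jitter)))
    th
  }

  best <- NULL
  restart_values <- numeric(0)
  for (r in seq_len(config$restarts)) {
    th0 <- theta_init(r)
    fit <- stats::optim(th0, negpost, negpost_grad, method = "L-BFGS-B",
                        control = list(maxit = config$maxit,
                                       factr = 1e9))
    restart_values <- c(restart_values, -fit$value)
    if (config$verbose) {
      message(sprintf("restart %d: log-posterior %.3f (conv %d)",
                      r, -fit$value, fit$convergence))
    }
    if (is.null(best) || fit$value < best$value) best <- fit
  }

  p <- unpack_theta(best$par, N, tied, K)
  final_baselines <- if (K > 0L) {
    lapply(seq_len(N), function(n) {
      bm <- baselines[[n]]
      bm$coef <- p$beta[n, ]
      bm
    })
  } else baselines
  params <- mmddm_params(B = p$B, sigma_s2 = p$sigma_s2, mu0 = p$mu0,
                         w_EA = p$wEA, w_DC = p$wDC,
                         baseline = final_baselines,
                         dt = dt, n_interior = config$n_interior)
  structure(list(params = params, logpost = -best$value,
                 trace = obj_env$trace, convergence = best$convergence,
                 restart_values = restart_values, tied = tied,
                 config = config), class = "mmddm_fit")
}

#' @export
print.mmddm_fit <- function(x, ...) {
  cat(sprintf(
    "<mmddm_fit> %s: B = %.3f, sigma_s2 = %.3f, mu0 = %.3f, %d neurons\n",
    if (x$tied) "tied weights" else "switching weights",
    x$params$B, x$params$sigma_s2, x$params$mu0, length(x$params$w_EA)))
  cat(sprintf("  log-posterior %.3f (convergence code %d)\n",
              x$logpost, x$convergence))
  invisible(x)
}

#' Session log-likelihood under fitted parameters
#'
#' @param session An \code{\link{mmddm_session}}.
#' @param params An \code{\link{mmddm_params}}.
#' @param trial_idx Optional subset of trials.
#' @return Vector of per-trial log-likelihoods.
#' @export
session_loglik <- function(session, params, trial_idx = NULL) {
  dat <- prepare_session_data(session, params)
  if (is.null(trial_idx)) trial_idx <- seq_along(dat$trials)
  grid <- latent_grid(params$B, params$n_interior)
  vapply(trial_idx, function(i) {
    prepared_trial_fb(dat$trials[[i]], dat$b[[i]], grid, params$sigma_s2,
                      params$mu0, dat$dt, params$w_EA, params$w_DC)$loglik
  }, numeric(1))
}

#' k-fold cross-validation
#'
#' Trial-level folds; each fold's model is fitted on the remaining trials
#' and scored by per-trial out-of-sample log-likelihood on the held-out
#' trials. Setting \code{tied_weights} in the config fits the single-mode
#' comparison model instead.
#'
#' @param session An \code{\link{mmddm_session}}.
#' @param k Number of folds (>= 2; \code{k = n_trials} is leave-one-out).
#' @param config A \code{\link{fit_config}}.
#' @return A list of class \code{mmddm_cv}: \code{folds} (per-trial fold
#'   assignment), \code{fits} (per-fold \code{mmddm_fit}),
#'   \code{oos_loglik} (per-trial out-of-sample log-likelihood).
#' @export
crossvalidate <- function(session, k = 5L, config = fit_config()) {
  nt <- n_trials(session)
  if (k < 2L || k > nt) stop("k must lie in [2, n_trials]")
  set.seed(config$seed)
  folds <- sample(rep(seq_len(k), length.out = nt))
  oos <- numeric(nt)
  fits <- vector("list", k)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    if (!length(train)) stop("fold with zero training trials")
    sub <- subset_session(session, train)
    fits[[f]] <- fit_map(sub, config)
    oos[test] <- session_loglik(session, fits[[f]]$params, test)
  }
  structure(list(folds = folds, fits = fits, oos_loglik = oos, k = k),
            class = "mmddm_cv")
}

#' Subset a session by trial indices
#'
#' @param session An \code{\link{mmddm_session}}.
#' @param idx Trial indices to keep (original order preserved).
#' @return A new \code{mmddm_session}.
#' @export
subset_session <- function(session, idx) {
  idx <- sort(unique(idx))
  gt <- session$ground_truth
  if (!is.null(gt)) {
    for (f in c("z_final", "commit_step", "commit_side")) {
      if (!is.null(gt[[f]])) gt[[f]] <- gt[[f]][idx]
    }
    if (!is.null(gt$z_path)) gt$z_path <- gt$z_path[idx]
  }
  mmddm_session(session_id = paste0(session$session_id, "_sub"),
                trials = session$trials[idx],
                spikes = lapply(session$spikes, function(s) s[idx]),
                neuron_ids = session$neuron_ids,
                ground_truth = gt, dt = session$dt)
}
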