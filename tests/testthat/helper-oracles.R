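# Independent oracles and small fixtures used across the test files.
# Everything here uses plain-R reference implementations (transition_matrix,
# emission_loglik, choice_loglik) and exhaustive enumeration / Monte-Carlo,
# never the compiled forward-backward path that they check.

# Build a minimal trial object consumed by trial_loglik / smooth_trial.
make_toy_trial <- function(n_steps, n_neurons, seed = 1L,
                           duration = NULL, rates = c(20, 20),
                           choice = "R") {
  set.seed(seed)
  if (is.null(duration)) duration <- n_steps * 0.01
  cond <- list(rate_left = rates[1], rate_right = rates[2],
               duration = duration)
  clicks <- generate_click_trains(cond)
  y <- matrix(rpois(n_neurons * n_steps, 2), n_neurons, n_steps)
  list(clicks = clicks, spike_counts = y, choice = choice)
}

# Exhaustive path-sum likelihood over all S^T latent paths.
enum_loglik <- function(trial, params) {
  dt <- params$dt
  Tn <- ncol(trial$spike_counts)
  grid <- latent_grid(params$B, params$n_interior)
  S <- params$n_interior + 2L
  ad <- adapt_clicks(trial$clicks, params$adaptation)
  ad <- ad[ad$time < Tn * dt, , drop = FALSE]
  inp <- discretize_inputs(ad, params$sigma_s2, dt, Tn)
  b <- trial$baseline
  if (is.null(b)) b <- matrix(0, nrow(trial$spike_counts), Tn)
  pi0 <- mmddm:::gaussian_bin_probs(grid, params$mu0 + inp$m[1],
                                    1 + inp$v[1])
  As <- lapply(seq_len(Tn)[-1], function(t) {
    transition_matrix(grid, inp$m[t], inp$v[t], dt)
  })
  ems <- lapply(seq_len(Tn), function(t) {
    exp(emission_loglik(trial$spike_counts[, t], grid, params$w_EA,
                        params$w_DC, b[, t], dt))
  })
  chi <- exp(choice_loglik(trial$choice, grid))
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), Tn)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    p <- pi0[paths[r, 1]] * ems[[1]][paths[r, 1]]
    if (Tn > 1) {
      for (t in 2:Tn) {
        p <- p * As[[t - 1]][paths[r, t - 1], paths[r, t]] *
          ems[[t]][paths[r, t]]
      }
    }
    tot <- tot + p * chi[paths[r, Tn]]
  }
  log(tot)
}

# Exhaustive smoothed posterior over the same path sum.
enum_smoothed <- function(trial, params) {
  dt <- params$dt
  Tn <- ncol(trial$spike_counts)
  grid <- latent_grid(params$B, params$n_interior)
  S <- params$n_interior + 2L
  ad <- adapt_clicks(trial$clicks, params$adaptation)
  ad <- ad[ad$time < Tn * dt, , drop = FALSE]
  inp <- discretize_inputs(ad, params$sigma_s2, dt, Tn)
  b <- trial$baseline
  if (is.null(b)) b <- matrix(0, nrow(trial$spike_counts), Tn)
  pi0 <- mmddm:::gaussian_bin_probs(grid, params$mu0 + inp$m[1],
                                    1 + inp$v[1])
  As <- lapply(seq_len(Tn)[-1], function(t) {
    transition_matrix(grid, inp$m[t], inp$v[t], dt)
  })
  ems <- lapply(seq_len(Tn), function(t) {
    exp(emission_loglik(trial$spike_counts[, t], grid, params$w_EA,
                        params$w_DC, b[, t], dt))
  })
  chi <- exp(choice_loglik(trial$choice, grid))
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), Tn)))
  post <- matrix(0, S, Tn)
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    p <- pi0[paths[r, 1]] * ems[[1]][paths[r, 1]]
    if (Tn > 1) {
      for (t in 2:Tn) {
        p <- p * As[[t - 1]][paths[r, t - 1], paths[r, t]] *
          ems[[t]][paths[r, t]]
      }
    }
    p <- p * chi[paths[r, Tn]]
    tot <- tot + p
    for (t in seq_len(Tn)) post[paths[r, t], t] <- post[paths[r, t], t] + p
  }
  post / tot
}

# Bootstrap particle filter on the exact continuous-state generative
# dynamics: multinomial resampling every step keeps the weight variance
# bounded; the likelihood estimate is the product of per-step mean weights.
pf_loglik_once <- function(trial, params, n_particles, b) {
  dt <- params$dt
  Tn <- ncol(trial$spike_counts)
  ad <- adapt_clicks(trial$clicks, params$adaptation)
  ad <- ad[ad$time < Tn * dt, , drop = FALSE]
  n_clicks <- nrow(ad)
  step <- if (n_clicks) pmin(floor(ad$time / dt) + 1L, Tn) else integer(0)
  signC <- if (n_clicks) ifelse(ad$side == "R", 1, -1) * ad$magnitude else
    numeric(0)
  N <- nrow(trial$spike_counts)
  z <- params$mu0 + rnorm(n_particles)
  committed <- rep(FALSE, n_particles)
  ll <- 0
  for (t in seq_len(Tn)) {
    u <- numeric(n_particles)
    if (n_clicks && any(step == t)) {
      for (k in which(step == t)) {
        u <- u + signC[k] * rnorm(n_particles, 1, sqrt(params$sigma_s2))
      }
    }
    if (t == 1L) {
      z <- z + u                     # initial draw folds step-1 input
    } else {
      z <- ifelse(committed, z, z + u + rnorm(n_particles, 0, sqrt(dt)))
    }
    newly <- !committed & abs(z) >= params$B
    z[newly] <- params$B * sign(z[newly])
    committed <- committed | newly
    logw <- numeric(n_particles)
    for (n in seq_len(N)) {
      wn <- ifelse(committed, params$w_DC[n], params$w_EA[n])
      lam <- pmax(softplus(wn * z + b[n, t]) * dt, 1e-300)
      logw <- logw + dpois(trial$spike_counts[n, t], lam, log = TRUE)
    }
    if (t == Tn) {
      ok <- if (trial$choice == "R") z > 0 else z < 0
      ok <- ok | (z == 0 & runif(n_particles) < 0.5)
      logw[!ok] <- -Inf
    }
    mx <- max(logw)
    if (!is.finite(mx)) return(-Inf)
    w <- exp(logw - mx)
    ll <- ll + log(mean(w)) + mx
    idx <- sample.int(n_particles, replace = TRUE, prob = w)
    z <- z[idx]
    committed <- committed[idx]
  }
  ll
}

# Replicated particle-filter likelihood: returns the mean estimate and the
# Monte-Carlo standard error across independent replicates.
particle_loglik <- function(trial, params, n_particles = 1e5, seed = 99L,
                            n_reps = 10L) {
  set.seed(seed)
  b <- trial$baseline
  if (is.null(b)) {
    b <- matrix(0, nrow(trial$spike_counts), ncol(trial$spike_counts))
  }
  per <- max(500L, floor(n_particles / n_reps))
  lls <- vapply(seq_len(n_reps), function(r) {
    pf_loglik_once(trial, params, per, b)
  }, numeric(1))
  list(loglik = mean(lls), se = sd(lls) / sqrt(n_reps), reps = lls)
}

# Small simulated session with known generative parameters.
make_sim_session <- function(n_neurons = 8L, n_trials = 40L, seed = 42L,
                             B = 5.5, sigma_s2 = 2, mu0 = 0,
                             weight_sd = 0.8, n_interior = 49L) {
  set.seed(seed)
  np <- sample_neuron_params(n_neurons, weight_sd = weight_sd)
  pars <- mmddm_params(B = B, sigma_s2 = sigma_s2, mu0 = mu0,
                       w_EA = np$w_EA, w_DC = np$w_DC,
                       baseline = np$baseline, n_interior = n_interior)
  sess <- simulate_session(pars, n_trials = n_trials, seed = seed + 1L)
  list(session = sess, params = pars)
}
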