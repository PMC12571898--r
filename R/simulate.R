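#' Generative simulation of the multi-mode drift-diffusion model
#'
#' Synthesizes full sessions -- stimuli, latent paths, spike trains and
#' choices -- with ground truth recorded per trial, for testing, parameter
#' recovery and model-prediction curves.
#'
#' @name simulator
NULL

#' Euler-simulate the bounded latent path of one trial
#'
#' z starts at N(mu0, 1); each step adds the net noisy click input u(t) and
#' diffusion noise eta ~ N(0, dt) until |z| reaches the bound B, where it
#' freezes at B sign(z). The per-click input is the adapted magnitude C
#' corrupted by multiplicative noise zeta ~ N(1, sigma_s2), independently
#' per click.
#'
#' @param n_steps Number of steps.
#' @param params An \code{\link{mmddm_params}} (uses B, sigma_s2, mu0, dt).
#' @param clicks Optional \code{\link{adapt_clicks}} output; \code{NULL}
#'   means a click-free path.
#' @return A list: \code{z} (length n_steps), \code{commit_step} (first step
#'   with |z| >= B, or NA), \code{commit_side} ("L"/"R" or NA).
#' @export
simulate_latent_path <- function(n_steps, params, clicks = NULL) {
  dt <- params$dt
  u <- numeric(n_steps)
  if (!is.null(clicks) && nrow(clicks)) {
    keep <- clicks$time < n_steps * dt
    ck <- clicks[keep, , drop = FALSE]
    if (nrow(ck)) {
      zeta <- stats::rnorm(nrow(ck), 1, sqrt(params$sigma_s2))
      signed <- ifelse(ck$side == "R", 1, -1) * ck$magnitude * zeta
      step <- pmin(floor(ck$time / dt) + 1L, n_steps)
      for (k in seq_len(nrow(ck))) u[step[k]] <- u[step[k]] + signed[k]
    }
  }
  eta <- stats::rnorm(n_steps, 0, sqrt(dt))
  # step 1 folds the first-step input into the initial draw, mirroring the
  # inference convention
  incr <- u + eta
  incr[1L] <- params$mu0 + stats::rnorm(1, 0, 1) + u[1L]
  z <- cumsum(incr)
  hit <- which(abs(z) >= params$B)
  if (length(hit)) {
    s <- hit[1L]
    zb <- params$B * sign(z[s])
    z[s:n_steps] <- zb
    list(z = z, commit_step = s, commit_side = if (zb > 0) "R" else "L")
  } else {
    list(z = z, commit_step = NA_integer_, commit_side = NA_character_)
  }
}

#' Draw per-neuron generative parameters
#'
#' Baseline input currents are drawn so that baseline firing rates are
#' log-normal around ~8 spikes/s; encoding weights are zero-mean Gaussian.
#' A configurable fraction of neurons is made accumulation-only
#' (w_DC = 0) or commitment-only (w_EA = 0) to emulate the observed spread
#' of engagement.
#'
#' @param n_neurons Number of neurons.
#' @param weight_sd Standard deviation of the encoding weights.
#' @param frac_ea_only,frac_dc_only Fractions of neurons with w_DC = 0 and
#'   w_EA = 0 respectively.
#' @return A list with \code{w_EA}, \code{w_DC}, \code{baseline} (constant
#'   input currents).
#' @export
sample_neuron_params <- function(n_neurons, weight_sd = 0.8,
                                 frac_ea_only = 0.15, frac_dc_only = 0.15) {
  rate <- exp(stats::rnorm(n_neurons, log(8), 0.5))
  w_EA <- stats::rnorm(n_neurons, 0, weight_sd)
  w_DC <- stats::rnorm(n_neurons, 0, weight_sd)
  n_ea <- round(frac_ea_only * n_neurons)
  n_dc <- round(frac_dc_only * n_neurons)
  idx <- sample.int(n_neurons)
  if (n_ea > 0) w_DC[idx[seq_len(n_ea)]] <- 0
  if (n_dc > 0) w_EA[idx[n_ea + seq_len(n_dc)]] <- 0
  list(w_EA = w_EA, w_DC = w_DC, baseline = softplus_inv(rate))
}

#' Simulate a full session
#'
#' Per trial: sample a condition and Poisson click trains, adapt the clicks,
#' Euler-simulate the bounded latent, emit Poisson spike counts with the
#' regime-appropriate encoding weight, and set the choice to the sign of z at
#' the final step (ties broken at random). Ground truth (latent paths,
#' commitment steps and sides, generative weights) is stored in the session.
#'
#' @param params An \code{\link{mmddm_params}} carrying per-neuron weights
#'   and baselines (constants or \code{baseline_model}s).
#' @param task A \code{\link{trial_config}}.
#' @param n_trials Number of trials.
#' @param seed Integer seed; the session is reproducible given the seed.
#' @param session_id Identifier for the new session.
#' @param iti Inter-trial interval, seconds (trial start times).
#' @return An \code{\link{mmddm_session}} with a \code{ground_truth} block.
#' @export
simulate_session <- function(params, task = trial_config(), n_trials = 100L,
                             seed = 1L, session_id = "sim", iti = 5) {
  set.seed(seed)
  N <- length(params$w_EA)
  if (N < 1L) stop("params must carry at least one neuron")
  dt <- params$dt
  conds <- sample_trial_conditions(n_trials, task, seed = NULL)
  trials <- vector("list", n_trials)
  spikes <- lapply(seq_len(N), function(n) vector("list", n_trials))
  z_paths <- vector("list", n_trials)
  commit_step <- integer(n_trials)
  commit_side <- character(n_trials)
  z_final <- numeric(n_trials)

  bconst <- vapply(params$baseline, function(b) {
    if (inherits(b, "baseline_model")) NA_real_ else as.numeric(b)[1]
  }, numeric(1))

  for (i in seq_len(n_trials)) {
    cond <- conds[i, ]
    train <- generate_click_trains(cond)
    movement_onset <- cond$duration + stats::runif(1, 0, 0.2)
    start_time <- (i - 1) * iti
    tr <- list(clicks = train, choice = "R",
               movement_onset = movement_onset, start_time = start_time,
               duration = cond$duration,
               rate_left = cond$rate_left, rate_right = cond$rate_right)
    Tn <- trial_n_steps(tr, dt)
    ad <- adapt_clicks(train, params$adaptation)
    lp <- simulate_latent_path(Tn, params, ad)
    zt <- lp$z
    interior <- abs(zt) < params$B
    if (!is.na(lp$commit_step)) interior[seq(lp$commit_step, Tn)] <- FALSE
    # regime-dependent encoding weight per step
    for (n in seq_len(N)) {
      w <- ifelse(interior, params$w_EA[n], params$w_DC[n])
      b <- if (is.na(bconst[n])) {
        evaluate_baseline(params$baseline[[n]], tr, numeric(0), dt)
      } else rep(bconst[n], Tn)
      lam <- softplus(w * zt + b) * dt
      y <- stats::rpois(Tn, lam)
      # uniform spike times within each occupied bin
      st <- rep((seq_len(Tn) - 1L) * dt, y) + stats::runif(sum(y), 0, dt)
      spikes[[n]][[i]] <- sort(st)
    }
    zT <- zt[Tn]
    tr$choice <- if (zT > 0) "R" else if (zT < 0) "L" else
      sample(c("L", "R"), 1L)
    trials[[i]] <- tr
    z_paths[[i]] <- zt
    commit_step[i] <- lp$commit_step
    commit_side[i] <- lp$commit_side
    z_final[i] <- zT
  }

  mmddm_session(
    session_id = session_id, trials = trials, spikes = spikes,
    ground_truth = list(z_path = z_paths, z_final = z_final,
                        commit_step = commit_step,
                        commit_side = commit_side,
                        w_EA = params$w_EA, w_DC = params$w_DC,
                        B = params$B, sigma_s2 = params$sigma_s2,
                        mu0 = params$mu0, seed = seed),
    dt = dt)
}

#' Parameter-recovery experiment
#'
#' Simulates sessions from known parameters, refits each with
#' \code{\link{fit_map}}, and summarizes how well the generative parameters
#' and commitment times are recovered.
#'
#' @param true_params Generative \code{\link{mmddm_params}} (neuron
#'   parameters are redrawn per session via
#'   \code{\link{sample_neuron_params}} unless \code{redraw_neurons} is
#'   FALSE).
#' @param n_neurons,n_trials,n_sessions Sizes.
#' @param seed Base seed; session s uses seed + s.
#' @param config A \code{\link{fit_config}}.
#' @param redraw_neurons Redraw neuron parameters each session.
#' @param ntc_threshold Detection threshold for the commitment-time error.
#' @return A list of class \code{recovery_report}: per-session data.frame
#'   \code{latent} (true/estimated B, sigma_s2, mu0), \code{weights}
#'   (per-neuron true and estimated w_EA/w_DC, engagement indices),
#'   \code{ntc_error} (median |detected - true| steps over detected trials
#'   with true commitment), \code{failures}.
#' @export
recovery_experiment <- function(true_params, n_neurons = 40L,
                                n_trials = 500L, n_sessions = 10L,
                                seed = 1L, config = fit_config(),
                                redraw_neurons = TRUE,
                                ntc_threshold = 0.8) {
  latent <- data.frame()
  weights <- data.frame()
  ntc_err <- numeric(0)
  failures <- list()
  for (s in seq_len(n_sessions)) {
    sseed <- seed + s
    set.seed(sseed)
    pars <- true_params
    if (redraw_neurons) {
      np <- sample_neuron_params(n_neurons)
      pars <- mmddm_params(B = true_params$B,
                           sigma_s2 = true_params$sigma_s2,
                           mu0 = true_params$mu0,
                           w_EA = np$w_EA, w_DC = np$w_DC,
                           baseline = np$baseline,
                           adaptation = true_params$adaptation,
                           dt = true_params$dt,
                           n_interior = true_params$n_interior)
    }
    sess <- simulate_session(pars, n_trials = n_trials, seed = sseed,
                             session_id = sprintf("rec%02d", s))
    fit <- tryCatch(fit_map(sess, config), error = function(e) e)
    if (inherits(fit, "error")) {
      failures[[length(failures) + 1L]] <- list(session = s,
                                                message = fit$message)
      next
    }
    est <- fit$params
    latent <- rbind(latent, data.frame(
      session = s, B_true = pars$B, B_est = est$B,
      sigma_s2_true = pars$sigma_s2, sigma_s2_est = est$sigma_s2,
      mu0_true = pars$mu0, mu0_est = est$mu0))
    weights <- rbind(weights, data.frame(
      session = s, neuron = seq_along(pars$w_EA),
      w_EA_true = pars$w_EA, w_DC_true = pars$w_DC,
      w_EA_est = est$w_EA, w_DC_est = est$w_DC))
    # commitment-time error on trials with true commitment and detection
    ntc <- session_ntc(sess, est, ntc_threshold)
    gt <- sess$ground_truth
    both <- ntc$detected & !is.na(gt$commit_step)
    if (any(both)) {
      ntc_err <- c(ntc_err,
                   abs(ntc$nTc_step[both] - gt$commit_step[both]))
    }
  }
  structure(list(latent = latent, weights = weights,
                 ntc_error_steps = ntc_err,
                 median_ntc_error = stats::median(ntc_err),
                 failures = failures), class = "recovery_report")
}
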