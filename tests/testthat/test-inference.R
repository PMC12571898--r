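make_tiny_params <- function(n_neurons = 2L, seed = 1L, n_interior = 3L) {
  set.seed(seed)
  mmddm_params(B = 1.2, sigma_s2 = 0.3, mu0 = 0.1,
               w_EA = rnorm(n_neurons, 0, 0.8),
               w_DC = rnorm(n_neurons, 0, 0.8),
               baseline = rep(2, n_neurons),
               n_interior = n_interior)
}

test_that("forward likelihood matches exhaustive path enumeration", {
  # 5 states (3 interior + 2 bounds), up to 5 steps, several trials
  for (seed in 1:4) {
    pars <- make_tiny_params(2, seed)
    trial <- make_toy_trial(n_steps = 4 + seed %% 2, n_neurons = 2,
                            seed = seed * 10,
                            choice = c("L", "R")[1 + seed %% 2])
    ll <- trial_loglik(trial, pars)
    expect_equal(ll, enum_loglik(trial, pars), tolerance = 1e-10)
  }
})

test_that("smoothed posterior matches exhaustive enumeration", {
  pars <- make_tiny_params(2, 3)
  trial <- make_toy_trial(n_steps = 4, n_neurons = 2, seed = 21)
  post <- smooth_trial(trial, pars)
  ref <- enum_smoothed(trial, pars)
  expect_lt(max(abs(post$smoothed - ref)), 1e-10)
  # columns sum to 1
  expect_lt(max(abs(colSums(post$smoothed) - 1)), 1e-10)
  # final-step smoothed equals the choice-reweighted filtered distribution
  expect_equal(post$smoothed[, 4], post$filtered[, 4], tolerance = 1e-12)
})

test_that("forward likelihood matches a particle-filter estimate", {
  # full-size trial (1 s, 100 steps) at the default grid resolution
  set.seed(30)
  np <- sample_neuron_params(3)
  pars <- mmddm_params(B = 2.5, sigma_s2 = 0.5, mu0 = 0,
                       w_EA = np$w_EA, w_DC = np$w_DC,
                       baseline = np$baseline, n_interior = 99L)
  sess <- simulate_session(pars, n_trials = 2, seed = 31)
  counts <- bin_spike_counts(sess)
  for (i in 1:2) {
    trial <- list(clicks = sess$trials[[i]]$clicks,
                  spike_counts = counts[[i]],
                  choice = sess$trials[[i]]$choice,
                  baseline = matrix(unlist(pars$baseline), 3,
                                    ncol(counts[[i]])))
    ll <- trial_loglik(trial, pars)
    mc <- particle_loglik(trial, pars, n_particles = 1e5, seed = 90 + i)
    expect_lt(abs(ll - mc$loglik), 3 * mc$se + 0.05)
  }
})

test_that("likelihood is invariant to the regime label when weights are tied", {
  # with w_EA = w_DC the model reduces to the single-mode accumulator:
  # the emission matrix is a function of z only
  g <- latent_grid(2, 9)
  w <- c(0.7, -0.4)
  y <- matrix(rpois(2 * 5, 2), 2, 5)
  b <- matrix(2, 2, 5)
  L <- mmddm:::cpp_emission_matrix(y, g$centers, w, w, b, 0.01)
  # bound-state rows equal what interior encoding would give at z = +/-B
  for (t in 1:5) {
    expect_equal(L[g$i_hi, t],
                 sum(dpois(y[, t], softplus(w * 2 + 2) * 0.01, log = TRUE)),
                 tolerance = 1e-12)
  }
})

test_that("grid refinement changes the trial log-likelihood by little", {
  set.seed(33)
  np <- sample_neuron_params(3)
  base <- list(B = 2.5, sigma_s2 = 0.5, mu0 = 0)
  mk <- function(n_int) {
    mmddm_params(B = base$B, sigma_s2 = base$sigma_s2, mu0 = base$mu0,
                 w_EA = np$w_EA, w_DC = np$w_DC, baseline = np$baseline,
                 n_interior = n_int)
  }
  sess <- simulate_session(mk(99L), n_trials = 3, seed = 34)
  counts <- bin_spike_counts(sess)
  for (i in 1:3) {
    trial <- list(clicks = sess$trials[[i]]$clicks,
                  spike_counts = counts[[i]],
                  choice = sess$trials[[i]]$choice,
                  baseline = matrix(unlist(np$baseline), 3,
                                    ncol(counts[[i]])))
    l1 <- trial_loglik(trial, mk(99L))
    l2 <- trial_loglik(trial, mk(199L))
    expect_lt(abs(l1 - l2), 1e-3)
  }
})

test_that("nTc detection follows the max-bound threshold rule", {
  mkpost <- function(lo, hi) {
    structure(list(p_lo = lo, p_hi = hi, ok = TRUE),
              class = "latent_posterior")
  }
  d <- detect_ntc(mkpost(rep(0, 4), c(0.1, 0.5, 0.85, 0.9)), 0.8)
  expect_equal(d$step, 3L)
  expect_equal(d$side, "R")
  # never exceeded: no detection
  expect_null(detect_ntc(mkpost(rep(0.3, 4), rep(0.4, 4)), 0.8))
  # split bound mass never passes the max rule
  expect_null(detect_ntc(mkpost(rep(0.45, 4), rep(0.45, 4)), 0.8))
  expect_error(detect_ntc(mkpost(0, 1), 1.2), "threshold")
})

test_that("MAP fit contracts: prior pinning and non-decreasing objective", {
  sim <- make_sim_session(n_neurons = 4, n_trials = 25, seed = 50)
  # near-zero prior variance pins the estimates at the prior means
  cfg <- fit_config(restarts = 1, maxit = 40, basis = NULL,
                    n_interior = 21, latent_prior_sd = 1e-4,
                    weight_prior_sd = 1e-4)
  fit <- fit_map(sim$session, cfg)
  expect_lt(max(abs(c(fit$params$w_EA, fit$params$w_DC))), 1e-3)
  expect_lt(abs(fit$params$mu0), 1e-3)
  # free fit: the optimum is at least as good as any traced iterate start
  cfg2 <- fit_config(restarts = 1, maxit = 40, basis = NULL,
                     n_interior = 21)
  fit2 <- fit_map(sim$session, cfg2)
  # the optimum is no worse than the initial iterate (line-search
  # excursions in the trace may transiently exceed the accepted iterate)
  expect_gte(fit2$logpost, fit2$trace[1] - 1e-6)
  expect_lt(max(fit2$trace) - fit2$logpost, 1)
})

test_that("cross-validation folds are disjoint and cover all trials", {
  sim <- make_sim_session(n_neurons = 3, n_trials = 12, seed = 60)
  cv <- crossvalidate(sim$session, k = 3,
                      fit_config(restarts = 1, maxit = 15, basis = NULL,
                                 n_interior = 15))
  expect_setequal(unique(cv$folds), 1:3)
  expect_length(cv$folds, 12)
  expect_true(all(is.finite(cv$oos_loglik)))
  expect_error(crossvalidate(sim$session, k = 1), "k must")
})

test_that("session subsetting keeps ground truth aligned", {
  sim <- make_sim_session(n_neurons = 3, n_trials = 10, seed = 61)
  sub <- subset_session(sim$session, c(2, 5, 9))
  expect_equal(n_trials(sub), 3L)
  expect_equal(sub$ground_truth$commit_step,
               sim$session$ground_truth$commit_step[c(2, 5, 9)])
  expect_equal(sub$spikes[[1]][[2]], sim$session$spikes[[1]][[5]])
})
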