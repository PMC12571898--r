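test_that("latent grid is symmetric with a zero-centred bin", {
  g <- latent_grid(2, 9)
  expect_equal(g$centers[g$i_lo], -2)
  expect_equal(g$centers[g$i_hi], 2)
  expect_equal(g$centers[g$i_zero], 0)
  expect_equal(g$centers, -rev(g$centers))
  expect_error(latent_grid(-1), "positive")
  expect_error(latent_grid(1, 8), "odd")
})

test_that("input moments aggregate adapted clicks per step", {
  mk <- function(times, sides, mags) {
    structure(data.frame(time = times, side = sides, magnitude = mags),
              class = c("adapted_clicks", "data.frame"))
  }
  # no clicks
  z <- discretize_inputs(mk(numeric(0), character(0), numeric(0)),
                         0.09, 0.01, 10)
  expect_equal(z$m, rep(0, 10))
  expect_equal(z$v, rep(0, 10))
  # one right click, C = 1
  one <- discretize_inputs(mk(0.034, "R", 1), 0.09, 0.01, 10)
  expect_equal(one$m[4], 1)
  expect_equal(one$v[4], 0.09)
  expect_equal(sum(one$m != 0), 1L)
  # opposite-side clicks in one step: drift cancels partially, variance adds
  two <- discretize_inputs(mk(c(0.051, 0.057), c("R", "L"), c(1, 0.5)),
                           0.1, 0.01, 10)
  expect_equal(two$m[6], 0.5)
  expect_equal(two$v[6], 0.1 * (1 + 0.25))
  expect_error(discretize_inputs(mk(0.5, "R", 1), 0.1, 0.01, 10),
               "outside")
})

test_that("transition matrices are stochastic with absorbing bounds", {
  g <- latent_grid(1.5, 21)
  A <- transition_matrix(g, 0.1, 0.04, 0.01)
  expect_lt(max(abs(rowSums(A) - 1)), 1e-12)
  expect_equal(A[g$i_lo, g$i_lo], 1)
  expect_equal(A[g$i_hi, g$i_hi], 1)
  expect_true(all(A >= 0))
  # repeated application never decreases total bound mass
  p <- initial_distribution(g, 0)
  prev <- p[g$i_lo] + p[g$i_hi]
  for (k in 1:20) {
    p <- drop(p %*% A)
    cur <- p[g$i_lo] + p[g$i_hi]
    expect_gte(cur, prev - 1e-12)
    prev <- cur
  }
})

test_that("propagated moments match Monte-Carlo for a wide grid", {
  # with B large relative to the mass, the discretized step must reproduce
  # mean z + m and variance dt + v of the continuous kernel
  g <- latent_grid(8, 399)
  A <- transition_matrix(g, 0.2, 0.05, 0.01)
  i0 <- which.min(abs(g$centers - 0.5))
  p <- A[i0, ]
  mu <- sum(p * g$centers)
  v <- sum(p * g$centers^2) - mu^2
  set.seed(1)
  zs <- g$centers[i0] + 0.2 + rnorm(1e6, 0, sqrt(0.06))
  expect_lt(abs(mu - mean(zs)), 3e-3)
  expect_lt(abs(v - var(zs)), 3e-3)
})

test_that("initial distribution integrates N(mu0, 1) over the grid", {
  g <- latent_grid(1, 99)
  p <- initial_distribution(g, 0)
  expect_lt(abs(sum(p) - 1), 1e-12)
  expect_equal(p, rev(p), tolerance = 1e-12)           # symmetry at mu0 = 0
  expect_equal(p[g$i_lo], pnorm(-1), tolerance = 1e-9) # bound mass Phi(-1)
  expect_equal(p[g$i_hi], pnorm(-1), tolerance = 1e-9)
})

test_that("spike emission likelihoods switch weights at the bounds", {
  g <- latent_grid(2, 9)
  # zero weights: z-independence
  ll0 <- emission_loglik(c(1, 0), g, c(0, 0), c(0, 0), c(1, 1), 0.01)
  expect_true(all(abs(ll0 - ll0[1]) < 1e-12))
  # y = 0 with lambda dt = 1 contributes exactly -1
  b <- softplus_inv_scalar <- log(exp(100) - 1) # softplus(b) = 100
  ll1 <- emission_loglik(0L, g, 0, 0, b, 0.01)
  expect_equal(ll1[g$i_zero], -1, tolerance = 1e-9)
  # bound states use w_DC: likelihood differs from interior at same |z|
  ll2 <- emission_loglik(3L, g, 1, -1, 2, 0.01)
  lam_int <- softplus(1 * g$centers[g$i_hi - 1] + 2) * 0.01
  lam_dc <- softplus(-1 * g$centers[g$i_hi] + 2) * 0.01
  expect_equal(ll2[g$i_hi], dpois(3, lam_dc, log = TRUE), tolerance = 1e-12)
  expect_equal(ll2[g$i_hi - 1], dpois(3, lam_int, log = TRUE),
               tolerance = 1e-12)
  expect_error(emission_loglik(-1L, g, 0, 0, 0), "non-negative")
  # compiled emission matrix agrees with the plain-R reference
  set.seed(8)
  y <- matrix(rpois(3 * 4, 2), 3, 4)
  wEA <- rnorm(3); wDC <- rnorm(3); bmat <- matrix(rnorm(12, 2), 3, 4)
  Lc <- mmddm:::cpp_emission_matrix(y, g$centers, wEA, wDC, bmat, 0.01)
  for (t in 1:4) {
    Lr <- emission_loglik(y[, t], g, wEA, wDC, bmat[, t], 0.01)
    expect_equal(Lc[, t], Lr, tolerance = 1e-10)
  }
})

test_that("softplus is exact at 0 and overflow-safe", {
  expect_equal(softplus(0), log(2), tolerance = 1e-12)
  expect_equal(softplus(1000), 1000)
  expect_equal(softplus(-50), log1p(exp(-50)))
})

test_that("choice likelihood is the sign of z with a split tie at 0", {
  g <- latent_grid(1, 9)
  lr <- choice_loglik("R", g)
  expect_equal(lr[g$i_hi], 0)                    # log 1 at matching bound
  expect_true(all(lr[g$centers < 0] == -Inf))
  expect_equal(lr[g$i_zero], log(0.5))
  ll <- choice_loglik("L", g)
  expect_equal(exp(lr) + exp(ll), rep(1, length(lr)))  # partition of unity
  expect_error(choice_loglik("X", g), "choice")
})

test_that("baseline GLM recovers a constant rate and handles zero spikes", {
  set.seed(9)
  trials <- lapply(1:30, function(i) {
    list(clicks = NULL, choice = "R", movement_onset = 1.2,
         start_time = (i - 1) * 5, duration = 1)
  })
  # constant-rate Poisson neuron at 12 spikes/s, intercept-only basis
  spk <- lapply(trials, function(tr) sort(runif(rpois(1, 12), 0, 1)))
  cfg0 <- basis_config(n_cross = 0, n_stim = 0, n_move = 0, n_spike = 0)
  bm <- fit_baseline(spk, trials, session_span = 150, cfg = cfg0)
  expect_equal(softplus(bm$coef[1]), 12, tolerance = 0.15 * 12)
  # zero spikes: rate driven toward zero without error
  bm0 <- fit_baseline(lapply(trials, function(x) numeric(0)), trials,
                      session_span = 150, cfg = cfg0)
  expect_lt(softplus(bm0$coef[1]), 0.5)
})

test_that("baseline GLM recovers a known stimulus kernel", {
  set.seed(10)
  cfg <- basis_config(n_cross = 0, n_stim = 4, n_move = 0, n_spike = 0)
  span <- 2000
  true_beta <- c(2, 8, -4, 6, -3)
  X <- baseline_design(100, 0, 1.2, numeric(0), span, cfg)
  lam_true <- softplus(drop(X %*% true_beta))   # ~2-8 spikes/s modulation
  trials <- lapply(1:1000, function(i) {
    list(clicks = NULL, choice = "R", movement_onset = 1.2,
         start_time = (i - 1) * 2, duration = 1)
  })
  spk <- lapply(trials, function(tr) {
    rep((seq_len(100) - 1) * 0.01, rpois(100, lam_true * 0.01)) + 0.005
  })
  bm <- fit_baseline(spk, trials, session_span = span, cfg = cfg)
  # recovery is judged on the rate curve: the bump basis is nearly
  # collinear with the intercept, so coefficients are not identifiable
  expect_gt(cor(softplus(drop(X %*% bm$coef)), lam_true), 0.9)
})
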