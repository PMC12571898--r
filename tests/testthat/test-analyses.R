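test_that("auROC is the rank statistic and invariant to monotone maps", {
  x <- c(5, 7, 9, 12)
  y <- c(1, 2, 6, 8)
  a <- auroc(x, y)
  # brute-force pair counting oracle
  pairs <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(a, mean(pairs))
  expect_equal(auroc(exp(x), exp(y)), a)           # monotone transform
  expect_equal(auroc(sqrt(x), sqrt(y)), a)
  expect_equal(auroc(y, x), 1 - a)
  expect_true(is.na(auroc(numeric(0), y)))
})

test_that("neuron selection applies the auROC band and rate floor", {
  set.seed(11)
  nt <- 600   # large enough that an unselective auROC stays inside the band
  choices <- rep(c("L", "R"), nt / 2)
  trials <- lapply(seq_len(nt), function(i) {
    list(clicks = structure(list(left_times = 0, right_times = 0,
                                 stereoclick_time = 0, duration = 1),
                            class = "click_train"),
         choice = choices[i], movement_onset = 1.1,
         start_time = (i - 1) * 5, duration = 1)
  })
  mk_neuron <- function(rate_L, rate_R) {
    lapply(seq_len(nt), function(i) {
      r <- if (choices[i] == "R") rate_R else rate_L
      sort(runif(rpois(1, r), 0, 1))
    })
  }
  spikes <- list(
    mk_neuron(10, 10),   # unselective, high rate -> excluded
    mk_neuron(5, 14),    # selective, high rate -> included
    mk_neuron(0.4, 1.6)  # selective, rate ~1 spikes/s -> excluded
  )
  sess <- mmddm_session("sel", trials, spikes)
  sel <- select_neurons(sess)
  expect_false(1 %in% sel$included)
  expect_true(2 %in% sel$included)
  expect_false(3 %in% sel$included)
  expect_gt(sel$table$auroc4[2], 0.58)
  # all-one-choice session: auROC undefined, neuron flagged not included
  sessR <- mmddm_session("selR", trials[choices == "R"],
                         lapply(spikes, function(s) s[choices == "R"]))
  selR <- select_neurons(sessR)
  expect_length(selR$included, 0)
  expect_true(all(selR$table$flagged))
})

test_that("PSTH reproduces flat rates and the causal impulse response", {
  set.seed(12)
  nt <- 200
  blank <- structure(list(left_times = 0, right_times = 0,
                          stereoclick_time = 0, duration = 1),
                     class = "click_train")
  trials <- lapply(seq_len(nt), function(i) {
    list(clicks = blank, choice = "R", movement_onset = 1.1,
         start_time = (i - 1) * 5, duration = 1)
  })
  spikes <- list(lapply(seq_len(nt), function(i) {
    sort(runif(rpois(1, 10), 0, 1))
  }))
  sess <- mmddm_session("psth", trials, spikes)
  ps <- compute_psth(sess, 1, seq_len(nt))
  # flat at 10 spikes/s away from the leading edge (kernel warm-up)
  mid <- ps$time > 0.3
  expect_lt(abs(mean(ps$rate[mid]) - 10), 1)
  # normalized variant of a constant-rate neuron is ~1
  psn <- compute_psth(sess, 1, seq_len(nt), normalize = TRUE)
  expect_lt(abs(mean(psn$rate[mid]) - 1), 0.12)
  # impulse response: a single spike maps to the causal kernel shape
  one <- mmddm_session("one", trials[1],
                       list(list(0.405)))
  p1 <- compute_psth(one, 1, 1)
  expect_equal(which(p1$rate > 0)[1], 41L)   # nothing before the spike bin
  kern <- mmddm:::causal_gaussian_kernel(0.1, 0.3, 0.01)
  expect_equal(p1$rate[41:71] * 0.01, kern, tolerance = 1e-12)
  expect_error(compute_psth(sess, 1, integer(0)), "empty")
})

test_that("PSTH of merged conditions is the weighted mean of conditions", {
  set.seed(13)
  sim <- make_sim_session(n_neurons = 2, n_trials = 30, seed = 70)
  sess <- sim$session
  ch <- vapply(sess$trials, `[[`, character(1), "choice")
  iR <- which(ch == "R"); iL <- which(ch == "L")
  pR <- compute_psth(sess, 1, iR)
  pL <- compute_psth(sess, 1, iL)
  pAll <- compute_psth(sess, 1, seq_along(ch))
  # weight by per-bin trial counts (trials end at different times)
  num <- ifelse(is.na(pR$rate), 0, pR$rate * pR$n_trials) +
    ifelse(is.na(pL$rate), 0, pL$rate * pL$n_trials)
  den <- pR$n_trials + pL$n_trials
  expect_equal(pAll$rate[den > 0], (num / den)[den > 0], tolerance = 1e-9)
})

test_that("condition-split R2 follows its definition", {
  oR <- c(1, 2, 3); oL <- c(3, 2, 1)
  expect_equal(psth_r2(oR, oL, oR, oL), 1)
  expect_equal(psth_r2(oR, oL, rep(mean(oR), 3), rep(mean(oL), 3)), 0)
  # hand-computed toy: SS_res = 0.02+0.08 = 0.1... worked by hand below
  pR <- c(1.1, 2, 3.2); pL <- c(2.8, 2, 1)
  ss_res <- (0.1)^2 + (0.2)^2 + (0.2)^2
  ss_tot <- 2 * (1 + 0 + 1)
  expect_equal(psth_r2(oR, oL, pR, pL), 1 - ss_res / ss_tot,
               tolerance = 1e-12)
  expect_lte(psth_r2(oR, oL, pR, pL), 1)
  expect_error(psth_r2(c(1, 1), c(2, 2), c(1, 1), c(2, 2)), "SS_tot")
})

test_that("choice selectivity normalizes at the peak difference", {
  r <- c(1, 3); l <- c(1, 1)
  cs <- choice_selectivity(r, l)
  expect_equal(cs$t_star, 2L)
  expect_equal(cs$c, c(0, 1))
  # constant difference: c(t) = 1 everywhere
  cs2 <- choice_selectivity(c(4, 5, 6), c(2, 3, 4))
  expect_true(all(cs2$c == 1))
  # |c(t*)| = 1 under sign flips too
  cs3 <- choice_selectivity(c(1, 0, 2), c(2, 0, 1))
  expect_equal(abs(cs3$c[cs3$t_star]), 1)
  expect_error(choice_selectivity(c(1, 2), c(1, 2)), "identical")
})

test_that("engagement index endpoints and grouping", {
  expect_equal(engagement_index(1, 0), 1)
  expect_equal(engagement_index(0, 1), -1)
  expect_equal(engagement_index(0.3, 0.3), 0)
  expect_equal(engagement_index(-2, 1), 1 / 3)
  expect_warning(ei0 <- engagement_index(0, 0), "undefined")
  expect_true(is.na(ei0))
  expect_equal(ei_group(c(0.5, -0.5, 0, 1 / 3, -1 / 3)),
               c("accumulation", "commitment", "similar", "accumulation",
                 "similar"))
})

test_that("PCTH aligns to nTc, groups by EI, and shuffles correctly", {
  set.seed(14)
  sim <- make_sim_session(n_neurons = 6, n_trials = 60, seed = 71)
  sess <- sim$session
  ntc <- session_ntc(sess, sim$params)
  expect_gt(sum(ntc$detected), 4)  # stated world gives ~1/3 detected
  ei <- engagement_index(sim$params$w_EA, sim$params$w_DC)
  p <- compute_pcth(sess, ntc, ei, lags = c(-0.2, 0.2))
  expect_s3_class(p, "pcth")
  expect_equal(p$n_trials_used, sum(ntc$detected))
  expect_true(all(unlist(lapply(p$by_group, `[[`, "pref")) >= 0,
                  na.rm = TRUE))
  # shuffle preserves the detected-trial count and draws every unclipped
  # value from the original multiset (values beyond a trial's end are
  # clipped to its last step by design)
  sh <- shuffle_ntc(ntc, sess, seed = 3)
  expect_equal(sum(sh$detected), sum(ntc$detected))
  ends <- vapply(which(sh$detected), function(i) {
    trial_n_steps(sess$trials[[i]], sess$dt)
  }, integer(1))
  shs <- sh$nTc_step[sh$detected]
  expect_true(all(shs <= ends))
  unclipped <- shs[shs < ends]
  expect_true(all(unclipped %in% ntc$nTc_step[ntc$detected]))
})

test_that("state-space trajectories reconstruct and order variance", {
  set.seed(15)
  X <- matrix(rnorm(200 * 5), 200, 5) %*% diag(c(3, 2, 1, 0.5, 0.1))
  st <- state_space_trajectories(X)
  Xc <- sweep(X, 2, colMeans(X))
  expect_lt(max(abs(st$u %*% diag(st$d) %*% t(st$axes) - Xc)), 1e-10)
  expect_true(all(diff(st$d) <= 1e-12))
  # mirror-symmetric conditions give mirror-symmetric leading projections
  A <- matrix(rnorm(100 * 6), 100, 6)
  Xs <- rbind(A, -A)
  sts <- state_space_trajectories(Xs)
  expect_equal(sts$proj[1:100, 1], -sts$proj[101:200, 1], tolerance = 1e-8)
  expect_error(state_space_trajectories(matrix(1, 5, 1)), "two neurons")
})
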