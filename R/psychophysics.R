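#' Behavioural validation statistics
#'
#' Psychometric curves, nTc-aligned psychophysical kernels with a lapse
#' parameter, the nTc shuffle control, and the commitment-behaviour
#' summaries.
#'
#' @name psychophysics
NULL

click_diffs <- function(session) {
  vapply(session$trials, function(tr) {
    # non-stereo clicks only: the stereoclick contributes to both sides
    sum(tr$clicks$right_times > 0) - sum(tr$clicks$left_times > 0)
  }, numeric(1))
}

#' Psychometric curve
#'
#' Trials are grouped into eight bins of similar size by the difference in
#' the total number of right and left clicks; each bin reports the fraction
#' of right choices with a Clopper-Pearson confidence interval.
#'
#' @param session An \code{\link{mmddm_session}}.
#' @param n_bins Number of bins (default 8).
#' @param conf Confidence level.
#' @return A data.frame with columns \code{bin}, \code{mean_diff},
#'   \code{n}, \code{frac_right}, \code{ci_lo}, \code{ci_hi}.
#' @export
psychometric_curve <- function(session, n_bins = 8L, conf = 0.95) {
  nt <- n_trials(session)
  if (nt < n_bins) stop("fewer trials than bins")
  d <- click_diffs(session)
  right <- vapply(session$trials, `[[`, character(1), "choice") == "R"
  # similar-size bins by quantile rank with tie-stable ordering
  ord <- order(d, stats::runif(nt))
  bin <- integer(nt)
  bin[ord] <- ceiling(seq_len(nt) / (nt / n_bins))
  bin <- pmin(bin, n_bins)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(bb) {
    idx <- which(bin == bb)
    k <- sum(right[idx]); n <- length(idx)
    ci <- stats::binom.test(k, n, conf.level = conf)$conf.int
    data.frame(bin = bb, mean_diff = mean(d[idx]), n = n,
               frac_right = k / n, ci_lo = ci[1], ci_hi = ci[2])
  }))
  out
}

# Negative log-likelihood of the lapse-logistic model:
# P(right) = lapse/2 + (1 - lapse) * plogis(X beta); lapse in [0, 0.5]
# via a scaled logit, fixed when lapse_free = FALSE.
lapse_logistic_nll <- function(par, X, yr, lapse_free, lapse_fixed, ridge) {
  if (lapse_free) {
    lam <- 0.5 * stats::plogis(par[1L])
    beta <- par[-1L]
  } else {
    lam <- lapse_fixed
    beta <- par
  }
  p <- lam / 2 + (1 - lam) * stats::plogis(drop(X %*% beta))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(yr * log(p) + (1 - yr) * log(1 - p)) + ridge * sum(beta^2) / 2
}

#' Time-resolved psychophysical kernel
#'
#' Logistic regression of the choice on per-lag signed click counts
#' (right minus left), extended with a symmetric lapse parameter:
#' P(right) = lapse/2 + (1 - lapse) logistic(beta0 + sum_k beta_k x_k).
#' In nTc-aligned mode only trials with the stimulus playing at least 0.2 s
#' before and at least 0.2 s after nTc qualify, and lags are measured from
#' the per-trial commitment time; in stimulus-aligned mode lags are measured
#' from the stimulus onset, optionally parametrized over a raised-cosine
#' temporal basis with the basis count chosen by cross-validation.
#'
#' @param session An \code{\link{mmddm_session}}.
#' @param ntc \code{\link{session_ntc}} output (nTc-aligned mode) or NULL.
#' @param mode "ntc" or "stimulus".
#' @param lag_range Lag window, seconds (relative to the alignment event).
#' @param lag_bin Lag bin width, seconds.
#' @param lapse "free" (fitted) or a fixed numeric value in [0, 0.5].
#' @param basis_counts Candidate numbers of raised-cosine basis functions
#'   for the stimulus-aligned kernel (NULL disables the basis).
#' @param n_boot Bootstrap resamples for the weight CIs (0 disables).
#' @param ridge Ridge penalty on the kernel weights; the default (0.5) also
#'   blocks the lapse-model degeneracy on near-deterministic choice data
#'   (huge weights with errors absorbed by the lapse floor).
#' @param seed Seed for bootstrap/CV.
#' @return A list of class \code{psychophysical_kernel}: \code{lag} (bin
#'   centres, s), \code{weight} (log-odds per click), \code{lapse},
#'   \code{intercept}, \code{ci_lo}, \code{ci_hi}, \code{n_trials},
#'   \code{mode}, \code{basis_count} (stimulus-aligned with basis only).
#' @export
psychophysical_kernel <- function(session, ntc = NULL, mode = c("ntc",
                                  "stimulus"), lag_range = NULL,
                                  lag_bin = 0.1, lapse = "free",
                                  basis_counts = NULL, n_boot = 0L,
                                  ridge = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  choices <- vapply(session$trials, `[[`, character(1), "choice")
  if (mode == "ntc") {
    if (is.null(ntc)) stop("nTc table required for nTc-aligned mode")
    # pre-nTc coverage must span most of the stimulus: the per-trial
    # generative rates confound post-nTc click counts with the committed
    # side, and only conditioning on the earlier evidence absorbs it
    if (is.null(lag_range)) lag_range <- c(-0.6, 0.2)
    dur <- vapply(session$trials, `[[`, numeric(1), "duration")
    qual <- which(ntc$detected & !is.na(ntc$nTc_s) &
                    ntc$nTc_s >= 0.2 & dur - ntc$nTc_s >= 0.2)
    if (!length(qual)) stop("no qualifying trials for the nTc-aligned kernel")
    align <- ntc$nTc_s[qual]
  } else {
    if (is.null(lag_range)) lag_range <- c(0, 0.5)
    qual <- seq_len(n_trials(session))
    align <- rep(0, length(qual))
  }
  edges <- seq(lag_range[1], lag_range[2], by = lag_bin)
  n_lags <- length(edges) - 1L
  Xl <- matrix(0, length(qual), n_lags)
  x_rest <- numeric(length(qual))
  for (k in seq_along(qual)) {
    tr <- session$trials[[qual[k]]]
    rt <- tr$clicks$right_times; rt <- rt[rt > 0] - align[k]
    lt <- tr$clicks$left_times; lt <- lt[lt > 0] - align[k]
    for (j in seq_len(n_lags)) {
      Xl[k, j] <- sum(rt >= edges[j] & rt < edges[j + 1L]) -
        sum(lt >= edges[j] & lt < edges[j + 1L])
    }
    x_rest[k] <- sum(rt < edges[1L]) - sum(lt < edges[1L])
  }
  yr <- as.numeric(choices[qual] == "R")

  lapse_free <- identical(lapse, "free")
  lapse_fixed <- if (lapse_free) NA_real_ else as.numeric(lapse)

  basis_count <- NA_integer_
  Bmat <- NULL
  if (mode == "stimulus" && !is.null(basis_counts)) {
    centres_t <- (edges[-1L] + edges[-length(edges)]) / 2
    cv_ll <- vapply(basis_counts, function(nb) {
      Bm <- raised_cosine_basis(centres_t, nb)
      kernel_cv_loglik(Xl %*% Bm, yr, lapse_free, lapse_fixed, ridge, seed)
    }, numeric(1))
    basis_count <- basis_counts[which.max(cv_ll)]
    Bmat <- raised_cosine_basis((edges[-1L] + edges[-length(edges)]) / 2,
                                basis_count)
  }
  # in nTc-aligned mode all evidence earlier than the covered lags enters
  # as one catch-all regressor: without it, the trial's generative rates
  # confound the post-commitment bins with the committed side
  Xeff <- if (is.null(Bmat)) Xl else Xl %*% Bmat
  X <- if (mode == "ntc") cbind(1, x_rest, Xeff) else cbind(1, Xeff)
  n_head <- if (mode == "ntc") 2L else 1L

  fit_once <- function(X, yr) {
    p0 <- c(if (lapse_free) stats::qlogis(0.1), rep(0, ncol(X)))
    stats::optim(p0, lapse_logistic_nll, X = X, yr = yr,
                 lapse_free = lapse_free, lapse_fixed = lapse_fixed,
                 ridge = ridge, method = "BFGS",
                 control = list(maxit = 500))$par
  }
  lag_weights <- function(beta) {
    bb <- beta[-seq_len(n_head)]
    if (is.null(Bmat)) bb else drop(Bmat %*% bb)
  }
  par <- fit_once(X, yr)
  lam <- if (lapse_free) 0.5 * stats::plogis(par[1L]) else lapse_fixed
  beta <- if (lapse_free) par[-1L] else par
  w <- lag_weights(beta)

  ci_lo <- ci_hi <- rep(NA_real_, n_lags)
  boot <- NULL
  if (n_boot > 0L) {
    set.seed(seed)
    boot <- replicate(n_boot, {
      pick <- sample.int(length(yr), replace = TRUE)
      pb <- fit_once(X[pick, , drop = FALSE], yr[pick])
      lag_weights(if (lapse_free) pb[-1L] else pb)
    })
    ci_lo <- apply(boot, 1L, stats::quantile, 0.025)
    ci_hi <- apply(boot, 1L, stats::quantile, 0.975)
  }
  structure(list(lag = (edges[-1L] + edges[-length(edges)]) / 2,
                 weight = w, lapse = lam, intercept = beta[1L],
                 earlier_evidence_weight = if (mode == "ntc") beta[2L] else
                   NA_real_,
                 ci_lo = ci_lo, ci_hi = ci_hi, boot = boot,
                 n_trials = length(qual),
                 mode = mode, basis_count = basis_count),
            class = "psychophysical_kernel")
}

# Raised-cosine temporal basis over the lag grid (columns sum over bumps).
raised_cosine_basis <- function(x, n) {
  lo <- min(x); hi <- max(x)
  centres <- seq(lo, hi, length.out = n)
  width <- if (n > 1L) 2 * diff(centres)[1] else (hi - lo) + 1e-9
  sapply(seq_len(n), function(j) {
    u <- (x - centres[j]) * pi / width
    ifelse(abs(u) < pi / 2, cos(u)^2, 0)
  })
}

# 5-fold CV log-likelihood of the lapse-logistic kernel for basis selection.
kernel_cv_loglik <- function(Xeff, yr, lapse_free, lapse_fixed, ridge,
                             seed) {
  set.seed(seed)
  n <- length(yr)
  folds <- sample(rep(1:5, length.out = n))
  ll <- 0
  for (f in 1:5) {
    tr <- folds != f
    X <- cbind(1, Xeff)
    p0 <- c(if (lapse_free) stats::qlogis(0.1), rep(0, ncol(X)))
    par <- stats::optim(p0, lapse_logistic_nll, X = X[tr, , drop = FALSE],
                        yr = yr[tr], lapse_free = lapse_free,
                        lapse_fixed = lapse_fixed, ridge = ridge,
                        method = "BFGS", control = list(maxit = 300))$par
    lam <- if (lapse_free) 0.5 * stats::plogis(par[1L]) else lapse_fixed
    beta <- if (lapse_free) par[-1L] else par
    p <- lam / 2 + (1 - lam) *
      stats::plogis(drop(X[!tr, , drop = FALSE] %*% beta))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    ll <- ll + sum(yr[!tr] * log(p) + (1 - yr[!tr]) * log(1 - p))
  }
  ll
}

#' Shuffle an nTc table across detected trials
#'
#' Permutes the inferred commitment times among the detected trials only
#' (choices and click times untouched), the control used to show that the
#' post-commitment drop in psychophysical weight is tied to the per-trial
#' alignment.
#'
#' @param ntc \code{\link{session_ntc}} output.
#' @param session The matching session (commitment times reassigned beyond a
#'   trial's stimulus end are clipped to it).
#' @param seed Permutation seed.
#' @return A permuted copy of the nTc table.
#' @export
shuffle_ntc <- function(ntc, session, seed = 1L) {
  set.seed(seed)
  det <- which(ntc$detected)
  perm <- sample(det)
  out <- ntc
  out$nTc_step[det] <- ntc$nTc_step[perm]
  out$nTc_s[det] <- ntc$nTc_s[perm]
  out$side[det] <- ntc$side[perm]
  out$max_bound_prob[det] <- ntc$max_bound_prob[perm]
  # clip beyond trial end to the last step
  for (i in det) {
    Tn <- trial_n_steps(session$trials[[i]], session$dt)
    if (!is.na(out$nTc_step[i]) && out$nTc_step[i] > Tn) {
      out$nTc_step[i] <- Tn
      out$nTc_s[i] <- (Tn - 0.5) * session$dt
    }
  }
  out
}

#' Commitment-behaviour summaries
#'
#' (i) Behavioural accuracy split by whether nTc was detected, overall and
#' per evidence-strength bin; (ii) per evidence-strength bin, the fraction
#' of trials with a detected nTc divided by the overall detection fraction.
#' Pass a model-simulated session plus its nTc table to obtain the model
#' prediction curves computed by the identical procedure.
#'
#' @param session An \code{\link{mmddm_session}}.
#' @param ntc \code{\link{session_ntc}} output for that session.
#' @param n_bins Number of evidence-strength bins (|rate difference| or
#'   |click difference| quantile bins).
#' @return A list of class \code{commitment_summary}: \code{accuracy}
#'   (data.frame by detection status), \code{detection_ratio} (data.frame
#'   by evidence bin; bins with zero trials reported as NA rows),
#'   \code{overall_detection}.
#' @export
commitment_behaviour_summary <- function(session, ntc, n_bins = 4L) {
  nt <- n_trials(session)
  choices <- vapply(session$trials, `[[`, character(1), "choice")
  rewarded <- vapply(session$trials, function(tr) {
    if (!is.null(tr$rate_right)) {
      if (tr$rate_right >= tr$rate_left) "R" else "L"
    } else NA_character_
  }, character(1))
  if (all(is.na(rewarded))) {
    d <- click_diffs(session)
    rewarded <- ifelse(d >= 0, "R", "L")
  }
  correct <- choices == rewarded
  det <- ntc$detected
  strength <- abs(click_diffs(session))
  qs <- stats::quantile(strength, probs = seq(0, 1, length.out = n_bins + 1L))
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  bin <- cut(strength, qs, labels = FALSE)

  accuracy <- do.call(rbind, lapply(c(TRUE, FALSE), function(flag) {
    idx <- which(det == flag)
    data.frame(detected = flag, n = length(idx),
               accuracy = if (length(idx)) mean(correct[idx]) else NA_real_)
  }))
  overall <- mean(det)
  detection_ratio <- do.call(rbind, lapply(seq_len(n_bins), function(bb) {
    idx <- which(bin == bb)
    if (!length(idx)) {
      return(data.frame(bin = bb, mean_strength = NA_real_, n = 0L,
                        detection_frac = NA_real_, ratio = NA_real_))
    }
    f <- mean(det[idx])
    data.frame(bin = bb, mean_strength = mean(strength[idx]),
               n = length(idx), detection_frac = f,
               ratio = if (overall > 0) f / overall else NA_real_)
  }))
  accuracy_by_bin <- do.call(rbind, lapply(seq_len(n_bins), function(bb) {
    do.call(rbind, lapply(c(TRUE, FALSE), function(flag) {
      idx <- which(bin == bb & det == flag)
      data.frame(bin = bb, detected = flag, n = length(idx),
                 accuracy = if (length(idx)) mean(correct[idx]) else
                   NA_real_)
    }))
  }))
  structure(list(accuracy = accuracy, accuracy_by_bin = accuracy_by_bin,
                 detection_ratio = detection_ratio,
                 overall_detection = overall),
            class = "commitment_summary")
}
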