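#' Neural summary statistics
#'
#' Neuron selection by choice-selectivity auROC, peri-stimulus and
#' peri-commitment time histograms, choice selectivity series, engagement
#' indices and trial-averaged state-space trajectories.
#'
#' @name analyses
NULL

#' Area under the ROC curve for two count samples
#'
#' Ideal-observer discrimination of right- from left-choice trials based on
#' spike counts; equals the Mann-Whitney U statistic normalized by n1 * n2
#' (ties counted half). Invariant to strictly monotone transforms of the
#' counts.
#'
#' @param x Counts on right-choice trials.
#' @param y Counts on left-choice trials.
#' @return auROC in [0, 1], or NA if either sample is empty.
#' @export
auroc <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  r <- rank(c(x, y))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Select choice-selective neurons
#'
#' Spikes are counted in four non-overlapping windows after stimulus onset
#' (0.01-0.21, 0.21-0.40, 0.41-0.60, 0.61-0.90 s, clipped to each trial's
#' window); a neuron is included if any window's auROC is < 0.42 or > 0.58
#' and its average firing rate is at least 2 spikes/s. Neurons whose auROC
#' is undefined (all trials one choice) are excluded and flagged.
#'
#' @param session An \code{\link{mmddm_session}}.
#' @param lo,hi auROC exclusion band (default 0.42 / 0.58).
#' @param min_rate Minimum average firing rate, spikes/s.
#' @return A list: \code{included} (neuron indices), \code{table}
#'   (per-neuron auROC by window, mean rate, inclusion flag).
#' @export
select_neurons <- function(session, lo = 0.42, hi = 0.58, min_rate = 2) {
  windows <- rbind(c(0.01, 0.21), c(0.21, 0.40), c(0.41, 0.60),
                   c(0.61, 0.90))
  nt <- n_trials(session)
  N <- n_neurons(session)
  choices <- vapply(session$trials, `[[`, character(1), "choice")
  ends <- vapply(session$trials, function(tr) {
    trial_n_steps(tr, session$dt) * session$dt
  }, numeric(1))
  tab <- data.frame(neuron = seq_len(N), mean_rate = NA_real_,
                    auroc1 = NA_real_, auroc2 = NA_real_, auroc3 = NA_real_,
                    auroc4 = NA_real_, included = FALSE,
                    flagged = FALSE)
  for (n in seq_len(N)) {
    tot <- 0; tottime <- 0
    aucs <- rep(NA_real_, 4L)
    for (w in 1:4) {
      cnt <- vapply(seq_len(nt), function(i) {
        st <- session$spikes[[n]][[i]]
        sum(st >= windows[w, 1] & st < min(windows[w, 2], ends[i]))
      }, numeric(1))
      valid <- ends > windows[w, 1]
      if (any(valid & choices == "R") && any(valid & choices == "L")) {
        aucs[w] <- auroc(cnt[valid & choices == "R"],
                         cnt[valid & choices == "L"])
      }
    }
    for (i in seq_len(nt)) {
      st <- session$spikes[[n]][[i]]
      tot <- tot + sum(st >= 0 & st < ends[i])
      tottime <- tottime + ends[i]
    }
    rate <- tot / tottime
    tab$mean_rate[n] <- rate
    tab[n, paste0("auroc", 1:4)] <- aucs
    if (all(is.na(aucs))) {
      tab$flagged[n] <- TRUE          # auROC undefined: excluded
    } else {
      sel <- any(aucs < lo | aucs > hi, na.rm = TRUE)
      tab$included[n] <- sel && rate >= min_rate
    }
  }
  list(included = which(tab$included), table = tab)
}

# Causal Gaussian kernel over lags [0, width], sd sigma, unit sum.
causal_gaussian_kernel <- function(sigma, width, dt) {
  lags <- seq(0, width, by = dt)
  k <- exp(-0.5 * (lags / sigma)^2)
  k / sum(k)
}

# Convolve a count vector with a causal kernel: rate at t uses counts at
# t, t - dt, ..., t - width.
causal_filter <- function(x, kernel) {
  n <- length(x)
  out <- numeric(n)
  for (j in seq_len(min(length(kernel), n))) {
    idx <- seq_len(n - j + 1L)
    out[idx + j - 1L] <- out[idx + j - 1L] + kernel[j] * x[idx]
  }
  out
}

#' Peri-stimulus time histogram
#'
#' Spikes are binned at 0.01 s from stimulus onset up to 1 s (or trial end),
#' each trial's train is convolved with a causal Gaussian kernel (sd 0.1 s,
#' width 0.3 s, unit sum) and the filtered rates are averaged across trials;
#' bins beyond a trial's window do not contribute to that trial's average.
#'
#' @param session An \code{\link{mmddm_session}}.
#' @param neuron Neuron index.
#' @param trial_idx Trials to average over (a condition).
#' @param normalize Divide by the neuron's grand-mean rate over all trials.
#' @param sigma,width Kernel parameters, seconds.
#' @param n_boot Bootstrap resamples for the CI (0 to skip).
#' @return A list of class \code{psth}: \code{time} (bin centres, s),
#'   \code{rate} (spikes/s, or unitless if normalized), \code{n_trials} (per
#'   bin), \code{ci_lo}, \code{ci_hi}.
#' @export
compute_psth <- function(session, neuron, trial_idx, normalize = FALSE,
                         sigma = 0.1, width = 0.3, n_boot = 0L) {
  if (!length(trial_idx)) stop("empty condition: no trials")
  dt <- session$dt
  n_bins <- round(1 / dt)
  kern <- causal_gaussian_kernel(sigma, width, dt)
  rates <- matrix(NA_real_, length(trial_idx), n_bins)
  for (k in seq_along(trial_idx)) {
    i <- trial_idx[k]
    Tn <- min(trial_n_steps(session$trials[[i]], dt), n_bins)
    st <- session$spikes[[neuron]][[i]]
    st <- st[st >= 0 & st < Tn * dt]
    cnt <- tabulate(floor(st / dt) + 1L, Tn)
    rates[k, seq_len(Tn)] <- causal_filter(cnt, kern) / dt
  }
  avg <- colMeans(rates, na.rm = TRUE)
  nn <- colSums(!is.na(rates))
  avg[nn == 0L] <- NA_real_
  if (normalize) {
    gm <- mean(rates, na.rm = TRUE)
    if (gm > 0) avg <- avg / gm
  }
  ci_lo <- ci_hi <- rep(NA_real_, n_bins)
  if (n_boot > 0L && length(trial_idx) > 1L) {
    bs <- replicate(n_boot, {
      pick <- sample.int(nrow(rates), replace = TRUE)
      colMeans(rates[pick, , drop = FALSE], na.rm = TRUE)
    })
    ci_lo <- apply(bs, 1L, stats::quantile, 0.025, na.rm = TRUE)
    ci_hi <- apply(bs, 1L, stats::quantile, 0.975, na.rm = TRUE)
  }
  structure(list(time = (seq_len(n_bins) - 0.5) * dt, rate = avg,
                 n_trials = nn, ci_lo = ci_lo, ci_hi = ci_hi,
                 normalize = normalize), class = "psth")
}

#' Goodness of fit of condition-split PSTH predictions
#'
#' R^2 = 1 - SS_res / SS_tot over the right- and left-condition PSTHs
#' jointly, where SS_tot sums squared deviations of each observed PSTH from
#' its own temporal mean.
#'
#' @param obs_R,obs_L Observed PSTH rate vectors (matching grids).
#' @param pred_R,pred_L Predicted PSTH rate vectors.
#' @return Scalar R^2 (<= 1; 1 iff residuals vanish).
#' @export
psth_r2 <- function(obs_R, obs_L, pred_R, pred_L) {
  keep <- stats::complete.cases(obs_R, obs_L, pred_R, pred_L)
  oR <- obs_R[keep]; oL <- obs_L[keep]
  pR <- pred_R[keep]; pL <- pred_L[keep]
  ss_res <- sum((oR - pR)^2 + (oL - pL)^2)
  ss_tot <- sum((oR - mean(oR))^2 + (oL - mean(oL))^2)
  if (ss_tot == 0) stop("SS_tot is zero: constant observed PSTHs")
  1 - ss_res / ss_tot
}

#' Choice-selectivity series
#'
#' c(t) = (r(t) - l(t)) / (r(t*) - l(t*)), where r and l are the right- and
#' left-choice PSTHs and t* is the time of the maximum absolute difference;
#' |c(t*)| = 1 by construction. Also returns the centre of mass of |c(t)|
#' (used for sorting neurons).
#'
#' @param psth_R,psth_L Rate vectors on matching grids.
#' @param time Optional time grid for the centre of mass (default bin
#'   index).
#' @return A list of class \code{selectivity_series}: \code{c} (series),
#'   \code{t_star} (index), \code{com} (centre of mass of |c|).
#' @export
choice_selectivity <- function(psth_R, psth_L, time = NULL) {
  keep <- !is.na(psth_R) & !is.na(psth_L)
  d <- psth_R - psth_L
  d_ok <- d[keep]
  if (!length(d_ok) || all(d_ok == 0)) {
    stop("right and left PSTHs are identical: selectivity undefined")
  }
  idx_ok <- which(keep)
  t_star <- idx_ok[which.max(abs(d_ok))]
  cc <- d / d[t_star]
  if (is.null(time)) time <- seq_along(psth_R)
  com <- sum(time[keep] * abs(cc[keep])) / sum(abs(cc[keep]))
  structure(list(c = cc, t_star = t_star, com = com),
            class = "selectivity_series")
}

#' Engagement index
#'
#' EI = (|w_EA| - |w_DC|) / (|w_EA| + |w_DC|): 1 means the neuron encodes
#' the latent only during evidence accumulation, -1 only during decision
#' commitment, 0 a similar strength in both regimes.
#'
#' @param w_EA,w_DC Encoding weights (vectors allowed).
#' @return EI in [-1, 1]; NA with a warning where both weights are zero.
#' @export
engagement_index <- function(w_EA, w_DC) {
  denom <- abs(w_EA) + abs(w_DC)
  out <- (abs(w_EA) - abs(w_DC)) / denom
  if (any(denom == 0)) {
    warning("engagement index undefined for neurons with both weights zero")
    out[denom == 0] <- NA_real_
  }
  out
}

#' Group label from an engagement index
#'
#' EI >= 1/3: "accumulation"; EI < -1/3: "commitment"; otherwise "similar".
#'
#' @param ei Engagement-index vector.
#' @return Character vector of group labels (NA preserved).
#' @export
ei_group <- function(ei) {
  out <- rep(NA_character_, length(ei))
  out[!is.na(ei) & ei >= 1 / 3] <- "accumulation"
  out[!is.na(ei) & ei < -1 / 3] <- "commitment"
  out[!is.na(ei) & ei >= -1 / 3 & ei < 1 / 3] <- "similar"
  out
}

#' Peri-commitment time histograms
#'
#' Spike trains of trials with a detected nTc are aligned to the per-trial
#' commitment time, averaged across those trials, and filtered with a causal
#' Gaussian kernel (sd 0.05 s). Neurons are grouped by engagement index and
#' split by preferred vs null choice (the choice eliciting higher firing).
#' The shuffle control permutes the nTc values among detected trials only,
#' clipping any reassigned time beyond a trial's end to the last step.
#'
#' @param session An \code{\link{mmddm_session}}.
#' @param ntc Output of \code{\link{session_ntc}}.
#' @param ei Per-neuron engagement indices.
#' @param lags Lag range around nTc, seconds (default -0.5..0.5).
#' @param shuffle Permute nTc among detected trials (control).
#' @param seed Seed for the shuffle.
#' @param sigma Kernel sd, seconds.
#' @return A list of class \code{pcth}: \code{lag} (s), \code{by_group}
#'   (per EI group: mean preferred, null and difference rates across
#'   neurons), \code{by_neuron} (neuron x lag matrices \code{pref},
#'   \code{null}), \code{n_trials_used}.
#' @export
compute_pcth <- function(session, ntc, ei, lags = c(-0.5, 0.5),
                         shuffle = FALSE, seed = 1L, sigma = 0.05) {
  dt <- session$dt
  det <- which(ntc$detected)
  if (!length(det)) stop("no trials with detected nTc")
  steps <- ntc$nTc_step[det]
  if (shuffle) {
    set.seed(seed)
    steps <- sample(steps)
    ends <- vapply(det, function(i) {
      trial_n_steps(session$trials[[i]], dt)
    }, integer(1))
    steps <- pmin(steps, ends)   # clip beyond trial end to the last step
  }
  lag_steps <- seq(round(lags[1] / dt), round(lags[2] / dt))
  L <- length(lag_steps)
  kern <- causal_gaussian_kernel(sigma, 3 * sigma, dt)
  N <- n_neurons(session)
  choices <- vapply(session$trials, `[[`, character(1), "choice")

  align_counts <- function(n, trial, step0) {
    Tn <- trial_n_steps(session$trials[[trial]], dt)
    st <- session$spikes[[n]][[trial]]
    st <- st[st >= 0 & st < Tn * dt]
    cnt <- tabulate(floor(st / dt) + 1L, Tn)
    idx <- step0 + lag_steps
    ok <- idx >= 1L & idx <= Tn
    out <- rep(NA_real_, L)
    out[ok] <- cnt[idx[ok]]
    out
  }

  pref_mat <- matrix(NA_real_, N, L)
  null_mat <- matrix(NA_real_, N, L)
  for (n in seq_len(N)) {
    tot <- vapply(c("R", "L"), function(ch) {
      tr <- det[choices[det] == ch]
      if (!length(tr)) return(0)
      mean(vapply(tr, function(i) length(session$spikes[[n]][[i]]),
                  numeric(1)))
    }, numeric(1))
    pref_choice <- if (tot["R"] >= tot["L"]) "R" else "L"
    for (ch in c("R", "L")) {
      rows <- which(choices[det] == ch)
      if (!length(rows)) next
      acc <- matrix(NA_real_, length(rows), L)
      for (k in seq_along(rows)) {
        acc[k, ] <- align_counts(n, det[rows[k]], steps[rows[k]])
      }
      avg <- colMeans(acc, na.rm = TRUE)
      avg[colSums(!is.na(acc)) == 0L] <- NA_real_
      filt <- avg
      okk <- !is.na(avg)
      if (any(okk)) {
        tmp <- avg; tmp[!okk] <- 0
        filt <- causal_filter(tmp, kern) / dt
        filt[!okk] <- NA_real_
      }
      if (ch == pref_choice) pref_mat[n, ] <- filt else null_mat[n, ] <- filt
    }
  }

  groups <- ei_group(ei)
  by_group <- list()
  for (g in c("accumulation", "similar", "commitment")) {
    rows <- which(!is.na(groups) & groups == g)
    if (!length(rows)) next                      # empty group: skipped
    by_group[[g]] <- list(
      pref = colMeans(pref_mat[rows, , drop = FALSE], na.rm = TRUE),
      null = colMeans(null_mat[rows, , drop = FALSE], na.rm = TRUE),
      diff = colMeans(pref_mat[rows, , drop = FALSE] -
                        null_mat[rows, , drop = FALSE], na.rm = TRUE),
      n_neurons = length(rows))
  }
  structure(list(lag = lag_steps * dt, by_group = by_group,
                 by_neuron = list(pref = pref_mat, null = null_mat),
                 n_trials_used = length(det), shuffled = shuffle),
            class = "pcth")
}

#' Trial-averaged trajectories in neural state space
#'
#' Stacks condition PSTHs into a (time x condition) x neuron matrix,
#' subtracts the grand row-mean vector (column centring) and takes the
#' singular value decomposition; the trajectories are the first two columns
#' of U S and the principal axes the columns of V.
#'
#' @param X Matrix with T*C rows (conditions stacked in time blocks) and N
#'   neurons as columns.
#' @return A list of class \code{state_space_traj}: \code{proj} (rows of X
#'   projected onto the first two axes), \code{axes} (V), \code{d} (singular
#'   values), \code{center} (subtracted mean vector).
#' @export
state_space_trajectories <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least two neurons")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sv <- svd(Xc)
  proj <- sv$u %*% diag(sv$d)
  structure(list(proj = proj[, 1:2, drop = FALSE], axes = sv$v,
                 d = sv$d, center = ctr, u = sv$u),
            class = "state_space_traj")
}
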