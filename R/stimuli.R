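#' Task-stimulus generation for the pulsatile click task
#'
#' Trials present two simultaneous Poisson click trains, one per speaker, with
#' a combined generative rate fixed at 40 clicks/s. Difficulty is set by the
#' ratio of the two rates. Every train starts with a click played from both
#' speakers at once (the "stereoclick") that marks stimulus onset.
#'
#' @name stimuli
NULL

#' Default generative click-rate ratios
#'
#' Eight difficulty levels spanning the easiest (39:1) to the hardest (26:14)
#' ratio, all summing to the fixed combined rate of 40 clicks/s.
#'
#' @return A two-column matrix with columns \code{hi} and \code{lo} (clicks/s).
#' @export
default_rate_ratios <- function() {
  cbind(hi = c(39, 38, 36, 34, 32, 30, 28, 26),
        lo = c(1, 2, 4, 6, 8, 10, 12, 14))
}

#' Configuration for the trial-condition generator
#'
#' @param ratios Two-column matrix of generative rates (clicks/s); each row is
#'   one difficulty level \code{(hi, lo)}. Rows must sum to a common combined
#'   rate.
#' @param duration_range Stimulus duration range in seconds; durations are
#'   drawn uniformly from this interval.
#' @return A list of class \code{trial_config}.
#' @export
trial_config <- function(ratios = default_rate_ratios(),
                         duration_range = c(0.2, 1.0)) {
  ratios <- as.matrix(ratios)
  if (nrow(ratios) == 0L) stop("ratio list must not be empty")
  if (any(ratios < 0)) stop("generative rates must be non-negative")
  if (length(duration_range) != 2L || any(duration_range <= 0) ||
      diff(duration_range) < 0) {
    stop("duration_range must be a positive, non-decreasing pair of seconds")
  }
  structure(list(ratios = ratios, duration_range = duration_range),
            class = "trial_config")
}

#' Sample trial conditions
#'
#' Each condition is drawn uniformly over difficulty levels and sides; the
#' rewarded side is the side with the greater generative rate. Duration is
#' uniform over the configured range.
#'
#' @param n_trials Number of trials (>= 1).
#' @param config A \code{\link{trial_config}}.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A data.frame with columns \code{rate_left}, \code{rate_right},
#'   \code{duration}, \code{rewarded_side} ("L"/"R").
#' @export
sample_trial_conditions <- function(n_trials, config = trial_config(),
                                    seed = NULL) {
  if (!inherits(config, "trial_config")) config <- do.call(trial_config, config)
  if (n_trials < 1L) stop("n_trials must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  lev <- sample.int(nrow(config$ratios), n_trials, replace = TRUE)
  right_is_hi <- sample(c(TRUE, FALSE), n_trials, replace = TRUE)
  hi <- config$ratios[lev, "hi"]
  lo <- config$ratios[lev, "lo"]
  data.frame(
    rate_left = ifelse(right_is_hi, lo, hi),
    rate_right = ifelse(right_is_hi, hi, lo),
    duration = stats::runif(n_trials, config$duration_range[1],
                            config$duration_range[2]),
    rewarded_side = ifelse(right_is_hi, "R", "L"),
    stringsAsFactors = FALSE
  )
}

#' Generate the click train of one trial
#'
#' Left and right click times are independent homogeneous Poisson samples at
#' the generative rates over \code{[0, duration)}; the stereoclick at t = 0 is
#' present on both sides.
#'
#' @param condition One row of the output of
#'   \code{\link{sample_trial_conditions}} (or any list with fields
#'   \code{rate_left}, \code{rate_right}, \code{duration}).
#' @param seed Optional integer seed.
#' @return A list of class \code{click_train} with fields \code{left_times},
#'   \code{right_times} (sorted, seconds, including the stereoclick at 0),
#'   \code{stereoclick_time} (0) and \code{duration}.
#' @export
generate_click_trains <- function(condition, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dur <- condition$duration
  if (is.null(dur) || dur <= 0) stop("condition must have a positive duration")
  sample_side <- function(rate) {
    n <- stats::rpois(1L, rate * dur)
    # strictly after the stereoclick, strictly before stimulus offset
    sort(stats::runif(n, min = .Machine$double.eps, max = dur * (1 - 1e-12)))
  }
  structure(list(
    left_times = c(0, sample_side(condition$rate_left)),
    right_times = c(0, sample_side(condition$rate_right)),
    stereoclick_time = 0,
    duration = dur
  ), class = "click_train")
}

#' Sensory-adaptation parameters
#'
#' Each click's input magnitude is multiplicatively depressed by preceding
#' clicks: an adaptation state a starts at 1, each click is delivered with
#' magnitude C = a and then depresses the state, a <- a * phi; between clicks
#' the state recovers towards 1 as da/dt = (1 - a)/tau_phi. Clicks played
#' simultaneously from both speakers (the stereoclick) share the same
#' pre-update state and depress it once for the pair. phi = 1 disables
#' adaptation.
#'
#' @param phi Depression factor in (0, 1].
#' @param tau_phi Recovery time constant, seconds, > 0.
#' @param include_stereoclick Keep the stereoclick in the adapted output
#'   (it still always participates in the adaptation bookkeeping).
#' @return A list of class \code{adaptation_params}.
#' @export
adaptation_params <- function(phi = 0.6, tau_phi = 0.2,
                              include_stereoclick = TRUE) {
  if (phi <= 0 || phi > 1) stop("phi must lie in (0, 1]")
  if (tau_phi <= 0) stop("tau_phi must be positive")
  structure(list(phi = phi, tau_phi = tau_phi,
                 include_stereoclick = include_stereoclick),
            class = "adaptation_params")
}

#' Compute per-click adaptation magnitudes
#'
#' Merges both sides into one stream ordered by time and runs the
#' depression/recovery recursion of \code{\link{adaptation_params}}.
#'
#' @param train A \code{\link{generate_click_trains}} output.
#' @param params An \code{\link{adaptation_params}} object.
#' @return A data.frame of class \code{adapted_clicks} with columns
#'   \code{time} (s), \code{side} ("L"/"R") and \code{magnitude} (in (0, 1]),
#'   in the merged time order.
#' @export
adapt_clicks <- function(train, params = adaptation_params()) {
  lt <- train$left_times
  rt <- train$right_times
  if (is.unsorted(lt) || is.unsorted(rt)) stop("click times must be sorted")
  times <- c(lt, rt)
  side <- rep(c("L", "R"), c(length(lt), length(rt)))
  ord <- order(times)
  times <- times[ord]
  side <- side[ord]
  n <- length(times)
  mag <- numeric(n)
  a <- 1
  i <- 1L
  while (i <= n) {
    # group clicks sharing the same time (the stereoclick pair): same
    # pre-update state, one depression for the group
    j <- i
    while (j < n && times[j + 1L] == times[i]) j <- j + 1L
    mag[i:j] <- a
    a <- a * params$phi
    if (j < n) {
      gap <- times[j + 1L] - times[j]
      a <- 1 - (1 - a) * exp(-gap / params$tau_phi)
    }
    i <- j + 1L
  }
  out <- data.frame(time = times, side = side, magnitude = mag,
                    stringsAsFactors = FALSE)
  if (!params$include_stereoclick) {
    out <- out[out$time != train$stereoclick_time, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("adapted_clicks", "data.frame")
  out
}
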