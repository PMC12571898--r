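#' Session container
#'
#' A session bundles the aligned behavioural and neural data consumed by the
#' fitting and analysis routines: per-trial click trains, choices,
#' movement-onset times and trial start times, and per-neuron spike times per
#' trial (seconds, trial clock 0 at stimulus onset). Simulated sessions carry
#' an optional ground-truth block.
#'
#' @param session_id Character identifier.
#' @param trials List, one element per trial, each a list with fields
#'   \code{clicks} (a \code{\link{generate_click_trains}} object),
#'   \code{choice} ("L"/"R"), \code{movement_onset} (s from stimulus onset),
#'   \code{start_time} (s from session start) and \code{duration} (s).
#' @param spikes List over neurons; each element a list over trials of
#'   numeric spike-time vectors (s from stimulus onset).
#' @param neuron_ids Character vector of neuron identifiers.
#' @param ground_truth Optional list (simulator provenance): per-trial latent
#'   paths, true commitment steps and sides, and the generative parameters.
#' @param dt Time step used for binning, seconds.
#' @return An object of class \code{mmddm_session}.
#' @export
mmddm_session <- function(session_id, trials, spikes,
                          neuron_ids = NULL, ground_truth = NULL,
                          dt = 0.01) {
  n_neurons <- length(spikes)
  if (is.null(neuron_ids)) {
    neuron_ids <- sprintf("n%03d", seq_len(n_neurons))
  }
  s <- structure(list(
    schema_version = "1.0",
    session_id = session_id,
    trials = trials,
    spikes = spikes,
    neuron_ids = neuron_ids,
    ground_truth = ground_truth,
    dt = dt
  ), class = "mmddm_session")
  validate_session(s)
  s
}

#' @export
print.mmddm_session <- function(x, ...) {
  cat(sprintf("<mmddm_session> %s: %d trials, %d neurons\n",
              x$session_id, length(x$trials), length(x$spikes)))
  invisible(x)
}

#' Number of trials / neurons in a session
#' @param session An \code{mmddm_session}.
#' @return Integer count.
#' @export
n_trials <- function(session) length(session$trials)

#' @rdname n_trials
#' @export
n_neurons <- function(session) length(session$spikes)

#' Validate session invariants
#'
#' Checks mandatory fields, monotone trial start times, sorted spike times
#' and in-range click times; stops with a typed error naming the offending
#' field.
#'
#' @param session Candidate session object.
#' @return The session, invisibly, if valid.
#' @export
validate_session <- function(session) {
  fail <- function(field, msg) {
    stop(structure(class = c("mmddm_validation_error", "error", "condition"),
                   list(message = sprintf("invalid session field '%s': %s",
                                          field, msg),
                        call = sys.call(-1))))
  }
  for (f in c("session_id", "trials", "spikes", "dt")) {
    if (is.null(session[[f]])) fail(f, "missing")
  }
  nt <- length(session$trials)
  if (nt == 0L) fail("trials", "no trials")
  for (i in seq_len(nt)) {
    tr <- session$trials[[i]]
    for (f in c("clicks", "choice", "movement_onset", "start_time",
                "duration")) {
      if (is.null(tr[[f]])) fail(f, sprintf("missing in trial %d", i))
    }
    if (!tr$choice %in% c("L", "R")) fail("choice", sprintf("trial %d", i))
    ck <- tr$clicks
    if (any(ck$left_times < 0) || any(ck$right_times < 0) ||
        any(ck$left_times >= ck$duration + 1e-9 & ck$left_times > 0) ||
        any(ck$right_times >= ck$duration + 1e-9 & ck$right_times > 0)) {
      fail("clicks", sprintf("click time outside [0, duration) in trial %d", i))
    }
  }
  starts <- vapply(session$trials, `[[`, numeric(1), "start_time")
  if (nt > 1L && any(diff(starts) <= 0)) {
    fail("start_time", "trial start times must be strictly increasing")
  }
  for (n in seq_along(session$spikes)) {
    if (length(session$spikes[[n]]) != nt) {
      fail("spikes", sprintf("neuron %d has %d trials, expected %d",
                             n, length(session$spikes[[n]]), nt))
    }
    for (i in seq_len(nt)) {
      st <- session$spikes[[n]][[i]]
      if (length(st) && is.unsorted(st)) {
        fail("spikes", sprintf("non-monotone spike times, neuron %d trial %d",
                               n, i))
      }
    }
  }
  invisible(session)
}

#' Trial emission window in steps
#'
#' The spike-train window runs from stimulus onset to the earlier of 1 s or
#' the moment the animal leaves the fixation port, binned at dt.
#'
#' @param trial One element of \code{session$trials}.
#' @param dt Step size, seconds.
#' @return Number of steps (>= 1).
#' @export
trial_n_steps <- function(trial, dt = 0.01) {
  max(1L, as.integer(floor(min(1, trial$movement_onset) / dt + 1e-9)))
}

#' Bin spike counts of one session
#'
#' @param session An \code{mmddm_session}.
#' @return List over trials of neuron x step count matrices.
#' @export
bin_spike_counts <- function(session) {
  dt <- session$dt
  N <- n_neurons(session)
  lapply(seq_len(n_trials(session)), function(i) {
    Tn <- trial_n_steps(session$trials[[i]], dt)
    y <- matrix(0, N, Tn)
    brks <- seq(0, Tn * dt, by = dt)
    for (n in seq_len(N)) {
      st <- session$spikes[[n]][[i]]
      st <- st[st >= 0 & st < Tn * dt]
      if (length(st)) {
        y[n, ] <- tabulate(findInterval(st, brks, left.open = FALSE,
                                        rightmost.closed = FALSE), Tn)
      }
    }
    y
  })
}

#' Write a session to disk
#'
#' The container is JSON (schema version attribute included): arrays of
#' ragged click and spike times serialized per trial. The round trip through
#' \code{\link{read_session}} is lossless to double precision.
#'
#' @param session An \code{mmddm_session}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  obj <- unclass(session)
  obj$trials <- lapply(obj$trials, function(tr) {
    tr$clicks <- unclass(tr$clicks)
    tr
  })
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null", pretty = FALSE)
  invisible(path)
}

#' Read a session from disk
#'
#' @param path Path written by \code{\link{write_session}}.
#' @return An \code{mmddm_session}; validation errors are raised for missing
#'   mandatory fields or an unknown schema version.
#' @export
read_session <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (is.null(obj$schema_version)) {
    stop("invalid session file: missing schema_version")
  }
  if (!identical(obj$schema_version, "1.0")) {
    stop(sprintf("unknown session schema version '%s'", obj$schema_version))
  }
  num <- function(x) if (is.null(x)) numeric(0) else as.numeric(unlist(x))
  trials <- lapply(obj$trials, function(tr) {
    tr$clicks <- structure(list(
      left_times = num(tr$clicks$left_times),
      right_times = num(tr$clicks$right_times),
      stereoclick_time = tr$clicks$stereoclick_time,
      duration = tr$clicks$duration
    ), class = "click_train")
    tr
  })
  spikes <- lapply(obj$spikes, function(per_neuron) lapply(per_neuron, num))
  gt <- obj$ground_truth
  if (!is.null(gt)) {
    for (f in c("z_final", "commit_step", "commit_side", "w_EA", "w_DC")) {
      if (!is.null(gt[[f]])) gt[[f]] <- unlist(gt[[f]])
    }
  }
  mmddm_session(session_id = obj$session_id, trials = trials,
                spikes = spikes, neuron_ids = unlist(obj$neuron_ids),
                ground_truth = gt, dt = obj$dt)
}
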