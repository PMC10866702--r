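#' Stimulation trigger policy
#'
#' @param mode `"single"` (fire on each target classification), `"sequence"`
#'   (classification of the first target arms; the next classification of the
#'   second target fires and disarms), `"random"` (Poisson schedule, used for
#'   contingency degradation) or `"off"`.
#' @param targets one action id (single) or two distinct ids `c(T1, T2)`
#'   (sequence).
#' @param random_rate triggers per minute (random mode).
#' @param latency decision latency range in seconds, uniform; default
#'   `c(0.035, 0.055)` (35-55 ms between action performance and sent
#'   decision). The latency shifts the train onset only.
#' @return object of class `trigger_policy`.
#' @export
trigger_policy <- function(mode = c("single", "sequence", "random", "off"),
                           targets = integer(0), random_rate = NULL,
                           latency = c(0.035, 0.055)) {
  mode <- match.arg(mode)
  if (mode == "single" && length(targets) != 1L)
    stopf("single mode needs exactly 1 target")
  if (mode == "sequence" &&
      (length(targets) != 2L || targets[1L] == targets[2L]))
    stopf("sequence mode needs exactly 2 distinct targets")
  if (mode == "random" && (is.null(random_rate) || random_rate <= 0))
    stopf("random mode needs random_rate > 0")
  stopifnot(length(latency) == 2L, latency[1] <= latency[2], latency[1] >= 0)
  structure(list(mode = mode, targets = as.integer(targets),
                 random_rate = random_rate, latency = latency),
            class = "trigger_policy")
}

#' Build a stimulation pulse train
#'
#' The standard train is 15 light pulses of 10 ms duration at 25 Hz, spanning
#' 600 ms at a 25\% duty cycle.
#'
#' @param rate_hz pulse rate (Hz).
#' @param width_ms pulse width (ms); must not exceed the inter-pulse period.
#' @param duration_ms train length (ms).
#' @param onset_s train onset (s).
#' @return object of class `stim_train` with `onset`, `pulse_times` (s),
#'   `pulse_width_ms`, `rate_hz`, `duration_ms`, `duty_cycle`, `n_pulses`.
#' @export
#' @examples
#' pulse_train(25, 10, 600)$n_pulses  # 15
pulse_train <- function(rate_hz = 25, width_ms = 10, duration_ms = 600,
                        onset_s = 0) {
  period_ms <- 1000 / rate_hz
  if (width_ms > period_ms) {
    stopf("pulse width (%g ms) exceeds inter-pulse period (%g ms)",
          width_ms, period_ms)
  }
  n <- floor(duration_ms * rate_hz / 1000)
  structure(list(onset = onset_s,
                 pulse_times = onset_s + (seq_len(n) - 1L) / rate_hz,
                 pulse_width_ms = width_ms, rate_hz = rate_hz,
                 duration_ms = duration_ms,
                 duty_cycle = width_ms * rate_hz / 1000, n_pulses = n),
            class = "stim_train")
}

#' Protocol phase annotations
#'
#' Presets mirror the reinforcement protocols: the single-action extinction
#' session (20 min maintenance, 60 min extinction, 20 min reacquisition), the
#' two-action sequence extinction session (25/40/25 min) and the contingency
#' degradation session (20 min maintenance, 60 min random-rate degradation,
#' 40 min reacquisition). Custom phase tables are accepted as a data.frame
#' with `phase`, `start_s`, `end_s`, `laser` columns.
#'
#' @param type preset name, or `"custom"` with `phases` supplied.
#' @param phases custom data.frame (checked for positive, non-overlapping
#'   contiguous intervals).
#' @return data.frame of class `protocol_phases` with columns `phase`,
#'   `start_s`, `end_s`, `laser` (`"closed_loop"`, `"random"` or `"off"`).
#' @export
protocol_phases <- function(type = c("single_extinction", "sequence_extinction",
                                     "degradation", "custom"),
                            phases = NULL) {
  type <- match.arg(type)
  preset <- switch(type,
    single_extinction = data.frame(
      phase = c("maintenance", "extinction", "reacquisition"),
      minutes = c(20, 60, 20),
      laser = c("closed_loop", "off", "closed_loop")),
    sequence_extinction = data.frame(
      phase = c("maintenance", "extinction", "reacquisition"),
      minutes = c(25, 40, 25),
      laser = c("closed_loop", "off", "closed_loop")),
    degradation = data.frame(
      phase = c("maintenance", "degradation", "reacquisition"),
      minutes = c(20, 60, 40),
      laser = c("closed_loop", "random", "closed_loop")),
    custom = NULL)
  if (!is.null(preset)) {
    ends <- cumsum(preset$minutes) * 60
    phases <- data.frame(phase = preset$phase,
                         start_s = c(0, ends[-length(ends)]),
                         end_s = ends, laser = preset$laser)
  }
  stopifnot(is.data.frame(phases),
            all(c("phase", "start_s", "end_s", "laser") %in% names(phases)))
  if (any(phases$end_s <= phases$start_s)) stopf("phase durations must be positive")
  o <- order(phases$start_s)
  phases <- phases[o, , drop = FALSE]
  if (nrow(phases) > 1L &&
      any(phases$start_s[-1L] < phases$end_s[-nrow(phases)] - 1e-9)) {
    stopf("phases must not overlap")
  }
  class(phases) <- c("protocol_phases", "data.frame")
  phases
}

#' @keywords internal
laser_mode_at <- function(t, phases) {
  if (is.null(phases)) return("closed_loop")
  i <- which(t >= phases$start_s & t < phases$end_s)
  if (length(i) == 0L) "off" else phases$laser[i[1L]]
}

# Shared trigger state machine. Returns trigger times (segment-end times of
# the firing classification, without latency).
#' @keywords internal
scan_triggers <- function(labels, times, policy, phases = NULL,
                          segment_s = 0.3, train_s = 0.6) {
  trig <- numeric(0)
  armed <- FALSE
  busy_until <- -Inf
  T1 <- if (policy$mode == "sequence") policy$targets[1L] else NA_integer_
  T2 <- if (policy$mode == "sequence") policy$targets[2L] else policy$targets[1L]
  for (i in seq_along(labels)) {
    t_end <- times[i] + segment_s
    if (t_end < busy_until) next # classifications during the train are inert
    if (laser_mode_at(times[i], phases) != "closed_loop") {
      # policy disarmed outside closed-loop phases; arming state is retained
      next
    }
    if (policy$mode == "single") {
      if (labels[i] == T2) {
        trig <- c(trig, t_end)
        busy_until <- t_end + train_s
      }
    } else if (policy$mode == "sequence") {
      if (labels[i] == T1) armed <- TRUE
      if (armed && labels[i] == T2) {
        trig <- c(trig, t_end)
        armed <- FALSE
        busy_until <- t_end + train_s
      }
    }
  }
  trig
}

#' Run the closed-loop classification/trigger/stimulation chain
#'
#' Each 300 ms segment is classified (histogram sets are matched against the
#' repertoire exemplars; precomputed integer labels are passed through), the
#' trigger policy is evaluated, and stimulation trains are emitted. Sequence
#' mode arms on the first target and fires on the next classification of the
#' second target regardless of the elapsed time; firing disarms, and a fresh
#' T1 is required before the next trigger (consecutive T1s keep the state
#' armed without stacking). Classifications arriving during an ongoing 600 ms
#' train are evaluated but can neither fire nor arm. The decision latency is
#' drawn uniformly from the policy's range and shifts the train onset only.
#'
#' @param segments list of `hist_set` objects, or an integer label vector.
#' @param rep `action_repertoire` (required when `segments` are histograms).
#' @param policy `trigger_policy`.
#' @param phases optional `protocol_phases`; triggers fire only in
#'   closed-loop phases (random-rate stimulation fires in `"random"` phases).
#' @param times segment start times (s); defaults to the 300 ms grid.
#' @param seed seed for latency draws and random schedules.
#' @param segment_s,train_s segment and train lengths (s).
#' @return object of class `session_log`: `labels`, `times`,
#'   `triggers` (data.frame `time` of firing classification, `onset` of the
#'   train after latency), `trains` (list of `stim_train`), `phases`,
#'   `policy`.
#' @export
run_closed_loop <- function(segments, rep = NULL, policy, phases = NULL,
                            times = NULL, seed = 0, segment_s = 0.3,
                            train_s = 0.6) {
  stopifnot(inherits(policy, "trigger_policy"))
  if (is.list(segments)) {
    if (is.null(rep)) stopf("matching histogram segments requires a repertoire")
    labels <- match_segments(segments, rep)
  } else {
    labels <- as.integer(segments)
  }
  if (!is.null(rep) && length(policy$targets) &&
      any(policy$targets > rep$n_actions)) {
    stopf("policy targets missing from the repertoire")
  }
  if (is.null(times)) times <- (seq_along(labels) - 1L) * segment_s
  duration <- length(labels) * segment_s
  if (policy$mode == "off") {
    trig <- numeric(0)
  } else if (policy$mode == "random") {
    trig <- random_schedule(policy$random_rate, duration, seed = seed)
    if (!is.null(phases)) {
      keep <- vapply(trig, function(t) laser_mode_at(t, phases) == "random",
                     logical(1))
      trig <- trig[keep]
    }
  } else {
    trig <- scan_triggers(labels, times, policy, phases, segment_s, train_s)
  }
  lat <- with_seed(seed + 1L,
                   stats::runif(length(trig), policy$latency[1], policy$latency[2]))
  onsets <- trig + lat
  trains <- lapply(onsets, function(o) pulse_train(onset_s = o))
  structure(list(labels = labels, times = times,
                 triggers = data.frame(time = trig, onset = onsets),
                 trains = trains, phases = phases, policy = policy),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> %d segments (%.1f min), %d triggers, policy '%s'\n",
              length(x$labels), length(x$labels) * 0.3 / 60,
              nrow(x$triggers), x$policy$mode))
  invisible(x)
}

#' Theoretical trigger times with stimulation suppressed
#'
#' Scans a label stream with the identical trigger state machine but without
#' emitting stimulation, as when baseline or open-field data are scanned as
#' if reinforcement had been available. Equals the trigger times of
#' [run_closed_loop()] at zero latency.
#'
#' @param labels integer action ids per segment.
#' @param times segment start times; defaults to the 300 ms grid.
#' @param policy `trigger_policy` (single or sequence).
#' @param segment_s,train_s grid constants.
#' @return numeric vector of theoretical trigger times (s).
#' @export
simulated_triggers <- function(labels, times = NULL, policy,
                               segment_s = 0.3, train_s = 0.6) {
  stopifnot(policy$mode %in% c("single", "sequence"))
  if (is.null(times)) times <- (seq_along(labels) - 1L) * segment_s
  scan_triggers(labels, times, policy, NULL, segment_s, train_s)
}

#' Random (contingency-degraded) stimulation schedule
#'
#' Homogeneous Poisson process times at the given mean rate, used to deliver
#' stimulation at a matched average frequency but unpaired from behaviour.
#'
#' @param rate_per_min mean triggers per minute (> 0).
#' @param duration_s schedule length (s).
#' @param seed integer seed.
#' @return increasing numeric vector of trigger times in `[0, duration_s)`.
#' @export
random_schedule <- function(rate_per_min, duration_s, seed = 0) {
  stopifnot(rate_per_min > 0, duration_s >= 0)
  rate_s <- rate_per_min / 60
  with_seed(seed, {
    # draw enough exponential gaps to cover the session
    n_guess <- max(10L, ceiling(duration_s * rate_s * 2 + 10 * sqrt(duration_s * rate_s)))
    gaps <- stats::rexp(n_guess, rate_s)
    t <- cumsum(gaps)
    while (length(t) && t[length(t)] < duration_s) {
      gaps <- stats::rexp(n_guess, rate_s)
      t <- c(t, t[length(t)] + cumsum(gaps))
    }
    t[t < duration_s]
  })
}
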