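#' Sensor specification for synthetic raw-signal generation
#'
#' Describes the simulated inertial sensor: sampling rate, mount misalignment
#' (pitch/roll, removed by calibration), per-axis gyroscope bias, and additive
#' noise levels. A 300 ms segment must contain an integer number of samples.
#'
#' @param sample_rate Hz (default 200).
#' @param tilt_pitch,tilt_roll mount misalignment in degrees.
#' @param gyro_bias length-3 bias in deg/s.
#' @param noise_sd_acc accelerometer noise s.d. (g).
#' @param noise_sd_gyr gyroscope noise s.d. (deg/s).
#' @return object of class `sensor_spec`.
#' @export
sensor_spec <- function(sample_rate = 200, tilt_pitch = 0, tilt_roll = 0,
                        gyro_bias = c(0, 0, 0), noise_sd_acc = 0.005,
                        noise_sd_gyr = 1) {
  stopifnot(sample_rate > 0, length(gyro_bias) == 3L,
            noise_sd_acc >= 0, noise_sd_gyr >= 0)
  spp <- sample_rate * 0.3
  if (abs(spp - round(spp)) > 1e-9) {
    stopf("a 300 ms segment must contain an integer number of samples (rate %g Hz)",
          sample_rate)
  }
  structure(list(sample_rate = sample_rate, tilt_pitch = tilt_pitch,
                 tilt_roll = tilt_roll, gyro_bias = gyro_bias,
                 noise_sd_acc = noise_sd_acc, noise_sd_gyr = noise_sd_gyr),
            class = "sensor_spec")
}

# pitch/roll mount rotation (sensor frame <- body frame)
#' @keywords internal
mount_rotation <- function(pitch_deg, roll_deg) {
  p <- pitch_deg * pi / 180; r <- roll_deg * pi / 180
  Ry <- matrix(c(cos(p), 0, -sin(p), 0, 1, 0, sin(p), 0, cos(p)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(r), sin(r), 0, -sin(r), cos(r)), 3, 3)
  Rx %*% Ry
}

# body-acceleration carrier: three 5 Hz sinusoids with 120-degree phase
# offsets, giving a near-constant-magnitude acceleration vector
.ba_amplitude <- 0.25
.ba_freq_hz <- 5

#' Construct an action prototype
#'
#' A prototype characterizes one synthetic action by its mean gravity-axis
#' pitch posture (degrees), its dorsal-ventral turn rate (deg/s), and its
#' mobility (the fraction of total-body-acceleration mass in the moving bin).
#' The associated four-feature histogram set is derived from those parameters
#' so that featurizing a synthesized raw segment recovers it.
#'
#' @param id integer action identifier.
#' @param mean_posture pitch in degrees.
#' @param turn_rate GYRdv rate in deg/s.
#' @param mobility fraction in \[0, 1\].
#' @param bins `feature_bins`.
#' @param spec `sensor_spec` whose noise levels set the histogram smear.
#' @return object of class `action_prototype` with fields `id`,
#'   `mean_posture`, `turn_rate`, `mobility`, `hist`.
#' @export
action_prototype <- function(id, mean_posture, turn_rate, mobility,
                             bins = feature_bins(), spec = sensor_spec()) {
  stopifnot(mobility >= 0, mobility <= 1)
  thr <- bins$thresholds
  p <- mean_posture * pi / 180
  gaap <- smeared_hist(sin(p), 0.02 + spec$noise_sd_acc, thr$gaap)
  # raw dv acceleration mixes the gravity projection with the moving-state
  # body-acceleration carrier (amplitude 0.25 g, sd 0.25/sqrt(2))
  sd_dv <- sqrt(spec$noise_sd_acc^2 + mobility * (.ba_amplitude^2 / 2))
  accdv <- smeared_hist(cos(p), 0.02 + sd_dv, thr$accdv)
  gyrdv <- smeared_hist(turn_rate, 1 + spec$noise_sd_gyr, thr$gyrdv)
  totba <- c(1 - mobility, mobility)
  structure(list(id = as.integer(id), mean_posture = mean_posture,
                 turn_rate = turn_rate, mobility = mobility,
                 hist = hist_set(gaap, accdv, gyrdv, totba)),
            class = "action_prototype")
}

#' Generate a synthetic action repertoire
#'
#' Draws `K` action prototypes whose postures, turn rates and mobilities are
#' spread over their natural ranges by farthest-point (maximin) selection
#' from a random candidate pool, emulating the size and mutual
#' discriminability of a spontaneous behavioural repertoire: clusters found
#' in real data are separable by construction. Mobility is pinned to exactly
#' 0 or 1 for a share of candidates so that fully resting and fully
#' accelerating exemplars exist. Deterministic for a fixed seed.
#'
#' @param K number of actions (>= 2).
#' @param seed integer seed.
#' @param bins `feature_bins`.
#' @param spec `sensor_spec`.
#' @return list of `action_prototype` objects.
#' @export
make_repertoire <- function(K, seed, bins = feature_bins(), spec = sensor_spec()) {
  if (!is_count(K) || K < 2) stopf("K must be an integer >= 2")
  with_seed(seed, {
    n_pool <- max(300L, 20L * K)
    posture <- stats::runif(n_pool, -60, 60)
    turn <- stats::runif(n_pool, -140, 140)
    u <- stats::runif(n_pool)
    mobility <- ifelse(u < 0.35, 1, ifelse(u < 0.55, 0, stats::runif(n_pool, 0.1, 0.9)))
    # maximin selection in EMD space: greedily pick the candidate farthest
    # (summed per-feature EMD) from every already-chosen prototype
    pool <- lapply(seq_len(n_pool), function(j) {
      action_prototype(j, posture[j], turn[j], mobility[j], bins, spec)
    })
    cs <- lapply(c("gaap", "accdv", "gyrdv", "totba"), function(f) {
      m <- vapply(pool, function(p) cumsum(p$hist[[f]]),
                  numeric(length(pool[[1L]]$hist[[f]])))
      list(m = m, norm = nrow(m) - 1L)
    })
    dem_to <- function(j) {
      Reduce(`+`, lapply(cs, function(x) {
        colSums(abs(x$m - x$m[, j])) / x$norm
      }))
    }
    chosen <- sample.int(n_pool, 1L)
    d_min <- dem_to(chosen)
    while (length(chosen) < K) {
      nxt <- which.max(d_min)
      chosen <- c(chosen, nxt)
      d_min <- pmin(d_min, dem_to(nxt))
    }
    lapply(seq_len(K), function(i) {
      j <- chosen[i]
      action_prototype(i, posture[j], turn[j], mobility[j], bins, spec)
    })
  })
}

#' Synthesize one 300 ms six-channel raw segment for a prototype
#'
#' Gravity is projected through the prototype's pitch posture, body
#' acceleration is a 5 Hz three-axis carrier (near-constant magnitude 0.3 g)
#' active for the `mobility` fraction of samples, and the dorsal-ventral
#' gyroscope channel carries the constant turn rate. The mount misalignment
#' and gyroscope bias of `spec` are then applied, followed by additive noise;
#' magnetometer channels are not synthesized.
#'
#' @param proto `action_prototype`.
#' @param spec `sensor_spec`.
#' @param seed integer seed.
#' @return n x 6 matrix (acc ap/ml/dv, gyr x/y/z) for one segment.
#' @export
synth_raw_segment <- function(proto, spec = sensor_spec(), seed = 0) {
  n <- as.integer(round(spec$sample_rate * 0.3))
  with_seed(seed, {
    p <- proto$mean_posture * pi / 180
    acc <- cbind(ap = rep(sin(p), n), ml = 0, dv = rep(cos(p), n))
    m <- round(proto$mobility * n)
    if (m > 0) {
      t <- (seq_len(m) - 1L) / spec$sample_rate
      ph <- stats::runif(1, 0, 2 * pi)
      w <- 2 * pi * .ba_freq_hz
      acc[seq_len(m), 1L] <- acc[seq_len(m), 1L] + .ba_amplitude * sin(w * t + ph)
      acc[seq_len(m), 2L] <- acc[seq_len(m), 2L] + .ba_amplitude * sin(w * t + ph + 2 * pi / 3)
      acc[seq_len(m), 3L] <- acc[seq_len(m), 3L] + .ba_amplitude * sin(w * t + ph + 4 * pi / 3)
    }
    gyr <- cbind(x = numeric(n), y = numeric(n), z = rep(proto$turn_rate, n))
    Rm <- mount_rotation(spec$tilt_pitch, spec$tilt_roll)
    acc <- acc %*% t(Rm)
    gyr <- gyr %*% t(Rm)
    gyr <- sweep(gyr, 2L, -spec$gyro_bias)
    acc <- acc + matrix(stats::rnorm(3L * n, 0, spec$noise_sd_acc), n, 3L)
    gyr <- gyr + matrix(stats::rnorm(3L * n, 0, spec$noise_sd_gyr), n, 3L)
    cbind(acc, gyr)
  })
}

#' Construct the state of a synthetic reinforcement-responsive agent
#'
#' The agent performs one action per 300 ms segment following a row-stochastic
#' Markov transition matrix, and responds to reinforcement by a
#' similarity-weighted, retrospectively time-decaying eligibility rule (see
#' [reinforce_update()]). With `learning_rate = 0` the transition matrix never
#' departs from `base_transition_matrix`.
#'
#' @param prototypes list of `action_prototype`.
#' @param transition_matrix row-stochastic K x K matrix.
#' @param learning_rate eligibility gain per reinforcement (eta >= 0).
#' @param similarity_bandwidth similarity kernel bandwidth (sigma > 0, in
#'   units of the S score).
#' @param eligibility_tau retrospective time constant (tau, seconds > 0).
#' @param decay per-update relaxation toward the base matrix (rho in \[0,1\]).
#' @return object of class `agent_state`.
#' @export
agent_state <- function(prototypes, transition_matrix, learning_rate = 0.002,
                        similarity_bandwidth = 0.5, eligibility_tau = 2,
                        decay = 0.002) {
  K <- length(prototypes)
  W <- as.matrix(transition_matrix)
  stopifnot(K >= 2L, nrow(W) == K, ncol(W) == K, all(W >= 0),
            learning_rate >= 0, similarity_bandwidth > 0, eligibility_tau > 0,
            decay >= 0, decay <= 1)
  if (any(abs(rowSums(W) - 1) > 1e-9)) stopf("transition rows must sum to 1")
  structure(list(prototypes = prototypes,
                 transition_matrix = W,
                 base_transition_matrix = W,
                 S_proto = similarity_matrix(lapply(prototypes, `[[`, "hist")),
                 learning_rate = learning_rate,
                 similarity_bandwidth = similarity_bandwidth,
                 eligibility_tau = eligibility_tau,
                 decay = decay),
            class = "agent_state")
}

#' Build an agent with sticky, near-uniform action dynamics
#'
#' Each action persists with probability `stickiness` per segment (bouts of a
#' few hundred milliseconds to seconds); leaving mass is spread uniformly.
#' Optional per-action entry hazards override the uniform share for chosen
#' actions, which is how baseline target rates and inter-target intervals are
#' controlled.
#'
#' @param K number of actions.
#' @param seed seed for the prototype draw.
#' @param stickiness self-transition probability.
#' @param entry_hazard optional named numeric: per-segment probability of
#'   entering the named action from any other action.
#' @param ... passed to [agent_state()].
#' @return `agent_state`.
#' @export
make_agent <- function(K = 30L, seed = 1L, stickiness = 0.6,
                       entry_hazard = NULL, ...) {
  protos <- make_repertoire(K, seed)
  leave <- 1 - stickiness
  W <- matrix(leave / (K - 1L), K, K)
  diag(W) <- stickiness
  if (!is.null(entry_hazard)) {
    ids <- as.integer(names(entry_hazard))
    stopifnot(all(ids >= 1L & ids <= K), all(entry_hazard < leave))
    for (r in seq_len(K)) {
      tgt <- setdiff(ids, r)
      if (length(tgt) == 0L) next
      others <- setdiff(seq_len(K), c(r, tgt))
      W[r, tgt] <- entry_hazard[as.character(tgt)]
      W[r, others] <- (leave - sum(W[r, tgt])) / length(others)
    }
  }
  agent_state(protos, W, ...)
}

#' Agent whose baseline T1 -> T2 interval is controlled
#'
#' Background dynamics are sticky and near-uniform, so any given action
#' starts a bout every 20 s or so, as in a repertoire of a few dozen actions.
#' On top of that, a behavioural "corridor" of intermediate actions links T1
#' to T2: after a T1 bout the chain tends to run through the corridor and
#' finish on T2, and the corridor length sets the natural (median) T1 -> T2
#' interval -- roughly one mean bout (about 0.75 s at the default
#' stickiness) per corridor step. Corridor follow-through is tuned so that a
#' small majority of T1 performances complete the corridor, which keeps the
#' median interval at the corridor's traversal time while the remainder
#' disperse into long background waits.
#'
#' @param K actions (needs headroom for the corridor).
#' @param T1,T2 distinct target ids.
#' @param t1t2_interval_s target median T1 -> T2 interval (s).
#' @param seed,stickiness passed to [make_agent()].
#' @param follow_mass fraction of leaving mass routed along the corridor at
#'   its entrance; later hops use the completion-calibrated fraction.
#' @param ... passed to [agent_state()].
#' @return `agent_state` with attribute `"corridor"` (the intermediate ids).
#' @export
make_sequence_agent <- function(K = 30L, T1 = 1L, T2 = 2L,
                                t1t2_interval_s = 4, seed = 1L,
                                stickiness = 0.6, follow_mass = NULL, ...) {
  if (T1 == T2) stopf("T1 and T2 must differ")
  mean_bout_s <- 0.3 / (1 - stickiness)
  m <- max(0L, as.integer(round(t1t2_interval_s / mean_bout_s)) - 1L)
  if (K < m + 5L) stopf("K = %d too small for a %d-step corridor", K, m)
  corridor <- setdiff(seq(K, 1L), c(T1, T2))[seq_len(m)]
  agent <- make_agent(K, seed, stickiness, ...)
  W <- agent$transition_matrix
  leave <- 1 - stickiness
  # route leave-mass along T1 -> corridor -> T2 so that slightly more than
  # half of T1 performances complete the chain
  f <- if (is.null(follow_mass)) 0.57^(1 / (m + 1)) else follow_mass
  path <- c(T1, corridor, T2)
  for (i in seq_len(length(path) - 1L)) {
    from <- path[i]; to <- path[i + 1L]
    others <- setdiff(seq_len(K), c(from, to))
    W[from, to] <- leave * f
    W[from, others] <- leave * (1 - f) / length(others)
    W[from, from] <- stickiness
  }
  out <- agent_state(agent$prototypes, W,
                     learning_rate = agent$learning_rate,
                     similarity_bandwidth = agent$similarity_bandwidth,
                     eligibility_tau = agent$eligibility_tau,
                     decay = agent$decay)
  attr(out, "corridor") <- corridor
  out
}

#' Simulate a session of agent behaviour
#'
#' Draws one action label per 300 ms segment from the agent's Markov chain.
#' In raw mode a six-channel stream is synthesized for the sampled labels:
#' the gravity trajectory follows each action's posture with a low-pass
#' postural ramp between bouts (postural change is continuous, not a step),
#' the 5 Hz body-acceleration carrier runs on a continuous session clock and
#' is gated by each action's mobility, and the dorsal-ventral gyroscope
#' carries each action's turn rate. Mount misalignment, gyroscope bias and
#' additive noise are applied as in [synth_raw_segment()].
#'
#' @param agent `agent_state`.
#' @param duration_s session length (multiple of 0.3 s).
#' @param mode `"labels"` or `"raw"`.
#' @param seed integer seed.
#' @param spec `sensor_spec` for raw mode.
#' @return object of class `labeled_session`: `labels` (integer per segment),
#'   `times` (segment starts, s), and in raw mode `stream` (`raw_stream`).
#' @export
simulate_session <- function(agent, duration_s, mode = c("labels", "raw"),
                             seed = 0, spec = sensor_spec()) {
  mode <- match.arg(mode)
  stopifnot(inherits(agent, "agent_state"))
  n <- n_segments(duration_s)
  labels <- with_seed(seed, sample_markov(agent$transition_matrix, n))
  out <- list(labels = labels, times = (seq_len(n) - 1L) * 0.3)
  if (mode == "raw") {
    out$stream <- with_seed(seed + 1L, {
      spp <- as.integer(round(spec$sample_rate * 0.3))
      ns <- n * spp
      t <- (seq_len(ns) - 1L) / spec$sample_rate
      posture <- rep(vapply(agent$prototypes[labels], `[[`, numeric(1),
                            "mean_posture"), each = spp) * pi / 180
      turn <- rep(vapply(agent$prototypes[labels], `[[`, numeric(1),
                         "turn_rate"), each = spp)
      mob <- rep(vapply(agent$prototypes[labels], `[[`, numeric(1),
                        "mobility"), each = spp)
      # postural ramp: 2 Hz zero-phase low-pass on the gravity components
      gx <- sin(posture); gz <- cos(posture)
      if (ns > 6L * spec$sample_rate / 2) {
        lp <- signal::butter(2, 2 / (spec$sample_rate / 2), type = "low")
        gx <- signal::filtfilt(lp, gx)
        gz <- signal::filtfilt(lp, gz)
      }
      moving <- stats::runif(ns) < mob
      ph <- stats::runif(1, 0, 2 * pi)
      w <- 2 * pi * .ba_freq_hz
      acc <- cbind(ap = gx + moving * .ba_amplitude * sin(w * t + ph),
                   ml = moving * .ba_amplitude * sin(w * t + ph + 2 * pi / 3),
                   dv = gz + moving * .ba_amplitude * sin(w * t + ph + 4 * pi / 3))
      gyr <- cbind(x = numeric(ns), y = numeric(ns), z = turn)
      Rm <- mount_rotation(spec$tilt_pitch, spec$tilt_roll)
      acc <- acc %*% t(Rm) +
        matrix(stats::rnorm(3L * ns, 0, spec$noise_sd_acc), ns, 3L)
      gyr <- sweep(gyr %*% t(Rm), 2L, -spec$gyro_bias) +
        matrix(stats::rnorm(3L * ns, 0, spec$noise_sd_gyr), ns, 3L)
      raw_stream(acc, gyr, spec$sample_rate)
    })
  }
  structure(out, class = "labeled_session")
}

#' @keywords internal
sample_markov <- function(W, n, start = NULL) {
  K <- nrow(W)
  cum <- t(apply(W, 1L, cumsum))
  labels <- integer(n)
  cur <- if (is.null(start)) sample.int(K, 1L) else start
  for (i in seq_len(n)) {
    labels[i] <- cur
    cur <- findInterval(stats::runif(1), cum[cur, ]) + 1L
    if (cur > K) cur <- K # guard against cumulative rounding
  }
  labels
}

#' Apply one retrospective reinforcement update to an agent
#'
#' Encodes the credit-assignment rule the simulator assumes: every action
#' performed during or in the seconds before stimulation gains inbound
#' transition weight, scaled by an exponential similarity kernel
#' \eqn{\exp(S(i, target)/\sigma)} and an exponential retrospective time
#' kernel \eqn{\exp(-\Delta t/\tau)}. Actions performed during the 600 ms
#' stimulation train count as \eqn{\Delta t = 0}; actions performed only
#' after the train gain nothing. Before the gains are added the matrix
#' relaxes toward the base matrix by the decay factor rho, and rows are
#' renormalized afterwards.
#'
#' @param agent `agent_state`.
#' @param history data.frame with columns `time` (s) and `action` covering
#'   the window before `stim_time`.
#' @param stim_time stimulation onset (s).
#' @param target action id whose exemplar anchors the similarity kernel.
#' @param train_s stimulation train length treated as "during" (default 0.6).
#' @return updated `agent_state`.
#' @export
reinforce_update <- function(agent, history, stim_time, target,
                             train_s = 0.6) {
  stopifnot(inherits(agent, "agent_state"))
  if (is.null(history) || nrow(history) == 0L) stopf("history must be non-empty")
  eta <- agent$learning_rate
  W <- agent$transition_matrix
  rho <- agent$decay
  if (rho > 0) W <- (1 - rho) * W + rho * agent$base_transition_matrix
  if (eta > 0) {
    h <- history[history$time < stim_time + train_s, , drop = FALSE]
    if (nrow(h) > 0L) {
      dt <- pmax(0, stim_time - h$time)
      gain_occ <- eta * exp(agent$S_proto[h$action, target] /
                              agent$similarity_bandwidth) *
        exp(-dt / agent$eligibility_tau)
      gains <- vapply(seq_len(nrow(W)), function(a) sum(gain_occ[h$action == a]),
                      numeric(1))
      W <- W + matrix(gains, nrow(W), ncol(W), byrow = TRUE)
    }
  }
  W <- W / rowSums(W)
  agent$transition_matrix <- W
  agent
}

#' Agent with stereotyped behaviour before and after a target action
#'
#' Real behaviour has sequential syntax: specific actions tend to precede and
#' follow a given action. This constructor routes the chain through a
#' pre-target path (`pre` actions leading into the target) and a post-target
#' path (the target tends to be followed by `post` specific actions), with
#' `follow` of the leaving mass carried along each step. Transitions on the
#' pre-path are then genuinely enriched in the seconds before closed-loop
#' stimulation and post-path transitions in the seconds after, which is what
#' the retrospective-window analysis measures.
#'
#' @details
#' Each of the `n_pre` feeder actions is entered from the background at a
#' reduced rate (`feeder_entry_scale` of the uniform share) and routes
#' `feed_follow` of its leaving mass into the target, so that every
#' feeder-to-target transition type occurs a handful of times per half-hour
#' -- the low-rate band the baseline count filter selects for. The target in
#' turn fans `post_mass` of its leaving mass uniformly over the `n_post`
#' post-target actions.
#'
#' @param K actions; `target` target id.
#' @param n_pre,n_post numbers of pre-/post-target feeder actions.
#' @param feed_follow fraction of each feeder's leaving mass routed into the
#'   target.
#' @param post_mass fraction of the target's leaving mass fanned over the
#'   post-target actions.
#' @param feeder_entry_scale background entry rate of feeders relative to the
#'   uniform share.
#' @param seed,stickiness passed to [make_agent()].
#' @param ... passed to [agent_state()].
#' @return `agent_state` with attributes `"pre_actions"` and `"post_actions"`.
#' @export
make_structured_agent <- function(K = 30L, target = 1L, n_pre = 10L,
                                  n_post = 10L, feed_follow = 0.5,
                                  post_mass = 0.6, feeder_entry_scale = 0.1,
                                  seed = 1L, stickiness = 0.6, ...) {
  if (K < n_pre + n_post + 2L) stopf("K too small for the requested structure")
  ids <- setdiff(seq(K, 1L), target)
  pre_actions <- ids[seq_len(n_pre)]
  post_actions <- ids[n_pre + seq_len(n_post)]
  agent <- make_agent(K, seed, stickiness, ...)
  W <- agent$transition_matrix
  leave <- 1 - stickiness
  for (r in seq_len(K)) {
    if (r %in% pre_actions) {
      # feeder row: route into the target
      others <- setdiff(seq_len(K), c(r, target))
      W[r, target] <- leave * feed_follow
      W[r, others] <- leave * (1 - feed_follow) / length(others)
    } else if (r == target) {
      # target row: fan over the post-target actions
      others <- setdiff(seq_len(K), c(r, post_actions))
      W[r, post_actions] <- leave * post_mass / n_post
      W[r, others] <- leave * (1 - post_mass) / length(others)
    } else {
      # background row: depress entry into the feeders
      pre_other <- setdiff(pre_actions, r)
      others <- setdiff(seq_len(K), c(r, pre_other))
      w_pre <- feeder_entry_scale * leave / (K - 1L)
      W[r, pre_other] <- w_pre
      W[r, others] <- (leave - length(pre_other) * w_pre) / length(others)
    }
    W[r, r] <- stickiness
  }
  out <- agent_state(agent$prototypes, W,
                     learning_rate = agent$learning_rate,
                     similarity_bandwidth = agent$similarity_bandwidth,
                     eligibility_tau = agent$eligibility_tau,
                     decay = agent$decay)
  attr(out, "pre_actions") <- pre_actions
  attr(out, "post_actions") <- post_actions
  out
}

#' Simulate closed-loop single-action reinforcement
#'
#' Every classification of the target action outside an ongoing train fires a
#' stimulation train, and the agent is updated by [reinforce_update()] after
#' each trigger. A pre-learning baseline session (stimulation withheld)
#' supplies baseline trigger times and labels.
#'
#' @param agent `agent_state`.
#' @param target action id.
#' @param sessions number of reinforcement sessions.
#' @param session_s,baseline_s durations (s).
#' @param seed integer seed.
#' @return list with `sessions` (label vectors + trigger times),
#'   `baseline` (labels + simulated trigger times), `trigger_freq` (/min),
#'   `baseline_freq`, and the final `agent`.
#' @export
simulate_single_learner <- function(agent, target, sessions = 3L,
                                    session_s = 900, baseline_s = 1800,
                                    seed = 1L) {
  stopifnot(inherits(agent, "agent_state"))
  seg <- 0.3
  base <- simulate_session(agent, baseline_s, "labels", seed = seed * 1000L)
  pol <- trigger_policy("single", targets = target, latency = c(0, 0))
  base_trig <- simulated_triggers(base$labels, base$times, pol)
  hist_keep_s <- min(5 * agent$eligibility_tau, session_s)
  out_sessions <- vector("list", sessions)
  freq <- numeric(sessions)
  for (s in seq_len(sessions)) {
    n <- n_segments(session_s)
    labels <- integer(n)
    trig <- numeric(0)
    W <- agent$transition_matrix
    cum <- t(apply(W, 1L, cumsum))
    busy_until <- -Inf
    with_seed(seed + s, {
      cur <- sample.int(nrow(W), 1L)
      for (i in seq_len(n)) {
        labels[i] <- cur
        t_end <- (i - 1L) * seg + seg
        if (t_end >= busy_until && cur == target) {
          trig <- c(trig, t_end)
          busy_until <- t_end + 0.6
          keep <- max(1L, i - as.integer(ceiling(hist_keep_s / seg)))
          hist <- data.frame(time = (keep:i - 1L) * seg,
                             action = labels[keep:i])
          agent <- reinforce_update(agent, hist, t_end, target = target)
          W <- agent$transition_matrix
          cum <- t(apply(W, 1L, cumsum))
        }
        cur <- findInterval(stats::runif(1), cum[cur, ]) + 1L
        if (cur > nrow(W)) cur <- nrow(W)
      }
    })
    freq[s] <- length(trig) / (session_s / 60)
    out_sessions[[s]] <- list(labels = labels, trigger_times = trig)
  }
  list(sessions = out_sessions,
       baseline = list(labels = base$labels, times = base$times,
                       trigger_times = base_trig),
       trigger_freq = freq,
       baseline_freq = length(base_trig) / (baseline_s / 60),
       agent = agent)
}

#' Simulate closed-loop two-action sequence learning
#'
#' Runs the sequence trigger policy (T1 arms, the next T2 fires and disarms,
#' classifications during the 600 ms train cannot retrigger) against an agent
#' whose transition matrix is updated by [reinforce_update()] after every
#' trigger. A pre-learning baseline session with stimulation withheld supplies
#' the baseline trigger frequency.
#'
#' @param agent `agent_state`.
#' @param T1,T2 distinct action ids.
#' @param sessions number of reinforcement sessions.
#' @param session_s session length (s).
#' @param baseline_s baseline session length (s).
#' @param seed integer seed.
#' @param criterion baseline-subtracted triggers/min defining the criterion
#'   session (default 3.2).
#' @return list with `trigger_freq` (per session, /min), `baseline_freq`,
#'   `baseline_subtracted`, `sessions_to_criterion` (`NA` if never reached),
#'   `sessions` (list of label vectors + trigger times), `t1t2_baseline_median`
#'   (median baseline T1 end to T2 end interval), and the final `agent`.
#' @export
simulate_sequence_learner <- function(agent, T1, T2, sessions = 8L,
                                      session_s = 900, baseline_s = 1800,
                                      seed = 1L, criterion = 3.2) {
  stopifnot(inherits(agent, "agent_state"))
  if (T1 == T2) stopf("T1 and T2 must differ")
  seg <- 0.3
  base <- simulate_session(agent, baseline_s, "labels", seed = seed * 1000L)
  pol <- trigger_policy("sequence", targets = c(T1, T2), latency = c(0, 0))
  base_trig <- simulated_triggers(base$labels, base$times, pol)
  baseline_freq <- length(base_trig) / (baseline_s / 60)
  t1t2_base <- t1t2_intervals(base_trig, base$labels, base$times, T1, T2)
  hist_keep_s <- min(5 * agent$eligibility_tau, session_s)
  out_sessions <- vector("list", sessions)
  freq <- numeric(sessions)
  for (s in seq_len(sessions)) {
    n <- n_segments(session_s)
    labels <- integer(n)
    trig <- numeric(0)
    W <- agent$transition_matrix
    cum <- t(apply(W, 1L, cumsum))
    armed <- FALSE
    busy_until <- -Inf
    with_seed(seed + s, {
      cur <- sample.int(nrow(W), 1L)
      for (i in seq_len(n)) {
        labels[i] <- cur
        t_end <- (i - 1L) * seg + seg
        if (t_end >= busy_until) { # same gating as the closed-loop scanner
          if (cur == T1) armed <- TRUE
          if (armed && cur == T2) {
            stim <- t_end # train starts at the segment end
            trig <- c(trig, stim)
            armed <- FALSE
            busy_until <- stim + 0.6
            keep <- max(1L, i - as.integer(ceiling(hist_keep_s / seg)))
            hist <- data.frame(time = (keep:i - 1L) * seg,
                               action = labels[keep:i])
            agent <- reinforce_update(agent, hist, stim, target = T2)
            W <- agent$transition_matrix
            cum <- t(apply(W, 1L, cumsum))
          }
        }
        cur <- findInterval(stats::runif(1), cum[cur, ]) + 1L
        if (cur > nrow(W)) cur <- nrow(W)
      }
    })
    freq[s] <- length(trig) / (session_s / 60)
    out_sessions[[s]] <- list(labels = labels, trigger_times = trig)
  }
  bs <- freq - baseline_freq
  crit <- which(bs >= criterion)
  list(trigger_freq = freq, baseline_freq = baseline_freq,
       baseline_subtracted = bs,
       sessions_to_criterion = if (length(crit)) crit[1L] else NA_integer_,
       sessions = out_sessions,
       t1t2_baseline_median = t1t2_base$median,
       agent = agent)
}
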