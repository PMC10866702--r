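level_calibration <- function() {
  estimate_rotation(raw_stream(matrix(rep(c(0, 0, 1), each = 200), ncol = 3),
                               matrix(0, 200, 3)))
}

test_that("repertoires are valid, seeded, and spread over similarity space", {
  expect_error(make_repertoire(1, seed = 0), ">= 2")
  protos <- make_repertoire(5, seed = 1)
  expect_length(protos, 5L)
  for (p in protos) {
    for (f in names(p$hist)) expect_equal(sum(p$hist[[f]]), 1, tolerance = 1e-9)
    expect_true(all(unlist(p$hist) >= 0))
  }
  expect_identical(make_repertoire(5, seed = 1), protos)
  # K = 30: the pairwise similarity matrix reaches into the dissimilar range
  # (verified against the transport oracle)
  protos30 <- make_repertoire(30, seed = 7)
  hs <- lapply(protos30, `[[`, "hist")
  S <- outer(seq_along(hs), seq_along(hs),
             Vectorize(function(i, j) oracle_emd_similarity(hs[[i]], hs[[j]])))
  expect_lt(min(S), -0.2)
  expect_true(all(S >= -1 & S <= 0))
  # maximum-dissimilarity construction: opposite extremes on all features
  a <- point_hist_set(1L, 1L, 1L, moving = FALSE)
  b <- point_hist_set(11L, 11L, 6L, moving = TRUE)
  expect_identical(emd_similarity(a, b), -1)
})

test_that("label sessions follow the Markov chain and the 300 ms grid", {
  protos <- make_repertoire(3, seed = 2)
  # absorbing chain: action 1 self-transition 1
  W <- matrix(0, 3, 3)
  W[1, 1] <- 1
  W[2, ] <- c(1, 0, 0)
  W[3, ] <- c(1, 0, 0)
  ag <- agent_state(protos, W)
  ses <- simulate_session(ag, 30, "labels", seed = 3)
  expect_true(all(ses$labels[-1] == 1L))
  # 0.9 s -> exactly 3 labels
  expect_length(simulate_session(ag, 0.9, seed = 1)$labels, 3L)
  expect_error(simulate_session(ag, 1, seed = 1), "multiple")
  expect_error(simulate_session(ag, 0.9, mode = "bogus", seed = 1))
  # bit-for-bit reproducibility
  ag2 <- make_agent(5, seed = 9)
  expect_identical(simulate_session(ag2, 120, seed = 5)$labels,
                   simulate_session(ag2, 120, seed = 5)$labels)
  # uniform 5-action chain: label frequencies within 3 sd of 1/5
  Wu <- matrix(1 / 5, 5, 5)
  agu <- agent_state(make_repertoire(5, seed = 4), Wu)
  lab <- simulate_session(agu, 3600, seed = 6)$labels
  n <- length(lab)
  sd3 <- 3 * sqrt(0.2 * 0.8 / n)
  for (a in 1:5) expect_lt(abs(mean(lab == a) - 0.2), sd3)
})

test_that("synthesized raw segments featurize back to their prototype", {
  calib <- level_calibration()
  spec0 <- sensor_spec(noise_sd_acc = 0, noise_sd_gyr = 0)
  featurize_blocks <- function(proto, spec, seeds, th = 0.05) {
    blocks <- do.call(rbind, lapply(seeds, function(s) {
      synth_raw_segment(proto, spec, seed = s)
    }))
    st <- apply_calibration(raw_stream(blocks[, 1:3], blocks[, 4:6],
                                       spec$sample_rate), calib)
    segment_histograms(feature_series(st),
                       feature_bins(totba_threshold = th))
  }
  # resting prototype, zero noise: all TotBA mass in the resting bin
  pr <- action_prototype(1, 20, 60, 0, spec = spec0)
  hs <- featurize_blocks(pr, spec0, 1:40)
  expect_equal(hs[[10]]$totba, c(1, 0))
  # the featurized histograms sit close to the prototype's (EMD similarity
  # above -0.05 without noise)
  expect_gt(emd_similarity(hs[[10]], pr$hist), -0.05)
  # Monte-Carlo: across replicate segments the mean per-feature EMD distance
  # to the prototype is small (checked with the transport oracle)
  pm <- action_prototype(2, -25, -60, 1)
  hsm <- featurize_blocks(pm, sensor_spec(), 1:100)
  mid <- hsm[20:80]
  d <- vapply(mid, function(h) {
    mean(c(oracle_emd_1d(h$gaap, pm$hist$gaap),
           oracle_emd_1d(h$accdv, pm$hist$accdv),
           oracle_emd_1d(h$gyrdv, pm$hist$gyrdv),
           oracle_emd_1d(h$totba, pm$hist$totba)))
  }, numeric(1))
  expect_lt(mean(d), 0.1)
})

test_that("mount tilt is removed by calibration", {
  spec0 <- sensor_spec(noise_sd_acc = 0, noise_sd_gyr = 0)
  spec_tilt <- sensor_spec(tilt_pitch = 30, noise_sd_acc = 0, noise_sd_gyr = 0)
  pr <- action_prototype(1, 10, 40, 0, spec = spec0)
  block_level <- synth_raw_segment(pr, spec0, seed = 1)
  # calibrate the tilted sensor from its own stationary reading
  still <- action_prototype(9, 0, 0, 0, spec = spec_tilt)
  stat_block <- do.call(rbind, lapply(1:10, function(s) {
    synth_raw_segment(still, spec_tilt, seed = s)
  }))
  calib <- estimate_rotation(raw_stream(stat_block[, 1:3], stat_block[, 4:6]))
  block_tilt <- synth_raw_segment(pr, spec_tilt, seed = 1)
  cal <- apply_calibration(raw_stream(block_tilt[, 1:3], block_tilt[, 4:6]),
                           calib)
  expect_equal(cal$acc, block_level[, 1:3], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(cal$gyr, block_level[, 4:6], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("raw-mode sessions are recovered by featurization and matching", {
  calib <- level_calibration()
  # slow-switching agent over a small repertoire: the regime where online
  # matching is reliable
  ag <- make_agent(K = 8, seed = 5, stickiness = 0.95)
  ses <- simulate_session(ag, 180, "raw", seed = 21)
  f <- feature_series(apply_calibration(ses$stream, calib))
  th <- suppressWarnings(rest_threshold(f$totba))
  h <- segment_histograms(f, feature_bins(totba_threshold = th))
  p <- match_segments(h, as_action_repertoire(lapply(ag$prototypes, `[[`,
                                                     "hist")))
  truth <- ses$labels[(length(ses$labels) - length(p) + 1):length(ses$labels)]
  expect_gte(mean(p == truth), 0.9)
})

test_that("reinforcement updates follow the eligibility kernel", {
  protos <- make_repertoire(4, seed = 3)
  W <- matrix(1 / 4, 4, 4)
  h <- data.frame(time = c(1, 2, 3), action = c(1L, 2L, 3L))

  # eta = 0: agent unchanged forever
  ag0 <- agent_state(protos, W, learning_rate = 0, decay = 0)
  up0 <- reinforce_update(ag0, h, stim_time = 3.3, target = 2L)
  expect_identical(up0$transition_matrix, W)

  # empty history is invalid
  ag <- agent_state(protos, W, learning_rate = 0.1, decay = 0)
  expect_error(reinforce_update(ag, h[0, ], 3.3, 2L), "non-empty")

  # sigma -> 0+ with only the target pre-stimulation: only the target's
  # inbound weights increase
  ag_s <- agent_state(protos, W, learning_rate = 0.1,
                      similarity_bandwidth = 1e-9, decay = 0)
  h2 <- data.frame(time = c(1, 2), action = c(3L, 2L))
  up_s <- reinforce_update(ag_s, h2, stim_time = 2, target = 2L)
  gain <- up_s$transition_matrix - W
  expect_true(all(gain[, 2] > 0))
  expect_true(all(gain[, -2] <= 0)) # renormalization only

  # closed-form time kernel: occurrences 10 s vs 0.5 s before stimulation
  # gain in the ratio exp(-10) / exp(-0.5) (tau = 1); the raw gain g is
  # recovered from the renormalized row via (w0 + g) / (1 + g) = w
  ag_t <- agent_state(protos, W, learning_rate = 0.1, eligibility_tau = 1,
                      decay = 0)
  g_of <- function(t_occ) {
    up <- reinforce_update(ag_t, data.frame(time = t_occ, action = 1L),
                           stim_time = 20, target = 2L)
    w <- up$transition_matrix[1, 1]
    (w - W[1, 1]) / (1 - w)
  }
  expect_equal(g_of(10) / g_of(19.5), exp(-10) / exp(-0.5), tolerance = 1e-6)

  # actions occurring only after the stimulation train gain nothing
  ag_p <- agent_state(protos, W, learning_rate = 0.1, decay = 0)
  h3 <- data.frame(time = c(1, 5.0), action = c(2L, 4L)) # 4 at stim + 0.9
  up_p <- reinforce_update(ag_p, h3, stim_time = 4.1, target = 2L)
  expect_lte(max(up_p$transition_matrix[, 4] - W[, 4]), 0)

  # during-train occurrences count as delta t = 0
  h4 <- data.frame(time = 4.4, action = 3L) # inside [4.1, 4.7)
  up_d <- reinforce_update(ag_p, h4, stim_time = 4.1, target = 3L)
  expect_gt(min(up_d$transition_matrix[, 3] - W[, 3]), 0)
})

test_that("transition rows stay stochastic through arbitrary update sequences", {
  ag <- make_agent(6, seed = 8, learning_rate = 0.05, decay = 0.01)
  withr::with_seed(13, {
    for (i in 1:20) {
      h <- data.frame(time = sort(stats::runif(8, 0, 10)),
                      action = sample.int(6, 8, replace = TRUE))
      ag <- reinforce_update(ag, h, stim_time = 10, target = sample.int(6, 1))
      expect_equal(rowSums(ag$transition_matrix), rep(1, 6), tolerance = 1e-9)
      expect_true(all(ag$transition_matrix >= 0))
    }
  })
})

test_that("sequence learner enforces preconditions and the eta = 0 null", {
  ag <- make_sequence_agent(K = 20, T1 = 1, T2 = 2, t1t2_interval_s = 2,
                            seed = 3, learning_rate = 0)
  expect_error(simulate_sequence_learner(ag, 1, 1, seed = 1), "differ")
  res <- simulate_sequence_learner(ag, 1, 2, sessions = 4, session_s = 600,
                                   baseline_s = 1200, seed = 5)
  # without learning the baseline-subtracted frequency fluctuates around zero
  expect_lt(abs(mean(res$baseline_subtracted)), 1)
  expect_true(is.na(res$sessions_to_criterion))
  expect_identical(res$agent$transition_matrix, ag$transition_matrix)
})

test_that("flat kernels reinforce all actions alike: no target-specific trend", {
  # tau, sigma -> infinity: every recent action gains equally per
  # occurrence, so no target-specific credit exists; in the small-eta limit
  # (where the occupancy drift of uniform credit is negligible) the
  # trigger-frequency trend is statistically indistinguishable from eta = 0
  slope <- function(eta, tau, sigma, sd) {
    ag <- make_sequence_agent(K = 20, T1 = 1, T2 = 2, t1t2_interval_s = 2,
                              seed = sd, learning_rate = eta,
                              eligibility_tau = tau,
                              similarity_bandwidth = sigma, decay = 0)
    res <- simulate_sequence_learner(ag, 1, 2, sessions = 4, session_s = 600,
                                     baseline_s = 600, seed = sd * 7)
    unname(stats::coef(stats::lm(res$trigger_freq ~ seq_along(res$trigger_freq)))[2])
  }
  s_flat <- vapply(1:6, function(sd) slope(1e-6, Inf, Inf, sd), numeric(1))
  s_null <- vapply(1:6, function(sd) slope(0, 2, 0.5, sd), numeric(1))
  expect_gt(stats::wilcox.test(s_flat, s_null)$p.value, 0.05)
})
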