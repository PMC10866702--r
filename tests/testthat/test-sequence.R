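test_that("criterion session is the first crossing of baseline + 3.2", {
  expect_equal(sequence_frequency(1:10, 300), 2)
  expect_identical(criterion_session(c(5, 6, 7), baseline_freq = 1), 1L)
  expect_identical(criterion_session(c(2, 3, 4.3), baseline_freq = 1), 3L)
  expect_true(is.na(criterion_session(c(2, 3, 4), baseline_freq = 1)))
  expect_error(criterion_session(c(2, 3), baseline_freq = NA), "baseline")
  # fixture curve against a first-crossing scan
  withr::with_seed(1, curve <- cumsum(stats::runif(12, 0, 1)))
  base <- 0.5
  oracle <- which(curve - base >= 3.2)[1]
  expect_identical(criterion_session(curve, base), oracle)
})

test_that("T1->T2 and T2->T1 intervals use the end-to-end convention", {
  # T1 in segment 3 (ends 0.9 s), T2 trigger at 2.9 s
  labels <- c(5L, 5L, 1L, 5L, 5L, 5L, 5L, 5L, 5L, 2L, 5L, 1L, 5L)
  iv <- t1t2_intervals(2.9, labels, T1 = 1L, T2 = 2L)
  expect_equal(iv$intervals, 2.9 - 0.9)
  # immediate adjacency gives one segment (0.3 s)
  lab2 <- c(1L, 2L, 5L)
  trig2 <- 0.6 # end of the T2 segment
  expect_equal(t1t2_intervals(trig2, lab2, T1 = 1L, T2 = 2L)$intervals, 0.3)
  # T2 -> next T1: ends of segments
  iv2 <- t2t1_intervals(2.9, labels, T1 = 1L, T2 = 2L)
  expect_equal(iv2$intervals, 12 * 0.3 - 2.9)
  # no qualifying pair flagged
  expect_true(t1t2_intervals(0.3, c(2L, 5L), T1 = 1L, T2 = 2L)$undefined)
  # random fixture equals a brute-force nearest scan
  withr::with_seed(6, lab3 <- sample.int(4, 600, replace = TRUE))
  pol <- trigger_policy("sequence", targets = c(1L, 2L), latency = c(0, 0))
  trig3 <- simulated_triggers(lab3, policy = pol)
  iv3 <- t1t2_intervals(trig3, lab3, T1 = 1L, T2 = 2L)
  t1_ends <- which(lab3 == 1L) * 0.3
  oracle <- vapply(trig3, function(tr) tr - max(t1_ends[t1_ends < tr]),
                   numeric(1))
  expect_equal(iv3$intervals, oracle)
  expect_equal(iv3$median, stats::median(oracle))
})

test_that("uniquely similar sets drop shared members and relax to top-9", {
  # crafted similarity matrix with known unique tops
  K <- 16L
  S <- matrix(-0.9, K, K)
  diag(S) <- 0
  T1 <- 1L; T2 <- 2L
  # actions 3..8 close to T1, 9..14 close to T2, 15..16 shared-intermediate
  S[T1, 3:8] <- S[3:8, T1] <- -0.05
  S[T2, 9:14] <- S[9:14, T2] <- -0.05
  S[T1, 15:16] <- S[15:16, T1] <- -0.1
  S[T2, 15:16] <- S[15:16, T2] <- -0.1
  us <- uniquely_similar_sets(S, T1, T2, top_n = 8L, fallback_n = 6L,
                              min_unique = 3L)
  expect_identical(us$set_T1, 3:8)
  expect_identical(us$set_T2, 9:14)
  expect_identical(us$n_used, 8L)
  # fully overlapping lists trigger the fallback and then error
  S2 <- matrix(-0.5, K, K); diag(S2) <- 0
  expect_error(uniquely_similar_sets(S2, T1, T2, top_n = 8L, fallback_n = 6L),
               "uniquely similar")
})

test_that("refinement index is target-normalized, scale-invariant and scalable", {
  freqs <- c(2, 1, 4, 2, 2)
  expect_equal(refinement_index(freqs, 1, c(3, 4, 5)), 1)
  expect_equal(refinement_index(freqs, 3, c(1, 2)), 1.5 / 4)
  expect_equal(refinement_index(c(2, 0, 0), 1, c(2, 3)), 0)
  expect_true(is.na(refinement_index(c(0, 1), 1, 2)))
  # scale invariance under c > 0
  expect_equal(refinement_index(freqs * 7.3, 3, c(1, 2)),
               refinement_index(freqs, 3, c(1, 2)))
  # scaling: minimum maps to 0, an index of 1 stays 1
  curve <- c(1, 0.6, 0.2, 0.4)
  sc <- scale_refinement(curve)
  expect_equal(sc, (curve - 0.2) / 0.8)
  expect_equal(sc[1], 1)
  expect_equal(min(sc), 0)
  expect_equal(scale_refinement(c(1, 0.2, 0.6))[3], 0.5)
  expect_error(scale_refinement(c(1.2, 1.1)), ">= 1")
})

test_that("differential refinement is a trapezoid area difference", {
  c1 <- c(1, 0.8, 0.6, 0.4, 0.2)
  expect_equal(differential_refinement(c1, c1, up_to = 5)$D, 0)
  # T2 uniformly 0.1 below T1 over 5 sessions: D = 0.1 * 4 intervals
  c2 <- c1 - 0.1
  d <- differential_refinement(c1, c2, up_to = 5)
  expect_equal(d$D, 0.1 * 4)
  expect_equal(d$per_session, 0.4 / 5)
  # antisymmetry under curve swap
  expect_equal(differential_refinement(c2, c1, up_to = 5)$D, -0.4)
  # default endpoint: the session by which both curves reached their minimum
  c3 <- c(1, 0.5, 0, 0.2, 0.4)
  c4 <- c(1, 0.8, 0.6, 0.4, 0)
  expect_identical(differential_refinement(c3, c4)$up_to, 5L)
  expect_error(differential_refinement(c1, c1[1:3]), "aligned")
})

test_that("starting point scans retrospectively from the interval anchor", {
  # D = T1 - T2 scaled refinement; D <= 0 at sessions 2 and 4, anchor at 6
  t1 <- c(0.9, 0.5, 0.8, 0.55, 0.9, 0.6, 0.5)
  t2 <- c(0.8, 0.6, 0.5, 0.6, 0.4, 0.3, 0.1)
  ivs <- c(9, 8, 7, 6, 5, 3, 2.5) # first <= 3 s at session 6
  sp <- starting_point(t1, t2, ivs)
  expect_identical(sp$anchor_session, 6L)
  expect_identical(sp$session, 4L)
  expect_identical(sp$rule, "balanced")
  # no balanced session: the early session of closest refinement is used
  t1b <- t2 + c(0.5, 0.1, 0.4, 0.3, 0.2, 0.25, 0.3)
  spb <- starting_point(t1b, t2, ivs)
  expect_identical(spb$rule, "closest")
  expect_identical(spb$session, 2L)
  expect_error(starting_point(t1, t2, rep(10, 7)), "<= 3")
})

test_that("turning point finds the local maximum of the progression", {
  # rise-then-fall: interior peak
  t1 <- c(0.5, 0.6, 0.8, 1.0, 0.7, 0.5)
  t2 <- c(0.5, 0.4, 0.3, 0.2, 0.3, 0.4)
  tp <- turning_point(t1, t2, start = 1L)
  d <- t1 - t2
  areas <- (d[1:5] + d[2:6]) / 2
  prog <- areas - areas[1]
  expect_equal(unname(tp$progression), unname(prog))
  expect_identical(tp$session, 4L)
  expect_false(tp$monotone)
  # monotone progression: last session, flagged
  t1m <- c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
  tpm <- turning_point(t1m, t2, start = 1L)
  expect_identical(tpm$session, 6L)
  expect_true(tpm$monotone)
})

test_that("odds ratios split interval change across learning phases", {
  # change split equally across phases
  expect_equal(odds_ratio(10, 6, 2)$ratio, 1)
  # 6 s then 2 s of an 8 s total: (6/8) / (2/8) = 3
  expect_equal(odds_ratio(10, 4, 2)$ratio, 3)
  # all change before the turning point: capped and flagged
  or <- odds_ratio(10, 2, 2)
  expect_true(or$capped)
  expect_identical(or$ratio, Inf)
  # zero total change undefined
  expect_true(odds_ratio(5, 5, 5)$undefined)
})

test_that("T1 rank profiles use mid-rank percentiles per 300 ms bin", {
  # T1 always the immediately preceding action: rank 100 in the first
  # pre-trigger bin
  lab <- rep(c(3L, 4L, 1L, 2L), 50)
  pol <- trigger_policy("sequence", targets = c(1L, 2L), latency = c(0, 0))
  trig <- simulated_triggers(lab, policy = pol)
  prof <- t1_rank_profile(trig, lab, n_actions = 4L, T1 = 1L)
  first_pre <- prof[prof$bin_s == -0.3, ]
  expect_equal(first_pre$rank, 100)
  expect_equal(first_pre$prob_T1, 1)
  # all actions equally probable in a bin: mid-rank midpoint (50)
  prof_flat <- t1_rank_profile(10, rep(1L, 100) * 0L + rep(c(1L, 2L, 3L, 4L), 25),
                               n_actions = 4L, T1 = 3L)
  # with a single trigger every action has some first-occurrence bin; ties
  # where probabilities are all equal give the midpoint percentile
  tied_bins <- prof_flat$rank[prof_flat$prob_T1 == 0]
  expect_true(all(tied_bins <= 50))
  # baseline self-subtraction is exactly zero
  expect_equal(pooled_rank_change(prof, prof), 0)
  expect_equal(pooled_rank_change(prof, prof, range_s = c(2.1, 3.6)), 0)
})

test_that("sigmoid and linear fits recover generating relationships", {
  withr::with_seed(12, {
    x <- stats::runif(40, 0, 10)
    y <- 1 + (9 - 1) / (1 + exp(-(x - 4.7) / 0.8)) + stats::rnorm(40, 0, 0.2)
    fit <- fit_sigmoid(x, y)
    expect_equal(fit$midpoint, 4.7, tolerance = 0.2)
    expect_equal(fit$half_max, 5, tolerance = 0.3)
    # half-max split divides fast and slow learners
    expect_identical(unname(fit$classes[y > fit$half_max][1]), "slow")
    # perfectly linear data
    lf <- fit_linear(1:10, 2 * (1:10) + 1)
    expect_equal(lf$slope, 2)
    expect_equal(lf$r_squared, 1)
    # flat data: slope not significant
    lf2 <- fit_linear(1:10, stats::rnorm(10))
    expect_gt(lf2$p_value, 0.05)
  })
})

test_that("matched reinforcement curves scale between first bin and maximum", {
  withr::with_seed(14, {
    # accelerating trigger rate: gaps shrink across 1000 reinforcements
    gaps <- stats::rexp(1000, rate = rep(seq(0.5, 4, length.out = 10), each = 100))
    trig <- cumsum(gaps)
  })
  mc <- matched_reinforcement_curves(trig, bin = 200L)
  expect_equal(mc$scaled[1], 0)
  expect_equal(max(mc$scaled), 1)
  expect_true(all(mc$scaled >= 0 & mc$scaled <= 1))
  # crossing bin equals a brute-force scan
  expect_identical(mc$criterion_bin, which(mc$scaled >= 0.25)[1])
  # constant rate: no dynamic range, flagged
  mc2 <- matched_reinforcement_curves(seq(1, 400) * 1.0, bin = 100L)
  expect_true(mc2$degenerate)
  expect_error(matched_reinforcement_curves(1:300, bin = 200L), "at least")
})
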