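test_that("moving-mean frequency equals the naive windowed oracle", {
  w <- 500L
  # one event per segment: constant 1 once the window has filled
  ser <- moving_mean_frequency(rep(1, 600))
  expect_true(all(ser$values == 1))
  expect_length(ser$values, 600 - w + 1)
  expect_equal(ser$times[1], w * 0.3)
  # no events
  expect_true(all(moving_mean_frequency(rep(0, 600))$values == 0))
  # bursty fixture against the oracle
  withr::with_seed(2, counts <- stats::rbinom(800, 1, 0.1))
  expect_equal(moving_mean_frequency(counts)$values,
               oracle_moving_mean(counts, w))
  # shorter than one window: nothing emitted
  expect_length(moving_mean_frequency(rep(1, 100))$values, 0L)
})

test_that("stage rates average the defined spans", {
  mk <- function(vals) {
    structure(list(values = vals, times = seq_along(vals) * 0.3 + 149.7,
                   window_s = 150, segment_s = 0.3),
              class = "frequency_series")
  }
  # constant rate: all stages equal
  s1 <- mk(rep(0.4, 14000))
  sr <- stage_rates(s1, first_reinforcement_s = 1500, s1, s1)
  expect_equal(unlist(sr), c(f0 = 0.4, f1 = 0.4, f2 = 0.4, f3 = 0.4))
  # step increase exactly at the first trigger
  vals <- c(rep(0.2, 5000), rep(0.7, 9000))
  t_step <- (5000 * 0.3) + 149.7 # time of the last 0.2 value
  s2 <- mk(vals)
  sr2 <- stage_rates(s2, first_reinforcement_s = t_step, s2, s2)
  expect_equal(sr2$f0, 0.2)
  expect_equal(sr2$f1, 0.7)
  expect_equal(sr2$f1 - sr2$f0, 0.5)
  # piecewise fixture: stage means equal hand arithmetic
  v3 <- c(rep(1, 3000), rep(3, 11000))
  s3 <- mk(v3)
  sr3 <- stage_rates(s3, first_reinforcement_s = 3000 * 0.3 + 149.7, s3, s3)
  expect_equal(sr3$f2, mean(v3[1:6000])) # first 30 min of the series
  # insufficient baseline errors
  expect_error(stage_rates(s1, first_reinforcement_s = 200, s1, s1),
               "baseline")
})

test_that("stage modulation applies the literal run-of-500 rule", {
  ref <- stats::runif(2000, 0.2, 0.4)
  # uniformly above the 99th percentile: positive
  expect_identical(stage_modulation(ref, rep(0.5, 600)), "positive")
  # alternating above/below: no qualifying run
  expect_identical(stage_modulation(ref, rep(c(0.5, 0.3), 400)), "none")
  # run of exactly 500 qualifying windows embedded mid-stage
  test <- c(stats::runif(200, 0.25, 0.35), rep(0.45, 500),
            stats::runif(200, 0.25, 0.35))
  expect_identical(stage_modulation(ref, test), "positive")
  # 499 is not enough (brute-force run-length check)
  test499 <- c(stats::runif(200, 0.25, 0.35), rep(0.45, 499),
               stats::runif(301, 0.25, 0.35))
  runs <- rle(test499 > stats::quantile(ref, 0.99))
  expect_false(any(runs$values & runs$lengths >= 500))
  expect_identical(stage_modulation(ref, test499), "none")
  # negative run
  expect_identical(stage_modulation(ref, rep(0.01, 600)), "negative")
  # both qualify -> delegated to positive
  both <- c(rep(0.5, 500), rep(0.01, 500))
  expect_identical(stage_modulation(ref, both), "positive")
  # short stage warns and returns none
  expect_warning(out <- stage_modulation(ref, rep(0.5, 100)), "shorter")
  expect_identical(out, "none")
})

test_that("dynamics classification applies the five ordered rules", {
  base <- list(f0_f1 = "none", f0_f2 = "none", f0_f3 = "none",
               f1_f2 = "none", f1_f3 = "none", f2_f3 = "none")
  up <- function(l, ...) { l[c(...)] <- "positive"; l }
  dn <- function(l, ...) { l[c(...)] <- "negative"; l }
  # increasing: up early, up mid, sustained (or up) late
  expect_identical(classify_dynamics(up(base, "f0_f1", "f1_f2")), "increasing")
  expect_identical(classify_dynamics(up(base, "f0_f1", "f1_f2", "f2_f3")),
                   "increasing")
  # sustained: up from baseline, flat afterwards
  expect_identical(classify_dynamics(up(base, "f0_f1")), "sustained")
  # transient: up early, down by late
  expect_identical(classify_dynamics(dn(up(base, "f0_f1"), "f1_f3")),
                   "transient")
  # decreasing: down early and late
  expect_identical(classify_dynamics(dn(base, "f0_f1", "f0_f3")), "decreasing")
  # otherwise: other (catch-all, e.g. late-only rise)
  expect_identical(classify_dynamics(up(base, "f2_f3")), "other")
  # reporting groups pool increasing and sustained
  expect_identical(dynamics_group(c("increasing", "sustained", "transient",
                                    "decreasing", "other")),
                   c("sustained_increase", "sustained_increase", "transient",
                     "decreasing", "other"))
})

test_that("inter-target intervals are start-to-start medians", {
  # target every 5 s on the grid: 0.3 s segments, period 5.1 s
  labels <- rep(c(1L, rep(2L, 16L)), 10L)
  iv <- inter_target_intervals(labels, 1L)
  expect_equal(iv$median, 5.1)
  # consecutive repeats contribute 0.3 s
  labels2 <- c(1L, 1L, 1L, 2L, 1L)
  iv2 <- inter_target_intervals(labels2, 1L)
  expect_equal(sort(iv2$intervals), c(0.3, 0.3, 0.6))
  # random fixture equals the sorted-gap oracle
  withr::with_seed(5, labels3 <- sample.int(3, 500, replace = TRUE))
  occ <- which(labels3 == 2L)
  expect_equal(inter_target_intervals(labels3, 2L)$median,
               stats::median(diff(occ * 0.3 - 0.3)))
  # fewer than two occurrences flagged
  expect_true(inter_target_intervals(c(2L, 2L), 1L)$undefined)
})

test_that("rapid adaptation normalizes to the final baseline triggers", {
  base <- seq(0, by = 10, length.out = 20) # one simulated trigger per 10 s
  # unchanged behaviour: all metrics about 1
  trig <- seq(200, by = 10, length.out = 40)
  ra <- rapid_adaptation(trig, base, n = 10)
  expect_equal(ra$norm_latency, 1)
  expect_equal(ra$norm_frequency, 1, tolerance = 0.01)
  # latency halved after learning
  trig2 <- seq(200, by = 5, length.out = 40)
  expect_equal(rapid_adaptation(trig2, base, n = 10)$norm_latency, 0.5)
  # all triggered segments exactly the exemplar: similarity numerator zero
  ra3 <- rapid_adaptation(trig, base, n = 10,
                          trigger_similarity = rep(0, 40),
                          baseline_similarity = rep(-0.2, 20))
  expect_equal(ra3$norm_similarity, 0)
  # insufficient events flagged
  expect_true(rapid_adaptation(trig[1:5], base, n = 10)$undefined)
})

test_that("Fano factor measures dispersion of windowed counts", {
  # perfectly periodic events: every window holds the same count
  periodic <- rep(c(1, rep(0, 9)), 60)
  fb <- fano_burstiness(periodic)
  expect_lt(fb$fano, 0.05)
  # Poisson counts: Fano near 1
  withr::with_seed(7, pois <- stats::rpois(4000, 0.3))
  fp <- fano_burstiness(pois)
  expect_equal(fp$fano, 1, tolerance = 0.15)
  # bootstrap verdicts classify references against the interval
  bt <- bootstrap_fano(fp$window_counts, B = 500, seed = 1)
  expect_identical(bootstrap_fano(fp$window_counts, B = 500, seed = 1,
                                  reference = bt$ci[1] - 1)$verdict, "below")
  expect_identical(bootstrap_fano(fp$window_counts, B = 500, seed = 1,
                                  reference = mean(bt$ci))$verdict, "within")
  expect_identical(bootstrap_fano(fp$window_counts, B = 500, seed = 1,
                                  reference = bt$ci[2] + 1)$verdict, "above")
  # doubling every count doubles the Fano factor
  expect_equal(fano_burstiness(2 * pois)$fano, 2 * fp$fano, tolerance = 1e-9)
  # zero mean undefined
  expect_true(fano_burstiness(rep(0, 100))$undefined)
})

test_that("extinction windows are anchored per their definitions", {
  phases <- protocol_phases("single_extinction")
  n <- 100 * 60 / 0.3
  labels <- rep(9L, n)
  # crafted target performances: first at 120 s, first after extinction
  # onset at 1260 s, first after reacquisition onset at 4890 s
  anchor <- function(t) t / 0.3 + 1
  labels[anchor(120)] <- 1L
  labels[anchor(600)] <- 1L
  labels[anchor(1260)] <- 1L
  labels[anchor(2400)] <- 1L
  labels[anchor(4890)] <- 1L
  labels[anchor(5700)] <- 1L
  w <- extinction_windows(labels, 1L, phases)
  expect_identical(w$window, c("M1", "M2", "E1", "E2", "E3", "R1", "R2"))
  expect_equal(w$start_s[w$window == "M1"], 120)
  expect_equal(w$start_s[w$window == "E1"], 1260)
  expect_equal(w$start_s[w$window == "R1"], 4890)
  # M2 ends at the E1 anchor; E3 ends at the R1 anchor
  expect_equal(w$start_s[w$window == "M2"], 1260 - 600)
  expect_equal(w$start_s[w$window == "E3"], 4890 - 600)
  # E2 starts at the midpoint between the starts of E1 and E3
  expect_equal(w$start_s[w$window == "E2"],
               (w$start_s[w$window == "E1"] + w$start_s[w$window == "E3"]) / 2)
  # all windows are 10 min
  expect_true(all(w$end_s - w$start_s == 600))
  # a missing anchor names the window
  labels2 <- labels
  labels2[labels2 == 1L & seq_along(labels2) > anchor(4800)] <- 9L
  expect_error(extinction_windows(labels2, 1L, phases), "R1")
})

test_that("repertoire trajectories normalize to baseline and drop non-finite", {
  freq <- rbind(c(2, 4, 6), # target-like action, baseline 2
                c(1, 1, 1),
                c(0, 3, 3)) # zero baseline: dropped
  sim <- c(0, -0.2, -0.5)
  rt <- repertoire_trajectories(freq, sim)
  expect_identical(rt$n_dropped, 1L)
  expect_equal(rt$trajectories[1, 3], 1) # own baseline normalizes to 1
  expect_equal(unname(unlist(rt$trajectories[1, 4:5])), c(2, 3))
  expect_error(repertoire_trajectories(rbind(c(0, 1)), 0), "dropped")
})

test_that("exponential decay fits recover generating parameters", {
  withr::with_seed(9, {
    d <- stats::runif(60, 0, 1)
    y <- 3.5 * exp(-2.2 * d) * exp(stats::rnorm(60, 0, 0.05))
    fit <- fit_decay(d, y)
    expect_equal(fit$a, 3.5, tolerance = 0.15)
    expect_equal(fit$b, 2.2, tolerance = 0.15)
  })
})
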