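#' Moving-mean frequency of action events
#'
#' Counts per 300 ms segment are averaged over a moving 2.5 min window
#' stepping at the segment grid. Values are emitted only once the window has
#' accumulated its full complement of bins, so the first emitted value covers
#' the first complete window.
#'
#' @param counts numeric vector of per-segment event counts (e.g. the 0/1
#'   indicator of an action's performance), or a logical vector.
#' @param window_s window length (s); default 150 (2.5 min).
#' @param segment_s segment length (s).
#' @return object of class `frequency_series`: list with `values` (moving
#'   means, one per window position), `times` (window end times), `window_s`,
#'   `segment_s`.
#' @export
moving_mean_frequency <- function(counts, window_s = 150, segment_s = 0.3) {
  counts <- as.numeric(counts)
  w <- n_segments(window_s, segment_s)
  if (length(counts) < w) {
    return(structure(list(values = numeric(0), times = numeric(0),
                          window_s = window_s, segment_s = segment_s),
                     class = "frequency_series"))
  }
  vals <- as.numeric(zoo::rollmean(counts, k = w, align = "right"))
  structure(list(values = vals,
                 times = (seq_along(vals) + w - 1L) * segment_s,
                 window_s = window_s, segment_s = segment_s),
            class = "frequency_series")
}

#' @keywords internal
segment_counts <- function(labels, target) as.numeric(labels == target)

#' Stage frequency rates f0..f3 for one action
#'
#' The baseline rate f0 averages 5 min of moving-mean values preceding the
#' first reinforcement event; f1 averages the 30 min immediately after it.
#' f2 and f3 average the initial 30 min of the session-2 and session-3 series
#' (each series already excludes values before its window has filled).
#'
#' @param series_s1 `frequency_series` for session 1.
#' @param first_reinforcement_s time of the first reinforcement in session 1.
#' @param series_s2,series_s3 `frequency_series` for sessions 2 and 3.
#' @param baseline_min,post_min averaging spans (min), defaults 5 and 30.
#' @return list with `f0`, `f1`, `f2`, `f3`.
#' @export
stage_rates <- function(series_s1, first_reinforcement_s, series_s2, series_s3,
                        baseline_min = 5, post_min = 30) {
  pick <- function(ser, from, to) {
    sel <- ser$times > from & ser$times <= to
    if (!any(sel)) stopf("no moving-mean values in [%g, %g] s", from, to)
    mean(ser$values[sel])
  }
  if (first_reinforcement_s - baseline_min * 60 < series_s1$times[1L] - 1e-9) {
    stopf("insufficient baseline before the first reinforcement event")
  }
  f0 <- pick(series_s1, first_reinforcement_s - baseline_min * 60,
             first_reinforcement_s)
  f1 <- pick(series_s1, first_reinforcement_s,
             first_reinforcement_s + post_min * 60)
  early30 <- function(ser) {
    sel <- seq_len(min(length(ser$values), n_segments(post_min * 60, ser$segment_s)))
    if (length(sel) == 0L) stopf("session series too short for the 30 min stage")
    mean(ser$values[sel])
  }
  list(f0 = f0, f1 = f1, f2 = early30(series_s2), f3 = early30(series_s3))
}

#' Significance of stage-vs-reference frequency modulation
#'
#' Implements the run-of-windows rule: a stage is positively modulated above a
#' reference stage if some 500 consecutive moving windows (a 2.5 min period)
#' all exceed the 99th percentile bin of the reference values, negatively
#' modulated if some 500 consecutive windows are all at or below the 5th
#' percentile bin, and unmodulated otherwise. A stage satisfying both is
#' delegated to the positive group.
#'
#' @param reference numeric moving-mean values of the reference stage.
#' @param test numeric moving-mean values of the scanned stage.
#' @param run_length qualifying run length (default 500 windows).
#' @param hi,lo percentiles (defaults 0.99 and 0.05).
#' @return `"positive"`, `"negative"` or `"none"` (with a warning if the
#'   stage is shorter than the run length).
#' @export
stage_modulation <- function(reference, test, run_length = 500L,
                             hi = 0.99, lo = 0.05) {
  if (length(test) < run_length) {
    warning("stage shorter than the qualifying run; returning 'none'")
    return("none")
  }
  q_hi <- stats::quantile(reference, hi, names = FALSE)
  q_lo <- stats::quantile(reference, lo, names = FALSE)
  has_run <- function(flag) {
    r <- rle(flag)
    any(r$values & r$lengths >= run_length)
  }
  pos <- has_run(test > q_hi)
  neg <- has_run(test <= q_lo)
  if (pos) "positive" else if (neg) "negative" else "none"
}

#' Classify an action's reinforcement dynamics
#'
#' Applies the five ordered category rules to the stage modulation verdicts.
#' Comparisons are encoded as `stage_modulation()` results; "f1/2" means the
#' comparison holds for the f1 or the f2 stage.
#'
#' \enumerate{
#'   \item increasing: significant increase f0->f1/2 and f1->f2/3, and
#'     increase or no change f1/2->f3;
#'   \item sustained: significant increase f0->f1/2, no change f1->f2/3 and
#'     f1/2->f3;
#'   \item transient: significant increase f0->f1/2 and significant decrease
#'     f1/2->f3;
#'   \item decreasing: significant decrease f0->f1/2 and f0->f3;
#'   \item other: everything else.
#' }
#'
#' @param cmp named list of modulation verdicts with elements
#'   `f0_f1`, `f0_f2`, `f0_f3`, `f1_f2`, `f1_f3`, `f2_f3` (reference stage
#'   first; each `"positive"`, `"negative"` or `"none"`).
#' @return one of `"increasing"`, `"sustained"`, `"transient"`,
#'   `"decreasing"`, `"other"`.
#' @export
classify_dynamics <- function(cmp) {
  need <- c("f0_f1", "f0_f2", "f0_f3", "f1_f2", "f1_f3", "f2_f3")
  stopifnot(all(need %in% names(cmp)))
  up <- function(x) identical(cmp[[x]], "positive")
  dn <- function(x) identical(cmp[[x]], "negative")
  none <- function(x) identical(cmp[[x]], "none")
  up01 <- up("f0_f1") || up("f0_f2")          # f0 -> f1/2
  up123 <- up("f1_f2") || up("f1_f3")         # f1 -> f2/3
  dn123_f3 <- dn("f1_f3") || dn("f2_f3")      # f1/2 -> f3 decrease
  up123_f3 <- up("f1_f3") || up("f2_f3")      # f1/2 -> f3 increase
  none123_f3 <- none("f1_f3") && none("f2_f3")
  if (up01 && up123 && (up123_f3 || none123_f3)) return("increasing")
  if (up01 && none("f1_f2") && none("f1_f3") && none123_f3) return("sustained")
  if (up01 && dn123_f3) return("transient")
  if ((dn("f0_f1") || dn("f0_f2")) && dn("f0_f3")) return("decreasing")
  "other"
}

#' Map a dynamics label to its reporting group
#'
#' Increasing and sustained actions are pooled as "sustained increase" for
#' reporting and modelling.
#' @param label dynamics label(s).
#' @return character vector over
#'   \{"sustained_increase", "transient", "decreasing", "other"\}.
#' @export
dynamics_group <- function(label) {
  vapply(as.character(label), function(l) {
    switch(l,
           increasing = ,
           sustained = "sustained_increase",
           transient = "transient",
           decreasing = "decreasing",
           "other")
  }, character(1), USE.NAMES = FALSE)
}

#' Median inter-target interval
#'
#' Median time between the starts of successive target actions in a window.
#' Consecutively repeating target segments contribute 300 ms intervals.
#'
#' @param labels integer action ids per segment.
#' @param target action id.
#' @param times segment start times; defaults to the 300 ms grid.
#' @return list with `median` (s), `intervals`, `n`; `NA` median (flagged via
#'   `undefined`) when the target occurs fewer than twice.
#' @export
inter_target_intervals <- function(labels, target, times = NULL) {
  if (is.null(times)) times <- (seq_along(labels) - 1L) * 0.3
  occ <- times[labels == target]
  if (length(occ) < 2L) {
    return(list(median = NA_real_, intervals = numeric(0), n = length(occ),
                undefined = TRUE))
  }
  iv <- diff(occ)
  list(median = stats::median(iv), intervals = iv, n = length(occ),
       undefined = FALSE)
}

#' Rapid-adaptation metrics after the n-th reinforcement
#'
#' Three normalized read-outs of behavioural adaptation after `n` cumulative
#' reinforcements: the mean latency across ten consecutive triggers, the
#' trigger frequency over the following minute, and the mean similarity of
#' the triggered segments to the target exemplar -- each normalized to the
#' value over the final ten baseline target instances that would have
#' triggered reinforcement in simulation.
#'
#' @param trigger_times actual reinforcement times (s), increasing.
#' @param baseline_trigger_times simulated baseline trigger times (s).
#' @param n number of cumulated reinforcements anchoring the read-out.
#' @param trigger_similarity optional numeric similarity score per trigger
#'   (same length as `trigger_times`); baseline similarities likewise.
#' @param baseline_similarity optional numeric per baseline trigger.
#' @return list with `norm_latency`, `norm_frequency`, `norm_similarity`
#'   (`NA` when the corresponding inputs are absent), or `undefined = TRUE`
#'   when fewer than `n + 10` triggers or 10 baseline triggers exist.
#' @export
rapid_adaptation <- function(trigger_times, baseline_trigger_times, n,
                             trigger_similarity = NULL,
                             baseline_similarity = NULL) {
  if (length(baseline_trigger_times) < 10L ||
      length(trigger_times) < n + 10L) {
    return(list(norm_latency = NA_real_, norm_frequency = NA_real_,
                norm_similarity = NA_real_, undefined = TRUE))
  }
  base10 <- utils::tail(baseline_trigger_times, 10L)
  base_lat <- mean(diff(base10))
  base_freq <- (length(base10) - 1L) / (max(base10) - min(base10)) * 60
  idx <- (n + 1L):(n + 10L)
  lat <- mean(diff(trigger_times[idx]))
  t0 <- trigger_times[n + 1L]
  freq <- sum(trigger_times >= t0 & trigger_times < t0 + 60)
  out <- list(norm_latency = lat / base_lat,
              norm_frequency = freq / base_freq,
              norm_similarity = NA_real_, undefined = FALSE)
  if (!is.null(trigger_similarity) && !is.null(baseline_similarity)) {
    base_sim <- mean(utils::tail(baseline_similarity, 10L))
    out$norm_similarity <- if (base_sim != 0) {
      mean(trigger_similarity[idx]) / base_sim
    } else {
      NA_real_
    }
  }
  out
}

#' Fano factor of windowed action counts
#'
#' Variance-to-mean ratio of event counts in 15 s moving windows (50 action
#' units of 300 ms), the dispersion measure used to quantify burstiness.
#'
#' @param counts per-segment event counts.
#' @param window_s window length (s; default 15).
#' @param segment_s segment length.
#' @return list with `fano`, `window_counts`; `NA` and `undefined = TRUE`
#'   when the mean count is zero.
#' @export
fano_burstiness <- function(counts, window_s = 15, segment_s = 0.3) {
  w <- n_segments(window_s, segment_s)
  if (length(counts) < w) stopf("series shorter than one window")
  wc <- as.numeric(zoo::rollsum(counts, k = w, align = "right"))
  m <- mean(wc)
  if (m == 0) {
    return(list(fano = NA_real_, window_counts = wc, undefined = TRUE))
  }
  list(fano = stats::var(wc) / m, window_counts = wc, undefined = FALSE)
}

#' Bootstrap confidence interval for the Fano factor
#'
#' Resamples windows with replacement `B` times; a reference Fano factor is
#' judged significantly different if it falls outside the 95\% interval of
#' the bootstrap distribution.
#'
#' @param window_counts windowed counts (from [fano_burstiness()]).
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @param reference optional reference Fano factor to test.
#' @return list with `ci` (length 2), `boot` (the B resampled Fano factors),
#'   and, when `reference` is given, `verdict` in
#'   \{"below", "within", "above"\}.
#' @export
bootstrap_fano <- function(window_counts, B = 1000L, seed = 0, conf = 0.95,
                           reference = NULL) {
  stopifnot(length(window_counts) >= 2L)
  boot <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      x <- sample(window_counts, replace = TRUE)
      m <- mean(x)
      if (m == 0) NA_real_ else stats::var(x) / m
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  out <- list(ci = ci, boot = boot)
  if (!is.null(reference)) {
    out$verdict <- if (reference < ci[1L]) "below"
      else if (reference > ci[2L]) "above" else "within"
  }
  out
}

#' Ten-minute analysis windows along an extinction protocol
#'
#' Anchors the seven canonical windows of a
#' maintenance/extinction/reacquisition session: early maintenance (M1) at
#' the first target performance of the session; late maintenance (M2) ending
#' at the first target performance after extinction begins (= E1 start); E1
#' at that performance; late extinction (E3) ending at the first target
#' performance after reacquisition begins (= R1 start); mid extinction (E2)
#' starting at the midpoint of the E1 and E3 starts; R1 at the first target
#' performance after reacquisition; late reacquisition (R2) as the final
#' window of the session.
#'
#' @param labels integer action ids per segment.
#' @param target target action id.
#' @param phases `protocol_phases` containing `maintenance`, `extinction`,
#'   `reacquisition` rows.
#' @param times segment start times; defaults to the grid.
#' @param window_min window length (min; default 10).
#' @return data.frame with `window`, `start_s`, `end_s`.
#' @export
extinction_windows <- function(labels, target, phases, times = NULL,
                               window_min = 10) {
  if (is.null(times)) times <- (seq_along(labels) - 1L) * 0.3
  w <- window_min * 60
  ph <- function(p) {
    i <- which(phases$phase == p)
    if (length(i) != 1L) stopf("phases must contain one '%s' row", p)
    c(phases$start_s[i], phases$end_s[i])
  }
  first_after <- function(t0, window_name) {
    occ <- times[labels == target & times >= t0]
    if (length(occ) == 0L) {
      stopf("no target performance anchors window %s", window_name)
    }
    occ[1L]
  }
  m <- ph("maintenance"); e <- ph("extinction"); r <- ph("reacquisition")
  m1 <- first_after(m[1L], "M1")
  e1 <- first_after(e[1L], "E1")
  r1 <- first_after(r[1L], "R1")
  e3_end <- r1
  e2 <- (e1 + e3_end - w) / 2 # midpoint of E1 and E3 starts
  out <- data.frame(
    window = c("M1", "M2", "E1", "E2", "E3", "R1", "R2"),
    start_s = c(m1, e1 - w, e1, e2, e3_end - w, r1, max(times) + 0.3 - w))
  out$end_s <- out$start_s + w
  out
}

#' Baseline-normalized repertoire trajectories against target similarity
#'
#' For every action, the stage frequencies are normalized to the action's
#' baseline frequency and paired with its similarity to the target. Actions
#' whose normalized series contain non-finite values (zero baseline) are
#' dropped and counted.
#'
#' @param freq matrix of frequencies, actions x stages; first column is the
#'   baseline stage.
#' @param similarity numeric similarity score of each action to the target.
#' @return list with `trajectories` (data.frame `action`, `similarity`, one
#'   column per stage, sorted by decreasing similarity), `n_dropped`.
#' @export
repertoire_trajectories <- function(freq, similarity) {
  freq <- as.matrix(freq)
  stopifnot(nrow(freq) == length(similarity))
  norm <- freq / freq[, 1L]
  ok <- apply(is.finite(norm), 1L, all)
  if (!any(ok)) stopf("all actions dropped (no finite baseline-normalized series)")
  df <- data.frame(action = which(ok), similarity = similarity[ok],
                   norm[ok, , drop = FALSE])
  df <- df[order(-df$similarity), ]
  list(trajectories = df, n_dropped = sum(!ok))
}

#' One-phase exponential decay fit of frequency against EMD distance
#'
#' Fits `freq = a * exp(-b * distance)` by nonlinear least squares, where
#' `distance` is the magnitude of the (negative) similarity score.
#'
#' @param distance non-negative distances (e.g. `-S`).
#' @param freq frequencies at those distances.
#' @return list with `a`, `b`, `fitted`, and the `nls` object.
#' @export
fit_decay <- function(distance, freq) {
  ok <- is.finite(distance) & is.finite(freq)
  distance <- distance[ok]; freq <- freq[ok]
  stopifnot(length(freq) >= 3L)
  start_b <- if (all(freq > 0)) {
    max(1e-6, -stats::coef(stats::lm(log(freq) ~ distance))[[2L]])
  } else 1
  fit <- minpack.lm::nlsLM(freq ~ a * exp(-b * distance),
                           start = list(a = max(freq), b = start_b))
  co <- stats::coef(fit)
  list(a = co[["a"]], b = co[["b"]], fitted = stats::fitted(fit), fit = fit)
}
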