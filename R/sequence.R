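#' Sequence performance frequency
#'
#' @param trigger_times trigger times (s) within one session.
#' @param duration_s session length (s).
#' @return triggers per minute.
#' @export
sequence_frequency <- function(trigger_times, duration_s) {
  stopifnot(duration_s > 0)
  length(trigger_times) / (duration_s / 60)
}

#' First session reaching the criterion frequency
#'
#' The criterion is a baseline-subtracted sequence frequency of 3.2 triggers
#' per minute, chosen above the highest open-field baseline-subtracted value.
#'
#' @param freqs per-session trigger frequencies (/min).
#' @param baseline_freq baseline frequency (/min).
#' @param criterion threshold (default 3.2).
#' @return integer session index, or `NA` if the criterion is never reached.
#' @export
criterion_session <- function(freqs, baseline_freq, criterion = 3.2) {
  if (is.null(baseline_freq) || is.na(baseline_freq)) {
    stopf("baseline frequency required for subtraction")
  }
  hit <- which(freqs - baseline_freq >= criterion)
  if (length(hit)) hit[1L] else NA_integer_
}

#' T1 -> T2 intervals at triggers
#'
#' For each trigger, the time distance between the end of the latest distal
#' action (T1) and the end of the proximal action (T2) whose classification
#' triggers the laser. Trigger times are segment-end times, so immediate
#' T1-then-T2 adjacency yields 0.3 s.
#'
#' @param trigger_times actual or simulated trigger times (s).
#' @param labels integer action ids per segment.
#' @param times segment start times; defaults to the 300 ms grid.
#' @param T1,T2 action ids.
#' @param segment_s segment length.
#' @return list with `intervals` (per trigger, s), `median`, `n`; flagged
#'   `undefined` when no qualifying pair exists.
#' @export
t1t2_intervals <- function(trigger_times, labels, times = NULL, T1, T2,
                           segment_s = 0.3) {
  if (is.null(times)) times <- (seq_along(labels) - 1L) * segment_s
  ends <- times + segment_s
  t1_ends <- ends[labels == T1]
  iv <- vapply(trigger_times, function(tr) {
    prev <- t1_ends[t1_ends < tr]
    if (length(prev) == 0L) return(NA_real_)
    tr - max(prev)
  }, numeric(1))
  iv <- iv[!is.na(iv)]
  if (length(iv) == 0L) {
    return(list(intervals = numeric(0), median = NA_real_, n = 0L,
                undefined = TRUE))
  }
  list(intervals = iv, median = stats::median(iv), n = length(iv),
       undefined = FALSE)
}

#' T2 -> T1 intervals at triggers
#'
#' Time distance between the end of the triggering T2 and the end of the next
#' closest T1.
#'
#' @inheritParams t1t2_intervals
#' @return as [t1t2_intervals()].
#' @export
t2t1_intervals <- function(trigger_times, labels, times = NULL, T1, T2,
                           segment_s = 0.3) {
  if (is.null(times)) times <- (seq_along(labels) - 1L) * segment_s
  ends <- times + segment_s
  t1_ends <- ends[labels == T1]
  iv <- vapply(trigger_times, function(tr) {
    nxt <- t1_ends[t1_ends > tr]
    if (length(nxt) == 0L) return(NA_real_)
    min(nxt) - tr
  }, numeric(1))
  iv <- iv[!is.na(iv)]
  if (length(iv) == 0L) {
    return(list(intervals = numeric(0), median = NA_real_, n = 0L,
                undefined = TRUE))
  }
  list(intervals = iv, median = stats::median(iv), n = length(iv),
       undefined = FALSE)
}

#' Actions uniquely similar to each sequence target
#'
#' Ranks all non-target actions by exemplar similarity to T1 and to T2, takes
#' the top `top_n` of each list, and removes actions common to both. If
#' either unique set has fewer than `min_unique` members the stringency is
#' relaxed to the top `fallback_n`; if that also fails, an error is raised.
#'
#' @param rep `action_repertoire` (or a similarity matrix).
#' @param T1,T2 target action ids.
#' @param top_n primary list length (default 12).
#' @param fallback_n relaxed list length (default 9).
#' @param min_unique minimum unique members per target (default 3).
#' @return list with `set_T1`, `set_T2` (integer ids), `n_used`.
#' @export
uniquely_similar_sets <- function(rep, T1, T2, top_n = 12L, fallback_n = 9L,
                                  min_unique = 3L) {
  S <- if (inherits(rep, "action_repertoire")) rep$S_ex else as.matrix(rep)
  K <- nrow(S)
  if (K < top_n) stopf("repertoire has %d actions; need at least top_n = %d", K, top_n)
  top <- function(target, n) {
    s <- S[target, ]
    s[c(T1, T2)] <- -Inf
    order(-s, seq_len(K))[seq_len(n)]
  }
  for (n in c(top_n, fallback_n)) {
    l1 <- top(T1, n); l2 <- top(T2, n)
    u1 <- setdiff(l1, l2); u2 <- setdiff(l2, l1)
    if (length(u1) >= min_unique && length(u2) >= min_unique) {
      return(list(set_T1 = sort(u1), set_T2 = sort(u2), n_used = n))
    }
  }
  stopf("fewer than %d uniquely similar actions per target even at top-%d",
        min_unique, fallback_n)
}

#' Refinement index of a target's uniquely similar actions
#'
#' The median target-normalized frequency of the actions uniquely similar to
#' the target. Values below 1 indicate refinement: the target is performed
#' preferentially relative to its similar neighbours.
#'
#' @param freqs named (or indexed) numeric vector of per-action frequencies
#'   for one session.
#' @param target target action id.
#' @param unique_set integer ids of the uniquely similar actions.
#' @return scalar index (>= 0), or `NA` when the target frequency is zero.
#' @export
refinement_index <- function(freqs, target, unique_set) {
  ft <- freqs[target]
  if (is.na(ft) || ft == 0) return(NA_real_)
  stats::median(freqs[unique_set]) / ft
}

#' Scale a refinement curve to its per-animal minimum
#'
#' Maps `x -> (x - m) / (1 - m)` with `m` the minimum over sessions, so the
#' minimum session scores 0 and an index of 1 remains 1. Requires `m < 1`.
#'
#' @param curve per-session refinement indices.
#' @return scaled curve.
#' @export
scale_refinement <- function(curve) {
  m <- min(curve, na.rm = TRUE)
  if (m >= 1) stopf("minimum refinement index is %g (>= 1); curve cannot be scaled", m)
  (curve - m) / (1 - m)
}

#' Savitzky-Golay smoothing for refinement curves
#'
#' Visualization/landmark smoothing (window 5 sessions, order 2); raw curves
#' should be retained alongside.
#'
#' @param curve numeric vector.
#' @param window odd window length (default 5).
#' @param order polynomial order (default 2).
#' @return smoothed vector (input returned unchanged when shorter than the
#'   window).
#' @export
smooth_refinement <- function(curve, window = 5L, order = 2L) {
  if (length(curve) < window) return(curve)
  as.numeric(signal::sgolayfilt(curve, p = order, n = window))
}

#' Differential refinement between T1 and T2 curves
#'
#' Trapezoid area under the T1 scaled-refinement curve minus that under the
#' T2 curve, summed across sessions up to `up_to` (by default the session by
#' which both curves have reached their minimum). Positive values indicate
#' differential refinement favouring T2 (its index is lower). The
#' per-session variant divides by the number of sessions analysed.
#'
#' @param curve_T1,curve_T2 scaled refinement curves on the same sessions.
#' @param up_to last session included; `NULL` for the both-at-minimum rule.
#' @return list with `D`, `per_session`, `up_to`.
#' @export
differential_refinement <- function(curve_T1, curve_T2, up_to = NULL) {
  if (length(curve_T1) != length(curve_T2)) {
    stopf("curves must be aligned on the same sessions")
  }
  if (is.null(up_to)) {
    up_to <- max(which.min(curve_T1), which.min(curve_T2))
  }
  stopifnot(up_to >= 1L, up_to <= length(curve_T1))
  trapz <- function(y) if (length(y) < 2L) 0 else sum((y[-1L] + y[-length(y)]) / 2)
  idx <- seq_len(up_to)
  D <- trapz(curve_T1[idx]) - trapz(curve_T2[idx])
  list(D = D, per_session = D / up_to, up_to = up_to)
}

#' Per-session refinement difference and the analysis starting point
#'
#' The per-session difference `D_s = scaled_T1(s) - scaled_T2(s)` is positive
#' when T2 is the more refined target. The starting point for progression
#' analysis is found by scanning retrospectively from the anchor session --
#' the first session whose median T1->T2 interval is at or below
#' `anchor_threshold` seconds -- for the latest earlier session with
#' `D_s <= 0` (T1 at least as refined as T2). If no such session exists, the
#' earliest session minimizing `|D_s|` before the anchor is used.
#'
#' @param curve_T1,curve_T2 scaled refinement curves.
#' @param t1t2_medians per-session median T1->T2 intervals (s).
#' @param anchor_threshold seconds (default 3).
#' @return list with `session`, `anchor_session`, `D` (per-session
#'   differences), `rule` ("balanced" or "closest").
#' @export
starting_point <- function(curve_T1, curve_T2, t1t2_medians,
                           anchor_threshold = 3) {
  stopifnot(length(curve_T1) == length(curve_T2),
            length(t1t2_medians) == length(curve_T1))
  D <- curve_T1 - curve_T2
  anchor <- which(t1t2_medians <= anchor_threshold)
  if (length(anchor) == 0L) {
    stopf("no session has median T1->T2 interval <= %g s", anchor_threshold)
  }
  anchor <- anchor[1L]
  early <- seq_len(anchor)
  bal <- early[D[early] <= 0]
  if (length(bal)) {
    list(session = max(bal), anchor_session = anchor, D = D, rule = "balanced")
  } else {
    list(session = early[which.min(abs(D[early]))], anchor_session = anchor,
         D = D, rule = "closest")
  }
}

#' Turning point of the starting-point-subtracted refinement difference
#'
#' Per-interval trapezoid areas of the T1 - T2 scaled-refinement difference
#' are computed from the starting point on; the initial interval's area is
#' subtracted from all subsequent ones (the starting-point-subtracted
#' refinement difference, positive when T2 outpaces T1 in refinement). The
#' turning point is the session carrying the local maximum of this
#' progression; for a monotone progression the last session is used and
#' flagged.
#'
#' @param curve_T1,curve_T2 scaled refinement curves.
#' @param start starting-point session (from [starting_point()]).
#' @return list with `session`, `progression` (named by session), and
#'   `monotone` flag.
#' @export
turning_point <- function(curve_T1, curve_T2, start) {
  n <- length(curve_T1)
  stopifnot(length(curve_T2) == n, start >= 1L, start < n)
  d <- curve_T1 - curve_T2
  # area over each inter-session interval [k, k+1]
  areas <- (d[start:(n - 1L)] + d[(start + 1L):n]) / 2
  prog <- areas - areas[1L]
  sessions <- (start + 1L):n
  names(prog) <- sessions
  if (length(prog) >= 3L) {
    interior <- 2L:(length(prog) - 1L)
    loc <- interior[prog[interior] > prog[interior - 1L] &
                      prog[interior] > prog[interior + 1L]]
  } else {
    loc <- integer(0)
  }
  if (length(loc)) {
    best <- loc[which.max(prog[loc])]
    list(session = sessions[best], progression = prog, monotone = FALSE)
  } else {
    # monotone (or end-tied) progression: use the last maximal session
    best <- max(which(prog == max(prog)))
    list(session = sessions[best], progression = prog, monotone = TRUE)
  }
}

#' Odds ratio of interval change before versus after the turning point
#'
#' The total change in a median interval from the open field to the criterion
#' session is split into the open-field-to-turning-point and
#' turning-point-to-criterion phases; the odds ratio is the ratio of the two
#' phases' proportions of the total change.
#'
#' @param iv_openfield,iv_turning,iv_criterion median intervals (s) at the
#'   three landmarks.
#' @param cap value substituted (and flagged) when the second-phase change is
#'   zero.
#' @return list with `ratio`, `prop_phase1`, `prop_phase2`, `capped`,
#'   `undefined` (total change zero).
#' @export
odds_ratio <- function(iv_openfield, iv_turning, iv_criterion, cap = Inf) {
  d1 <- iv_openfield - iv_turning
  d2 <- iv_turning - iv_criterion
  total <- d1 + d2
  if (total == 0) {
    return(list(ratio = NA_real_, prop_phase1 = NA_real_,
                prop_phase2 = NA_real_, capped = FALSE, undefined = TRUE))
  }
  p1 <- d1 / total; p2 <- d2 / total
  if (p2 == 0) {
    return(list(ratio = cap, prop_phase1 = p1, prop_phase2 = p2,
                capped = TRUE, undefined = FALSE))
  }
  list(ratio = p1 / p2, prop_phase1 = p1, prop_phase2 = p2, capped = FALSE,
       undefined = FALSE)
}

#' Percentile rank of T1's first-occurrence probability around T2 triggers
#'
#' For every trigger, the first occurrence of each action is located in 300 ms
#' bins up to `span_s` seconds before and after the trigger. Per bin, the
#' probability of each action appearing first there is computed across
#' triggers, and T1's probability is expressed as a percentile rank among all
#' actions (mid-rank for ties; 100 = most probable).
#'
#' @param trigger_times trigger times (s).
#' @param labels integer action ids per segment.
#' @param n_actions repertoire size.
#' @param T1 distal action id.
#' @param times segment start times; defaults to the grid.
#' @param span_s window half-width (default 6 s).
#' @param segment_s segment length.
#' @return data.frame with `bin_s` (signed bin centre offset; negative =
#'   before the trigger), `rank` (percentile), `prob_T1`.
#' @export
t1_rank_profile <- function(trigger_times, labels, n_actions, T1,
                            times = NULL, span_s = 6, segment_s = 0.3) {
  if (length(trigger_times) == 0L) stopf("at least one trigger required")
  if (is.null(times)) times <- (seq_along(labels) - 1L) * segment_s
  nb <- as.integer(round(span_s / segment_s))
  # bins are anchored at the performance segment of the triggering action:
  # trigger times are train onsets, one segment after that segment's start
  refs <- trigger_times - segment_s
  # counts[action, bin]: bins 1..nb pre, nb+1..2nb post
  cnt <- matrix(0, n_actions, 2L * nb)
  for (ref in refs) {
    for (a in seq_len(n_actions)) {
      occ <- times[labels == a]
      pre <- occ[occ < ref - 1e-9 & occ >= ref - span_s]
      if (length(pre)) {
        b <- as.integer(round((ref - max(pre)) / segment_s))
        if (b >= 1L && b <= nb) cnt[a, b] <- cnt[a, b] + 1
      }
      post <- occ[occ > ref + 1e-9 & occ <= ref + span_s]
      if (length(post)) {
        b <- as.integer(round((min(post) - ref) / segment_s))
        if (b >= 1L && b <= nb) cnt[a, nb + b] <- cnt[a, nb + b] + 1
      }
    }
  }
  prob <- cnt / length(trigger_times)
  pct <- vapply(seq_len(2L * nb), function(b) {
    r <- rank(prob[, b], ties.method = "average")[T1]
    100 * (r - 1) / (n_actions - 1)
  }, numeric(1))
  data.frame(bin_s = c(-(nb:1), 1:nb) * segment_s,
             rank = c(rev(pct[seq_len(nb)]), pct[(nb + 1L):(2L * nb)]),
             prob_T1 = c(rev(prob[T1, seq_len(nb)]), prob[T1, (nb + 1L):(2L * nb)]))
}

#' Pooled rank change over a bin range, baseline-subtracted
#'
#' Trapezoid area under the percentile-rank curve across the pre-trigger bins
#' in `range_s` (e.g. proximal 0.3-1.8 s or distal 2.1-3.6 s), normalized by
#' subtracting the same animal's baseline-stage area.
#'
#' @param profile data.frame from [t1_rank_profile()] for the stage.
#' @param baseline_profile the baseline-stage profile.
#' @param range_s numeric length-2 range of pre-trigger offsets (s).
#' @return scalar baseline-subtracted area.
#' @export
pooled_rank_change <- function(profile, baseline_profile,
                               range_s = c(0.3, 1.8)) {
  auc <- function(p) {
    sel <- p$bin_s <= -range_s[1L] & p$bin_s >= -range_s[2L]
    y <- p$rank[sel][order(p$bin_s[sel])]
    if (length(y) < 2L) return(0)
    sum((y[-1L] + y[-length(y)]) / 2) * 0.3
  }
  auc(profile) - auc(baseline_profile)
}

#' Four-parameter logistic fit of sessions-to-criterion against interval
#'
#' Fits `y = bottom + (top - bottom) / (1 + exp(-(x - x0)/k))` by nonlinear
#' least squares. The half-maximum response value divides subjects into fast
#' (below) and slow (above) learners; the curve midpoint `x0` is the interval
#' at half-maximum.
#'
#' @param x baseline median T1->T2 intervals (s).
#' @param y sessions to criterion.
#' @return list with `coefficients` (bottom, top, x0, k), `half_max`,
#'   `midpoint`, `classes` ("fast"/"slow" per point), `fit`.
#' @export
fit_sigmoid <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 5L)
  st <- list(bottom = min(y), top = max(y), x0 = stats::median(x),
             k = diff(range(x)) / 4)
  fit <- minpack.lm::nlsLM(y ~ bottom + (top - bottom) / (1 + exp(-(x - x0) / k)),
                           start = st,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  half <- (co[["bottom"]] + co[["top"]]) / 2
  list(coefficients = co, half_max = half, midpoint = co[["x0"]],
       classes = ifelse(y > half, "slow", "fast"), fit = fit)
}

#' Linear fit with non-zero-slope test
#'
#' @param x,y numeric vectors (>= 3 points).
#' @return list with `slope`, `intercept`, `r_squared`, `p_value` (F test for
#'   non-zero slope), `fit`.
#' @export
fit_linear <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- stats::pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
                 lower.tail = FALSE)
  list(slope = stats::coef(fit)[["x"]], intercept = stats::coef(fit)[["(Intercept)"]],
       r_squared = sm$r.squared, p_value = unname(p), fit = fit)
}

#' Reinforcement-matched scaled learning curves
#'
#' Sequence rate is computed over consecutive spans of `bin` reinforcements,
#' smoothed (Savitzky-Golay), and anchored so the initial bin scores 0 and
#' the maximal bin 1. The criterion bin is the first crossing 25\% of the
#' maximal scaled frequency.
#'
#' @param trigger_times cumulative reinforcement times (s) across sessions.
#' @param bin reinforcements per bin (default 200).
#' @param criterion_frac criterion as a fraction of maximum (default 0.25).
#' @return list with `rate` (per-bin /min), `scaled`, `criterion_bin`
#'   (`NA`, flagged `degenerate`, when the curve has no dynamic range).
#' @export
matched_reinforcement_curves <- function(trigger_times, bin = 200L,
                                         criterion_frac = 0.25) {
  n <- length(trigger_times)
  if (n < 2L * bin) stopf("need at least %d reinforcements (2 bins)", 2L * bin)
  nb <- n %/% bin
  rate <- vapply(seq_len(nb), function(b) {
    idx <- ((b - 1L) * bin + 1L):(b * bin)
    span <- max(trigger_times[idx]) - min(trigger_times[idx])
    if (span <= 0) return(NA_real_)
    (bin - 1L) / (span / 60)
  }, numeric(1))
  sm <- smooth_refinement(rate)
  rng <- max(sm) - sm[1L]
  if (!is.finite(rng) || rng <= 0) {
    return(list(rate = rate, scaled = rep(NA_real_, nb), criterion_bin = NA,
                degenerate = TRUE))
  }
  scaled <- (sm - sm[1L]) / rng
  hit <- which(scaled >= criterion_frac)
  list(rate = rate, scaled = scaled,
       criterion_bin = if (length(hit)) hit[1L] else NA_integer_,
       degenerate = FALSE)
}
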