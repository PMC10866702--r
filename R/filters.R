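#' Probability that a target or its most similar actions reappear in a window
#'
#' For each onset of the target action, computes the indicator that the target
#' or any of its `n_similar` most similar actions (by exemplar similarity,
#' ties to the lowest id) occurs again in the window `(t + 3 s, t + 18 s]`.
#' The per-candidate probabilities (one for the target itself and one for each
#' similar action) summarize how serially the action tends to be performed.
#'
#' @param labels integer action id per 300 ms segment.
#' @param target action id.
#' @param rep `action_repertoire` supplying exemplar similarities.
#' @param window numeric length-2, seconds after each onset; default `c(3, 18)`.
#' @param n_similar number of most-similar actions considered (default 5).
#' @param segment_s segment length in seconds.
#' @return list with `median`, `range`, `prob_any` (probability that any
#'   candidate reappears), `per_candidate` probabilities, `n_onsets`.
#'   If the target never occurs the result is `NA` with `undefined = TRUE`.
#' @export
repeat_window_probability <- function(labels, target, rep, window = c(3, 18),
                                      n_similar = 5L, segment_s = 0.3) {
  stopifnot(inherits(rep, "action_repertoire"))
  onsets <- which(labels == target & c(TRUE, labels[-length(labels)] != target))
  # only onsets whose full window lies inside the session are informative
  # (sessions are expected to extend past the last occurrence by the window)
  onsets <- onsets[onsets + floor(window[2] / segment_s) <= length(labels)]
  if (length(onsets) == 0L) {
    return(list(median = NA_real_, range = NA_real_, prob_any = NA_real_,
                per_candidate = numeric(0), n_onsets = 0L, undefined = TRUE))
  }
  sims <- rep$S_ex[target, ]
  sims[target] <- -Inf
  similar <- order(-sims, seq_along(sims))[seq_len(min(n_similar, length(sims) - 1L))]
  candidates <- c(target, similar)
  lo <- ceiling(window[1] / segment_s)
  hi <- floor(window[2] / segment_s)
  per <- vapply(candidates, function(cand) {
    mean(vapply(onsets, function(o) {
      idx <- (o + lo):(o + hi)
      idx <- idx[idx <= length(labels) & idx > o]
      length(idx) > 0L && any(labels[idx] == cand)
    }, logical(1)))
  }, numeric(1))
  any_p <- mean(vapply(onsets, function(o) {
    idx <- (o + lo):(o + hi)
    idx <- idx[idx <= length(labels) & idx > o]
    length(idx) > 0L && any(labels[idx] %in% candidates)
  }, logical(1)))
  list(median = stats::median(per), range = diff(range(per)), prob_any = any_p,
       per_candidate = stats::setNames(per, candidates),
       n_onsets = length(onsets), undefined = FALSE)
}

#' Sensitivity of cluster matching to anterior-posterior sensor shifts
#'
#' Re-featurizes a session with the GAap series shifted by `+delta` and
#' `-delta`, re-matches every segment against the repertoire exemplars, and
#' reports the percentage deviation from the original matching:
#' the summed label changes of the two shifted datasets divided by two,
#' divided by the total number of original cluster calls, times 100.
#'
#' @param feats a `feature_series` (see [feature_series()]).
#' @param rep `action_repertoire`.
#' @param delta shift magnitude in g; defaults to one GAap interior bin width.
#' @param bins `feature_bins` used for featurization.
#' @return list with `percent_deviation` overall and `per_cluster` data.frame
#'   (percentage of each original cluster's calls that flipped, same
#'   two-direction averaging).
#' @export
shift_sensitivity <- function(feats, rep, delta = NULL, bins = feature_bins()) {
  if (is.null(delta)) delta <- diff(bins$thresholds$gaap[1:2])
  stopifnot(delta > 0)
  orig <- match_segments(segment_histograms(feats, bins), rep)
  shifted_labels <- lapply(c(delta, -delta), function(d) {
    f2 <- feats
    f2$gaap <- feats$gaap + d
    match_segments(segment_histograms(f2, bins), rep)
  })
  changes <- vapply(shifted_labels, function(l) sum(l != orig), numeric(1))
  total <- length(orig)
  per <- vapply(seq_len(rep$n_actions), function(c) {
    n_c <- sum(orig == c)
    if (n_c == 0L) return(NA_real_)
    ch <- vapply(shifted_labels, function(l) sum(l != orig & orig == c), numeric(1))
    mean(ch) / n_c * 100
  }, numeric(1))
  list(percent_deviation = mean(changes) / total * 100,
       per_cluster = data.frame(action = seq_len(rep$n_actions),
                                percent_deviation = per))
}

#' Filter the repertoire for actions eligible as reinforcement targets
#'
#' Applies the five eligibility criteria used to choose closed-loop target
#' actions. An action survives only if it passes all of:
#' \enumerate{
#'   \item low false-positive rate: below 5.5\% *and* below the 60th
#'     percentile of false-positive rates across the repertoire;
#'   \item not a high false-negative action (above the 90th percentile);
#'   \item not serially repeated: neither the median nor the range of its
#'     3-18 s reappearance probabilities exceeds the 90th percentile;
#'   \item not shift-sensitive: percentage deviation under anterior-posterior
#'     sensor shifts at or below the 90th percentile;
#'   \item fully accelerating movement: the exemplar's TotBA histogram has
#'     value 1 in the moving bin.
#' }
#'
#' @param rep `action_repertoire`.
#' @param error_rates data.frame from [match_error_rates()].
#' @param repeat_stats data.frame with columns `action`, `median`, `range`
#'   (from [repeat_window_probability()] per action).
#' @param shift_dev numeric vector of per-action percentage deviations
#'   (from [shift_sensitivity()]).
#' @param fp_max absolute false-positive ceiling (default 0.055).
#' @param fp_pct,fn_pct,repeat_pct,shift_pct percentile cut-offs.
#' @return integer vector of surviving action ids (possibly empty, with a
#'   warning). The `criteria` attribute holds the per-action logical matrix.
#' @export
filter_eligible_targets <- function(rep, error_rates, repeat_stats, shift_dev,
                                    fp_max = 0.055, fp_pct = 0.60,
                                    fn_pct = 0.90, repeat_pct = 0.90,
                                    shift_pct = 0.90) {
  k <- rep$n_actions
  fp <- error_rates$fp[match(seq_len(k), error_rates$action)]
  fn <- error_rates$fn[match(seq_len(k), error_rates$action)]
  rmed <- repeat_stats$median[match(seq_len(k), repeat_stats$action)]
  rrng <- repeat_stats$range[match(seq_len(k), repeat_stats$action)]
  stopifnot(length(shift_dev) == k)
  q <- function(x, p) stats::quantile(x, p, na.rm = TRUE, names = FALSE)
  c1 <- !is.na(fp) & fp < fp_max & fp < q(fp, fp_pct)
  c2 <- !is.na(fn) & fn <= q(fn, fn_pct)
  c3 <- !is.na(rmed) & rmed <= q(rmed, repeat_pct) & rrng <= q(rrng, repeat_pct)
  c4 <- !is.na(shift_dev) & shift_dev <= q(shift_dev, shift_pct)
  c5 <- vapply(rep$exemplars, function(e) isTRUE(all.equal(e$totba[2], 1)), logical(1))
  keep <- c1 & c2 & c3 & c4 & c5
  out <- which(keep)
  if (length(out) == 0L) warning("no actions pass all five eligibility criteria")
  attr(out, "criteria") <- cbind(low_fp = c1, low_fn = c2, non_repeating = c3,
                                 shift_stable = c4, full_moving = c5)
  out
}

# weighted median bin index of a histogram
#' @keywords internal
median_bin <- function(p) {
  cs <- cumsum(p)
  which(cs >= 0.5)[1L]
}

#' Select a maximally dissimilar action pair from a repertoire
#'
#' Pools all exemplar histogram mass to find the occupied (non-zero) bin range
#' of the GAap and GYRdv features, splits that range into low/middle/high
#' thirds, and picks action A from the exemplars whose median GAap and GYRdv
#' bins fall in the high group and action B from the low group (or the
#' reverse, under `orientation = "low_first"`). Alternating the orientation
#' across subjects spreads target identities over the action space; use
#' [make_pair_selector()] for an alternation-tracking selector.
#'
#' @param rep `action_repertoire`.
#' @param eligible optional integer ids to restrict the candidate pool.
#' @param orientation `"high_first"` (A = high GAap/GYRdv) or `"low_first"`.
#' @return list with `A`, `B` action ids, the `orientation` used, and the
#'   candidate pools.
#' @export
select_dissimilar_pair <- function(rep, eligible = seq_len(rep$n_actions),
                                   orientation = c("high_first", "low_first")) {
  orientation <- match.arg(orientation)
  med_bins <- function(feat) {
    pooled <- Reduce(`+`, lapply(rep$exemplars, `[[`, feat))
    occ <- which(pooled > 0)
    lo_edge <- occ[1L] + (occ[length(occ)] - occ[1L]) / 3
    hi_edge <- occ[length(occ)] - (occ[length(occ)] - occ[1L]) / 3
    m <- vapply(rep$exemplars, function(e) median_bin(e[[feat]]), numeric(1))
    list(high = m >= hi_edge, low = m <= lo_edge)
  }
  ga <- med_bins("gaap")
  gy <- med_bins("gyrdv")
  high_pool <- intersect(eligible, which(ga$high & gy$high))
  low_pool <- intersect(eligible, which(ga$low & gy$low))
  if (length(high_pool) == 0L) stopf("no eligible exemplar in the high GAap/GYRdv group")
  if (length(low_pool) == 0L) stopf("no eligible exemplar in the low GAap/GYRdv group")
  first_pool <- if (orientation == "high_first") high_pool else low_pool
  second_pool <- if (orientation == "high_first") low_pool else high_pool
  A <- first_pool[1L]
  second_pool <- setdiff(second_pool, A)
  if (length(second_pool) == 0L) {
    stopf("no eligible exemplar left in the %s GAap/GYRdv group",
          if (orientation == "high_first") "low" else "high")
  }
  list(A = A, B = second_pool[1L], orientation = orientation,
       high_pool = high_pool, low_pool = low_pool)
}

#' Pair selector that alternates the A/B criterion across calls
#'
#' Successive subjects receive reversed selection criteria for actions A and
#' B, so that targets are broadly distributed over the action space.
#'
#' @return a function with the same signature as [select_dissimilar_pair()]
#'   minus `orientation`; each call flips the orientation used.
#' @export
make_pair_selector <- function() {
  state <- new.env(parent = emptyenv())
  state$next_orientation <- "high_first"
  function(rep, eligible = seq_len(rep$n_actions)) {
    ori <- state$next_orientation
    state$next_orientation <- if (ori == "high_first") "low_first" else "high_first"
    select_dissimilar_pair(rep, eligible, orientation = ori)
  }
}
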