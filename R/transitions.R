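#' Lag grid for the retrospective transition-window analysis
#'
#' Transitions are 600 ms events spanning two consecutive 300 ms segments;
#' a transition's lag is the onset of its first segment relative to the
#' stimulation onset. The grid spans 2.4 s before to 2.4 s after stimulation,
#' so transition onsets run from -2.4 s to +1.8 s in 300 ms steps (15 lags).
#' A sliding 1.2 s window holds 3 transition onsets; the remaining 12 lags
#' (3.6 s of onsets) form the surrounding "outside" span.
#'
#' @param span_s half-width of the grid (s; default 2.4).
#' @param window_s within-window length (s; default 1.2).
#' @param segment_s segment length.
#' @return object of class `window_grid` with `lags` (transition onsets, s),
#'   `window_s`, `n_within` (transitions per window), `window_starts`
#'   (candidate within-window start lags).
#' @export
window_grid <- function(span_s = 2.4, window_s = 1.2, segment_s = 0.3) {
  trans_s <- 2 * segment_s
  lags <- seq(-span_s, span_s - trans_s, by = segment_s)
  n_within <- as.integer(round((window_s - trans_s) / segment_s)) + 1L
  starts <- lags[seq_len(length(lags) - n_within + 1L)]
  structure(list(lags = round(lags, 10), window_s = window_s,
                 n_within = n_within, window_starts = round(starts, 10),
                 segment_s = segment_s),
            class = "window_grid")
}

#' @keywords internal
transition_key <- function(from, to) paste(from, to, sep = "->")

#' Count transition types at each lag around triggers
#'
#' For every trigger and every grid lag, the 600 ms transition whose first
#' segment starts at `trigger + lag` is identified and counted per
#' transition type (X->Y over two adjacent segments), summing over triggers.
#'
#' @param trigger_times stimulation onsets (s), e.g. from
#'   [simulated_triggers()] for the baseline condition.
#' @param labels integer action ids per segment.
#' @param times segment start times; defaults to the 300 ms grid.
#' @param grid `window_grid`.
#' @return matrix of counts, rows = transition types (named "X->Y"),
#'   columns = lags (named by lag seconds). Empty when no triggers.
#' @export
window_counts <- function(trigger_times, labels, times = NULL,
                          grid = window_grid()) {
  if (is.null(times)) times <- (seq_along(labels) - 1L) * grid$segment_s
  L <- length(grid$lags)
  if (length(trigger_times) == 0L) {
    return(matrix(numeric(0), 0L, L, dimnames = list(NULL, grid$lags)))
  }
  t0 <- times[1L]
  seg <- grid$segment_s
  rows <- list()
  counts <- new.env(parent = emptyenv())
  for (tr in trigger_times) {
    for (j in seq_len(L)) {
      i <- round((tr + grid$lags[j] - t0) / seg) + 1L
      if (i < 1L || i + 1L > length(labels)) next
      key <- transition_key(labels[i], labels[i + 1L])
      v <- counts[[key]]
      if (is.null(v)) v <- numeric(L)
      v[j] <- v[j] + 1
      counts[[key]] <- v
    }
  }
  keys <- sort(ls(counts))
  out <- do.call(rbind, lapply(keys, function(k) counts[[k]]))
  if (is.null(out)) out <- matrix(numeric(0), 0L, L)
  dimnames(out) <- list(keys, grid$lags)
  out
}

#' Per-type probabilities across lag windows
#'
#' Each transition type's count at a lag is divided by the type's total count
#' over all lags, giving a probability profile per type that sums to one.
#' Types with zero total count are dropped.
#'
#' @param counts matrix from [window_counts()].
#' @return probability matrix with the same shape (zero-total rows removed).
#' @export
window_probabilities <- function(counts) {
  tot <- rowSums(counts)
  counts <- counts[tot > 0, , drop = FALSE]
  counts / rowSums(counts)
}

#' Differential probability of transition types in a within-window
#'
#' The probability mass of a type inside the 1.2 s within-window minus its
#' mass in the 3.6 s outside span scaled to the same window length
#' (outside mass times `n_within / n_outside`), so a type occurring uniformly
#' over the grid scores 0 and a type occurring only inside scores its full
#' within probability.
#'
#' @param probs probability matrix from [window_probabilities()].
#' @param window_start lag (s) at which the within-window starts; must be one
#'   of `grid$window_starts`.
#' @param grid `window_grid`.
#' @return named numeric vector of differential-probability scores per type.
#' @export
differential_probability <- function(probs, window_start, grid = window_grid()) {
  j0 <- which(abs(grid$window_starts - window_start) < 1e-9)
  if (length(j0) != 1L) stopf("window_start %g is not on the grid", window_start)
  within_idx <- which(abs(grid$lags - window_start) < 1e-9) + 0:(grid$n_within - 1L)
  outside_idx <- setdiff(seq_along(grid$lags), within_idx)
  p_in <- rowSums(probs[, within_idx, drop = FALSE])
  p_out <- rowSums(probs[, outside_idx, drop = FALSE])
  p_in - p_out * (length(within_idx) / length(outside_idx))
}

#' Filter transition types enriched in a window
#'
#' @param scores differential-probability scores.
#' @param threshold minimum score (default 0.001).
#' @return character vector of enriched type names.
#' @export
enrich_filter <- function(scores, threshold = 0.001) {
  names(scores)[scores >= threshold]
}

#' Filter transition types by baseline occurrence count
#'
#' Keeps types that occurred 2 to 6 times (inclusive) during the baseline
#' period -- frequent enough to not be single events, rare enough to have low
#' initial frequency (0.067 to 0.2 transitions per minute over 30 min).
#'
#' @param type_totals named numeric vector of baseline occurrence counts per
#'   type (all occurrences, not only those near triggers).
#' @param lo,hi inclusive bounds (defaults 2 and 6).
#' @return character vector of retained type names.
#' @export
baseline_count_filter <- function(type_totals, lo = 2, hi = 6) {
  names(type_totals)[type_totals >= lo & type_totals <= hi]
}

#' Count all occurrences of each transition type in a label stream
#'
#' @param labels integer action ids per segment.
#' @return named numeric vector of counts per "X->Y" type.
#' @export
transition_totals <- function(labels) {
  if (length(labels) < 2L) return(stats::setNames(numeric(0), character(0)))
  keys <- transition_key(labels[-length(labels)], labels[-1L])
  tab <- table(keys)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Track baseline-normalized frequencies of enriched transition types
#'
#' For each lag window's enriched type set, each session's frequency of every
#' type (all occurrences, regardless of distance to the target) is normalized
#' to its baseline frequency; values are averaged within animals first and
#' the animal means are then averaged, producing animal-balanced trajectories
#' per lag window and session.
#'
#' @param enriched list (one element per animal) of lists mapping lag-window
#'   name to a character vector of enriched type names.
#' @param session_labels list per animal of lists per session of label
#'   vectors.
#' @param baseline_labels list per animal of baseline label vectors.
#' @param baseline_min,session_min durations (min) used to convert counts to
#'   per-minute rates.
#' @return matrix lag-window x session of animal-balanced normalized
#'   frequencies (`NaN` where no animal contributes, flagged by attribute
#'   `n_animals`).
#' @export
track_enriched <- function(enriched, session_labels, baseline_labels,
                           baseline_min = 30, session_min = 60) {
  stopifnot(length(enriched) == length(session_labels),
            length(enriched) == length(baseline_labels))
  windows <- unique(unlist(lapply(enriched, names)))
  n_sessions <- max(vapply(session_labels, length, integer(1)))
  out <- matrix(NA_real_, length(windows), n_sessions,
                dimnames = list(windows, NULL))
  n_anim <- matrix(0L, length(windows), n_sessions)
  for (w in seq_along(windows)) {
    for (s in seq_len(n_sessions)) {
      per_animal <- c()
      for (a in seq_along(enriched)) {
        types <- enriched[[a]][[windows[w]]]
        if (is.null(types) || length(types) == 0L) next
        if (length(session_labels[[a]]) < s) next
        base <- transition_totals(baseline_labels[[a]]) / baseline_min
        ses <- transition_totals(session_labels[[a]][[s]]) / session_min
        bf <- base[types]
        sf <- ses[types]
        sf[is.na(sf)] <- 0
        norm <- sf / bf
        norm <- norm[is.finite(norm)]
        if (length(norm)) per_animal <- c(per_animal, mean(norm))
      }
      if (length(per_animal)) {
        out[w, s] <- mean(per_animal)
        n_anim[w, s] <- length(per_animal)
      }
    }
  }
  attr(out, "n_animals") <- n_anim
  out
}
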