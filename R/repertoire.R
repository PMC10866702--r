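#' Cluster segment histograms into an action repertoire
#'
#' Runs affinity propagation on the pairwise EMD similarity matrix of the
#' per-segment feature histograms, with the preference parameter set to the
#' minimal value of the similarity matrix. Each resulting cluster is an
#' "action"; its exemplar histogram set is the representative used for online
#' matching.
#'
#' @param hists list of `hist_set` objects (one per 300 ms segment).
#' @param S optional precomputed similarity matrix (see [similarity_matrix()]).
#' @param ... passed to [affinity_propagation()].
#' @return an `action_repertoire`: list with `exemplars` (list of `hist_set`),
#'   `exemplar_index` (segment index of each exemplar), `labels` (action id
#'   per input segment), `n_actions`, and `S_ex` (exemplar-vs-exemplar
#'   similarity matrix).
#' @export
cluster_repertoire <- function(hists, S = NULL, ...) {
  stopifnot(length(hists) >= 1L)
  if (is.null(S)) S <- similarity_matrix(hists)
  ap <- affinity_propagation(S, ...)
  exemplars <- hists[ap$exemplars]
  structure(list(exemplars = exemplars,
                 exemplar_index = ap$exemplars,
                 labels = ap$labels,
                 n_actions = length(ap$exemplars),
                 S_ex = similarity_matrix(exemplars),
                 ap_iterations = ap$iterations),
            class = "action_repertoire")
}

#' Build a repertoire directly from known prototype histogram sets
#'
#' Convenience constructor used when the exemplars are given (for example the
#' prototypes of a synthetic agent) rather than discovered by clustering.
#'
#' @param exemplars list of `hist_set` objects.
#' @param labels optional per-segment action ids.
#' @return `action_repertoire`.
#' @export
as_action_repertoire <- function(exemplars, labels = integer(0)) {
  stopifnot(length(exemplars) >= 1L)
  structure(list(exemplars = exemplars,
                 exemplar_index = seq_along(exemplars),
                 labels = as.integer(labels),
                 n_actions = length(exemplars),
                 S_ex = similarity_matrix(exemplars)),
            class = "action_repertoire")
}

#' @export
print.action_repertoire <- function(x, ...) {
  cat(sprintf("<action_repertoire> %d actions, %d labelled segments\n",
              x$n_actions, length(x$labels)))
  invisible(x)
}

#' Match a histogram set to the most similar exemplar
#'
#' Online classification: the segment is assigned to the action whose exemplar
#' comparison gives the highest similarity score (equivalently, lowest EMD).
#' Exact ties are broken by the lowest action id.
#'
#' @param h a `hist_set`.
#' @param rep an `action_repertoire`.
#' @return integer action id in `1:rep$n_actions`.
#' @export
match_to_exemplar <- function(h, rep) {
  stopifnot(inherits(rep, "action_repertoire"), rep$n_actions >= 1L)
  scores <- vapply(rep$exemplars, emd_similarity, numeric(1), h1 = h)
  which.max(scores) # first (= lowest id) among tied maxima
}

#' Match a list of histogram sets to exemplars
#' @param hists list of `hist_set`.
#' @param rep an `action_repertoire`.
#' @return integer vector of action ids.
#' @export
match_segments <- function(hists, rep) {
  vapply(hists, match_to_exemplar, integer(1), rep = rep)
}

#' Per-cluster false-positive and false-negative matching rates
#'
#' Evaluates the precision with which exemplar matching reproduces reference
#' labels (typically the affinity-propagation labels of the same data, or
#' ground-truth labels of held-out synthetic segments).
#'
#' @param assigned integer action ids returned by the matcher.
#' @param truth integer reference action ids (same length).
#' @param n_actions number of actions (defaults to max id observed).
#' @return data.frame with `action`, `fp` (fraction of segments assigned to
#'   the action whose true label differs), `fn` (fraction of true members
#'   assigned elsewhere), `n_assigned`, `n_true`. Rates for empty clusters are
#'   `NA` and flagged in the `undefined` column.
#' @export
match_error_rates <- function(assigned, truth, n_actions = max(assigned, truth)) {
  stopifnot(length(assigned) == length(truth))
  out <- data.frame(action = seq_len(n_actions), fp = NA_real_, fn = NA_real_,
                    n_assigned = 0L, n_true = 0L, undefined = FALSE)
  for (c in seq_len(n_actions)) {
    na <- sum(assigned == c)
    nt <- sum(truth == c)
    out$n_assigned[c] <- na
    out$n_true[c] <- nt
    if (na > 0L) out$fp[c] <- sum(assigned == c & truth != c) / na
    if (nt > 0L) out$fn[c] <- sum(truth == c & assigned != c) / nt
    out$undefined[c] <- na == 0L || nt == 0L
  }
  out
}
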