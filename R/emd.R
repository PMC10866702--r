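#' One-dimensional earth-mover's distance between two histograms
#'
#' For histograms on a common ordered bin grid the earth-mover's (Wasserstein-1)
#' distance has the closed form \eqn{\sum_k |C_p(k) - C_q(k)|} where \eqn{C}
#' are cumulative sums. The ground distance between adjacent bins is
#' \eqn{1/(n_{bins}-1)}, so the distance of any pair of probability vectors
#' lies in \eqn{[0, 1]}: 0 for identical histograms and 1 when all mass sits
#' at opposite extreme bins.
#'
#' @param p,q probability vectors over the same bins (equal length >= 2).
#' @return scalar normalized EMD in \eqn{[0, 1]}.
#' @export
emd_1d <- function(p, q) {
  if (length(p) != length(q)) stopf("bin mismatch: %d vs %d", length(p), length(q))
  if (length(p) < 2L) stopf("need at least 2 bins")
  sum(abs(cumsum(p - q))) / (length(p) - 1L)
}

#' Earth-mover's-distance similarity between two feature histogram sets
#'
#' The behavioural similarity score is \eqn{S = -(dEM/4)^2}, where dEM is the
#' sum of the four per-feature normalized EM distances (GAap, ACCdv, GYRdv,
#' TotBA). The bin normalization in [emd_1d()] bounds each per-feature
#' distance by 1, so \eqn{S \in [-1, 0]}: 0 denotes identity and -1 maximum
#' dissimilarity between the two distributions.
#'
#' @param h1,h2 `hist_set` objects with matching bin structure.
#' @return similarity score in \eqn{[-1, 0]}.
#' @export
#' @examples
#' b <- feature_bins()
#' h <- hist_set(rep(1/11, 11), rep(1/11, 11), rep(1/6, 6), c(0.5, 0.5))
#' emd_similarity(h, h)  # 0
emd_similarity <- function(h1, h2) {
  stopifnot(inherits(h1, "hist_set"), inherits(h2, "hist_set"))
  dEM <- emd_1d(h1$gaap, h2$gaap) + emd_1d(h1$accdv, h2$accdv) +
    emd_1d(h1$gyrdv, h2$gyrdv) + emd_1d(h1$totba, h2$totba)
  -(dEM / 4)^2 + 0 # + 0 normalizes the signed zero of identical inputs
}

#' Pairwise similarity matrix over a list of histogram sets
#'
#' @param hists list of `hist_set` objects.
#' @return symmetric matrix with entries in \eqn{[-1, 0]} and zero diagonal,
#'   of class `similarity_matrix`.
#' @export
similarity_matrix <- function(hists) {
  n <- length(hists)
  if (n < 1L) stopf("empty histogram list")
  # stack per-feature cumulative sums once; the pairwise distance is then a
  # matrix of absolute cumulative differences
  feats <- c("gaap", "accdv", "gyrdv", "totba")
  d <- matrix(0, n, n)
  for (f in feats) {
    cs <- vapply(hists, function(h) cumsum(h[[f]]),
                 numeric(length(hists[[1L]][[f]])))
    nb <- nrow(cs)
    for (i in seq_len(n - 1L)) {
      di <- colSums(abs(cs[, (i + 1L):n, drop = FALSE] - cs[, i])) / (nb - 1L)
      d[i, (i + 1L):n] <- d[i, (i + 1L):n] + di
    }
  }
  S <- -(d / 4)^2 + 0
  S <- S + t(S)
  diag(S) <- 0
  class(S) <- c("similarity_matrix", class(S))
  S
}
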