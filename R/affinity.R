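#' Affinity propagation clustering
#'
#' Frey-Dueck affinity propagation on a similarity matrix: messages
#' (responsibilities and availabilities) are exchanged until the exemplar set
#' is stable. The update is fully deterministic -- no noise is injected -- so
#' repeated runs on identical input give identical labels, which matters
#' because the exemplars seed the online matcher.
#'
#' @param S square similarity matrix (larger = more similar).
#' @param preference diagonal self-similarity; default the minimum of `S`,
#'   which favours a stable, data-driven number of clusters.
#' @param damping message damping factor in \[0.5, 1).
#' @param max_iter maximum number of message-passing iterations.
#' @param conv_iter number of consecutive iterations with an unchanged
#'   exemplar set required to declare convergence.
#' @return list with `exemplars` (sorted indices), `labels` (cluster index per
#'   row, 1..K referring into `exemplars`), `iterations`, `converged`.
#' @export
affinity_propagation <- function(S, preference = min(S), damping = 0.9,
                                 max_iter = 1000L, conv_iter = 50L) {
  S <- unclass(S)
  stopifnot(is.matrix(S), nrow(S) == ncol(S), damping >= 0.5, damping < 1)
  n <- nrow(S)
  if (n == 1L) {
    return(list(exemplars = 1L, labels = 1L, iterations = 0L, converged = TRUE))
  }
  off <- S[row(S) != col(S)]
  if (max(off) - min(off) < 1e-12) {
    # degenerate input: all points mutually equidistant (e.g. identical
    # segments); message passing carries no evidence, so collapse to one
    # cluster anchored at the first point
    return(list(exemplars = 1L, labels = rep(1L, n), iterations = 0L,
                converged = TRUE))
  }
  diag(S) <- preference
  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  stable <- 0L
  last_ex <- integer(0)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + S
    max1 <- apply(AS, 1L, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1L, max)
    Rmax <- matrix(max1, n, n)
    Rmax[cbind(seq_len(n), which1)] <- max2
    R <- damping * R + (1 - damping) * (S - Rmax)
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(R) + diag(A) > 0)
    if (length(ex) > 0L && identical(ex, last_ex)) {
      stable <- stable + 1L
      if (stable >= conv_iter) break
    } else {
      stable <- 0L
      last_ex <- ex
    }
  }
  ex <- which(diag(R) + diag(A) > 0)
  if (length(ex) == 0L) {
    stopf("affinity propagation failed to identify exemplars after %d iterations", it)
  }
  converged <- stable >= conv_iter
  if (!converged && it >= max_iter) {
    stopf(paste0("affinity propagation did not converge: %d iterations, ",
                 "%d stable iterations (need %d), %d provisional exemplars"),
          it, stable, conv_iter, length(ex))
  }
  # assign each point to the best exemplar; exemplars belong to themselves
  lab <- max.col(S[, ex, drop = FALSE], ties.method = "first")
  lab[ex] <- seq_along(ex)
  list(exemplars = ex, labels = lab, iterations = it, converged = converged)
}
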