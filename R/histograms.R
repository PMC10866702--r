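#' Discretization thresholds for the four featurization channels
#'
#' The per-segment summary of behaviour uses four features: gravitational
#' acceleration along the anterior-posterior axis (GAap, g), raw dorsal-ventral
#' acceleration (ACCdv, g), the dorsal-ventral gyroscope rate (GYRdv, deg/s)
#' and total body acceleration (TotBA, g). GAap and ACCdv use ten equally
#' spaced thresholds spanning a configured range, which together with the two
#' unbounded outer bins gives 11 bins per feature. GYRdv uses the five fixed
#' thresholds 0, +/-50, +/-100 deg/s (6 bins) so that left and right turns are
#' discriminated. TotBA uses a single resting/moving threshold (2 bins), fixed
#' once per dataset (see [rest_threshold()]).
#'
#' @param gaap_range,accdv_range numeric length-2; span of the ten equally
#'   spaced thresholds for GAap and ACCdv. Defaults \eqn{[-1, 1]} g and
#'   \eqn{[-2, 2]} g.
#' @param totba_threshold scalar resting/moving threshold in g.
#' @return an object of class `feature_bins`: a list of threshold vectors
#'   (`gaap`, `accdv`, `gyrdv`, `totba`) with bin counts 11, 11, 6, 2.
#' @export
#' @examples
#' b <- feature_bins()
#' lengths(b$thresholds) + 1L  # bins per feature
feature_bins <- function(gaap_range = c(-1, 1), accdv_range = c(-2, 2),
                         totba_threshold = 0.05) {
  stopifnot(length(gaap_range) == 2, length(accdv_range) == 2,
            gaap_range[1] < gaap_range[2], accdv_range[1] < accdv_range[2],
            is.numeric(totba_threshold), totba_threshold > 0)
  thr <- list(
    gaap  = seq(gaap_range[1], gaap_range[2], length.out = 10L),
    accdv = seq(accdv_range[1], accdv_range[2], length.out = 10L),
    gyrdv = c(-100, -50, 0, 50, 100),
    totba = totba_threshold
  )
  structure(list(thresholds = thr,
                 n_bins = vapply(thr, function(t) length(t) + 1L, integer(1))),
            class = "feature_bins")
}

#' @keywords internal
discretize_feature <- function(x, thresholds) {
  # bins: (-Inf, t1], (t1, t2], ..., (t_k, Inf)
  idx <- findInterval(x, thresholds, left.open = TRUE) + 1L
  tabulate(idx, nbins = length(thresholds) + 1L)
}

#' Construct a four-feature histogram set
#'
#' A `hist_set` summarizes one 300 ms segment as four probability vectors over
#' the GAap, ACCdv, GYRdv and TotBA discretization bins. Each histogram must
#' be non-negative and sum to 1 (to 1e-9); `normalize = TRUE` rescales counts.
#'
#' @param gaap,accdv,gyrdv,totba numeric probability (or count) vectors with
#'   11, 11, 6 and 2 elements respectively.
#' @param normalize divide each vector by its sum first?
#' @return object of class `hist_set`.
#' @export
hist_set <- function(gaap, accdv, gyrdv, totba, normalize = FALSE) {
  h <- list(gaap = as.numeric(gaap), accdv = as.numeric(accdv),
            gyrdv = as.numeric(gyrdv), totba = as.numeric(totba))
  expected <- c(gaap = 11L, accdv = 11L, gyrdv = 6L, totba = 2L)
  for (nm in names(h)) {
    if (length(h[[nm]]) != expected[[nm]]) {
      stopf("feature '%s' must have %d bins, got %d", nm, expected[[nm]],
            length(h[[nm]]))
    }
    if (any(!is.finite(h[[nm]])) || any(h[[nm]] < 0)) {
      stopf("feature '%s' must be finite and non-negative", nm)
    }
    if (normalize) {
      s <- sum(h[[nm]])
      if (s <= 0) stopf("feature '%s' has zero total mass", nm)
      h[[nm]] <- h[[nm]] / s
    } else if (abs(sum(h[[nm]]) - 1) > 1e-9) {
      stopf("feature '%s' must sum to 1 (got %.12f)", nm, sum(h[[nm]]))
    }
  }
  structure(h, class = "hist_set")
}

#' @export
print.hist_set <- function(x, ...) {
  cat("<hist_set>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-5s [%s]\n", nm, paste(formatC(x[[nm]], digits = 3,
                                                   format = "fg"),
                                           collapse = " ")))
  }
  invisible(x)
}

# point-mass-with-spread histogram: discretized normal around `value`
#' @keywords internal
smeared_hist <- function(value, sd, thresholds) {
  edges <- c(-Inf, thresholds, Inf)
  p <- diff(stats::pnorm(edges, mean = value, sd = max(sd, 1e-12)))
  p / sum(p)
}
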