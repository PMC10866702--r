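#' Construct a raw six-channel inertial sensor stream
#'
#' Uniformly sampled 3-axis accelerometer (anterior-posterior, medial-lateral,
#' dorsal-ventral; units of g) and 3-axis gyroscope (deg/s) series. The
#' dorsal-ventral axis is positive downward, so a level stationary sensor
#' reads approximately (0, 0, 1) g. Magnetometer channels of nine-axis
#' hardware are accepted upstream but ignored: the featurization never uses
#' them.
#'
#' @param acc n x 3 numeric matrix (ap, ml, dv) in g.
#' @param gyr n x 3 numeric matrix in deg/s.
#' @param sample_rate sampling rate in Hz.
#' @param t0 time of the first sample (s).
#' @return object of class `raw_stream`.
#' @export
raw_stream <- function(acc, gyr, sample_rate = 200, t0 = 0) {
  acc <- as.matrix(acc); gyr <- as.matrix(gyr)
  stopifnot(ncol(acc) == 3L, ncol(gyr) == 3L, nrow(acc) == nrow(gyr),
            sample_rate > 0, all(is.finite(acc)), all(is.finite(gyr)))
  colnames(acc) <- c("ap", "ml", "dv")
  colnames(gyr) <- c("x", "y", "z")
  structure(list(acc = acc, gyr = gyr, sample_rate = sample_rate,
                 time = t0 + (seq_len(nrow(acc)) - 1L) / sample_rate),
            class = "raw_stream")
}

#' @export
print.raw_stream <- function(x, ...) {
  cat(sprintf("<raw_stream> %d samples @ %g Hz (%.1f s)\n",
              nrow(x$acc), x$sample_rate, nrow(x$acc) / x$sample_rate))
  invisible(x)
}

# Rodrigues rotation taking unit vector `u` onto unit vector `v`; the rotation
# axis lies in the plane orthogonal to both, so mapping gravity onto +z uses
# pitch/roll only (no yaw component).
#' @keywords internal
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(w^2)); cth <- sum(u * v)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # antiparallel: rotate pi about any horizontal axis orthogonal to u
    a <- c(1, 0, 0)
    if (abs(sum(a * u)) > 0.9) a <- c(0, 1, 0)
    a <- a - sum(a * u) * u; a <- a / sqrt(sum(a^2))
    return(2 * outer(a, a) - diag(3))
  }
  K <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

#' Estimate the calibration rotation from a stationary window
#'
#' Computes the rotation matrix that maps the mean gravity vector of an
#' immobile, mounted sensor onto the universal vertical axis (0, 0, +1), so
#' that after calibration the only non-zero stationary acceleration is on the
#' universal z-axis. The rotation involves pitch and roll only. The gyroscope
#' baseline (mean stationary reading per axis) is recorded for subtraction.
#'
#' @param stream `raw_stream` recorded from the immobile sensor.
#' @param motion_tol maximum allowed standard deviation of the acceleration
#'   magnitude (g); above it the window is rejected as non-stationary.
#' @return object of class `calibration`: `rotation` (3 x 3 orthonormal,
#'   det +1), `gyro_baseline` (deg/s).
#' @export
estimate_rotation <- function(stream, motion_tol = 0.02) {
  stopifnot(inherits(stream, "raw_stream"))
  mag <- sqrt(rowSums(stream$acc^2))
  if (stats::sd(mag) > motion_tol) {
    stopf("window is not stationary: acceleration magnitude s.d. %.4f g > %.4f g",
          stats::sd(mag), motion_tol)
  }
  g <- colMeans(stream$acc)
  R <- rotation_between(g, c(0, 0, 1))
  structure(list(rotation = R, gyro_baseline = colMeans(stream$gyr)),
            class = "calibration")
}

#' Apply a calibration to a raw stream
#'
#' The gyroscope baseline is subtracted from all gyroscope values first; the
#' rotation matrix is then applied to both accelerometer and gyroscope
#' vectors.
#'
#' @param stream `raw_stream`.
#' @param calib `calibration` from [estimate_rotation()].
#' @return calibrated `raw_stream`.
#' @export
apply_calibration <- function(stream, calib) {
  stopifnot(inherits(stream, "raw_stream"), inherits(calib, "calibration"))
  R <- calib$rotation
  if (!isTRUE(all.equal(dim(R), c(3L, 3L))))
    stopf("calibration rotation must be 3x3")
  gyr <- sweep(stream$gyr, 2L, calib$gyro_baseline) %*% t(R)
  acc <- stream$acc %*% t(R)
  raw_stream(acc, gyr, stream$sample_rate, t0 = stream$time[1L])
}

#' Body-acceleration components of a calibrated stream
#'
#' Each axis is median-filtered and then passed through a fourth-order
#' Butterworth high-pass filter (0.5 Hz cut-off), removing the gravitational
#' (DC/postural) component. The filter is applied forward-backward
#' (zero-phase) so body and gravitational components stay aligned in time.
#'
#' @param stream calibrated `raw_stream`.
#' @param cutoff_hz high-pass cut-off (default 0.5 Hz).
#' @param order filter order (default 4).
#' @param median_k median filter kernel length in samples (odd; default 11,
#'   i.e. 55 ms at 200 Hz).
#' @return list with `ba` (n x 3 matrix of body acceleration) and `med`
#'   (n x 3 median-filtered raw signals).
#' @export
body_acceleration <- function(stream, cutoff_hz = 0.5, order = 4L,
                              median_k = 11L) {
  stopifnot(inherits(stream, "raw_stream"))
  n <- nrow(stream$acc)
  fs <- stream$sample_rate
  # filtfilt needs a few filter lengths of data; require 2 s minimum
  if (n < 2 * fs) stopf("stream too short for filter warm-up (need >= 2 s)")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "high")
  med <- apply(stream$acc, 2L, stats::runmed, k = median_k, endrule = "median")
  ba <- apply(med, 2L, function(x) signal::filtfilt(bf, x))
  colnames(ba) <- colnames(med) <- c("ap", "ml", "dv")
  list(ba = ba, med = med)
}

#' Gravitational acceleration along the anterior-posterior axis
#'
#' The body-acceleration component is subtracted from the median-filtered raw
#' anterior-posterior signal, leaving the gravity projection that tracks
#' postural (pitch) changes.
#'
#' @param ba result of [body_acceleration()].
#' @return numeric GAap series in g.
#' @export
gravitational_component <- function(ba) {
  ba$med[, "ap"] - ba$ba[, "ap"]
}

#' Total body acceleration
#'
#' Pointwise Euclidean norm of the three body-acceleration components:
#' `sqrt(BAap^2 + BAml^2 + BAdv^2)`.
#'
#' @param ba n x 3 body-acceleration matrix (or the list from
#'   [body_acceleration()]).
#' @return non-negative numeric series in g.
#' @export
total_body_acceleration <- function(ba) {
  if (is.list(ba) && !is.data.frame(ba)) ba <- ba$ba
  sqrt(rowSums(ba^2))
}

#' Resting/moving threshold from the bimodal log-TotBA distribution
#'
#' Fits a two-component Gaussian mixture to the natural log of TotBA and
#' returns the antilog of the midpoint between the two component means -- the
#' average value separating the bimodal distribution. The threshold is
#' intended to be estimated once and reused unchanged for all sessions of a
#' dataset. If the distribution is effectively unimodal (component means
#' closer than `min_separation` log units, or a degenerate fit), a warning is
#' emitted and `fallback` is returned.
#'
#' @param totba TotBA series in g.
#' @param fallback threshold used when no bimodal structure is found.
#' @param min_separation minimum log-unit separation between component means.
#' @return scalar threshold in g.
#' @export
rest_threshold <- function(totba, fallback = 0.05, min_separation = 1) {
  x <- log(totba[is.finite(totba) & totba > 0])
  if (length(x) < 50L) {
    warning("too few TotBA samples for mixture fit; using fallback threshold")
    return(fallback)
  }
  mclustBIC <- mclust::mclustBIC # Mclust() resolves this in the caller frame
  fit <- tryCatch(
    mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || length(fit$parameters$mean) != 2L ||
      abs(diff(fit$parameters$mean)) < min_separation) {
    warning("log(TotBA) distribution not bimodal; using fallback threshold")
    return(fallback)
  }
  exp(mean(fit$parameters$mean))
}

#' Extract the four featurization time series from a calibrated stream
#'
#' Computes GAap (gravitational anterior-posterior acceleration), ACCdv (raw
#' calibrated dorsal-ventral acceleration), GYRdv (calibrated dorsal-ventral
#' gyroscope rate) and TotBA (total body acceleration) on the input time
#' base. The first `warmup_s` seconds are flagged so segment featurization
#' can exclude the filter transient.
#'
#' @param stream calibrated `raw_stream`.
#' @param warmup_s initial span excluded from downstream segmentation.
#' @param ... passed to [body_acceleration()].
#' @return object of class `feature_series` with elements `gaap`, `accdv`,
#'   `gyrdv`, `totba`, `ba`, `time`, `sample_rate`, `warmup_s`.
#' @export
feature_series <- function(stream, warmup_s = 2, ...) {
  stopifnot(inherits(stream, "raw_stream"))
  ba <- body_acceleration(stream, ...)
  structure(list(gaap = gravitational_component(ba),
                 accdv = stream$acc[, "dv"],
                 gyrdv = stream$gyr[, "z"],
                 totba = total_body_acceleration(ba),
                 ba = ba$ba,
                 time = stream$time,
                 sample_rate = stream$sample_rate,
                 warmup_s = warmup_s),
            class = "feature_series")
}

#' Summarize a feature series as per-segment histogram sets
#'
#' Bins the four feature series into non-overlapping 300 ms segments and
#' discretizes each segment's sample values with fixed thresholds, yielding
#' one normalized four-feature histogram set per segment. A trailing partial
#' segment is dropped; segments overlapping the filter warm-up are dropped
#' when `drop_warmup` is set.
#'
#' @param feats `feature_series`.
#' @param bins `feature_bins` discretization spec.
#' @param segment_s segment length (s); must contain an integer number of
#'   samples.
#' @param drop_warmup exclude segments inside `feats$warmup_s`?
#' @return list of `hist_set` objects with attribute `times` (segment start
#'   times, s).
#' @export
segment_histograms <- function(feats, bins = feature_bins(), segment_s = 0.3,
                               drop_warmup = TRUE) {
  stopifnot(inherits(feats, "feature_series"), inherits(bins, "feature_bins"))
  spp <- feats$sample_rate * segment_s
  if (abs(spp - round(spp)) > 1e-9) {
    stopf("%g s segment does not contain an integer number of samples at %g Hz",
          segment_s, feats$sample_rate)
  }
  spp <- as.integer(round(spp))
  n_seg <- length(feats$gaap) %/% spp
  first <- if (drop_warmup) ceiling(feats$warmup_s / segment_s) + 1L else 1L
  if (n_seg < first) return(structure(list(), times = numeric(0)))
  thr <- bins$thresholds
  out <- vector("list", n_seg - first + 1L)
  times <- numeric(length(out))
  for (s in first:n_seg) {
    idx <- ((s - 1L) * spp + 1L):(s * spp)
    out[[s - first + 1L]] <- hist_set(
      discretize_feature(feats$gaap[idx], thr$gaap),
      discretize_feature(feats$accdv[idx], thr$accdv),
      discretize_feature(feats$gyrdv[idx], thr$gyrdv),
      discretize_feature(feats$totba[idx], thr$totba),
      normalize = TRUE)
    times[s - first + 1L] <- feats$time[idx[1L]]
  }
  attr(out, "times") <- times
  out
}
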