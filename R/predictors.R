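#' Build the predictor table for dynamics-type modelling
#'
#' Rows are non-target actions; predictors are the action's similarity to the
#' target (EMD score) and its median baseline time to the closest preceding
#' occurrence of the target. Rows labelled "other" are excluded, and both
#' predictors are normalized to z scores before fitting.
#'
#' @param similarity numeric EMD similarity scores.
#' @param time_to_target numeric median preceding-time intervals (s).
#' @param label dynamics reporting group per action; one of
#'   "sustained_increase", "transient", "decreasing" (or "other", dropped).
#' @return data.frame of class `predictor_table` with z-scored `similarity`
#'   and `time_to_target` and factor `label` (reference level "decreasing").
#' @export
predictor_table <- function(similarity, time_to_target, label) {
  stopifnot(length(similarity) == length(time_to_target),
            length(similarity) == length(label))
  keep <- label != "other" & is.finite(similarity) & is.finite(time_to_target)
  z <- function(x) as.numeric(scale(x))
  df <- data.frame(similarity = z(similarity[keep]),
                   time_to_target = z(time_to_target[keep]),
                   label = factor(label[keep],
                                  levels = c("decreasing", "sustained_increase",
                                             "transient")))
  df$label <- droplevels(df$label)
  df$label <- stats::relevel(df$label, ref = "decreasing")
  class(df) <- c("predictor_table", "data.frame")
  df
}

#' Collinearity diagnostics for the predictor table
#'
#' Pearson correlation between the predictors, variance inflation factors,
#' and condition indices of the standardized design matrix, reported next to
#' the conventional thresholds (|r| < 0.8, VIF < 5-10, condition index <
#' 10-30).
#'
#' @param table `predictor_table` (or data.frame with numeric predictor
#'   columns).
#' @param predictors column names (default the two standard factors).
#' @return list with `pearson_r`, `vif` (named), `condition_indices`,
#'   `thresholds`, `flagged` (any undefined VIF from constant predictors).
#' @export
collinearity_diagnostics <- function(table,
                                     predictors = c("similarity",
                                                    "time_to_target")) {
  X <- as.matrix(table[, predictors, drop = FALSE])
  stopifnot(nrow(X) >= 3L)
  flagged <- FALSE
  vif <- vapply(seq_along(predictors), function(j) {
    if (stats::sd(X[, j]) == 0) { flagged <<- TRUE; return(Inf) }
    r2 <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    if (1 - r2 < 1e-12) { flagged <<- TRUE; return(Inf) }
    1 / (1 - r2)
  }, numeric(1))
  names(vif) <- predictors
  r <- if (ncol(X) == 2L) stats::cor(X[, 1L], X[, 2L]) else stats::cor(X)
  # condition indices on the scaled design matrix (unit column lengths)
  Xs <- cbind(intercept = 1, X)
  Xs <- sweep(Xs, 2L, sqrt(colSums(Xs^2)), "/")
  sv <- svd(Xs)$d
  ci <- max(sv) / sv
  list(pearson_r = r, vif = vif, condition_indices = ci,
       thresholds = list(pearson_r = 0.8, vif = c(5, 10),
                         condition_index = c(10, 30)),
       flagged = flagged)
}

# test-set (or training-set) deviance of predicted class probabilities:
# twice the gap between the saturated log likelihood (0 for individual
# multinomial outcomes) and the model log likelihood
#' @keywords internal
multinom_deviance <- function(prob, truth) {
  prob <- as.matrix(prob)
  p <- prob[cbind(seq_along(truth), as.integer(truth))]
  -2 * sum(log(pmax(p, 1e-300)))
}

#' Area under the precision-recall curve
#'
#' Step-wise average precision: precision is accumulated at each recall
#' increment of the score-ranked positives. A no-skill classifier scores
#' about the positive-class prevalence.
#'
#' @param scores numeric predicted scores (higher = more positive).
#' @param truth logical (or 0/1) class membership.
#' @return scalar in \[0, 1\] (`NA` when no positives).
#' @export
auprc <- function(scores, truth) {
  truth <- as.logical(truth)
  np <- sum(truth)
  if (np == 0L) return(NA_real_)
  o <- order(-scores)
  tp <- cumsum(truth[o])
  fp <- cumsum(!truth[o])
  prec <- tp / (tp + fp)
  rec <- tp / np
  dr <- diff(c(0, rec))
  sum(prec * dr)
}

#' Fit the multinomial logit model of action dynamics
#'
#' Maximum-likelihood multinomial logistic regression of the dynamics
#' reporting group on the chosen factors, with the decreased type as the
#' reference class: each other class's relative risk is a linear combination
#' of the predictors.
#'
#' @param table `predictor_table`.
#' @param factors predictor column names (subset of
#'   `c("similarity", "time_to_target")`).
#' @return object of class `model_report`: list with `coefficients` (matrix,
#'   one row per non-reference class), `deviance`, `auprc` (per class and
#'   `macro`), `factors`, `fit` (the underlying `multinom` object).
#' @export
fit_multinomial <- function(table, factors = c("similarity", "time_to_target")) {
  stopifnot(all(factors %in% names(table)))
  if (nlevels(droplevels(table$label)) < 2L) {
    stopf("need at least 2 dynamics classes to fit")
  }
  f <- stats::as.formula(paste("label ~", paste(factors, collapse = " + ")))
  fit <- nnet::multinom(f, data = table, trace = FALSE, maxit = 500)
  if (fit$convergence != 0) stopf("multinomial fit did not converge")
  prob <- stats::fitted(fit)
  if (is.null(dim(prob))) prob <- cbind(1 - prob, prob) # 2-class case
  colnames(prob) <- fit$lev
  per_class <- vapply(fit$lev, function(cl) {
    auprc(prob[, cl], table$label == cl)
  }, numeric(1))
  structure(list(coefficients = stats::coef(fit),
                 deviance = multinom_deviance(prob[, levels(table$label)],
                                              table$label),
                 auprc = c(per_class, macro = mean(per_class, na.rm = TRUE)),
                 factors = factors, n = nrow(table), fit = fit),
            class = "model_report")
}

#' @keywords internal
stratified_folds <- function(label, folds, seed) {
  with_seed(seed, {
    f <- integer(length(label))
    for (cl in levels(label)) {
      idx <- sample(which(label == cl))
      f[idx] <- rep_len(sample(folds), length(idx))
    }
    f
  })
}

#' Cross-validated evaluation of the multinomial model
#'
#' Repeated stratified k-fold cross-validation: each of `repeats` x `folds`
#' models is fitted on the training portion and scored on the held-out fold
#' (test deviance and per-class/macro AUPRC). Should a class be missing from
#' a training fold despite stratification, the repeat is refolded with a new
#' seed and the event logged in the result.
#'
#' @param table `predictor_table`.
#' @param factors predictor columns.
#' @param repeats,folds cross-validation design (defaults 20 and 10 give 200
#'   models).
#' @param seed integer seed.
#' @return data.frame with one row per model: `repeat_`, `fold`, `deviance`,
#'   per-class AUPRC columns and `macro_auprc`; attribute `refolds` counts
#'   refold events.
#' @export
cv_evaluate <- function(table, factors = c("similarity", "time_to_target"),
                        repeats = 20L, folds = 10L, seed = 1L) {
  stopifnot(nrow(table) >= folds)
  lev <- levels(droplevels(table$label))
  rows <- list()
  refolds <- 0L
  for (r in seq_len(repeats)) {
    attempt <- 0L
    repeat {
      fold_id <- stratified_folds(table$label, folds,
                                  seed + r * 1000L + attempt)
      ok <- all(vapply(seq_len(folds), function(k) {
        all(lev %in% table$label[fold_id != k])
      }, logical(1)))
      if (ok) break
      attempt <- attempt + 1L
      refolds <- refolds + 1L
      if (attempt > 20L) stopf("could not build folds containing every class")
    }
    for (k in seq_len(folds)) {
      train <- table[fold_id != k, , drop = FALSE]
      test <- table[fold_id == k, , drop = FALSE]
      f <- stats::as.formula(paste("label ~", paste(factors, collapse = " + ")))
      fit <- nnet::multinom(f, data = train, trace = FALSE, maxit = 500)
      prob <- stats::predict(fit, newdata = test, type = "probs")
      if (is.null(dim(prob))) {
        prob <- cbind(1 - prob, prob)
        colnames(prob) <- fit$lev
      }
      per_class <- vapply(lev, function(cl) auprc(prob[, cl], test$label == cl),
                          numeric(1))
      rows[[length(rows) + 1L]] <- c(
        repeat_ = r, fold = k,
        deviance = multinom_deviance(prob[, lev, drop = FALSE],
                                     factor(test$label, levels = lev)),
        stats::setNames(per_class, paste0("auprc_", lev)),
        macro_auprc = mean(per_class, na.rm = TRUE))
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "refolds") <- refolds
  attr(out, "factors") <- factors
  out
}

#' Label-shuffled null distribution of cross-validated metrics
#'
#' Permutes labels against predictors `n_shuffles` times and runs the same
#' cross-validation on each shuffled table (`models_per` models each, e.g.
#' 50 x 200 = 10,000 null models).
#'
#' @param table `predictor_table`.
#' @param factors predictor columns.
#' @param n_shuffles number of shuffled datasets (default 50).
#' @param models_per models per shuffled dataset (default 200 =
#'   `folds` x `models_per / folds` repeats).
#' @param folds folds per repeat.
#' @param seed integer seed.
#' @return data.frame as [cv_evaluate()] with an extra `shuffle` column.
#' @export
shuffle_baseline <- function(table, factors = c("similarity", "time_to_target"),
                             n_shuffles = 50L, models_per = 200L, folds = 10L,
                             seed = 1L) {
  if (models_per %% folds != 0L) {
    stopf("models_per (%d) must be a multiple of folds (%d)", models_per, folds)
  }
  repeats <- models_per %/% folds
  out <- lapply(seq_len(n_shuffles), function(s) {
    tab <- table
    tab$label <- with_seed(seed + 7L * s, sample(tab$label))
    cv <- cv_evaluate(tab, factors, repeats = repeats, folds = folds,
                      seed = seed + 100000L + s)
    cv$shuffle <- s
    cv
  })
  do.call(rbind, out)
}

#' Compare factor combinations with an AIC penalty
#'
#' Pairwise comparison of model deviances across factor sets, adding the AIC
#' penalty 2k (k = number of predictors) to each model's deviance so that the
#' two-factor model carries a 4-point handicap against the one-factor models.
#'
#' @param reports named list of `model_report` objects fitted on identical
#'   data (e.g. `list(similarity = ..., time = ..., both = ...)`).
#' @return data.frame with `model`, `k`, `deviance`, `penalized` (deviance +
#'   2k), ordered by penalized deviance.
#' @export
compare_models <- function(reports) {
  stopifnot(length(reports) >= 2L)
  n <- vapply(reports, function(r) r$n, numeric(1))
  if (length(unique(n)) != 1L) stopf("reports must be fitted on identical data")
  out <- data.frame(
    model = names(reports),
    k = vapply(reports, function(r) length(r$factors), numeric(1)),
    deviance = vapply(reports, function(r) r$deviance, numeric(1)))
  out$penalized <- out$deviance + 2 * out$k
  out[order(out$penalized), ]
}
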