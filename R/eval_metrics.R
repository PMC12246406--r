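#' Discrimination, calibration and decision-analytic metrics
#'
#' The evaluation layer used for patient-level LNM predictions: ROC and
#' precision-recall AUC, Pearson correlation for regressions, operating
#' points constrained to sensitivity >= 90%, the confusion-matrix metrics,
#' SLNB reduction rate, net benefit and decision curves, calibration curves,
#' paired bootstrap reports with reversed-percentile confidence intervals,
#' and the two-model paired permutation test.
#'
#' @name eval_metrics
NULL

check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (length(scores) == 0) stop("empty input")
  if (any(!labels %in% c(0, 1))) stop("labels must be 0/1")
  if (any(!is.finite(scores))) stop("non-finite scores")
  invisible(TRUE)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with ties counted one half.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels 0/1 outcome labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes required for ROC AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-interpolated average precision: the sum over positives, in decreasing
#' score order, of precision at each positive's rank. Ties are broken by
#' averaging over the tie group (precision computed at the group boundary).
#'
#' @inheritParams roc_auc
#' @return Average precision in `(0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  if (sum(labels == 1) == 0) stop("no positives")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  # collapse tie groups: within a tie group precision is evaluated at the end
  grp <- cumsum(!duplicated(s))
  tp_g <- as.vector(rowsum(y, grp))              # group order = 1, 2, ...
  n_g <- as.vector(rowsum(rep(1, length(y)), grp))
  tp_cum <- cumsum(tp_g)
  n_cum <- cumsum(n_g)
  prec <- tp_cum / n_cum
  sum(prec * tp_g) / sum(labels == 1)
}

#' Pearson product-moment correlation
#'
#' @param pred,truth Numeric vectors of equal length with positive variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  ok <- is.finite(pred) & is.finite(truth)
  pred <- pred[ok]; truth <- truth[ok]
  if (length(pred) < 2L) stop("need at least two paired values")
  if (stats::var(pred) == 0 || stats::var(truth) == 0)
    stop("zero variance")
  stats::cor(pred, truth)
}

#' Operating threshold at a sensitivity floor
#'
#' The largest threshold t (predict positive iff score >= t) whose
#' sensitivity on the given set is at least `s_min`; by construction this
#' maximizes specificity subject to the sensitivity constraint.
#'
#' @inheritParams roc_auc
#' @param s_min Sensitivity floor, default 0.90.
#' @return The threshold (a score value present among the positives, or
#'   `-Inf` when even the lowest positive score cannot reach the floor due
#'   to ties -- in practice the minimum positive score).
#' @export
threshold_at_sensitivity <- function(scores, labels, s_min = 0.90) {
  check_scores_labels(scores, labels)
  pos <- scores[labels == 1]
  if (length(pos) == 0) stop("at least one positive required")
  cand <- sort(unique(pos), decreasing = TRUE)
  for (t in cand) {
    if (mean(pos >= t) >= s_min) return(t)
  }
  min(pos)
}

#' Confusion-matrix metrics at a threshold
#'
#' Predict positive iff `score >= threshold` (closed on the positive side).
#' Undefined 0/0 ratios are returned as `NA` with a `defined` flag.
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold.
#' @return A list with counts `tp, fp, tn, fn, n` and metrics `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy` (proportions in `[0, 1]`), plus
#'   `defined`, a named logical vector flagging 0/0 ratios.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  check_scores_labels(scores, labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  n <- tp + fp + tn + fn
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(tp = tp, fp = fp, tn = tn, fn = fn, n = n,
              sensitivity = safe(tp, tp + fn),
              specificity = safe(tn, tn + fp),
              ppv = safe(tp, tp + fp),
              npv = safe(tn, tn + fn),
              accuracy = (tp + tn) / n)
  out$defined <- !vapply(out[c("sensitivity", "specificity", "ppv", "npv")],
                         is.na, logical(1))
  out
}

#' Sentinel lymph node biopsy reduction rate
#'
#' The share of patients a deployed model would spare surgical staging:
#' the fraction predicted node-negative, `100 * (TN + FN) / n` percent.
#'
#' @param conf Confusion counts as returned by [confusion_metrics()] (any
#'   list with `tn`, `fn`, `n`).
#' @return Percentage in `[0, 100]`.
#' @export
slnb_reduction_rate <- function(conf) {
  if (conf$n < 1) stop("empty confusion table")
  100 * (conf$tn + conf$fn) / conf$n
}

#' Net benefit at a threshold probability
#'
#' Decision-analytic utility `tp/n - (fp/n) * pt / (1 - pt)` at threshold
#' probability `pt`: true positives credited in full, false positives
#' debited at the odds of the threshold probability.
#'
#' @param conf Confusion counts (list with `tp`, `fp`, `n`).
#' @param threshold_prob Threshold probability in (0, 1).
#' @return Net benefit (per patient; multiply by 100 for percent).
#' @export
net_benefit <- function(conf, threshold_prob) {
  if (threshold_prob <= 0 || threshold_prob >= 1)
    stop("threshold_prob must lie in (0, 1)")
  conf$tp / conf$n - (conf$fp / conf$n) * threshold_prob / (1 - threshold_prob)
}

#' Decision curve
#'
#' Net benefit of the model (treating score >= pt as positive), of treating
#' everyone, and of treating no one, over a grid of threshold probabilities.
#'
#' @inheritParams roc_auc
#' @param pt_grid Threshold probabilities, all in (0, 1).
#' @return A `data.frame` with `pt`, `model`, `treat_all`, `treat_none`.
#' @export
decision_curve <- function(scores, labels, pt_grid = seq(0.05, 0.95, by = 0.05)) {
  check_scores_labels(scores, labels)
  if (any(pt_grid <= 0 | pt_grid >= 1)) stop("pt grid must lie in (0, 1)")
  prev <- mean(labels == 1)
  rows <- lapply(pt_grid, function(pt) {
    nb <- net_benefit(confusion_metrics(scores, labels, pt), pt)
    data.frame(pt = pt, model = nb,
               treat_all = prev - (1 - prev) * pt / (1 - pt),
               treat_none = 0)
  })
  do.call(rbind, rows)
}

#' Calibration curve
#'
#' Equal-width bins on `[0, 1]`; per non-empty bin, the mean predicted
#' probability and the observed event rate.
#'
#' @inheritParams roc_auc
#' @param n_bins Number of equal-width bins.
#' @return A `data.frame` with `bin`, `mean_pred`, `obs_rate`, `n`.
#' @export
calibration_curve <- function(scores, labels, n_bins = 10) {
  check_scores_labels(scores, labels)
  if (any(scores < 0 | scores > 1)) stop("scores must be probabilities in [0,1]")
  bin <- pmin(pmax(ceiling(scores * n_bins), 1L), n_bins)
  keep <- sort(unique(bin))
  data.frame(
    bin = keep,
    mean_pred = vapply(keep, function(b) mean(scores[bin == b]), numeric(1)),
    obs_rate = vapply(keep, function(b) mean(labels[bin == b]), numeric(1)),
    n = vapply(keep, function(b) sum(bin == b), numeric(1))
  )
}

#' Reversed-percentile bootstrap confidence interval
#'
#' `[2*estimate - Q(1 - alpha/2), 2*estimate - Q(alpha/2)]` where Q are
#' quantiles of the bootstrap replicates.
#'
#' @param estimate Point estimate on the full sample.
#' @param replicates Bootstrap replicates of the estimate.
#' @param conf Coverage, default 0.95.
#' @return Length-2 vector `c(lower, upper)`.
#' @export
reversed_percentile_ci <- function(estimate, replicates, conf = 0.95) {
  a <- (1 - conf) / 2
  q <- stats::quantile(replicates, c(1 - a, a), names = FALSE, type = 7)
  c(lower = 2 * estimate - q[1], upper = 2 * estimate - q[2])
}

#' Paired bootstrap evaluation report
#'
#' Draws `B` patient-level bootstrap resamples (the same resampled indices
#' applied to every model, so model differences are paired), evaluates each
#' metric per model per resample, and reports point value, bootstrap
#' mean/SD, and reversed-percentile CI; for each model beyond the first the
#' improvement over the first model gets its own reversed-percentile CI.
#' Resamples where a classification metric is undefined because only one
#' class was drawn are redrawn, keeping B effective samples.
#'
#' @param scores_by_model Named list of score vectors, all aligned to `labels`.
#' @param labels 0/1 outcomes (or numeric truth for regression metrics).
#' @param metrics Named list of functions `f(scores, labels) -> scalar`;
#'   defaults to ROC and PR AUC.
#' @param B Number of bootstrap samples (default 1000).
#' @param seed Integer seed for the resampling.
#' @param conf CI coverage.
#' @return A list with `point`, `boot_mean`, `boot_sd`, `ci` (arrays
#'   metric x model), `improvement_ci` (metric x model, vs the first model)
#'   and the resample index matrix `indices` (n x B).
#' @export
bootstrap_report <- function(scores_by_model, labels,
                             metrics = list(roc_auc = roc_auc, pr_auc = pr_auc),
                             B = 1000, seed = 1, conf = 0.95) {
  if (B < 1) stop("B must be >= 1")
  if (!is.list(scores_by_model) || length(scores_by_model) == 0)
    stop("scores_by_model must be a non-empty list")
  n <- length(labels)
  stopifnot(all(vapply(scores_by_model, length, integer(1)) == n))
  mnames <- names(metrics); snames <- names(scores_by_model)
  needs_both <- length(unique(labels[is.finite(labels)])) <= 2
  rng <- local_rng(seed)
  idx <- matrix(0L, n, B)
  for (b in seq_len(B)) {
    repeat {
      take <- sample.int(n, n, replace = TRUE)
      if (!needs_both || length(unique(labels[take])) > 1) break
    }
    idx[, b] <- take
  }
  point <- sapply(scores_by_model, function(s)
    vapply(metrics, function(f) f(s, labels), numeric(1)))
  point <- matrix(point, nrow = length(metrics),
                  dimnames = list(mnames, snames))
  reps <- array(NA_real_, c(length(metrics), length(scores_by_model), B),
                dimnames = list(mnames, snames, NULL))
  for (b in seq_len(B)) {
    take <- idx[, b]
    for (s in seq_along(scores_by_model))
      for (m in seq_along(metrics))
        reps[m, s, b] <- metrics[[m]](scores_by_model[[s]][take], labels[take])
  }
  boot_mean <- apply(reps, c(1, 2), mean)
  boot_sd <- apply(reps, c(1, 2), stats::sd)
  ci <- array(NA_real_, c(length(metrics), length(scores_by_model), 2),
              dimnames = list(mnames, snames, c("lower", "upper")))
  for (m in seq_along(metrics))
    for (s in seq_along(scores_by_model))
      ci[m, s, ] <- reversed_percentile_ci(point[m, s], reps[m, s, ], conf)
  improvement_ci <- NULL
  if (length(scores_by_model) > 1) {
    improvement_ci <- array(NA_real_,
      c(length(metrics), length(scores_by_model) - 1, 2),
      dimnames = list(mnames, snames[-1], c("lower", "upper")))
    for (m in seq_along(metrics))
      for (s in seq_along(scores_by_model)[-1]) {
        d_hat <- point[m, s] - point[m, 1]
        d_rep <- reps[m, s, ] - reps[m, 1, ]
        improvement_ci[m, s - 1, ] <- reversed_percentile_ci(d_hat, d_rep, conf)
      }
  }
  list(point = point, boot_mean = boot_mean, boot_sd = boot_sd, ci = ci,
       improvement_ci = improvement_ci, indices = idx, B = B)
}

#' Paired two-model permutation test
#'
#' Two-tailed test of a performance difference between two models evaluated
#' on the same patients: per permutation the two models' predictions are
#' swapped within each patient with probability one half, and
#' `p = (1 + #{|diff_perm| >= |diff_obs|}) / (B + 1)`.
#'
#' @param scores_a,scores_b Paired prediction vectors.
#' @param labels Outcomes.
#' @param metric Function `f(scores, labels) -> scalar` (default [roc_auc()]).
#' @param B Number of permutations.
#' @param seed Integer seed.
#' @return Two-tailed p-value in `[1/(B+1), 1]`.
#' @export
permutation_test <- function(scores_a, scores_b, labels, metric = roc_auc,
                             B = 1000, seed = 1) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) stop("length mismatch")
  n <- length(labels)
  d_obs <- metric(scores_a, labels) - metric(scores_b, labels)
  rng <- local_rng(seed)
  hits <- 0L
  for (b in seq_len(B)) {
    swap <- stats::runif(n) < 0.5
    pa <- ifelse(swap, scores_b, scores_a)
    pb <- ifelse(swap, scores_a, scores_b)
    d_perm <- metric(pa, labels) - metric(pb, labels)
    if (abs(d_perm) >= abs(d_obs) - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (B + 1)
}
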