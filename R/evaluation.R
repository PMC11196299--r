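# Statistical evaluation: correlations, incremental regression, ROC/AUC
# with DeLong confidence intervals, balanced optimal cutoffs, and binary /
# four-level severity confusion metrics.

#' Pearson product-moment correlation with domain checks
#'
#' @param x,y Equal-length numeric vectors (n >= 3), both non-constant.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input")
  }
  stats::cor(x, y)
}

#' Does Fcv add predictive power once REI is in the model?
#'
#' Ordinary least squares of AHI on REI alone and on REI + Fcv; the
#' incremental value of Fcv is tested by the partial F statistic
#' `((RSS1 - RSS2)/1) / (RSS2/(n-3))` with (1, n-3) degrees of freedom.
#'
#' @param ahi,rei,fcv Equal-length numeric vectors, n >= 5.
#' @return List with `multiple_R` (of the two-predictor model),
#'   `partial_f`, and `p_value` for adding `fcv`.
#' @export
incremental_regression <- function(ahi, rei, fcv) {
  n <- length(ahi)
  if (length(rei) != n || length(fcv) != n) stop("unequal lengths")
  if (n < 5) stop("need at least 5 observations")
  if (qr(cbind(1, rei, fcv))$rank < 3) {
    stop("singular design: predictors are collinear")
  }
  fit1 <- stats::lm(ahi ~ rei)
  fit2 <- stats::lm(ahi ~ rei + fcv)
  rss1 <- sum(stats::residuals(fit1)^2)
  rss2 <- sum(stats::residuals(fit2)^2)
  f <- ((rss1 - rss2) / 1) / (rss2 / (n - 3))
  list(
    multiple_R = sqrt(summary(fit2)$r.squared),
    partial_f = f,
    p_value = stats::pf(f, 1, n - 3, lower.tail = FALSE)
  )
}

#' ROC curve and AUC with DeLong confidence interval
#'
#' AUC is the Mann-Whitney concordance probability (ties counted 1/2). The
#' 95% CI uses the DeLong variance of the placement values with a logit
#' transform, clipped to \[0, 1\]; for degenerate zero-variance cases the
#' interval collapses to the point estimate.
#'
#' @param scores Numeric predictor values (higher = more positive).
#' @param labels Binary labels (0/1 or logical); both classes must occur.
#' @return An object of class `roc_result`: `auc`, `ci95` (length 2),
#'   `curve` (data frame of fpr/tpr from (0,0) to (1,1)), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("unequal lengths")
  if (anyNA(scores) || anyNA(labels)) stop("missing values")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("degenerate labels: both classes must be present")
  }
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]

  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # ROC curve: thresholds at each distinct score, predicted positive >= t
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  curve <- unique(curve)

  # DeLong placement values
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  var_auc <- stats::var(v10) / n_pos + stats::var(v01) / n_neg
  if (!is.finite(var_auc) || var_auc <= 0 || auc <= 0 || auc >= 1) {
    ci <- c(auc, auc)
  } else {
    se_logit <- sqrt(var_auc) / (auc * (1 - auc))
    lo <- stats::plogis(stats::qlogis(auc) - 1.959964 * se_logit)
    hi <- stats::plogis(stats::qlogis(auc) + 1.959964 * se_logit)
    ci <- pmin(1, pmax(0, c(lo, hi)))
  }

  structure(
    list(auc = auc, ci95 = ci, curve = curve, n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Optimal cutoff balancing sensitivity and specificity
#'
#' Scans candidate thresholds (midpoints between adjacent distinct scores;
#' predicted positive = score >= cutoff) and returns the one maximizing
#' `min(sensitivity, specificity)`. Ties are broken by the larger Youden
#' index, then by the lower cutoff.
#'
#' @param scores Numeric predictor values.
#' @param labels Binary labels; both classes must occur.
#' @return The selected cutoff value.
#' @export
optimal_cutoff <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0) {
    stop("degenerate labels: both classes must be present")
  }
  s <- sort(unique(scores))
  if (length(s) < 2) stop("need at least two distinct scores")
  cand <- (s[-length(s)] + s[-1]) / 2
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  sens <- vapply(cand, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(neg < t), numeric(1))
  balance <- pmin(sens, spec)
  youden <- sens + spec - 1
  ord <- order(-balance, -youden, cand)
  cand[ord[1]]
}

# Half-up decimal rounding used for displayed percentages (R's round() is
# half-even); only ever applied to non-negative percent values.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' Binary confusion metrics
#'
#' Sensitivity, specificity, accuracy, and positive/negative percent
#' agreement from a 2x2 confusion table. Positive means reference AHI at or
#' above the severity cutoff; predicted positive means REI at or above its
#' cutoff. Values are percentages at full precision; metrics with a zero
#' denominator are `NA`. The print method rounds half-up to one decimal.
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return An object of class `binary_metrics`: `sensitivity`,
#'   `specificity`, `accuracy`, `ppa`, `npa` plus the counts.
#' @export
#' @examples
#' m <- binary_metrics(tp = 14, fp = 2, fn = 4, tn = 19)
#' round(m$sensitivity, 1)  # 77.8
binary_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts %% 1 != 0)) {
    stop("counts must be non-negative integers")
  }
  total <- sum(counts)
  if (total == 0) stop("all-zero confusion table")
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(
    list(
      sensitivity = pct(tp, tp + fn),
      specificity = pct(tn, tn + fp),
      accuracy = pct(tp + tn, total),
      ppa = pct(tp, tp + fp),
      npa = pct(tn, tn + fn),
      counts = counts
    ),
    class = "binary_metrics"
  )
}

#' @export
print.binary_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else
    sprintf("%.1f%%", round_half_up(v, 1))
  cat(sprintf(
    "<binary_metrics> sens %s, spec %s, acc %s, PPA %s, NPA %s\n",
    fmt(x$sensitivity), fmt(x$specificity), fmt(x$accuracy),
    fmt(x$ppa), fmt(x$npa)
  ))
  invisible(x)
}

#' Four-level severity confusion metrics
#'
#' Accuracy, the distribution of misclassification distances, and
#' per-class sensitivity/specificity from a k x k confusion matrix with
#' rows = predicted class and columns = reference class (both ordered
#' normal, mild, moderate, severe). Per-class sensitivity is the share of
#' each reference class predicted as itself; per-class specificity the
#' share of non-members identified as non-members.
#'
#' @param m Square numeric matrix of counts (rows predicted, columns
#'   reference).
#' @return List with `accuracy` (percent), `off_by_share` (percent of
#'   misclassifications off by 1, 2, ... classes; `NA` when there are
#'   none), `per_class_sensitivity`, `per_class_specificity`, `total`.
#' @export
multilevel_metrics <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  if (any(m < 0)) stop("counts must be non-negative")
  total <- sum(m)
  if (total == 0) stop("empty confusion table")
  k <- nrow(m)
  dist <- abs(row(m) - col(m))
  correct <- sum(m[dist == 0])
  mis <- total - correct
  off <- vapply(seq_len(k - 1), function(d) sum(m[dist == d]), numeric(1))
  off_share <- if (mis > 0) 100 * off / mis else rep(NA_real_, k - 1)
  names(off_share) <- paste0("off_by_", seq_len(k - 1))
  sens <- vapply(seq_len(k), function(j) {
    n_ref <- sum(m[, j])
    if (n_ref > 0) 100 * m[j, j] / n_ref else NA_real_
  }, numeric(1))
  spec <- vapply(seq_len(k), function(j) {
    n_non <- total - sum(m[, j])
    if (n_non > 0) 100 * sum(m[-j, -j, drop = FALSE]) / n_non else NA_real_
  }, numeric(1))
  list(
    accuracy = 100 * correct / total,
    off_by_share = off_share,
    per_class_sensitivity = sens,
    per_class_specificity = spec,
    total = total
  )
}

#' Classify sleep apnea severity from REI
#'
#' Bands the respiratory event index into the four severity classes using
#' the REI cutoffs tuned on training data: < 9 normal, 9-14 mild, 14-24
#' moderate, >= 24 severe. Boundary values go to the higher class.
#'
#' @param rei Numeric vector of REI values (events/h), non-negative.
#' @param cutoffs Increasing length-3 vector of class boundaries
#'   (default `c(9, 14, 24)`).
#' @return An ordered factor with levels [severity_levels].
#' @export
#' @examples
#' classify_severity_by_rei(c(8.9, 14, 24))  # normal, moderate, severe
classify_severity_by_rei <- function(rei, cutoffs = c(9, 14, 24)) {
  if (!is.numeric(rei) || anyNA(rei)) stop("rei must be numeric")
  if (any(rei < 0)) stop("rei must be non-negative")
  if (length(cutoffs) != 3 || any(diff(cutoffs) <= 0)) {
    stop("cutoffs must be 3 increasing values")
  }
  cut(rei, breaks = c(-Inf, cutoffs, Inf), right = FALSE,
      labels = severity_levels, ordered_result = TRUE)
}

#' Build a predicted-vs-reference severity confusion matrix
#'
#' @param predicted,reference Factors (or vectors coercible to the
#'   [severity_levels] factor) of equal length.
#' @return A 4x4 count matrix, rows = predicted, columns = reference.
#' @export
severity_confusion <- function(predicted, reference) {
  predicted <- factor(predicted, levels = severity_levels)
  reference <- factor(reference, levels = severity_levels)
  if (length(predicted) != length(reference)) stop("unequal lengths")
  table(predicted = predicted, reference = reference)
}

#' Score detected events against ground-truth events
#'
#' Greedy one-to-one matching of detected to true intervals: a pair matches
#' when their overlap covers at least `min_overlap` of the shorter
#' interval; pairs are matched in order of decreasing overlap.
#'
#' @param truth Data frame with `start_s`, `end_s` of true events.
#' @param detected Data frame with `start_s`, `end_s` of detected events.
#' @param min_overlap Required overlap as a fraction of the shorter
#'   interval (default 0.5).
#' @return List with `tp`, `fn`, `fp`, `recall`, `precision` (the rates are
#'   `NA` when their denominator is zero).
#' @export
match_events <- function(truth, detected, min_overlap = 0.5) {
  nt <- nrow(truth)
  nd <- nrow(detected)
  if (nt == 0 || nd == 0) {
    return(list(tp = 0, fn = nt, fp = nd,
                recall = if (nt > 0) 0 else NA_real_,
                precision = if (nd > 0) 0 else NA_real_))
  }
  ov <- matrix(0, nt, nd)
  for (i in seq_len(nt)) {
    lo <- pmax(truth$start_s[i], detected$start_s)
    hi <- pmin(truth$end_s[i], detected$end_s)
    inter <- pmax(0, hi - lo)
    shorter <- pmin(truth$end_s[i] - truth$start_s[i],
                    detected$end_s - detected$start_s)
    ov[i, ] <- ifelse(inter >= min_overlap * shorter, inter, 0)
  }
  tp <- 0
  while (any(ov > 0)) {
    idx <- arrayInd(which.max(ov), dim(ov))
    tp <- tp + 1
    ov[idx[1], ] <- 0
    ov[, idx[2]] <- 0
  }
  list(
    tp = tp, fn = nt - tp, fp = nd - tp,
    recall = tp / nt, precision = tp / nd
  )
}
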