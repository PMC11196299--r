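test_that("pearson_r matches hand-computed values and rejects degenerate input", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1:4, 1:5), "equal length")
})

test_that("incremental regression quantifies what Fcv adds to REI", {
  # REI an essentially perfect predictor: an unrelated fcv adds nothing
  # (its partial F p-value is uniform; the replicate median sits far from
  # significance)
  ps <- vapply(1:11, function(s) {
    set.seed(s)
    rei <- runif(50, 0, 60)
    ahi <- rei + rnorm(50, 0, 0.5)
    fcv <- rnorm(50)
    fit <- incremental_regression(ahi, rei, fcv)
    expect_gt(fit$multiple_R, 0.999)
    fit$p_value
  }, numeric(1))
  expect_gt(median(ps), 0.05)

  # when fcv carries real independent signal, the partial F detects it
  set.seed(6)
  rei2 <- runif(200, 0, 60)
  fcv2 <- rnorm(200, 0, 5)
  ahi2 <- rei2 + 1.0 * fcv2 + rnorm(200, 0, 1)
  fit2 <- incremental_regression(ahi2, rei2, fcv2)
  expect_lt(fit2$p_value, 0.01)

  # cross-check the partial F against R's own nested-model ANOVA
  a <- anova(lm(ahi2 ~ rei2), lm(ahi2 ~ rei2 + fcv2))
  expect_equal(fit2$partial_f, a$F[2], tolerance = 1e-10)
  expect_equal(fit2$p_value, a$`Pr(>F)`[2], tolerance = 1e-10)

  expect_error(incremental_regression(ahi2, rei2, rei2), "singular")
})

test_that("AUC equals pairwise Mann-Whitney counting with ties at 1/2", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 2, 3), c(0, 0, 1, 1))$auc, 0.875)
  expect_equal(roc_auc(c(1, 2, 2, 3), c(1, 1, 0, 0))$auc, 0.125)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "degenerate")

  set.seed(8)
  for (i in 1:30) {
    n <- sample(4:30, 1)
    scores <- sample(1:8, n, replace = TRUE)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, brute_auc(scores, labels), tolerance = 1e-12)
    # curve sanity: starts (0,0), ends (1,1), monotone, AUC inside the CI
    expect_equal(unlist(r$curve[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
    expect_gte(r$auc, r$ci95[1])
    expect_lte(r$auc, r$ci95[2])
  }
})

test_that("AUC and DeLong variance agree with the pROC reference", {
  set.seed(12)
  scores <- rnorm(60)
  labels <- as.integer(scores + rnorm(60) > 0)
  ours <- roc_auc(scores, labels)
  ref <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  # reconstruct our DeLong variance from the logit-scale interval
  se_logit <- (stats::qlogis(ours$ci95[2]) - stats::qlogis(ours$auc)) / 1.959964
  var_ours <- (se_logit * ours$auc * (1 - ours$auc))^2
  expect_equal(var_ours, as.numeric(pROC::var(ref, method = "delong")),
               tolerance = 1e-8)
})

test_that("optimal cutoff balances sensitivity and specificity", {
  expect_equal(optimal_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1)), 2.5)

  # independent exhaustive-scan oracle with the same tie rules
  brute_cutoff <- function(scores, labels) {
    s <- sort(unique(scores))
    cand <- (s[-length(s)] + s[-1]) / 2
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    best <- c(-Inf, -Inf)
    best_c <- NA_real_
    for (ct in cand) {
      se <- mean(pos >= ct)
      sp <- mean(neg < ct)
      key <- c(min(se, sp), se + sp - 1)
      if (key[1] > best[1] ||
          (key[1] == best[1] && key[2] > best[2]) ||
          (identical(key, best) && ct < best_c)) {
        best <- key
        best_c <- ct
      }
    }
    best_c
  }

  # noisy surrogate of a 15/h boundary: matches the oracle exactly and
  # recovers the generating boundary within +/- 3 in the typical replicate
  devs <- vapply(1:11, function(s) {
    set.seed(s)
    ahi <- runif(40, 0, 40)
    rei <- ahi + rnorm(40, 0, 3)
    cut <- optimal_cutoff(rei, ahi >= 15)
    expect_equal(cut, brute_cutoff(rei, ahi >= 15))
    abs(cut - 15)
  }, numeric(1))
  expect_lte(median(devs), 3)
})

test_that("binary metrics reproduce their defining formulas", {
  m <- binary_metrics(tp = 14, fp = 2, fn = 4, tn = 19)
  expect_equal(round_half_up(m$sensitivity, 1), 77.8)
  expect_equal(round_half_up(m$specificity, 1), 90.5)
  expect_equal(round_half_up(m$accuracy, 1), 84.6)
  expect_equal(round_half_up(m$ppa, 1), 87.5)
  expect_equal(round_half_up(m$npa, 1), 82.6)

  m0 <- binary_metrics(tp = 0, fp = 0, fn = 0, tn = 10)
  expect_equal(m0$specificity, 100)
  expect_true(is.na(m0$sensitivity))
  expect_true(is.na(m0$ppa))
  expect_error(binary_metrics(0, 0, 0, 0), "all-zero")

  # identity: accuracy = (sens * P + spec * N) / (P + N), on random tables
  set.seed(2)
  for (i in 1:20) {
    cts <- rmultinom(1, 40, c(0.3, 0.1, 0.15, 0.45))[, 1] + 1
    m <- binary_metrics(cts[1], cts[2], cts[3], cts[4])
    p <- cts[1] + cts[3]; n <- cts[2] + cts[4]
    expect_equal(m$accuracy, (m$sensitivity * p + m$specificity * n) / (p + n))
  }
})

test_that("four-level metrics summarize a confusion matrix correctly", {
  test_m <- rbind(c(7, 7, 2, 0), c(4, 3, 0, 0), c(1, 1, 5, 1), c(0, 0, 1, 7))
  mm <- multilevel_metrics(test_m)
  expect_equal(round_half_up(mm$accuracy, 1), 56.4)
  expect_equal(round_half_up(mm$off_by_share[["off_by_1"]], 0), 82)
  expect_equal(round_half_up(mm$off_by_share[["off_by_2"]], 0), 18)

  train_m <- rbind(c(12, 3, 2, 0), c(1, 3, 2, 0), c(0, 1, 4, 0),
                   c(0, 1, 0, 10))
  mt <- multilevel_metrics(train_m)
  expect_equal(round_half_up(mt$accuracy, 1), 74.4)
  expect_equal(round_half_up(mt$off_by_share[["off_by_1"]], 0), 70)
  expect_equal(round_half_up(mt$off_by_share[["off_by_2"]], 0), 30)
  expect_equal(round_half_up(mt$per_class_sensitivity, 0),
               c(92, 38, 50, 100))
  expect_equal(round_half_up(mt$per_class_specificity, 0),
               c(81, 90, 97, 97))

  perfect <- multilevel_metrics(diag(c(5, 5, 5, 5)))
  expect_equal(perfect$accuracy, 100)
  expect_true(all(is.na(perfect$off_by_share)))
})

test_that("REI severity bands use the 9/14/24 cutoffs, higher class wins", {
  expect_equal(as.character(classify_severity_by_rei(8.9)), "normal")
  expect_equal(as.character(classify_severity_by_rei(c(9, 14, 24))),
               c("mild", "moderate", "severe"))
  expect_error(classify_severity_by_rei(-1), "non-negative")
  set.seed(4)
  rei <- sort(runif(100, 0, 50))
  expect_true(all(diff(as.integer(classify_severity_by_rei(rei))) >= 0))

  conf <- severity_confusion(
    classify_severity_by_rei(c(5, 10, 20, 30)),
    severity_class(c(4, 10, 20, 40))
  )
  expect_equal(unname(diag(conf)), c(1, 1, 1, 1))
})

test_that("event matching scores recall and precision by interval overlap", {
  truth <- data.frame(start_s = c(100, 300, 500), end_s = c(130, 340, 560))
  det <- data.frame(start_s = c(105, 450, 700), end_s = c(128, 462, 720))
  m <- match_events(truth, det)
  expect_equal(m$tp, 1)   # only the first detection overlaps enough
  expect_equal(m$fn, 2)
  expect_equal(m$fp, 2)
  expect_equal(m$recall, 1 / 3)
  expect_equal(m$precision, 1 / 3)

  none <- match_events(truth, det[0, ])
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))
})
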