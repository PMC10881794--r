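test_that("dice matches the overlap formula and its edge conventions", {
  a <- matrix(0, 8, 8); a[2:5, 2:5] <- 1
  expect_equal(dice(a, a), 1)
  b <- matrix(0, 8, 8); b[6:8, 6:8] <- 1
  expect_equal(dice(a, b), 0)
  # |A| = |B| = 4 with overlap 2 -> 2*2/(4+4) = 0.5
  a2 <- matrix(0, 4, 4); a2[1, 1:4] <- 1
  b2 <- matrix(0, 4, 4); b2[1, 3:4] <- 1; b2[2, 1:2] <- 1
  expect_equal(dice(a2, b2), 0.5)
  # both empty: defined as agreement, flagged
  e <- matrix(0, 4, 4)
  d <- dice(e, e)
  expect_equal(as.numeric(d), 1)
  expect_true(attr(d, "both_empty"))
  expect_error(dice(a, matrix(0, 4, 4)), "shape")
  expect_error(dice(a * 2, a), "binary")
})

test_that("dice is symmetric and monotone in growing overlap", {
  set.seed(31)
  for (i in 1:20) {
    a <- matrix(rbinom(64, 1, 0.4), 8)
    b <- matrix(rbinom(64, 1, 0.4), 8)
    expect_equal(dice(a, b), dice(b, a))
  }
  # fixed areas, growing overlap: slide one 2x4 block over another
  base <- matrix(0, 8, 8); base[4:5, 1:4] <- 1
  dvals <- sapply(0:3, function(shift) {
    m <- matrix(0, 8, 8); m[4:5, (1 + shift):(4 + shift)] <- 1
    dice(m, base)
  })
  expect_true(all(diff(dvals) < 0))
})

test_that("confusion counts agree with brute-force pair counting", {
  expect_equal(unclass(confusion_counts(c(1, 0, 1), c(1, 0, 1)))[c("FP", "FN")],
               list(FP = 0L, FN = 0L), ignore_attr = TRUE)
  cc <- confusion_counts(rep(1, 10), rep(c(1, 0), 5))
  expect_equal(c(cc$TP, cc$FP, cc$TN, cc$FN), c(5, 5, 0, 0))
  set.seed(7)
  for (i in 1:20) {
    p <- rbinom(20, 1, 0.5); t <- rbinom(20, 1, 0.5)
    cc <- confusion_counts(p, t)
    ref <- c(TP = 0, FP = 0, TN = 0, FN = 0)
    for (j in 1:20) {
      k <- if (p[j] == 1 && t[j] == 1) "TP" else if (p[j] == 1) "FP"
           else if (t[j] == 0) "TN" else "FN"
      ref[k] <- ref[k] + 1
    }
    expect_equal(c(cc$TP, cc$FP, cc$TN, cc$FN), unname(ref))
  }
  expect_error(confusion_counts(c(1, 2), c(0, 1)), "0 or 1")
  expect_error(confusion_counts(c(1), c(0, 1)), "equal length")
})

test_that("diagnostic metrics reproduce a hand-computed confusion table", {
  m <- diagnostic_metrics(list(TP = 8, FN = 2, TN = 9, FP = 1))
  expect_equal(m$sen, 0.8)
  expect_equal(m$spe, 0.9)
  expect_equal(m$acc, 0.85)
  expect_equal(m$ppv, 8 / 9)
  expect_equal(m$npv, 9 / 11)
  expect_equal(m$plr, 8)
  expect_equal(m$nlr, 2 / 9)
  expect_length(m$undefined, 0)
})

test_that("zero-denominator metrics are flagged undefined, not zeroed", {
  m <- diagnostic_metrics(list(TP = 0, FN = 0, TN = 5, FP = 5))
  expect_true(is.na(m$sen))
  expect_true("sen" %in% m$undefined)
  expect_false(is.na(m$spe))
  expect_error(diagnostic_metrics(list(TP = 0, FN = 0, TN = 0, FP = 0)),
               "zero")
})

test_that("accuracy lies between sensitivity and specificity for balanced classes", {
  set.seed(11)
  for (i in 1:30) {
    t <- rep(c(0, 1), each = 25)
    p <- rbinom(50, 1, runif(1, 0.2, 0.8))
    m <- diagnostic_metrics(confusion_counts(p, t))
    if (is.na(m$sen) || is.na(m$spe)) next
    expect_gte(m$acc, min(m$sen, m$spe) - 1e-12)
    expect_lte(m$acc, max(m$sen, m$spe) + 1e-12)
  }
})

test_that("likelihood ratios follow their defining identities and conventions", {
  expect_equal(unname(likelihood_ratios(0.5, 0.5)), c(1, 1))
  lr <- likelihood_ratios(1, 1)
  expect_equal(unname(lr), c(Inf, 0))
  set.seed(3)
  for (i in 1:20) {
    sen <- runif(1); spe <- runif(1, 0.01, 0.99)
    lr <- likelihood_ratios(sen, spe)
    expect_equal(unname(lr["plr"]), sen / (1 - spe))
    expect_equal(unname(lr["nlr"]), (1 - sen) / spe)
  }
})

test_that("AUC equals the Mann-Whitney concordance on random instances", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC hits its separability anchors", {
  labels <- rep(c(0, 1), each = 10)
  expect_equal(roc_auc(c(rnorm(10), rnorm(10) + 100), labels)$auc, 1)
  set.seed(9)
  r <- roc_auc(runif(2000), rbinom(2000, 1, 0.5))
  expect_lt(abs(r$auc - 0.5), 0.05)
  expect_error(roc_auc(1:5, rep(1, 5)), "one class")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:5) {
    labels <- c(0, 1, rbinom(48, 1, 0.5))
    scores <- rnorm(50) + labels
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-10)
  }
})

test_that("cutoff selection maximises Youden's J", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n) + 0.8 * labels, 1)
    r <- roc_auc(scores, labels)
    cut <- choose_cutoff(r)
    expect_equal(cut$j, oracle_best_j(scores, labels), tolerance = 1e-12)
  }
  # perfect separation: J = 1 and the threshold separates the classes
  labels <- rep(c(0, 1), each = 8)
  scores <- c(runif(8, 0, 0.3), runif(8, 0.7, 1))
  cut <- choose_cutoff(roc_auc(scores, labels))
  expect_equal(cut$j, 1)
  expect_true(cut$threshold > 0.3 && cut$threshold <= 1)
  # uninformative scores: J near 0
  set.seed(19)
  cut0 <- choose_cutoff(roc_auc(runif(2000), rbinom(2000, 1, 0.5)))
  expect_lt(cut0$j, 0.1)
})

test_that("ties in J are broken toward higher specificity", {
  # two thresholds reach J = 0.5; the higher-specificity one must win
  scores <- c(0.1, 0.2, 0.3, 0.4)
  labels <- c(0, 1, 0, 1)
  cut <- choose_cutoff(roc_auc(scores, labels))
  expect_equal(cut$spe, 1)
  expect_equal(cut$threshold, 0.4)
})

test_that("Dice summaries use the linear-interpolation quartile convention", {
  s <- summarize_dice(0.5)
  expect_equal(s$median, 0.5)
  expect_equal(s$lower_quartile, 0.5)
  expect_equal(s$upper_quartile, 0.5)
  s2 <- summarize_dice(c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(s2$median, 0.5)
  expect_equal(s2$lower_quartile, 0.25)
  set.seed(23)
  s3 <- summarize_dice(runif(1000))
  expect_lt(abs(s3$lower_quartile - 0.25), 0.03)
  expect_lt(abs(s3$median - 0.5), 0.03)
  expect_lt(abs(s3$upper_quartile - 0.75), 0.03)
  expect_true(s3$lower_quartile <= s3$median && s3$median <= s3$upper_quartile)
  expect_error(summarize_dice(numeric()), "empty")
  expect_error(summarize_dice(c(0.5, 1.2)), "\\[0, 1\\]")
})
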