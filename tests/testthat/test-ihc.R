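test_that("hscore implements the weighted-percentage formula with bounds", {
  expect_equal(hscore(0, 0, 100), 300)
  expect_equal(hscore(0, 0, 0), 0)
  expect_equal(hscore(10, 20, 30), 140)
  expect_equal(hscore(c(0, 10), c(0, 20), c(100, 30)), c(300, 140))
  expect_error(hscore(60, 30, 20), "sum")
  expect_error(hscore(-5, 0, 0), "\\[0, 100\\]")
})

test_that("layer_score maps epithelial thirds, with the TOP2A collapse", {
  expect_equal(layer_score(0.5, "Ki-67"), 2L)
  expect_equal(layer_score(0.9, "TOP2A"), 2L)   # 3+ collapsed for TOP2A
  expect_equal(layer_score(1.0, "Ki-67"), 3L)
  expect_equal(layer_score(0.2, "Ki-67"), 1L)
  expect_equal(layer_score(0.2, "Ki-67", parabasal_only = TRUE), 0L)
  expect_error(layer_score(1.5), "\\[0, 1\\]")
})

test_that("binarize_marker applies the strict >10% SCC rule and noninvasive thresholds", {
  expect_identical(binarize_marker(list(percent_positive = 10), "RFC4", "SCC"),
                   "negative")
  expect_identical(binarize_marker(list(percent_positive = 11), "RFC4", "SCC"),
                   "positive")
  expect_identical(binarize_marker(list(layer = 2), "Ki-67", "noninvasive"),
                   "positive")
  expect_identical(binarize_marker(list(layer = 1), "Ki-67", "noninvasive"),
                   "negative")
  expect_identical(
    binarize_marker(list(intensity = 2, beyond_basal_flag = FALSE), "RFC4",
                    "noninvasive"), "negative")
  expect_identical(
    binarize_marker(list(intensity = 2, beyond_basal_flag = TRUE), "RFC4",
                    "noninvasive"), "positive")
  expect_error(binarize_marker(list(layer = 2), "NOVEL", "noninvasive"),
               "no positivity rule")
})

test_that("diagnostic_metrics reproduces a published-style row and degenerate tables", {
  m <- diagnostic_metrics(confusion_table(60, 8, 91, 10))
  est <- setNames(m$estimate, m$metric)
  expect_equal(round_half_up(100 * est[["sensitivity"]], 1), 88.2)
  expect_equal(round_half_up(100 * est[["specificity"]], 1), 90.1)
  expect_equal(round_half_up(100 * est[["ppv"]], 1), 85.7)
  expect_equal(round_half_up(100 * est[["npv"]], 1), 91.9)
  expect_equal(round_half_up(est[["auc"]], 2), 0.89)
  # exact CI bounds round to the published interval
  expect_equal(round_half_up(100 * m$lo[m$metric == "sensitivity"], 1), 78.1)
  expect_equal(round_half_up(100 * m$hi[m$metric == "sensitivity"], 1), 94.8)

  perfect <- diagnostic_metrics(confusion_table(10, 0, 10, 0))
  expect_equal(perfect$estimate, rep(1, 5))
  flat <- diagnostic_metrics(confusion_table(5, 5, 5, 5))
  expect_equal(flat$estimate, rep(0.5, 5))
  expect_error(diagnostic_metrics(confusion_table(0, 0, 5, 5)), "diseased")
})

test_that("diagnostic_metrics equals brute-force proportions for all small tables", {
  for (tp in 0:6) for (fn in 0:6) for (tn in 0:6) for (fp in 0:6) {
    if (tp + fn == 0 || tn + fp == 0 || tp + fp == 0 || tn + fn == 0) next
    m <- diagnostic_metrics(confusion_table(tp, fn, tn, fp))
    est <- setNames(m$estimate, m$metric)
    expect_identical(est[["sensitivity"]], tp / (tp + fn))
    expect_identical(est[["specificity"]], tn / (tn + fp))
    expect_identical(est[["ppv"]], tp / (tp + fp))
    expect_identical(est[["npv"]], tn / (tn + fn))
    expect_identical(est[["auc"]], (est[["sensitivity"]] + est[["specificity"]]) / 2)
  }
})

test_that("Clopper-Pearson intervals achieve nominal coverage", {
  n <- 68
  for (p in c(0.5, 0.9)) {
    set.seed(round(1000 * p))
    x <- rbinom(10000, n, p)
    lo <- qbeta(0.025, x, n - x + 1); lo[x == 0] <- 0
    hi <- qbeta(0.975, x + 1, n - x); hi[x == n] <- 1
    expect_gte(mean(lo <= p & p <= hi), 0.95)
    # the package CI matches the qbeta form on a spot check
    ci <- diagnostic_metrics(confusion_table(61, 7, 1, 1))
    expect_equal(ci$lo[1], qbeta(0.025, 61, 8), tolerance = 1e-9)
  }
})

test_that("roc_auc equals the pairwise Mann-Whitney count", {
  expect_equal(roc_auc(c(3, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 0.875)
  expect_equal(roc_auc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  set.seed(90)
  for (i in 1:10) {
    sc <- sample(1:4, 20, TRUE)
    tr <- sample(c(TRUE, FALSE), 20, TRUE)
    if (!any(tr) || all(tr)) next
    expect_equal(roc_auc(sc, tr), oracle_auc(sc, tr), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "control")
})

test_that("mcnemar_exact matches the binomial enumeration oracle", {
  expect_equal(mcnemar_exact(rep("positive", 10), rep("negative", 10))$p,
               2 * 0.5^10)
  mk <- function(b, cc, a = 3) {
    list(A = rep(c("positive", "positive", "negative"), c(a, b, cc)),
         B = rep(c("positive", "negative", "positive"), c(a, b, cc)))
  }
  expect_equal(mcnemar_exact(mk(3, 3)$A, mk(3, 3)$B)$p, 1)
  expect_equal(mcnemar_exact(mk(0, 0)$A, mk(0, 0)$B)$p, 1)
  for (b in 0:10) for (cc in 0:(10 - b %% 3)) {
    x <- mk(b, cc)
    expect_equal(mcnemar_exact(x$A, x$B)$p, oracle_mcnemar(b, cc),
                 tolerance = 1e-12)
  }
  # missing calls excluded pairwise
  A <- c("positive", NA, "negative"); B <- c("negative", "positive", NA)
  expect_equal(mcnemar_exact(A, B)$b, 1)
  expect_equal(mcnemar_exact(A, B)$c, 0)
})

test_that("cohens_kappa: perfect, chance-level and published-style agreement", {
  a <- rep(c("positive", "negative"), c(10, 8))
  expect_equal(cohens_kappa(a, a)$kappa, 1)

  set.seed(91)
  x <- sample(c("positive", "negative"), 10000, TRUE)
  y <- sample(c("positive", "negative"), 10000, TRUE)
  expect_lt(abs(cohens_kappa(x, y)$kappa), 0.05)

  # 2x2 table a=60, b=2, c=0, d=6
  A <- rep(c("pos", "pos", "neg", "neg"), c(60, 2, 0, 6))
  B <- rep(c("pos", "neg", "pos", "neg"), c(60, 2, 0, 6))
  k <- cohens_kappa(A, B)
  expect_equal(k$po, 66 / 68)
  expect_equal(k$pe, (62 * 60 + 6 * 8) / 68^2)
  expect_equal(round_half_up(k$kappa, 2), 0.84)
  # both raters constant and equal: chance agreement is 1, kappa defined as 1
  expect_equal(cohens_kappa(rep("x", 5), rep("x", 5))$kappa, 1)
  # one rater constant, imperfect agreement: kappa is 0 (po equals pe)
  expect_equal(cohens_kappa(rep("x", 5), c(rep("x", 4), "y"))$kappa, 0)
})

test_that("combine_markers obeys serial/parallel set logic and its metric bounds", {
  A <- c("positive", "positive", "negative", NA)
  B <- c("positive", "negative", "positive", "positive")
  expect_identical(combine_markers(A, B, "serial"),
                   c("positive", "negative", "negative", NA))
  expect_identical(combine_markers(A, B, "parallel"),
                   c("positive", "positive", "positive", NA))
  expect_identical(combine_markers(A, A, "serial"), A)
  expect_identical(combine_markers(A, A, "parallel"), A)

  # serial sensitivity <= min individual; parallel >= max (100 cohorts)
  set.seed(92)
  ok <- vapply(1:100, function(i) {
    truth <- rep(c(TRUE, FALSE), c(40, 40))
    pa <- ifelse(runif(80) < ifelse(truth, 0.8, 0.2), "positive", "negative")
    pb <- ifelse(runif(80) < ifelse(truth, 0.7, 0.3), "positive", "negative")
    sens <- function(calls) mean(calls[truth] == "positive")
    s_ser <- sens(combine_markers(pa, pb, "serial"))
    s_par <- sens(combine_markers(pa, pb, "parallel"))
    s_ser <= min(sens(pa), sens(pb)) && s_par >= max(sens(pa), sens(pb))
  }, TRUE)
  expect_true(all(ok))
})

test_that("confusion tables are assembled from calls with pairwise NA exclusion", {
  calls <- c("positive", "negative", NA, "positive")
  truth <- c(TRUE, TRUE, TRUE, FALSE)
  ct <- confusion_from_calls(calls, truth)
  expect_equal(unlist(ct[c("tp", "fn", "tn", "fp")]),
               c(tp = 1, fn = 1, tn = 0, fp = 1))
})
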