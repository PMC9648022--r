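make_cohort <- function(time, event, ...) {
  data.frame(time_months = time, event = event, ...)
}

test_that("apply_censor_rule truncates at the 5-year horizon, boundary inclusive", {
  co <- make_cohort(c(72, 48, 60), c(1, 1, 1))
  out <- apply_censor_rule(co)
  expect_equal(out$time_months, c(60, 48, 60))
  expect_equal(out$event, c(0, 1, 1))    # exactly 60 months unchanged
  expect_error(apply_censor_rule(make_cohort(c(-1, 5), c(1, 0))), ">= 0")
})

test_that("km_estimate equals the empirical survival function without censoring", {
  time <- c(2, 5, 5, 9, 14)
  km <- km_estimate(make_cohort(time, rep(1, 5)))
  ecdf_surv <- vapply(km$time, function(t) mean(time > t), 0)
  expect_equal(km$surv, ecdf_surv)
  # and the closed-form product at distinct event times
  expect_equal(km$surv[km$time == 9],
               oracle_km(time, rep(1, 5), 9))
  # with censoring, matches the product-limit oracle
  ev <- c(1, 0, 1, 1, 0)
  km2 <- km_estimate(make_cohort(time, ev))
  for (t in km2$time) expect_equal(km2$surv[km2$time == t],
                                   oracle_km(time, ev, t))
})

test_that("logrank_test matches the O-E/variance oracle and is null on duplicated groups", {
  set.seed(100)
  time <- round(rexp(40, 0.05), 1); ev <- rbinom(40, 1, 0.8)
  grp <- rep(c("a", "b"), 20)
  lt <- logrank_test(make_cohort(time, ev), grp)
  expect_equal(lt$chisq, oracle_logrank(time, ev, grp), tolerance = 1e-9)
  expect_equal(lt$z^2, lt$chisq, tolerance = 1e-9)

  co2 <- make_cohort(rep(time, 2), rep(ev, 2))
  lt2 <- logrank_test(co2, rep(c("a", "b"), each = 40))
  expect_lt(lt2$chisq, 1e-9)
  expect_equal(lt2$p, 1, tolerance = 1e-6)
  expect_error(logrank_test(make_cohort(1:3, c(1, 1, 1)),
                            factor(c("a", "a", "a"), levels = c("a", "b"))),
               "non-empty")
})

test_that("log-rank has power against a hazard ratio of 3 and holds its level", {
  # power: HR 3 at n = 200/200
  sig <- vapply(1:50, function(r) {
    set.seed(200 + r)
    t1 <- rexp(200, 0.03); t2 <- rexp(200, 0.09)
    co <- make_cohort(c(t1, t2), rep(1, 400))
    logrank_test(co, rep(c("lo", "hi"), each = 200))$p < 0.001
  }, TRUE)
  expect_gte(mean(sig), 0.99)
  # level under the exchangeable null (within the spec's [0.03, 0.07] band)
  rej <- vapply(1:2000, function(r) {
    set.seed(3000 + r)
    co <- make_cohort(rexp(60, 0.05), rbinom(60, 1, 0.8))
    logrank_test(co, rep(c("a", "b"), 30))$p < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.03); expect_lte(mean(rej), 0.07)
})

test_that("optimal_cutpoint finds a separating gap and flags selection bias", {
  # low marker half dies early, high half late: cutoff at the gap
  set.seed(110)
  n <- 60
  marker <- c(runif(n / 2, 0, 1), runif(n / 2, 2, 3))
  time <- c(rexp(n / 2, 1), 50 + rexp(n / 2, 0.01))
  co <- make_cohort(time, rep(1, n), marker_value = marker)
  oc <- optimal_cutpoint(co)
  # the selected cutoff sits at the design gap (up to one boundary subject:
  # the log-rank maximum can sit one split away from the clean partition)
  expect_lt(oc$cutoff, min(marker[(n / 2 + 1):n]))
  expect_lte(sum(marker[1:(n / 2)] > oc$cutoff), 1)
  expect_gt(abs(oc$z), 5)
  expect_true(oc$selection_biased)

  # minprop = 0.5 with even n: only the median split is considered
  co2 <- make_cohort(rexp(20, 0.1), rep(1, 20), marker_value = 1:20)
  oc2 <- optimal_cutpoint(co2, minprop = 0.5)
  expect_equal(oc2$n_low, 10); expect_equal(oc2$n_high, 10)
  expect_equal(oc2$cutoff, 10)

  expect_error(optimal_cutpoint(make_cohort(1:4, rep(1, 4),
                                            marker_value = rep(1, 4))),
               "no valid split")
})

test_that("naive p at the selected cutpoint is anti-conservative; permutation p is not", {
  # marker independent of survival: the maximal statistic's naive p inflates
  naive_p <- vapply(1:60, function(r) {
    set.seed(400 + r)
    co <- make_cohort(rexp(50, 0.05), rep(1, 50), marker_value = runif(50))
    oc <- optimal_cutpoint(co)
    2 * pnorm(-abs(oc$z))
  }, 0)
  expect_gt(mean(naive_p < 0.05), 0.12)   # well above the nominal 5%
  # permutation-calibrated p for one instance is unremarkable
  set.seed(461)
  co <- make_cohort(rexp(40, 0.05), rep(1, 40), marker_value = runif(40))
  oc <- optimal_cutpoint(co, n_perm = 60)
  expect_gt(oc$perm_p, 0.01)
})

test_that("cox_fit recovers a planted hazard ratio and matches the analytic two-event case", {
  # parameter recovery: true HR = 2, n = 1000, ~20% censoring; the
  # estimator is unbiased on the log scale and its Wald CI holds coverage
  res <- vapply(1:100, function(r) {
    set.seed(500 + r)
    x <- rbinom(1000, 1, 0.5)
    t_ev <- rexp(1000, 0.02 * exp(log(2) * x))
    cens <- rexp(1000, 0.005)
    co <- make_cohort(pmin(t_ev, cens), as.integer(t_ev <= cens), x = x)
    fit <- cox_fit(co, "x")
    c(fit$beta, fit$lo <= 2 && 2 <= fit$hi)
  }, c(0, 0))
  expect_lt(abs(mean(res[1, ]) - log(2)), 3 * sd(res[1, ]) / 10)
  expect_gte(mean(res[2, ]), 0.9)    # 95% CI coverage

  # two subjects, one covariate, no ties: partial likelihood maximum is
  # analytic -- with x = (1, 0) and the x=1 subject dying first while both
  # are at risk, the score is 1 - e^b/(1+e^b) > 0 for all finite b, so the
  # MLE diverges; the separation guard must fire
  co_sep <- make_cohort(c(1, 2), c(1, 1), x = c(1, 0))
  expect_error(suppressWarnings(cox_fit(co_sep, "x")), "separation|converge")
  # with the order reversed the partial likelihood is maximized at a
  # finite beta: only the first event (x=0 subject) carries information,
  # score = -e^b/(1+e^b) + ... solves to the coxph estimate; compare to a
  # direct grid maximization of the partial likelihood
  co2 <- make_cohort(c(2, 1, 3), c(1, 1, 1), x = c(1, 0, 0))
  fit <- cox_fit(co2, "x")
  pl <- function(b) {
    # risk sets: t=1 {all}, t=2 {x=1, x=0(t=3)}, t=3 {x=0}
    log(1 / (2 + exp(b))) + log(exp(b) / (1 + exp(b))) + log(1)
  }
  grid <- seq(-5, 5, 1e-4)
  expect_equal(fit$beta, grid[which.max(vapply(grid, pl, 0))], tolerance = 1e-3)

  expect_error(cox_fit(make_cohort(1:4, rep(1, 4), x = rep(1, 4)), "x"),
               "constant")
})

test_that("cox_fit Wald p-values are uniform under the null", {
  pv <- vapply(1:500, function(r) {
    set.seed(700 + r)
    x <- rnorm(300)
    co <- make_cohort(rexp(300, 0.05), rbinom(300, 1, 0.8), x = x)
    cox_fit(co, "x")$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("cox score test at beta = 0 equals the log-rank statistic", {
  set.seed(120)
  time <- rexp(50, 0.05); ev <- rbinom(50, 1, 0.9)
  x <- rbinom(50, 1, 0.5)
  co <- make_cohort(time, ev, x = x)
  fit <- survival::coxph(survival::Surv(time_months, event) ~ x, data = co,
                         ties = "breslow")
  expect_equal(unname(fit$score), oracle_logrank(time, ev, x), tolerance = 1e-6)
})

test_that("time_dependent_auc: identity without censoring, 1 for perfect ranking, 0.5 null", {
  # no censoring: IPCW AUC equals the empirical case/control AUC at each t
  set.seed(130)
  n <- 300
  risk <- rnorm(n)
  time <- rexp(n, 0.03 * exp(0.8 * risk))
  co <- make_cohort(pmin(time, 80), as.integer(time <= 80))
  co$event[co$time_months == 80] <- 0   # administrative only
  td <- time_dependent_auc(co, risk, times = c(12, 24, 36), n_boot = 0)
  for (j in seq_along(td$time)) {
    t <- td$time[j]
    case <- co$event == 1 & co$time_months <= t
    ctrl <- co$time_months > t
    keep <- case | ctrl
    expect_equal(td$auc[j], roc_auc(risk[keep], case[keep]), tolerance = 1e-9)
  }

  # perfect risk ranking: AUC(t) = 1 at all t with events before t
  co2 <- make_cohort(c(5, 10, 15, 70, 80, 90), c(1, 1, 1, 0, 0, 0))
  td2 <- time_dependent_auc(co2, risk = c(6, 5, 4, 1, 2, 3),
                            times = c(12, 24), n_boot = 0)
  expect_equal(td2$auc, c(1, 1))

  # independent risk score: AUC ~ 0.5
  set.seed(131)
  co3 <- make_cohort(rexp(1000, 0.03), rep(1, 1000))
  td3 <- time_dependent_auc(co3, rnorm(1000), times = c(12, 24, 36), n_boot = 0)
  expect_true(all(abs(td3$auc - 0.5) < 0.05))
  expect_error(time_dependent_auc(make_cohort(c(50, 60), c(1, 1)), c(1, 2),
                                  times = 12), "no events")
})

test_that("nested-model AUC comparison returns bootstrap and Holm-adjusted p-values", {
  set.seed(140)
  n <- 150
  x <- rnorm(n)
  time <- rexp(n, 0.05 * exp(1.2 * x))
  co <- make_cohort(time, rep(1, n))
  td <- time_dependent_auc(co, risk = x, risk2 = rnorm(n),
                           times = c(12, 24), n_boot = 200)
  expect_true(all(td$p_holm >= td$p - 1e-12))
  expect_lt(td$p[1], 0.05)   # informative model beats noise
})
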