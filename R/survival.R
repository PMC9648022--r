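# Prognostic evaluation: administrative censoring, Kaplan-Meier/log-rank,
# maximally selected cutpoint dichotomization, multivariate Cox
# proportional hazards (Efron ties), and IPCW time-dependent AUC.
#
# A cohort is a data.frame with at least `time_months` (>= 0) and `event`
# (0/1); typical extra columns: patient_id, cohort, endpoint, age,
# figo_stage, grade, marker_value.

.check_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort),
            all(c("time_months", "event") %in% names(cohort)))
  if (any(is.na(cohort$time_months)) || any(is.na(cohort$event)))
    stop("time/event must not be missing")
  if (any(cohort$time_months < 0)) stop("times must be >= 0")
  if (!all(cohort$event %in% c(0, 1))) stop("event must be 0/1")
  invisible(cohort)
}

#' Administrative censoring at a follow-up horizon
#'
#' Subjects followed beyond the horizon (default 60 months = 5 years) are
#' censored there: records with `time > horizon` are truncated to the
#' horizon with `event = 0`; a record exactly at the horizon is kept as is
#' (boundary inclusive).
#'
#' @param cohort survival cohort data.frame.
#' @param horizon months (default 60).
#' @return the cohort with the rule applied.
#' @export
apply_censor_rule <- function(cohort, horizon = 60) {
  .check_cohort(cohort)
  over <- cohort$time_months > horizon
  cohort$event[over] <- 0
  cohort$time_months[over] <- horizon
  cs_log("apply_censor_rule: %d record(s) truncated at %g months",
         sum(over), horizon)
  cohort
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function, optionally by group.
#'
#' @param cohort survival cohort data.frame.
#' @param group optional grouping vector (length nrow).
#' @return data.frame with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` (and `group` when grouped).
#' @export
km_estimate <- function(cohort, group = NULL) {
  .check_cohort(cohort)
  s <- survival::Surv(cohort$time_months, cohort$event)
  if (is.null(group)) {
    fit <- survival::survfit(s ~ 1)
    data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               n_censor = fit$n.censor, surv = fit$surv)
  } else {
    fit <- survival::survfit(s ~ grp, data = data.frame(grp = group))
    data.frame(group = rep(sub("^grp=", "", names(fit$strata)), fit$strata),
               time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               n_censor = fit$n.censor, surv = fit$surv)
  }
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square; for two groups also returns the signed
#' standardized statistic `z = (O1 - E1) / sqrt(V1)`.
#'
#' @param cohort survival cohort data.frame.
#' @param group grouping vector (>= 2 levels, each non-empty).
#' @return list with `chisq`, `df`, `p`, and `z` (two groups only).
#' @export
logrank_test <- function(cohort, group) {
  .check_cohort(cohort)
  group <- as.factor(group)
  if (any(table(group) == 0) || nlevels(group) < 2)
    stop("every group must be non-empty")
  if (sum(cohort$event) < 1) stop("need at least one event")
  sd_ <- survival::survdiff(
    survival::Surv(time_months, event) ~ grp,
    data = data.frame(cohort, grp = group))
  df <- nlevels(group) - 1
  z <- if (nlevels(group) == 2)
    (sd_$obs[1] - sd_$exp[1]) / sqrt(sd_$var[1, 1]) else NA_real_
  list(chisq = unname(sd_$chisq), df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE), z = z)
}

#' Maximally selected log-rank cutpoint
#'
#' Dichotomizes a continuous marker at the cutoff maximizing the absolute
#' standardized two-group log-rank statistic, over all candidate cutoffs
#' leaving at least `minprop` of subjects on each side; ties go to the
#' smallest cutoff.  The p-value of a log-rank test re-run at the selected
#' cutoff on the same data is selection-inflated, so the result carries a
#' `selection_biased` flag and, optionally, a permutation-based p-value for
#' the maximal statistic.
#'
#' @param cohort survival cohort data.frame.
#' @param marker numeric marker vector (length nrow) or the name of a
#'   cohort column (default `"marker_value"`).
#' @param minprop minimum group fraction (default 0.1).
#' @param n_perm permutations for the unbiased p-value of the maximal
#'   statistic (0 = skip, the default).
#' @return list with `cutoff`, `statistic` (|z| at the cutoff), `z`,
#'   `n_low`, `n_high`, `selection_biased = TRUE`, and `perm_p` when
#'   requested.
#' @export
optimal_cutpoint <- function(cohort, marker = "marker_value", minprop = 0.1,
                             n_perm = 0) {
  .check_cohort(cohort)
  x <- if (is.character(marker) && length(marker) == 1) cohort[[marker]] else marker
  stopifnot(length(x) == nrow(cohort))
  max_abs_z <- function(xv) {
    cuts <- sort(unique(xv))
    cuts <- cuts[-length(cuts)]          # "high" group = x > cutoff
    n <- length(xv)
    best <- NULL
    for (ct in cuts) {
      hi <- xv > ct
      if (min(sum(hi), n - sum(hi)) < minprop * n) next
      lt <- tryCatch(logrank_test(cohort, ifelse(hi, "high", "low")),
                     error = function(e) NULL)
      if (is.null(lt)) next
      if (is.null(best) || abs(lt$z) > best$stat + 1e-12)
        best <- list(cut = ct, stat = abs(lt$z), z = lt$z, n_hi = sum(hi))
    }
    best
  }
  best <- max_abs_z(x)
  if (is.null(best)) stop("no valid split satisfies minprop")
  out <- list(cutoff = best$cut, statistic = best$stat, z = best$z,
              n_low = nrow(cohort) - best$n_hi, n_high = best$n_hi,
              selection_biased = TRUE)
  if (n_perm > 0) {
    obs <- best$stat
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      bb <- max_abs_z(sample(x))
      if (!is.null(bb) && bb$stat >= obs) exceed <- exceed + 1L
    }
    out$perm_p <- (exceed + 1) / (n_perm + 1)
  }
  cs_log("optimal_cutpoint: cutoff %g (|z| = %.3f, %d low / %d high)",
         out$cutoff, out$statistic, out$n_low, out$n_high)
  out
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling; Wald confidence
#' intervals and p-values.  Errors on non-convergence (100 iterations) and
#' on monotone-likelihood separation (|beta| > 15).
#'
#' @param cohort survival cohort data.frame.
#' @param covariates character vector of cohort column names to adjust for.
#' @return data.frame per covariate: `term`, `beta`, `hr`, `lo`, `hi`,
#'   `p`; attribute `loglik` holds the fitted model log-likelihood,
#'   attribute `fit` the `coxph` object.
#' @export
cox_fit <- function(cohort, covariates) {
  .check_cohort(cohort)
  if (sum(cohort$event) < 1) stop("need at least one event")
  for (cv in covariates) {
    v <- cohort[[cv]]
    if (is.null(v)) stop("missing covariate column ", cv)
    if (length(unique(v)) < 2) stop("covariate ", cv, " is constant")
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time_months, event) ~",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = cohort, ties = "efron",
                         control = survival::coxph.control(iter.max = 100,
                                                           eps = 1e-9))
  if (!is.null(fit$info) && grepl("did not converge", paste(fit$info, collapse = " ")))
    stop("Cox fit did not converge")
  if (fit$iter >= 100) stop("Cox fit did not converge in 100 iterations")
  beta <- coef(fit)
  if (any(abs(beta) > 15))
    stop("separation detected: |beta| > 15 for ",
         paste(names(beta)[abs(beta) > 15], collapse = ", "))
  sev <- sqrt(diag(vcov(fit)))
  z <- qnorm(0.975)
  out <- data.frame(term = names(beta), beta = unname(beta),
                    hr = exp(unname(beta)),
                    lo = exp(unname(beta) - z * sev),
                    hi = exp(unname(beta) + z * sev),
                    p = 2 * pnorm(-abs(unname(beta) / sev)),
                    row.names = NULL)
  attr(out, "loglik") <- fit$loglik[2]
  attr(out, "fit") <- fit
  out
}

# Kaplan-Meier estimate of the censoring distribution G(t); returns a step
# function giving G at t (right-continuous) -- left limits via t - eps.
.censor_km <- function(cohort) {
  fit <- survival::survfit(
    survival::Surv(time_months, 1 - event) ~ 1, data = cohort)
  stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
}

#' IPCW time-dependent ROC AUC
#'
#' Cumulative-case / dynamic-control AUC at each evaluation time:
#' cases are subjects with an observed event by `t`, controls those still
#' at risk beyond `t`; cases are weighted by the inverse of the
#' Kaplan-Meier censoring survival just before their event time (the
#' common control weight `1/G(t)` cancels).  With no censoring this equals
#' the empirical case/control AUC at each time.  When a second risk score
#' is supplied, the AUC difference (`risk` minus `risk2`) is tested at each
#' time by a paired bootstrap, with Holm adjustment across times.
#'
#' @param cohort survival cohort data.frame.
#' @param risk numeric risk score (higher = worse prognosis).
#' @param times evaluation times in months (default `c(12,24,36,48,60)`).
#' @param risk2 optional second (e.g. nested-model) risk score.
#' @param n_boot bootstrap resamples for the comparison (default 1000).
#' @return data.frame: `time`, `auc` (and with `risk2`: `auc2`, `diff`,
#'   `p`, `p_holm`).
#' @export
time_dependent_auc <- function(cohort, risk, times = c(12, 24, 36, 48, 60),
                               risk2 = NULL, n_boot = 1000) {
  .check_cohort(cohort)
  stopifnot(length(risk) == nrow(cohort))
  if (!any(cohort$event == 1 & cohort$time_months <= min(times)))
    stop("no events before the first evaluation time")
  auc_at <- function(time_v, event_v, score, t) {
    case <- event_v == 1 & time_v <= t
    # event-free at t: strictly later follow-up, or censored exactly at t
    # (keeps the last evaluation time usable under an administrative
    # horizon, where no observation can exceed t)
    ctrl <- time_v > t | (time_v == t & event_v == 0)
    if (!any(case) || !any(ctrl)) return(NA_real_)
    G <- .censor_km(data.frame(time_months = time_v, event = event_v))
    w <- 1 / pmax(G(time_v[case] - 1e-9), 1e-12)
    sc_case <- score[case]; sc_ctrl <- score[ctrl]
    conc <- vapply(seq_along(sc_case), function(i) {
      sum(sc_case[i] > sc_ctrl) + 0.5 * sum(sc_case[i] == sc_ctrl)
    }, 0)
    sum(w * conc) / (sum(w) * length(sc_ctrl))
  }
  auc1 <- vapply(times, function(t)
    auc_at(cohort$time_months, cohort$event, risk, t), 0)
  out <- data.frame(time = times, auc = auc1)
  if (!is.null(risk2)) {
    out$auc2 <- vapply(times, function(t)
      auc_at(cohort$time_months, cohort$event, risk2, t), 0)
    out$diff <- out$auc - out$auc2
    n <- nrow(cohort)
    boot_diff <- matrix(NA_real_, n_boot, length(times))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      boot_diff[b, ] <- vapply(times, function(t) {
        a1 <- auc_at(cohort$time_months[idx], cohort$event[idx], risk[idx], t)
        a2 <- auc_at(cohort$time_months[idx], cohort$event[idx], risk2[idx], t)
        a1 - a2
      }, 0)
    }
    out$p <- vapply(seq_along(times), function(j) {
      d <- boot_diff[, j]; d <- d[!is.na(d)]
      if (!length(d)) return(NA_real_)
      min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
    }, 0)
    out$p_holm <- p.adjust(out$p, method = "holm")
  }
  out
}
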