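# Immunohistochemistry scoring systems and diagnostic evaluation of binary
# marker calls against gold-standard histology: H-score, epithelial-layer
# score, positivity rules, confusion-table metrics with exact CIs, ROC AUC,
# exact McNemar, Cohen's kappa, and serial/parallel marker combination.

#' Semi-quantitative histologic score (H-score)
#'
#' `HSCORE = 1 * (% cells 1+) + 2 * (% cells 2+) + 3 * (% cells 3+)`,
#' ranging 0-300, from the percentages of cells staining at each intensity.
#'
#' @param pct1,pct2,pct3 percentages of cells (0-100) at intensities 1+,
#'   2+, 3+; vectors recycle.
#' @return numeric H-score(s) in `[0, 300]`.
#' @export
hscore <- function(pct1, pct2, pct3) {
  if (any(c(pct1, pct2, pct3) < 0 | c(pct1, pct2, pct3) > 100))
    stop("percentages must be in [0, 100]")
  if (any(pct1 + pct2 + pct3 > 100 + 1e-9))
    stop("intensity percentages sum to more than 100")
  1 * pct1 + 2 * pct2 + 3 * pct3
}

#' Epithelial-layer score for noninvasive lesions
#'
#' Staining extent as a fraction of the epithelial height, scored
#' parabasal-only = 0, lower third = 1+, lower two thirds = 2+, more than
#' two thirds up to full thickness = 3+.  For TOP2A the 3+ score is
#' collapsed into 2+.
#'
#' @param stained_fraction fraction of epithelial height stained, in
#'   `[0, 1]`.
#' @param marker marker name; `"TOP2A"` triggers the 3+ -> 2+ collapse.
#' @param parabasal_only logical; TRUE scores 0 regardless of fraction.
#' @return integer score in `{0, 1, 2, 3}` (`{0, 1, 2}` for TOP2A).
#' @export
layer_score <- function(stained_fraction, marker = "", parabasal_only = FALSE) {
  if (any(stained_fraction < 0 | stained_fraction > 1))
    stop("stained_fraction must be in [0, 1]")
  sc <- ifelse(stained_fraction <= 1 / 3, 1L,
               ifelse(stained_fraction <= 2 / 3, 2L, 3L))
  sc[parabasal_only] <- 0L
  if (toupper(marker) == "TOP2A") sc[sc == 3L] <- 2L
  sc
}

#' Default positivity rules for noninvasive lesions
#'
#' Reconstructed marker-specific thresholds on the raw scores (the original
#' scoring table is not fully published; these defaults are explicit
#' reconstructions and are configurable): p16 uses a supplied diffuse
#' block-positivity flag; Ki-67 and TOP2A are positive at layer score >= 2;
#' AURKA and CEP55 at staining intensity >= 2; RFC4 at intensity >= 2 with
#' staining beyond the basal layer (flag column).
#'
#' @return named list of rules, one per marker.
#' @export
default_positivity_rules <- function() {
  list(
    p16   = list(kind = "flag"),
    `Ki-67` = list(kind = "layer", threshold = 2),
    TOP2A = list(kind = "layer", threshold = 2),
    AURKA = list(kind = "intensity", threshold = 2),
    CEP55 = list(kind = "intensity", threshold = 2),
    RFC4  = list(kind = "intensity_flag", threshold = 2)
  )
}

#' Binary positivity call from a raw IHC score record
#'
#' SCC sections are positive when strictly more than 10% of cancer cells
#' stain, for every marker.  Noninvasive sections use the marker-specific
#' rule (see [default_positivity_rules()]).
#'
#' @param score one-row list/data.frame with fields among `layer`,
#'   `intensity`, `percent_positive`, `block_positive_flag`,
#'   `beyond_basal_flag`.
#' @param marker marker name (must be present in `rules`).
#' @param lesion_kind `"noninvasive"` or `"SCC"`.
#' @param rules rule list (default [default_positivity_rules()]).
#' @return `"positive"`, `"negative"`, or `NA` if the needed field is
#'   missing.
#' @export
binarize_marker <- function(score, marker,
                            lesion_kind = c("noninvasive", "SCC"),
                            rules = default_positivity_rules()) {
  lesion_kind <- match.arg(lesion_kind)
  as_call <- function(x) if (is.na(x)) NA_character_ else
    if (x) "positive" else "negative"
  if (lesion_kind == "SCC") {
    pp <- score$percent_positive
    if (is.null(pp)) stop("SCC rule needs percent_positive")
    return(as_call(pp > 10))
  }
  rule <- rules[[marker]]
  if (is.null(rule)) stop("no positivity rule for marker ", marker)
  switch(rule$kind,
    flag = as_call(as.logical(score$block_positive_flag)),
    layer = as_call(score$layer >= rule$threshold),
    intensity = as_call(score$intensity >= rule$threshold),
    intensity_flag = as_call(score$intensity >= rule$threshold &
                               as.logical(score$beyond_basal_flag)),
    stop("unknown rule kind ", rule$kind)
  )
}

#' Confusion table
#' @param tp,fn,tn,fp non-negative counts (true/false positives/negatives
#'   with respect to the gold-standard diagnosis).
#' @return list of class `confusion_table`.
#' @export
confusion_table <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp),
            class = "confusion_table")
}

#' Confusion table from calls and truth
#' @param calls character vector of `"positive"`/`"negative"` (NA dropped
#'   pairwise with truth).
#' @param truth logical vector, TRUE = diseased.
#' @return a [confusion_table()].
#' @export
confusion_from_calls <- function(calls, truth) {
  ok <- !is.na(calls) & !is.na(truth)
  calls <- calls[ok] == "positive"; truth <- truth[ok]
  confusion_table(tp = sum(calls & truth), fn = sum(!calls & truth),
                  tn = sum(!calls & !truth), fp = sum(calls & !truth))
}

# exact (Clopper-Pearson) two-sided 95% CI for x successes of n
.cp_ci <- function(x, n, conf = 0.95) {
  as.numeric(binom.test(x, n, conf.level = conf)$conf.int)
}

#' Diagnostic metrics of a binary test
#'
#' Sensitivity, specificity, PPV and NPV with exact Clopper-Pearson 95%
#' CIs, and the binary-test AUC `(sensitivity + specificity) / 2` with a
#' Hanley-McNeil variance CI.
#'
#' @param ct a [confusion_table()].
#' @return data.frame with one row per metric (`sensitivity`,
#'   `specificity`, `ppv`, `npv`, `auc`): `estimate`, `lo`, `hi`.
#' @export
diagnostic_metrics <- function(ct) {
  n_dis <- ct$tp + ct$fn; n_con <- ct$tn + ct$fp
  if (n_dis < 1 || n_con < 1) stop("need at least one diseased and one control")
  n_pos <- ct$tp + ct$fp; n_neg <- ct$tn + ct$fn
  if (n_pos < 1 || n_neg < 1) stop("empty test margin")
  prop <- function(x, n) c(x / n, .cp_ci(x, n))
  se <- prop(ct$tp, n_dis)
  sp <- prop(ct$tn, n_con)
  ppv <- prop(ct$tp, n_pos)
  npv <- prop(ct$tn, n_neg)
  auc <- (se[1] + sp[1]) / 2
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  se_auc <- sqrt((auc * (1 - auc) + (n_dis - 1) * (q1 - auc^2) +
                    (n_con - 1) * (q2 - auc^2)) / (n_dis * n_con))
  z <- qnorm(0.975)
  out <- rbind(sensitivity = se, specificity = sp, ppv = ppv, npv = npv,
               auc = c(auc, max(0, auc - z * se_auc), min(1, auc + z * se_auc)))
  out <- data.frame(metric = rownames(out), estimate = out[, 1],
                    lo = out[, 2], hi = out[, 3], row.names = NULL)
  out
}

#' Empirical ROC AUC of an ordinal score
#'
#' Mann-Whitney form: the fraction of case/control pairs ranked correctly,
#' ties counted 1/2.
#'
#' @param scores numeric (or ordinal) marker scores.
#' @param truth logical, TRUE = case.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("need at least one case and one control")
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Exact McNemar test for paired binary calls
#'
#' With discordant counts `b` (A positive, B negative) and `c` (A negative,
#' B positive), the two-sided exact binomial p-value
#' `min(1, 2 * P(X <= min(b, c)))` for `X ~ Bin(b + c, 1/2)`.  Pairs with a
#' missing call in either marker are excluded.
#'
#' @param calls_a,calls_b character vectors of `"positive"`/`"negative"`
#'   (or logical), paired by position.
#' @return list with `b`, `c`, `p`.
#' @export
mcnemar_exact <- function(calls_a, calls_b) {
  a <- if (is.logical(calls_a)) calls_a else calls_a == "positive"
  b_ <- if (is.logical(calls_b)) calls_b else calls_b == "positive"
  ok <- !is.na(a) & !is.na(b_)
  a <- a[ok]; b_ <- b_[ok]
  b <- sum(a & !b_); cc <- sum(!a & b_)
  p <- if (b + cc == 0) 1 else min(1, 2 * pbinom(min(b, cc), b + cc, 0.5))
  list(b = b, c = cc, p = p)
}

#' Cohen's kappa for paired calls
#'
#' Observed agreement `po`, chance agreement `pe` from the marginal
#' products, and `kappa = (po - pe) / (1 - pe)`.  Works for any number of
#' categories; missing pairs are excluded.
#'
#' @param calls_a,calls_b paired categorical vectors.
#' @return list with `po`, `pe`, `kappa`, `n`.
#' @export
cohens_kappa <- function(calls_a, calls_b) {
  ok <- !is.na(calls_a) & !is.na(calls_b)
  a <- as.character(calls_a[ok]); b <- as.character(calls_b[ok])
  n <- length(a)
  if (n < 1) stop("need at least one paired observation")
  cats <- union(unique(a), unique(b))
  ta <- table(factor(a, cats)); tb <- table(factor(b, cats))
  po <- mean(a == b)
  pe <- sum(as.numeric(ta) * as.numeric(tb)) / n^2
  if (1 - pe < .Machine$double.eps) {
    if (po == 1) return(list(po = 1, pe = pe, kappa = 1, n = n))
    stop("chance agreement is 1 but observed agreement is not; kappa undefined")
  }
  list(po = po, pe = pe, kappa = (po - pe) / (1 - pe), n = n)
}

#' Serial / parallel combination of two markers
#'
#' Serial interpretation is positive only when both markers are positive
#' (raises specificity); parallel is positive when either is (raises
#' sensitivity).  A missing call in either marker yields a missing
#' combined call.
#'
#' @param calls_a,calls_b paired `"positive"`/`"negative"` vectors.
#' @param mode `"serial"` or `"parallel"`.
#' @return combined call vector.
#' @export
combine_markers <- function(calls_a, calls_b, mode = c("serial", "parallel")) {
  mode <- match.arg(mode)
  a <- calls_a == "positive"; b <- calls_b == "positive"
  comb <- if (mode == "serial") a & b else a | b
  out <- ifelse(comb, "positive", "negative")
  out[is.na(a) | is.na(b)] <- NA_character_
  out
}
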