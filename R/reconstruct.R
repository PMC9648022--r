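# Recovery of integer confusion tables from published summary rows: a
# diagnostic-performance table typically prints each proportion rounded to
# one decimal together with its exact 95% CI, which pins down the
# underlying counts uniquely once a maximum cohort size is assumed.

#' Candidate (x, n) pairs matching a printed proportion and exact CI
#'
#' Searches all `1 <= n <= max_n`, `0 <= x <= n` for counts whose
#' percentage and exact Clopper-Pearson 95% CI bounds round (half-up, one
#' decimal) to the printed values.
#'
#' @param pct printed percentage (one decimal).
#' @param ci_lo,ci_hi printed CI bounds (percent, one decimal).
#' @param max_n largest cohort size considered (default 300).
#' @return data.frame of matching `x`, `n` (possibly several rows).
#' @export
match_proportion <- function(pct, ci_lo, ci_hi, max_n = 300) {
  hits <- list()
  for (n in seq_len(max_n)) {
    # only x near pct*n/100 can round to pct
    x0 <- round(pct * n / 100)
    for (x in max(0, x0 - 1):min(n, x0 + 1)) {
      if (round_half_up(100 * x / n, 1) != pct) next
      ci <- .cp_ci(x, n)
      if (round_half_up(100 * ci[1], 1) == ci_lo &&
          round_half_up(100 * ci[2], 1) == ci_hi)
        hits[[length(hits) + 1]] <- data.frame(x = x, n = n)
    }
  }
  if (length(hits) == 0) return(data.frame(x = integer(), n = integer()))
  do.call(rbind, hits)
}

#' Reconstruct a confusion table from printed sensitivity and specificity
#'
#' Recovers (TP, FN) from the printed sensitivity row and (TN, FP) from
#' the printed specificity row via [match_proportion()]; errors unless each
#' recovery is unique within the size bounds.
#'
#' @param sens,sens_lo,sens_hi printed sensitivity and CI (percent).
#' @param spec,spec_lo,spec_hi printed specificity and CI (percent).
#' @param max_diseased,max_controls search bounds (default 300).
#' @return a [confusion_table()].
#' @export
reconstruct_confusion <- function(sens, sens_lo, sens_hi,
                                  spec, spec_lo, spec_hi,
                                  max_diseased = 300, max_controls = 300) {
  m1 <- match_proportion(sens, sens_lo, sens_hi, max_diseased)
  m2 <- match_proportion(spec, spec_lo, spec_hi, max_controls)
  if (nrow(m1) != 1)
    stop(sprintf("sensitivity row not uniquely recovered (%d matches)", nrow(m1)))
  if (nrow(m2) != 1)
    stop(sprintf("specificity row not uniquely recovered (%d matches)", nrow(m2)))
  confusion_table(tp = m1$x, fn = m1$n - m1$x, tn = m2$x, fp = m2$n - m2$x)
}

#' Agreement table implied by marginals and printed percent agreement
#'
#' For two binary raters over `n` paired sections with `pos_a` and `pos_b`
#' positives and a printed overall agreement percentage, solves the unique
#' 2x2 table (a = both positive, b = A only, c = B only, d = both
#' negative): the concordant count is the integer whose percentage rounds
#' to the printed agreement, and `b + c = n - (a + d)` splits according to
#' the marginals.
#'
#' @param n number of paired sections.
#' @param pos_a,pos_b positive counts of the two raters.
#' @param agreement_pct printed percent agreement (one decimal).
#' @return list with `a`, `b`, `c`, `d` and the implied [cohens_kappa()]
#'   result under `kappa`.
#' @export
implied_agreement_table <- function(n, pos_a, pos_b, agreement_pct) {
  conc <- which(round_half_up(100 * (0:n) / n, 1) == agreement_pct) - 1L
  if (length(conc) == 0) stop("no concordant count matches the printed agreement")
  for (ad in conc) {
    disc <- n - ad
    # b - c = pos_a - pos_b and b + c = disc
    b <- (disc + pos_a - pos_b) / 2
    cc <- disc - b
    if (b == floor(b) && b >= 0 && cc >= 0) {
      a <- pos_a - b
      d <- ad - a
      if (a >= 0 && d >= 0 && a + b + cc + d == n) {
        calls_a <- rep(c("pos", "pos", "neg", "neg"), c(a, b, cc, d))
        calls_b <- rep(c("pos", "neg", "pos", "neg"), c(a, b, cc, d))
        kap <- cohens_kappa(calls_a, calls_b)
        return(list(a = a, b = b, c = cc, d = d, kappa = kap))
      }
    }
  }
  stop("no consistent 2x2 table found")
}
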