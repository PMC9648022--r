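# Stage-vs-normal differential expression per dataset, the cross-study
# direction-consistent DEG unions ("Sets1"), Spearman stepwise-gene
# detection, and the per-dataset DEG/stepwise intersection ("Sets2").

COMPARISON_LABELS <- c("1" = "LN", "2" = "HN", "3" = "CN")

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment
#' `adj_(i) = min_(j >= i) (m * p_(j) / j)` on ascending-sorted p-values,
#' capped at 1 and mapped back to input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Differential expression of one lesion stage versus normal
#'
#' Per-gene Welch (unpooled-variance) two-sample t-test on log2 values.
#' The fold change is the difference of log2 group means (log2 of the
#' geometric-mean ratio); genes are called `up` when `log2FC > log2(fc)`
#' and the BH-adjusted p-value is below `alpha`, `down` symmetrically,
#' `none` otherwise.
#'
#' Degenerate genes: when both groups are constant and equal the p-value is
#' 1; when both are constant but unequal the Welch denominator is zero and
#' the p-value is 0.
#'
#' @param ds an [expression_dataset()].
#' @param lesion_stage stage code in `1:3` (LSIL/HSIL/SCC) to contrast with
#'   Normal (code 0).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param fc fold-change threshold on the natural scale (default 2, i.e.
#'   |log2FC| > 1).
#' @return data.frame with columns `gene`, `comparison` (LN/HN/CN),
#'   `log2FC`, `p`, `p_adj`, `direction`.
#' @export
differential_expression <- function(ds, lesion_stage, alpha = 0.05, fc = 2) {
  stopifnot(lesion_stage %in% 1:3)
  g1 <- ds$values[, ds$stage == lesion_stage, drop = FALSE]
  g0 <- ds$values[, ds$stage == 0L, drop = FALSE]
  n1 <- ncol(g1); n0 <- ncol(g0)
  if (n1 < 2 || n0 < 2) stop("each group needs at least 2 samples")
  m1 <- rowMeans(g1); m0 <- rowMeans(g0)
  v1 <- apply(g1, 1, var); v0 <- apply(g0, 1, var)
  se2 <- v1 / n1 + v0 / n0
  dm <- m1 - m0
  tstat <- dm / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * pt(-abs(tstat), df)
  zero <- se2 == 0
  p[zero & dm == 0] <- 1
  p[zero & dm != 0] <- 0
  p_adj <- bh_adjust(p)
  direction <- rep("none", length(p))
  direction[p_adj < alpha & dm > log2(fc)] <- "up"
  direction[p_adj < alpha & dm < -log2(fc)] <- "down"
  comparison <- COMPARISON_LABELS[[as.character(lesion_stage)]]
  cs_log("differential_expression(%s, %s): %d up, %d down of %d genes",
         ds$dataset_id, comparison, sum(direction == "up"),
         sum(direction == "down"), length(p))
  data.frame(gene = ds$genes, comparison = comparison, log2FC = dm,
             p = p, p_adj = p_adj, direction = direction,
             row.names = NULL)
}

#' All three stage-vs-normal comparisons of one dataset
#'
#' Convenience wrapper running [differential_expression()] for every lesion
#' stage present with at least two samples.
#'
#' @inheritParams differential_expression
#' @return row-bound DEG table over the available comparisons.
#' @export
differential_expression_all <- function(ds, alpha = 0.05, fc = 2) {
  stages <- intersect(1:3, unique(ds$stage))
  stages <- stages[vapply(stages, function(s) sum(ds$stage == s) >= 2, TRUE)]
  do.call(rbind, lapply(stages, differential_expression, ds = ds,
                        alpha = alpha, fc = fc))
}

#' Cross-study DEG unions with direction-consistency filtering ("Sets1")
#'
#' Per comparison (LN/HN/CN): the union of up-calls and the union of
#' down-calls across datasets, after removing any gene called up in one
#' dataset and down in another.  By default consistency is enforced per
#' comparison; `scope = "global"` removes a gene from every comparison when
#' its direction conflicts anywhere.
#'
#' @param deg_tables list of per-dataset DEG tables (as from
#'   [differential_expression_all()]).
#' @param scope `"per_comparison"` (default) or `"global"`.
#' @return named list: comparison -> list(up = chr, down = chr), plus an
#'   attribute `inconsistent` with the removed genes per comparison.
#' @export
cross_study_sets1 <- function(deg_tables, scope = c("per_comparison", "global")) {
  scope <- match.arg(scope)
  if (length(deg_tables) < 2) stop("need at least 2 datasets")
  all_deg <- do.call(rbind, deg_tables)
  out <- list()
  removed <- list()
  comparisons <- intersect(c("LN", "HN", "CN"), unique(all_deg$comparison))
  for (cmp in comparisons) {
    sub <- all_deg[all_deg$comparison == cmp, ]
    up <- unique(sub$gene[sub$direction == "up"])
    down <- unique(sub$gene[sub$direction == "down"])
    bad <- intersect(up, down)
    removed[[cmp]] <- bad
    out[[cmp]] <- list(up = sort(setdiff(up, bad)),
                       down = sort(setdiff(down, bad)))
  }
  if (scope == "global") {
    bad_any <- unique(unlist(removed))
    for (cmp in names(out)) {
      out[[cmp]]$up <- setdiff(out[[cmp]]$up, bad_any)
      out[[cmp]]$down <- setdiff(out[[cmp]]$down, bad_any)
    }
  }
  for (cmp in names(out))
    cs_log("sets1[%s]: %d up, %d down (%d inconsistent removed)", cmp,
           length(out[[cmp]]$up), length(out[[cmp]]$down),
           length(removed[[cmp]]))
  structure(out, inconsistent = removed)
}

# Exact two-sided permutation p-value for the Spearman correlation of y
# against an ordinal x with at most a handful of distinct levels.  The
# statistic depends on y only through the per-level sums of y-ranks, so the
# permutation null is enumerated over assignments of rank indices to levels
# (multinomial enumeration) rather than over all n! permutations.
spearman_exact_perm_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(1)
  obs <- abs(cor(rx, ry))
  groups <- split(seq_len(n), x)
  sizes <- lengths(groups)
  gx <- vapply(groups, function(i) rx[i[1]], 0)   # rank value of each level
  cx <- rx - mean(rx)
  denom <- sqrt(sum(cx^2)) # times sd(ry) part handled via centered ry
  cyv <- ry - mean(ry)
  deny <- sqrt(sum(cyv^2))
  count <- 0L
  total <- 0L
  recurse <- function(level, avail, acc) {
    if (level == length(sizes)) {
      s <- acc + sum((gx[level] - mean(rx)) * cyv[avail])
      rho <- s / (denom * deny)
      if (abs(rho) >= obs - 1e-12) count <<- count + 1L
      total <<- total + 1L
      return(invisible())
    }
    picks <- combn(avail, sizes[level], simplify = FALSE)
    for (pk in picks) {
      recurse(level + 1L, setdiff(avail, pk),
              acc + sum((gx[level] - mean(rx)) * cyv[pk]))
    }
    invisible()
  }
  recurse(1L, seq_len(n), 0)
  count / total
}

#' Stepwise (monotone-with-stage) gene detection
#'
#' Spearman correlation (average ranks for ties) of per-sample expression
#' with the ordinal stage code; two-sided p via the t approximation, or by
#' exact permutation enumeration when the total sample count is at most 10.
#' A gene is called monotone (direction = sign of rho) when p < `alpha`.
#' Constant genes get rho = 0, p = 1.
#'
#' @param ds an [expression_dataset()] with at least 3 distinct stages.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with columns `gene`, `rho`, `p`, `monotone_direction`.
#' @export
stepwise_genes <- function(ds, alpha = 0.05) {
  if (length(unique(ds$stage)) < 3) stop("need >= 3 distinct stage codes")
  n <- length(ds$stage)
  rx <- rank(ds$stage)
  ry <- t(apply(ds$values, 1, rank))
  cxv <- rx - mean(rx)
  ryc <- ry - rowMeans(ry)
  denom_y <- sqrt(rowSums(ryc^2))
  rho <- as.vector(ryc %*% cxv) / (sqrt(sum(cxv^2)) * denom_y)
  rho[denom_y == 0] <- 0
  if (n <= 10) {
    p <- vapply(seq_len(nrow(ds$values)), function(i) {
      spearman_exact_perm_p(ds$stage, ds$values[i, ])
    }, 0)
  } else {
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  p[denom_y == 0] <- 1
  dir <- ifelse(p < alpha, ifelse(rho > 0, "up", "down"), "none")
  cs_log("stepwise_genes(%s): %d up, %d down of %d genes", ds$dataset_id,
         sum(dir == "up"), sum(dir == "down"), length(dir))
  data.frame(gene = ds$genes, rho = rho, p = p, monotone_direction = dir,
             row.names = NULL)
}

#' Per-dataset DEG/stepwise intersection ("Sets2")
#'
#' Up-set: genes called `up` in at least one stage-vs-normal comparison of
#' the dataset (or in the specific comparison given by `comparison`) that
#' are also stepwise-up; down symmetric.
#'
#' @param deg_table DEG table of one dataset
#'   ([differential_expression_all()]).
#' @param stepwise_table stepwise table of the same dataset
#'   ([stepwise_genes()]).
#' @param comparison optional single comparison (e.g. `"CN"`) the DEG call
#'   must come from; default: any comparison.
#' @return list(up = chr, down = chr).
#' @export
cross_stage_sets2 <- function(deg_table, stepwise_table, comparison = NULL) {
  if (!is.null(comparison))
    deg_table <- deg_table[deg_table$comparison %in% comparison, ]
  deg_up <- unique(deg_table$gene[deg_table$direction == "up"])
  deg_down <- unique(deg_table$gene[deg_table$direction == "down"])
  sw_up <- stepwise_table$gene[stepwise_table$monotone_direction == "up"]
  sw_down <- stepwise_table$gene[stepwise_table$monotone_direction == "down"]
  list(up = sort(intersect(deg_up, sw_up)),
       down = sort(intersect(deg_down, sw_down)))
}
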