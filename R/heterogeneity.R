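# Inter-/intra-lesional heterogeneity assessment: PCA of the most variable
# genes, within-stage pairwise Pearson correlations, and stage-wise
# distribution comparisons (Kruskal-Wallis + pairwise Wilcoxon, Bonferroni).

#' Most variable genes
#'
#' Genes ranked by descending variance across all samples; ties broken by
#' gene-symbol lexicographic order so the selection is deterministic.
#'
#' @param ds an [expression_dataset()].
#' @param n number of genes to return (default 1000).
#' @return character vector of `n` gene symbols.
#' @export
top_variable_genes <- function(ds, n = 1000) {
  if (n <= 0) stop("n must be positive")
  if (n > length(ds$genes)) stop("n exceeds the number of genes")
  v <- apply(ds$values, 1, var)
  ord <- order(-v, ds$genes)
  ds$genes[ord][seq_len(n)]
}

#' PCA embedding of samples
#'
#' Principal components of the samples over a gene subset, computed on
#' gene-centered but unscaled log2 values; the fraction of variance
#' explained is reported from the singular values.
#'
#' @param ds an [expression_dataset()].
#' @param genes gene subset to use (default: all genes; typically
#'   [top_variable_genes()]).
#' @param k number of components (default 2).
#' @return list with `scores` (samples x k matrix), `var_explained`
#'   (length-k fractions) and `stage` (per-sample codes, for plotting).
#' @export
pca_embed <- function(ds, genes = ds$genes, k = 2) {
  x <- t(ds$values[genes, , drop = FALSE])   # samples x genes
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (k > min(dim(x))) stop("k exceeds min(genes, samples)")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- ds$samples
  list(scores = scores, var_explained = ve[seq_len(k)], stage = ds$stage)
}

#' Within-stage pairwise sample correlations
#'
#' Pearson correlation over all genes (optionally a subset) for every
#' unordered pair of samples within each disease stage.  Stages with fewer
#' than two samples are omitted with a warning.
#'
#' @param ds an [expression_dataset()].
#' @param genes optional gene subset.
#' @return named list (stage name -> numeric vector of pairwise r), class
#'   `stage_correlations`.
#' @export
within_stage_correlations <- function(ds, genes = ds$genes) {
  out <- list()
  for (code in sort(unique(ds$stage))) {
    idx <- which(ds$stage == code)
    nm <- STAGE_NAMES[code + 1L]
    if (length(idx) < 2) {
      warning(sprintf("stage %s has < 2 samples; omitted", nm))
      next
    }
    cm <- cor(ds$values[genes, idx, drop = FALSE])
    out[[nm]] <- cm[upper.tri(cm)]
  }
  structure(out, class = "stage_correlations")
}

#' Compare within-stage correlation distributions
#'
#' Kruskal-Wallis omnibus test across stages followed by all pairwise
#' two-sided Wilcoxon rank-sum tests with Bonferroni correction (p
#' multiplied by the number of pairs, capped at 1).  Wilcoxon p-values use
#' exact enumeration when both groups have at most 50 observations and no
#' ties, and the tie-corrected normal approximation otherwise.
#'
#' @param sc a `stage_correlations` object from
#'   [within_stage_correlations()].
#' @return list with `kruskal_p`, `pairwise` (data.frame: stage_a, stage_b,
#'   p_raw, p_bonferroni).
#' @export
compare_stage_correlations <- function(sc) {
  groups <- unclass(sc)
  if (length(groups) < 2) stop("need at least 2 stages")
  if (any(lengths(groups) == 0)) stop("empty stage group")
  kw <- kruskal.test(groups)
  pairs <- combn(names(groups), 2)
  n_pairs <- ncol(pairs)
  res <- lapply(seq_len(n_pairs), function(j) {
    a <- groups[[pairs[1, j]]]
    b <- groups[[pairs[2, j]]]
    use_exact <- max(length(a), length(b)) <= 50 &&
      !anyDuplicated(c(a, b))
    p <- suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                  correct = TRUE)$p.value)
    data.frame(stage_a = pairs[1, j], stage_b = pairs[2, j], p_raw = p)
  })
  pw <- do.call(rbind, res)
  pw$p_bonferroni <- pmin(1, pw$p_raw * n_pairs)
  list(kruskal_p = kw$p.value, pairwise = pw)
}
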