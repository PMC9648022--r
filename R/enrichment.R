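# Hypergeometric over-representation testing of flat gene-set collections
# (cytobands, GO/KEGG as GMT) with BH q-values.

#' Over-representation of one gene set
#'
#' Upper-tail hypergeometric test: with a universe of size `N`, a target
#' set of size `K` in the universe and a query of size `n`, the p-value is
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` where `k` is the observed
#' overlap.
#'
#' @param query character vector of query genes.
#' @param target character vector of target-set genes.
#' @param universe character vector of background genes; query and target
#'   are restricted to it.
#' @return one-row data.frame: `N`, `K`, `n`, `k`, `p`, `gene_ratio`.
#' @export
ora <- function(query, target, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- intersect(unique(query), universe)
  target <- intersect(unique(target), universe)
  N <- length(universe); K <- length(target); n <- length(query)
  k <- length(intersect(query, target))
  p <- if (n == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(N = N, K = K, n = n, k = k, p = p,
             gene_ratio = if (n > 0) k / n else 0)
}

#' Over-representation across a gene-set collection
#'
#' One hypergeometric test per set with BH adjustment across the whole
#' collection; sets are flagged significant at `q < q_threshold`
#' (0.05 for cytobands, 0.1 for GO/KEGG in the source workflow).
#'
#' @param query character vector of query genes.
#' @param collection list with `universe` and `sets`
#'   (see [read_gene_sets()]).
#' @param q_threshold BH q-value threshold (default 0.05).
#' @return data.frame, one row per set, ordered by p: `set`, `N`, `K`,
#'   `n`, `k`, `p`, `q`, `gene_ratio`, `significant`.
#' @export
enrich_collection <- function(query, collection, q_threshold = 0.05) {
  if (length(collection$sets) == 0) stop("empty collection")
  rows <- lapply(names(collection$sets), function(nm) {
    r <- ora(query, collection$sets[[nm]], collection$universe)
    cbind(set = nm, r)
  })
  tab <- do.call(rbind, rows)
  tab$q <- bh_adjust(tab$p)
  tab$significant <- tab$q < q_threshold
  tab <- tab[order(tab$p, tab$set), ]
  rownames(tab) <- NULL
  cs_log("enrich_collection: %d / %d sets significant at q < %s",
         sum(tab$significant), nrow(tab), format(q_threshold))
  tab
}
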