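# The nine node-ranking methods of the cytoHubba family, computed on an
# undirected simple graph: Degree, Betweenness, Stress, Closeness
# (harmonic), Radiality, MNC, DMNC, Bottleneck, EPC.

CENTRALITY_METHODS <- c("degree", "betweenness", "stress", "closeness",
                        "radiality", "mnc", "dmnc", "bottleneck", "epc")

#' Centrality parameters
#'
#' Tuning knobs for the stochastic / parameterised ranking methods.
#'
#' @param epc_realizations Monte-Carlo realizations for the
#'   edge-percolated-component score (default 5000, the original plug-in's
#'   convention).
#' @param epc_seed integer seed for the EPC draws (NULL: use the current
#'   RNG state).
#' @param dmnc_epsilon exponent of the DMNC density (default 1.7, the
#'   original method constant).
#' @param bottleneck_fraction subtree-size fraction that makes a node a
#'   bottleneck of a BFS shortest-path tree (default 0.25).
#' @param top_k nodes taken from each ranking (default 10).
#' @param consensus_min number of datasets a candidate must appear in to be
#'   called a hub (default 2).
#' @return list of class `centrality_params`.
#' @export
centrality_params <- function(epc_realizations = 5000, epc_seed = NULL,
                              dmnc_epsilon = 1.7, bottleneck_fraction = 0.25,
                              top_k = 10, consensus_min = 2) {
  stopifnot(epc_realizations >= 1, dmnc_epsilon > 0,
            bottleneck_fraction > 0, bottleneck_fraction < 1, top_k >= 1,
            consensus_min >= 1)
  structure(list(epc_realizations = epc_realizations, epc_seed = epc_seed,
                 dmnc_epsilon = dmnc_epsilon,
                 bottleneck_fraction = bottleneck_fraction,
                 top_k = top_k, consensus_min = consensus_min),
            class = "centrality_params")
}

# hop-distance matrix with Inf for unreachable pairs
.hop_dist <- function(g) igraph::distances(g, weights = NA)

# Per-source BFS shortest-path counts and path-tail totals, used for the
# stress score: for source s, T(v) = number of shortest paths from s
# passing through interior v = sigma_sv * (number of shortest-path tails
# from v), accumulated over the BFS DAG in decreasing distance order.
.stress_from_source <- function(adj, s, n) {
  dist <- rep(Inf, n); sigma <- numeric(n)
  dist[s] <- 0; sigma[s] <- 1
  queue <- s; head_i <- 1
  order_v <- integer(0)
  while (head_i <= length(queue)) {
    v <- queue[head_i]; head_i <- head_i + 1
    order_v <- c(order_v, v)
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
      if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
    }
  }
  # T(v) = number of BFS-DAG paths from v to any strictly-downstream node;
  # sigma_sv * T(v) is the number of shortest s-* paths with v interior.
  tails <- numeric(n)
  for (v in rev(order_v)) {
    for (w in adj[[v]]) {
      if (dist[w] == dist[v] + 1) tails[v] <- tails[v] + tails[w] + 1
    }
  }
  contrib <- sigma * tails
  contrib[s] <- 0
  contrib
}

.adj_list <- function(g) {
  n <- igraph::vcount(g)
  lapply(seq_len(n), function(v) as.integer(igraph::neighbors(g, v)))
}

.stress_scores <- function(g) {
  n <- igraph::vcount(g)
  adj <- .adj_list(g)
  total <- numeric(n)
  for (s in seq_len(n)) total <- total + .stress_from_source(adj, s, n)
  total / 2   # unordered (s, t) pairs
}

.radiality_scores <- function(g) {
  d <- .hop_dist(g)
  n <- nrow(d)
  comp <- igraph::components(g)$membership
  score <- numeric(n)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) == 1) { score[idx] <- 0; next }
    dc <- d[idx, idx, drop = FALSE]
    diam <- max(dc)
    nc <- length(idx)
    score[idx] <- vapply(seq_len(nc), function(i) {
      sum(diam + 1 - dc[i, -i]) / (nc - 1)
    }, 0)
  }
  score
}

.closeness_harmonic <- function(g) {
  d <- .hop_dist(g)
  diag(d) <- Inf
  rowSums(1 / d)
}

.mnc_components <- function(g, v) {
  nb <- igraph::neighbors(g, v)
  if (length(nb) == 0) return(NULL)
  sub <- igraph::induced_subgraph(g, nb)
  comp <- igraph::components(sub)
  big <- which.max(comp$csize)
  igraph::induced_subgraph(sub, which(comp$membership == big))
}

.mnc_scores <- function(g) {
  vapply(seq_len(igraph::vcount(g)), function(v) {
    m <- .mnc_components(g, v)
    if (is.null(m)) 0 else igraph::vcount(m)
  }, 0)
}

.dmnc_scores <- function(g, eps) {
  vapply(seq_len(igraph::vcount(g)), function(v) {
    m <- .mnc_components(g, v)
    if (is.null(m) || igraph::vcount(m) <= 1) return(0)
    igraph::ecount(m) / igraph::vcount(m)^eps
  }, 0)
}

# Deterministic BFS shortest-path tree rooted at s: nodes discovered in
# canonical (vertex-name) order, parent = smallest-named already-visited
# neighbor at the previous depth.  Returns subtree sizes within the tree.
.bottleneck_tree_sizes <- function(g, s, name_order) {
  d <- igraph::distances(g, v = s, weights = NA)[1, ]
  in_tree <- is.finite(d)
  nodes <- which(in_tree)
  parent <- rep(NA_integer_, igraph::vcount(g))
  for (v in nodes) {
    if (v == s) next
    nb <- as.integer(igraph::neighbors(g, v))
    cand <- nb[d[nb] == d[v] - 1]
    parent[v] <- cand[which.min(name_order[cand])]
  }
  size <- rep(1L, igraph::vcount(g))
  size[!in_tree] <- 0L
  for (v in nodes[order(-d[nodes])]) {
    p <- parent[v]
    if (!is.na(p)) size[p] <- size[p] + size[v]
  }
  list(size = size, tree_n = length(nodes), in_tree = in_tree)
}

.bottleneck_scores <- function(g, fraction) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  name_order <- rank(nm, ties.method = "first")
  score <- numeric(n)
  for (s in seq_len(n)) {
    tr <- .bottleneck_tree_sizes(g, s, name_order)
    hit <- tr$in_tree & tr$size >= fraction * tr$tree_n
    score <- score + as.numeric(hit)
  }
  score
}

.epc_scores <- function(g, realizations, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  total <- numeric(n)
  for (r in seq_len(realizations)) {
    thr <- runif(1)
    keep <- runif(m) < thr
    sub <- igraph::subgraph_from_edges(g, which(keep), delete.vertices = FALSE)
    comp <- igraph::components(sub)
    total <- total + comp$csize[comp$membership]
  }
  total / realizations / n
}

#' Node centrality scores
#'
#' One of the nine ranking methods on an undirected simple graph.  Hop
#' distances (unweighted shortest paths) are used throughout; closeness is
#' the harmonic (sum of reciprocal distances) form so disconnected graphs
#' are well defined.
#'
#' @param g undirected simple igraph with named vertices.
#' @param method one of `"degree"`, `"betweenness"`, `"stress"`,
#'   `"closeness"`, `"radiality"`, `"mnc"`, `"dmnc"`, `"bottleneck"`,
#'   `"epc"`.
#' @param params a [centrality_params()] list.
#' @return named numeric vector of scores (one per vertex).
#' @export
centrality <- function(g, method, params = centrality_params()) {
  if (igraph::vcount(g) == 0) stop("empty graph")
  method <- match.arg(method, CENTRALITY_METHODS)
  score <- switch(
    method,
    degree = igraph::degree(g),
    betweenness = igraph::betweenness(g, weights = NA),
    stress = .stress_scores(g),
    closeness = .closeness_harmonic(g),
    radiality = .radiality_scores(g),
    mnc = .mnc_scores(g),
    dmnc = .dmnc_scores(g, params$dmnc_epsilon),
    bottleneck = .bottleneck_scores(g, params$bottleneck_fraction),
    epc = .epc_scores(g, params$epc_realizations, params$epc_seed)
  )
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  setNames(as.numeric(score), nm)
}

#' Top-ranked nodes with tie expansion
#'
#' The `k` highest-scoring nodes; every node tied with the k-th score is
#' included, so the result may exceed `k`.  Ordering is deterministic by
#' (-score, node name).
#'
#' @param scores named numeric vector from [centrality()].
#' @param k number of top nodes (default 10).
#' @return character vector of node names.
#' @export
top_nodes <- function(scores, k = 10) {
  stopifnot(k >= 1)
  if (k >= length(scores)) k <- length(scores)
  ord <- order(-scores, names(scores))
  cutoff <- scores[ord][k]
  names(scores)[ord][scores[ord] >= cutoff]
}

#' Per-dataset candidate hub set and induced sub-network
#'
#' Union over the nine ranking methods of their top-`k` nodes, plus the
#' sub-network induced by the union.
#'
#' @param g undirected simple igraph.
#' @param params a [centrality_params()] list.
#' @return list with `nodes` (character), `subnetwork` (igraph) and
#'   `per_method` (named list of each method's top nodes).
#' @export
candidate_set <- function(g, params = centrality_params()) {
  per_method <- lapply(CENTRALITY_METHODS, function(m) {
    top_nodes(centrality(g, m, params), params$top_k)
  })
  names(per_method) <- CENTRALITY_METHODS
  nodes <- sort(unique(unlist(per_method)))
  list(nodes = nodes,
       subnetwork = igraph::induced_subgraph(g, nodes),
       per_method = per_method)
}

#' Cross-dataset consensus hub calling
#'
#' Counts, for every candidate node, the number of datasets whose candidate
#' set contains it; hubs are the nodes reaching `consensus_min` (default 2,
#' the "at least two datasets" rule; set `consensus_min = length(sets)` for
#' the stricter all-datasets reading).
#'
#' @param candidate_sets list of character vectors (one per dataset).
#' @param consensus_min minimum membership count.
#' @return list with `hubs` (character), `membership` (named integer
#'   counts) and `candidate_sets` (the input).
#' @export
consensus_hubs <- function(candidate_sets, consensus_min = 2) {
  if (length(candidate_sets) < consensus_min)
    stop("fewer datasets than consensus_min")
  counts <- table(unlist(lapply(candidate_sets, unique)))
  membership <- setNames(as.integer(counts), names(counts))
  hubs <- sort(names(membership)[membership >= consensus_min])
  cs_log("consensus_hubs: %d hubs from %d candidates across %d datasets",
         length(hubs), length(membership), length(candidate_sets))
  list(hubs = hubs, membership = membership, candidate_sets = candidate_sets)
}
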