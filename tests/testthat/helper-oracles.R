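# Independent brute-force oracles used to verify the package's
# implementations on small instances.  Kept deliberately naive: explicit
# enumeration, no shared code with the package internals.

options(cervstage.verbose = FALSE)

# BH step-up adjustment computed literally from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- ps * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# All shortest paths between two vertices of an adjacency list, by
# exhaustive DFS restricted to BFS distances.
oracle_all_shortest_paths <- function(adj, s, t, dist_s) {
  if (!is.finite(dist_s[t])) return(list())
  paths <- list()
  walk <- function(v, acc) {
    if (v == t) {
      paths[[length(paths) + 1]] <<- acc
      return(invisible())
    }
    for (w in adj[[v]]) {
      if (is.finite(dist_s[w]) && dist_s[w] == dist_s[v] + 1) walk(w, c(acc, w))
    }
    invisible()
  }
  walk(s, s)
  paths
}

oracle_bfs_dist <- function(adj, s, n) {
  dist <- rep(Inf, n)
  dist[s] <- 0
  q <- s
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (w in adj[[v]]) if (is.infinite(dist[w])) {
      dist[w] <- dist[v] + 1
      q <- c(q, w)
    }
  }
  dist
}

# Betweenness, stress, harmonic closeness and radiality of every node, by
# enumerating every shortest path of every unordered pair.
oracle_path_centralities <- function(g) {
  n <- igraph::vcount(g)
  adj <- lapply(seq_len(n), function(v) as.integer(igraph::neighbors(g, v)))
  btw <- numeric(n); str_ <- numeric(n)
  dmat <- matrix(Inf, n, n)
  for (s in seq_len(n)) dmat[s, ] <- oracle_bfs_dist(adj, s, n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- oracle_all_shortest_paths(adj, s, t, dmat[s, ])
    if (!length(paths)) next
    sigma <- length(paths)
    interior <- table(unlist(lapply(paths, function(p) setdiff(p, c(s, t)))))
    for (nm in names(interior)) {
      v <- as.integer(nm)
      btw[v] <- btw[v] + interior[[nm]] / sigma
      str_[v] <- str_[v] + interior[[nm]]
    }
  }
  clo <- vapply(seq_len(n), function(v) {
    d <- dmat[v, -v]
    sum(1 / d[is.finite(d)])
  }, 0)
  comp <- igraph::components(g)$membership
  rad <- numeric(n)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) == 1) next
    diam <- max(dmat[idx, idx])
    for (v in idx)
      rad[v] <- sum(diam + 1 - dmat[v, setdiff(idx, v)]) / (length(idx) - 1)
  }
  deg <- vapply(adj, length, 0L)
  mnc <- vapply(seq_len(n), function(v) {
    nb <- adj[[v]]
    if (!length(nb)) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    as.numeric(max(igraph::components(sub)$csize))
  }, 0)
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  list(betweenness = setNames(btw, nm), stress = setNames(str_, nm),
       closeness = setNames(clo, nm), radiality = setNames(rad, nm),
       degree = setNames(as.numeric(deg), nm), mnc = setNames(as.numeric(mnc), nm))
}

# Hypergeometric upper tail by enumerating every n-subset of the universe.
oracle_hyper_tail <- function(N, K, n, k) {
  subsets <- combn(N, n, simplify = FALSE)
  target <- seq_len(K)
  hits <- vapply(subsets, function(s) length(intersect(s, target)) >= k, TRUE)
  mean(hits)
}

# Exact two-sided McNemar p by summing the Bin(b + c, 1/2) pmf.
oracle_mcnemar <- function(b, cc) {
  n <- b + cc
  if (n == 0) return(1)
  m <- min(b, cc)
  min(1, 2 * sum(choose(n, 0:m)) / 2^n)
}

# Two-sided Spearman permutation p by full enumeration of permutations.
oracle_spearman_perm <- function(x, y) {
  n <- length(y)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  obs <- abs(cor(rank(x), rank(y)))
  all_p <- perms(seq_len(n))
  stat <- vapply(all_p, function(idx) abs(cor(rank(x), rank(y[idx]))), 0)
  mean(stat >= obs - 1e-12)
}

# Pairwise-counting ROC AUC.
oracle_auc <- function(scores, truth) {
  cases <- scores[truth]; ctrls <- scores[!truth]
  tot <- 0
  for (a in cases) for (b in ctrls) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(ctrls))
}

# Log-rank chi-square from the textbook O-E / hypergeometric-variance sums.
oracle_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  stopifnot(max(g) == 2)
  tt <- sort(unique(time[event == 1]))
  O1 <- E1 <- V1 <- 0
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V1 <- V1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V1
}

# Kaplan-Meier product over event times.
oracle_km <- function(time, event, at) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  for (t in tt[tt <= at]) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
  }
  s
}

# DMNC by explicit neighborhood component search (own BFS, pair-counted
# edges), independent of the package's igraph-components route.
oracle_dmnc <- function(g, eps = 1.7) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  nm <- igraph::V(g)$name
  score <- setNames(numeric(n), nm)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1)
    if (length(nb) <= 1) { score[v] <- 0; next }
    # components of the induced subgraph on nb
    unvisited <- nb
    best <- integer(0)
    while (length(unvisited)) {
      q <- unvisited[1]; comp <- q; unvisited <- unvisited[-1]
      while (length(q)) {
        w <- q[1]; q <- q[-1]
        nxt <- intersect(which(A[w, ] == 1), unvisited)
        comp <- c(comp, nxt); unvisited <- setdiff(unvisited, nxt)
        q <- c(q, nxt)
      }
      if (length(comp) > length(best)) best <- comp
    }
    if (length(best) <= 1) { score[v] <- 0; next }
    e <- sum(A[best, best]) / 2
    score[v] <- e / length(best)^eps
  }
  score
}

# Bottleneck by explicit per-root tree construction: parent = smallest-named
# neighbor one BFS level up; subtree sizes counted by walking every node's
# ancestor chain.
oracle_bottleneck <- function(g, fraction = 0.25) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  adj <- lapply(seq_len(n), function(v) as.integer(igraph::neighbors(g, v)))
  score <- setNames(numeric(n), nm)
  for (s in seq_len(n)) {
    dist <- oracle_bfs_dist(adj, s, n)
    tree <- which(is.finite(dist))
    parent <- rep(NA_integer_, n)
    for (v in tree) {
      if (v == s) next
      up <- adj[[v]][dist[adj[[v]]] == dist[v] - 1]
      parent[v] <- up[order(nm[up])][1]
    }
    size <- setNames(rep(0, n), nm)
    for (v in tree) {
      w <- v
      repeat {
        size[w] <- size[w] + 1
        if (w == s) break
        w <- parent[w]
      }
    }
    score <- score + (is.finite(dist) & size >= fraction * length(tree))
  }
  score
}
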