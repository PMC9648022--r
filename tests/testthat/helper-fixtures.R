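# Small in-code fixtures shared across test files.

make_ds <- function(values, stage, id = "test") {
  expression_dataset(id, values, stage)
}

# dense random expression dataset, fixed dimensions, no planted structure
random_ds <- function(n_genes, n_per_stage, sd = 1, seed = 1, mean = 8,
                      stages = 0:3) {
  set.seed(seed)
  stage <- rep(stages, each = n_per_stage)
  m <- matrix(rnorm(n_genes * length(stage), mean, sd), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_along(stage))))
  make_ds(m, stage)
}

# random simple undirected graph with named vertices
random_graph <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  pairs <- combn(n, 2)
  keep <- runif(ncol(pairs)) < p
  nm <- sprintf("v%02d", seq_len(n))
  if (!any(keep)) return(igraph::make_empty_graph(n, directed = FALSE) |>
                           igraph::set_vertex_attr("name", value = nm))
  g <- igraph::graph_from_edgelist(
    cbind(nm[pairs[1, keep]], nm[pairs[2, keep]]), directed = FALSE)
  miss <- setdiff(nm, igraph::V(g)$name)
  if (length(miss)) g <- igraph::add_vertices(g, length(miss), name = miss)
  g
}

tmpfile <- function(ext = ".tsv") tempfile(fileext = ext)
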