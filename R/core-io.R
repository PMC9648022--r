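# Domain types and file IO shared by all pipeline stages.
#
# The ordinal disease-stage code used throughout:
#   0 = Normal, 1 = LSIL (CIN1), 2 = HSIL (CIN2/CIN3), 3 = SCC
# following the two-tier squamous intraepithelial lesion terminology; CIN
# sub-grades are kept as an auxiliary label so IHC results can still be
# stratified by CIN1/2/3.

STAGE_NAMES <- c("Normal", "LSIL", "HSIL", "SCC")

#' Parse disease-stage labels to ordinal codes
#'
#' Case-insensitive mapping of histology labels to the ordinal code
#' 0 = Normal, 1 = LSIL, 2 = HSIL, 3 = SCC.  CIN1 maps to LSIL and
#' CIN2/CIN3 to HSIL (two-tier terminology); "Cancer" is accepted for SCC.
#'
#' @param labels character vector of stage labels.
#' @return integer vector of stage codes in `0:3`.
#' @export
parse_stage_label <- function(labels) {
  key <- toupper(trimws(as.character(labels)))
  map <- c(
    NORMAL = 0L,
    LSIL = 1L, CIN1 = 1L,
    HSIL = 2L, CIN2 = 2L, CIN3 = 2L, `CIN2-3` = 2L,
    SCC = 3L, CANCER = 3L
  )
  out <- unname(map[key])
  if (anyNA(out)) {
    bad <- unique(labels[is.na(out)])
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Construct an expression dataset
#'
#' The unit of the meta-analysis: a genes x samples matrix of log2-scale
#' expression with an ordinal stage code per sample.
#'
#' @param dataset_id single string identifying the dataset.
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids), log2 scale.
#' @param stage integer vector of per-sample stage codes in `0:3`
#'   (0 Normal, 1 LSIL, 2 HSIL, 3 SCC), length `ncol(values)`.
#' @param annotations optional data.frame of per-sample annotations
#'   (e.g. HPV status, CIN sub-grade), one row per sample.
#' @return an object of class `expression_dataset` with elements
#'   `dataset_id`, `genes`, `samples`, `values`, `stage`, `annotations`.
#' @export
expression_dataset <- function(dataset_id, values, stage, annotations = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("gene symbols must be unique (collapse probes first)")
  if (!all(is.finite(values))) stop("expression values must be finite")
  stage <- as.integer(stage)
  if (length(stage) != ncol(values))
    stop("stage must have one code per sample")
  if (!all(stage %in% 0:3)) stop("stage codes must be in 0:3")
  if (!is.null(annotations)) {
    stopifnot(is.data.frame(annotations), nrow(annotations) == ncol(values))
  }
  structure(
    list(
      dataset_id = as.character(dataset_id),
      genes = rownames(values),
      samples = colnames(values),
      values = values,
      stage = stage,
      annotations = annotations
    ),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset> %s: %d genes x %d samples (%s)\n",
    x$dataset_id, length(x$genes), length(x$samples),
    paste(sprintf("%s=%d", STAGE_NAMES, tabulate(x$stage + 1L, 4L)),
          collapse = ", ")
  ))
  invisible(x)
}

#' Read an expression matrix and its sample metadata
#'
#' The matrix is tab-separated with genes in rows (first column = gene or
#' probe identifier) and samples in columns; the metadata file is
#' tab-separated with columns `sample_id`, `stage` and optionally further
#' annotation columns (e.g. `hpv_status`).  Sample order of the matrix is
#' preserved.
#'
#' @param matrix_path path to the genes x samples TSV.
#' @param metadata_path path to the sample metadata TSV.
#' @param dataset_id dataset identifier; defaults to the matrix file name.
#' @return an [expression_dataset()].
#' @export
read_expression <- function(matrix_path, metadata_path,
                            dataset_id = basename(matrix_path)) {
  tab <- data.table::fread(matrix_path, sep = "\t", header = TRUE,
                           colClasses = list(character = 1), data.table = FALSE)
  if (ncol(tab) < 2) stop("expression matrix needs at least one sample column")
  ids <- tab[[1]]
  num <- tab[, -1, drop = FALSE]
  for (j in seq_along(num)) {
    col <- num[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(conv <- as.numeric(col))
      bad <- which(is.na(conv) & !is.na(col))
      if (length(bad))
        stop(sprintf("non-numeric expression value at row '%s', column '%s'",
                     ids[bad[1]], names(num)[j]))
      num[[j]] <- conv
    }
  }
  values <- as.matrix(num)
  rownames(values) <- ids

  meta <- data.table::fread(metadata_path, sep = "\t", header = TRUE,
                            data.table = FALSE, colClasses = "character")
  if (!all(c("sample_id", "stage") %in% names(meta)))
    stop("metadata must have columns sample_id and stage")
  missing <- setdiff(colnames(values), meta$sample_id)
  if (length(missing))
    stop("sample(s) missing from metadata: ", paste(missing, collapse = ", "))
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  stage <- vapply(seq_len(nrow(meta)), function(i) {
    tryCatch(parse_stage_label(meta$stage[i]),
             error = function(e) stop(sprintf(
               "sample '%s': %s", meta$sample_id[i], conditionMessage(e)),
               call. = FALSE))
  }, integer(1))
  ann <- meta[, setdiff(names(meta), c("sample_id", "stage")), drop = FALSE]
  if (ncol(ann) == 0) ann <- NULL
  cs_log("read_expression(%s): %d genes x %d samples",
         dataset_id, nrow(values), ncol(values))
  expression_dataset(dataset_id, values, stage, annotations = ann)
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [read_expression()]: writes the matrix and a metadata table
#' (stage written back as its text label).
#'
#' @param ds an [expression_dataset()].
#' @param matrix_path,metadata_path output paths.
#' @return invisibly, `ds`.
#' @export
write_expression <- function(ds, matrix_path, metadata_path) {
  out <- data.frame(gene = ds$genes, ds$values, check.names = FALSE)
  data.table::fwrite(out, matrix_path, sep = "\t")
  meta <- data.frame(sample_id = ds$samples,
                     stage = STAGE_NAMES[ds$stage + 1L])
  if (!is.null(ds$annotations)) meta <- cbind(meta, ds$annotations)
  data.table::fwrite(meta, metadata_path, sep = "\t")
  invisible(ds)
}

#' Collapse probe-level rows to genes
#'
#' Genes measured by multiple probes are represented by the probe with the
#' highest mean expression across samples; ties are broken by file order
#' (first probe wins).  Unmapped probes are dropped.
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids).
#' @param map probe-to-gene map: either a named character vector
#'   (names = probe ids, values = gene symbols) or a two-column data.frame
#'   `(probe_id, gene)`.  Many probes may map to one gene; a probe may
#'   appear at most once.
#' @return numeric matrix with one row per mapped gene (rownames = gene
#'   symbols), sample columns unchanged.
#' @export
collapse_probes <- function(values, map) {
  stopifnot(is.matrix(values))
  if (is.data.frame(map)) map <- setNames(as.character(map[[2]]),
                                          as.character(map[[1]]))
  if (length(map) == 0) stop("empty probe map")
  if (anyDuplicated(names(map))) stop("a probe appears more than once in the map")
  keep <- rownames(values) %in% names(map)
  if (!any(keep)) stop("no probe in the matrix is covered by the map")
  vals <- values[keep, , drop = FALSE]
  gene <- unname(map[rownames(vals)])
  rmean <- rowMeans(vals)
  # stable: file order preserved within gene, so which.max takes first tie
  pick <- tapply(seq_len(nrow(vals)), gene, function(idx) idx[which.max(rmean[idx])])
  pick <- sort(unname(pick))   # keep original row order of retained probes
  out <- vals[pick, , drop = FALSE]
  rownames(out) <- gene[pick]
  cs_log("collapse_probes: %d probes -> %d genes", nrow(values), nrow(out))
  out
}

#' Read an undirected interaction network from an edge list
#'
#' Two-column (optionally scored third column) tab-separated symbol pairs,
#' STRING-style.  Duplicate and reversed pairs are merged, self-loops are
#' dropped with a warning, and an optional score threshold keeps only edges
#' with `score >= score_min`.
#'
#' @param path edge-list TSV; a header line is autodetected.
#' @param score_min optional minimum interaction score.
#' @return an undirected simple [igraph::graph] whose vertex names are gene
#'   symbols.
#' @export
read_network <- function(path, score_min = NULL) {
  tab <- if (file.size(path) == 0) data.frame() else
    data.table::fread(path, sep = "\t", header = "auto", data.table = FALSE)
  if (nrow(tab) == 0) {
    warning("empty network file: returning an empty graph")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  if (ncol(tab) < 2) stop("network file needs at least two columns")
  a <- as.character(tab[[1]])
  b <- as.character(tab[[2]])
  if (!is.null(score_min)) {
    if (ncol(tab) < 3) stop("score_min given but the file has no score column")
    score <- as.numeric(tab[[3]])
    keep <- score >= score_min
    cs_log("read_network: score >= %s keeps %d / %d edges",
           format(score_min), sum(keep), length(keep))
    a <- a[keep]; b <- b[keep]
  }
  loops <- a == b
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    a <- a[!loops]; b <- b[!loops]
  }
  g <- igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  cs_log("read_network: %d nodes, %d edges", igraph::vcount(g), igraph::ecount(g))
  g
}

#' Write a network back to an edge-list TSV
#' @param g undirected igraph.
#' @param path output path.
#' @return invisibly, `g`.
#' @export
write_network <- function(g, path) {
  el <- igraph::as_edgelist(g)
  data.table::fwrite(data.frame(node_a = el[, 1], node_b = el[, 2]),
                     path, sep = "\t")
  invisible(g)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name, description,
#' member, member, ...`; trailing empty fields are dropped.  Unless a
#' universe is supplied, the universe is the union of all members; with a
#' universe, members outside it are dropped (count logged).
#'
#' @param path GMT file.
#' @param universe optional character vector of gene symbols restricting
#'   the collection.
#' @return a list with elements `universe` (character) and `sets`
#'   (named list of character vectors).
#' @export
read_gene_sets <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(names_))
    stop("duplicate gene-set name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  sets <- lapply(parts, function(p) {
    members <- p[-(1:2)]
    unique(members[nzchar(members)])
  })
  names(sets) <- names_
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets)))
  } else {
    universe <- unique(as.character(universe))
    before <- sum(lengths(sets))
    sets <- lapply(sets, intersect, y = universe)
    cs_log("read_gene_sets: universe restriction dropped %d member(s)",
           before - sum(lengths(sets)))
  }
  cs_log("read_gene_sets: %d sets over %d universe genes",
         length(sets), length(universe))
  list(universe = universe, sets = sets)
}

#' Write a gene-set collection to GMT
#' @param collection list as returned by [read_gene_sets()].
#' @param path output path.
#' @return invisibly, `collection`.
#' @export
write_gene_sets <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(collection)
}
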