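# Reading expression matrices and writing results.

#' Read an expression matrix
#'
#' Dense TSV/CSV: genes in rows, cells in columns, a header row of cell ids
#' and the first column holding gene ids.  Sparse MatrixMarket: a `.mtx`
#' file with `features.tsv` and `barcodes.tsv` sidecars in the same
#' directory (first column of each used as ids); the matrix is densified.
#' Duplicate gene or cell ids are rejected.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format "tsv", "csv" or "mtx" (default: from the extension).
#' @return numeric genes x cells matrix with gene/cell ids as dimnames.
#' @export
read_expression <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "mtx") {
    dir <- dirname(path)
    fpath <- file.path(dir, "features.tsv")
    bpath <- file.path(dir, "barcodes.tsv")
    if (!file.exists(fpath) || !file.exists(bpath))
      stop("mtx input needs features.tsv and barcodes.tsv beside ", path)
    m <- as.matrix(Matrix::readMM(path))
    feats <- utils::read.delim(fpath, header = FALSE,
                               stringsAsFactors = FALSE)[[1L]]
    cells <- utils::read.delim(bpath, header = FALSE,
                               stringsAsFactors = FALSE)[[1L]]
    if (length(feats) != nrow(m))
      stop("features.tsv has ", length(feats), " rows but the matrix has ",
           nrow(m), " feature rows")
    if (length(cells) != ncol(m))
      stop("barcodes.tsv has ", length(cells), " rows but the matrix has ",
           ncol(m), " cell columns")
    rownames(m) <- feats
    colnames(m) <- cells
  } else {
    sep <- if (format == "csv") "," else "\t"
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            data.table = FALSE)
    ids <- as.character(dt[[1L]])
    m <- as.matrix(dt[, -1L, drop = FALSE])
    if (!is.numeric(m))
      stop("non-numeric expression values in ", path)
    rownames(m) <- ids
  }
  validate_expression(m)
  m
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()] for the dense format: gene ids in the
#' first column (`gene_id`), cell ids as the header.
#'
#' @param expr genes x cells matrix.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  expr <- validate_expression(expr)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cluster labels from a two-column TSV (cell_id, cluster)
#'
#' @param path file path.
#' @return named integer vector of cluster labels.
#' @export
read_clusters <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("cluster file needs columns cell_id and cluster")
  stats::setNames(as.integer(factor(df[[2L]])), as.character(df[[1L]]))
}

#' Write a pseudotime result table
#'
#' One row per cell with columns cell_id, pseudotime_rank, then score,
#' cluster and branch when available (stable column order).
#'
#' @param result named per-cell pseudotime ranks (e.g. `evolve()$pseudotime`
#'   or `pseudotime_large()$pseudotime`), or a data.frame already holding a
#'   `cell_id` and `pseudotime_rank` column.
#' @param path output TSV path.
#' @param score,cluster,branch optional per-cell annotations (named or
#'   aligned with `result`).
#' @export
write_pseudotime <- function(result, path, score = NULL, cluster = NULL,
                             branch = NULL) {
  if (is.data.frame(result)) {
    df <- result
  } else {
    df <- data.frame(cell_id = names(result),
                     pseudotime_rank = as.integer(result),
                     stringsAsFactors = FALSE)
  }
  add <- function(df, x, nm) {
    if (is.null(x)) return(df)
    df[[nm]] <- if (!is.null(names(x))) unname(x[df$cell_id]) else x
    df
  }
  df <- add(df, score, "score")
  df <- add(df, cluster, "cluster")
  df <- add(df, branch, "branch")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a lineage tree as an edge-list TSV
#'
#' Columns parent_node, child_node, weight (plus edge type).
#'
#' @param tree a `lineage_tree`.
#' @param path output TSV path.
#' @export
write_tree <- function(tree, path) {
  df <- data.frame(parent_node = tree$edges$from,
                   child_node = tree$edges$to,
                   weight = tree$edges$weight,
                   type = tree$edges$type,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
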