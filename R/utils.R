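# Internal helpers shared across modules.

#' Run code under a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive child seeds from a master seed, all below 2^31
#' @noRd
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

#' Validate a genes x cells expression matrix
#'
#' Checks the container used throughout the package: a non-negative numeric
#' matrix with genes in rows and cells in columns, unique rownames (gene ids)
#' and unique colnames (cell ids), and no missing entries.
#'
#' @param expr numeric matrix, genes in rows, cells in columns.
#' @return the matrix, invisibly, after validation (ids filled in if absent).
#' @export
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix (genes x cells)")
  if (nrow(expr) < 1L || ncol(expr) < 1L)
    stop("expression matrix is empty")
  if (anyNA(expr))
    stop("expression matrix contains missing values")
  if (is.null(rownames(expr)))
    rownames(expr) <- sprintf("gene%d", seq_len(nrow(expr)))
  if (is.null(colnames(expr)))
    colnames(expr) <- sprintf("cell%d", seq_len(ncol(expr)))
  if (anyDuplicated(rownames(expr)))
    stop("duplicated gene ids: ",
         paste(unique(rownames(expr)[duplicated(rownames(expr))]), collapse = ", "))
  if (anyDuplicated(colnames(expr)))
    stop("duplicated cell ids: ",
         paste(unique(colnames(expr)[duplicated(colnames(expr))]), collapse = ", "))
  invisible(expr)
}

#' @noRd
is_permutation <- function(x, n = length(x)) {
  length(x) == n && !anyNA(x) && all(sort(as.integer(x)) == seq_len(n))
}

#' @noRd
stopifnot_permutation <- function(x) {
  if (!is_permutation(x)) stop("not a valid permutation of 1..n")
  invisible(as.integer(x))
}
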