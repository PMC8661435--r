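# Optional gene filtering and cell clustering ahead of pseudotime estimation.

#' Filter genes by differential expression across clusters
#'
#' Ranks genes by a rank-based differential-expression score and keeps the
#' top `n_top`.  With cluster labels the score is the Kruskal-Wallis
#' statistic of the gene's expression across clusters; without labels it
#' falls back to the variance of the gene's rank-transformed expression.
#' Either way the score depends on the data only through within-gene ranks,
#' so the selected gene set is invariant to strictly monotone transforms of
#' the expression values.  Score ties are broken by gene id (lexicographic)
#' for reproducibility.
#'
#' @param expr genes x cells expression matrix.
#' @param clusters optional per-cell integer cluster labels (named by cell
#'   id or aligned with columns), e.g. from [cluster_cells()].
#' @param n_top number of genes to keep (default 2000, capped at the number
#'   of genes available).
#' @return the expression matrix restricted to the selected genes, ordered
#'   by decreasing score; the cell set is unchanged.
#' @export
filter_genes <- function(expr, clusters = NULL, n_top = 2000L) {
  expr <- validate_expression(expr)
  if (n_top <= 0) stop("n_top must be positive")
  n_top <- min(as.integer(n_top), nrow(expr))
  if (!is.null(clusters)) {
    labels <- align_labels(clusters, colnames(expr))
    if (length(unique(labels)) < 2L) {
      warning("fewer than 2 clusters supplied; falling back to rank variance")
      score <- rank_variance_score(expr)
    } else {
      g <- factor(labels)
      score <- apply(expr, 1L, function(row) {
        if (max(row) == min(row)) return(0)   # constant gene: no signal
        stats::kruskal.test(row, g)$statistic
      })
    }
  } else {
    score <- rank_variance_score(expr)
  }
  ord <- order(-score, rownames(expr))
  expr[ord[seq_len(n_top)], , drop = FALSE]
}

#' @noRd
rank_variance_score <- function(expr) {
  rk <- rank_transform(expr)
  apply(rk, 1L, stats::var)
}

#' @noRd
align_labels <- function(clusters, cell_ids) {
  if (!is.null(names(clusters))) {
    if (!all(cell_ids %in% names(clusters)))
      stop("cluster labels are missing for some cells")
    return(clusters[cell_ids])
  }
  if (length(clusters) != length(cell_ids))
    stop("cluster labels must cover every cell")
  clusters
}

#' Cluster cells for branch detection and gene filtering
#'
#' k-means on the leading principal components (at most 10) of the
#' rank-transformed expression matrix.  When `k = "auto"` the number of
#' clusters is chosen by mean silhouette width over 2..`k_max`.  Results are
#' reproducible bit-for-bit for a fixed seed.
#'
#' @param expr genes x cells expression matrix (>= 2 cells).
#' @param k number of clusters, or `"auto"` (default).
#' @param k_max largest k tried when `k = "auto"` (default 10).
#' @param seed integer seed for the k-means starts.
#' @return list with `labels` (integer cluster id 1..k per cell, named by
#'   cell id) and `k`.
#' @export
cluster_cells <- function(expr, k = "auto", k_max = 10L, seed = 1L) {
  expr <- validate_expression(expr)
  n <- ncol(expr)
  if (n < 2L) stop("clustering needs at least 2 cells")
  if (!identical(k, "auto") && k > n) stop("k cannot exceed the number of cells")
  rk <- rank_transform(expr)
  x <- t(rk)
  if (all(apply(x, 2L, function(c) max(c) == min(c)))) {
    # identical expression everywhere: clustering is arbitrary
    if (identical(k, "auto")) {
      warning("all cells identical; returning k = 2 arbitrary split")
      k <- 2L
    }
    labels <- rep_len(seq_len(k), n)
    return(list(labels = stats::setNames(as.integer(labels), colnames(expr)),
                k = as.integer(k)))
  }
  ncomp <- min(10L, n - 1L, nrow(expr))
  pcs <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = ncomp)$x
  km_at <- function(kk) with_seed(seed,
    stats::kmeans(pcs, centers = kk, nstart = 10L, iter.max = 50L))
  if (identical(k, "auto")) {
    k_max <- min(k_max, n - 1L)
    best <- NULL; best_sil <- -Inf
    d <- stats::dist(pcs)
    for (kk in 2:max(2L, k_max)) {
      km <- km_at(kk)
      sil <- mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
      if (sil > best_sil) { best_sil <- sil; best <- km; k <- kk }
    }
    km <- best
  } else {
    k <- as.integer(k)
    if (k == 1L)
      return(list(labels = stats::setNames(rep(1L, n), colnames(expr)), k = 1L))
    km <- km_at(k)
  }
  list(labels = stats::setNames(as.integer(km$cluster), colnames(expr)),
       k = as.integer(k))
}
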