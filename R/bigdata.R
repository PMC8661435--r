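# Scaling to large cell numbers: order a subsample by the genetic
# algorithm, propagate its pseudotime to every cell through r-nearest-
# neighbour score averaging, and pool B such score vectors with a
# one-dimensional principal curve.

#' Order a random subsample of cells
#'
#' Draws n cells uniformly without replacement and runs [evolve()] on the
#' subsample's own rank matrix.
#'
#' @param expr genes x cells expression matrix (N cells).
#' @param n subsample size, 5 <= n <= N.
#' @param config a [ga_config()]; its seed controls both the draw and the GA.
#' @return list with `ordering` (permutation of the subsample), `cells`
#'   (subsampled cell ids in trajectory order), `subsample` (column indices
#'   drawn, in draw order), and `cost`.
#' @export
subsample_order <- function(expr, n, config = ga_config()) {
  expr <- validate_expression(expr)
  N <- ncol(expr)
  if (n < 5L || n > N) stop("subsample size must be between 5 and the number of cells")
  seeds <- derive_seeds(config$seed, 2L)
  idx <- if (n == N) seq_len(N) else
    with_seed(seeds[1L], sort(sample.int(N, n)))
  sub <- expr[, idx, drop = FALSE]
  rk <- rank_transform(sub)
  cfg <- config
  cfg$seed <- seeds[2L]
  fit <- evolve(rk, cfg)
  list(ordering = fit$ordering, cells = colnames(sub)[fit$ordering],
       subsample = idx, cost = fit$cost)
}

#' Propagate subsample pseudotime to all cells by r nearest neighbours
#'
#' Each cell's score S_j is the mean pseudotime t of its r nearest
#' subsampled cells, with distance measured as Euclidean distance in
#' rank-transformed expression space (genes ranked across all cells).  Only
#' subsampled cells carry t values; a subsampled cell is its own nearest
#' neighbour at distance zero, so with r = 1 its score is its own t.
#'
#' @param expr genes x cells expression matrix (all N cells).
#' @param sub_ordering permutation of the subsample (positions within
#'   `subsample_ids`), e.g. `subsample_order()$ordering`.
#' @param subsample_ids column indices of the subsampled cells (draw order).
#' @param r number of neighbours (default 5).
#' @return list with `scores` (numeric per cell, named), `r`, and
#'   `degenerate` (TRUE when all cells are identical in expression so all
#'   scores coincide).
#' @export
knn_scores <- function(expr, sub_ordering, subsample_ids, r = 5L) {
  expr <- validate_expression(expr)
  n <- length(subsample_ids)
  if (r < 1L) stop("r must be at least 1")
  if (r > n) stop("r cannot exceed the subsample size")
  rk <- rank_transform(expr)
  t_of_sub <- order(sub_ordering)            # t value of each subsample cell
  X <- t(rk)                                  # cells x genes
  S <- X[subsample_ids, , drop = FALSE]       # subsample coordinates
  # squared Euclidean distances all-cells x subsample via the inner-product trick
  d2 <- outer(rowSums(X^2), rep(1, n)) - 2 * X %*% t(S) +
    outer(rep(1, nrow(X)), rowSums(S^2))
  d2[d2 < 0] <- 0
  scores <- apply(d2, 1L, function(row) {
    nb <- order(row)[seq_len(r)]
    mean(t_of_sub[nb])
  })
  names(scores) <- colnames(expr)
  list(scores = scores, r = as.integer(r),
       degenerate = stats::var(scores) < 1e-12)
}

#' Principal-curve consensus over subsample score columns
#'
#' Fits a one-dimensional principal curve through the cells in B-dimensional
#' score space by iterative projection and smoothing: arc-length positions
#' are initialised from the first principal component, each coordinate is
#' spline-smoothed against arc length, cells are re-projected onto the
#' resulting polyline, and the loop stops when the induced ordering
#' stabilises (at most `max_iter` sweeps).  Cells are returned ordered by
#' their final arc length.  Score columns must already be sign-aligned (see
#' [pseudotime_large()]).
#'
#' @param score_matrix cells x B matrix of per-subsample scores.
#' @param max_iter iteration cap (default 50).
#' @return list with `ordering` (permutation of cells by arc length),
#'   `lambda` (per-cell arc length), and `iterations`.
#' @export
consensus_curve <- function(score_matrix, max_iter = 50L) {
  X <- as.matrix(score_matrix)
  N <- nrow(X); B <- ncol(X)
  if (B < 1L) stop("at least one score column is required")
  if (all(apply(X, 2L, stats::var) < 1e-12))
    stop("degenerate score matrix: all cells identical")
  if (B == 1L) {
    lam <- X[, 1L]
    return(list(ordering = order(lam), lambda = lam, iterations = 0L))
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  lam <- stats::prcomp(Xc, rank. = 1L)$x[, 1L]
  ord_prev <- order(lam)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    o <- order(lam)
    lam_s <- lam[o]
    # smooth each coordinate against arc length on a fixed grid
    grid_n <- min(200L, N)
    grid <- seq(min(lam_s), max(lam_s), length.out = grid_n)
    curve <- matrix(0, grid_n, B)
    for (b in seq_len(B)) {
      fit <- tryCatch(
        stats::smooth.spline(lam_s, Xc[o, b], cv = FALSE),
        error = function(e) NULL)
      curve[, b] <- if (is.null(fit)) {
        stats::approx(lam_s, Xc[o, b], xout = grid, rule = 2, ties = mean)$y
      } else stats::predict(fit, grid)$y
    }
    lam <- project_polyline(Xc, curve)
    o2 <- order(lam)
    if (identical(o2, ord_prev) || iter >= max_iter) break
    ord_prev <- o2
  }
  list(ordering = order(lam), lambda = lam, iterations = iter)
}

# Project points onto the polyline through `curve` rows; return arc length
# of the projection of each point.
#' @noRd
project_polyline <- function(X, curve) {
  g <- nrow(curve)
  seg <- diff(curve)                              # (g-1) x B
  seg_len2 <- rowSums(seg^2)
  seg_len2[seg_len2 < 1e-30] <- 1e-30
  cum <- c(0, cumsum(sqrt(rowSums(seg^2))))       # arc length at each vertex
  N <- nrow(X)
  lam <- numeric(N)
  # for each segment, projection parameter of all points (vectorised per segment)
  best_d2 <- rep(Inf, N)
  for (s in seq_len(g - 1L)) {
    v <- seg[s, ]
    w <- sweep(X, 2L, curve[s, ])
    tt <- pmin(pmax(as.vector(w %*% v) / seg_len2[s], 0), 1)
    proj_d2 <- rowSums(w^2) - 2 * tt * as.vector(w %*% v) + tt^2 * seg_len2[s]
    better <- proj_d2 < best_d2
    if (any(better)) {
      best_d2[better] <- proj_d2[better]
      lam[better] <- cum[s] + tt[better] * sqrt(seg_len2[s])
    }
  }
  lam
}

#' Two-stage pseudotime for large datasets
#'
#' Runs [subsample_order()] and [knn_scores()] B times with seeds derived
#' from the master seed, sign-aligns the B score columns (each subsample
#' ordering has arbitrary orientation, so every column is flipped to
#' correlate positively with the reference column: the first column, or the
#' largest-variance column if the first is flat), and pools them with
#' [consensus_curve()].  Bit-reproducible for a fixed master seed; the B
#' subsample runs are independent of one another.
#'
#' @param expr genes x cells expression matrix.
#' @param B number of subsamples (default 30).
#' @param M subsample size (default 100).
#' @param r neighbours for score propagation (default 5).
#' @param config a [ga_config()]; its seed is the master seed.
#' @return list with `ordering` (all N cells by consensus arc length),
#'   `pseudotime` (rank per cell, named), `scores` (cells x B matrix after
#'   sign alignment), and `subsamples` (per-run outputs).
#' @export
pseudotime_large <- function(expr, B = 30L, M = 100L, r = 5L,
                             config = ga_config()) {
  expr <- validate_expression(expr)
  if (M < 5L) stop("M must be at least 5")
  if (B < 1L) stop("B must be at least 1")
  N <- ncol(expr)
  seeds <- derive_seeds(config$seed, B)
  runs <- vector("list", B)
  scores <- matrix(0, N, B)
  for (b in seq_len(B)) {
    cfg <- config
    cfg$seed <- seeds[b]
    so <- subsample_order(expr, min(M, N), cfg)
    ks <- knn_scores(expr, so$ordering, so$subsample, r = r)
    runs[[b]] <- list(order = so, scores = ks)
    scores[, b] <- ks$scores
  }
  scores <- align_score_columns(scores)
  rownames(scores) <- colnames(expr)
  if (B == 1L) {
    ordering <- order(scores[, 1L])
  } else {
    ordering <- consensus_curve(scores)$ordering
  }
  pt <- order(ordering)
  names(pt) <- colnames(expr)
  list(ordering = ordering, pseudotime = pt, scores = scores,
       subsamples = runs)
}

# Flip score columns so all correlate positively with the reference column.
#' @noRd
align_score_columns <- function(scores) {
  B <- ncol(scores)
  if (B == 1L) return(scores)
  vars <- apply(scores, 2L, stats::var)
  ref <- if (vars[1L] > 1e-12) 1L else which.max(vars)
  for (b in seq_len(B)) {
    if (b == ref) next
    rho <- suppressWarnings(
      stats::cor(scores[, ref], scores[, b], method = "spearman"))
    if (!is.na(rho) && rho < 0) scores[, b] <- -scores[, b]
  }
  scores
}
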