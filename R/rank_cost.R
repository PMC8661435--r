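# Rank-polynomial BIC cost over candidate cell orderings.
#
# The model: for gene j, the rank R_ij of cell i among that gene's expression
# values is a polynomial (degree at most 3) of the cell's pseudotime
# t_i in {1..n}, where (t_1..t_n) is a permutation of 1..n.  Each candidate
# ordering is scored per gene by the best of the degree-1/2/3 least-squares
# fits under BIC_dj = n*ln(sigma2) + d*ln(n), and the ordering's cost is the
# sum over genes of C_j = min_d BIC_dj.  Lower is better.
#
# Orderings are integer vectors `perm` with perm[k] = the (column) index of
# the cell placed at pseudotime position k; equivalently t = order(perm).

#' Row-wise rank transform of an expression matrix
#'
#' Replaces each gene's expression values across cells by their ranks, with
#' tied values (including zeros) receiving the average of the tied positions.
#' Ranks are computed once from the expression matrix; candidate orderings
#' permute time positions, never the ranks.
#'
#' @param expr numeric genes x cells matrix (see [validate_expression()]).
#' @return numeric matrix of the same shape; row j holds the ranks of the
#'   cells among gene j's expression values.
#' @examples
#' m <- rbind(g1 = c(0, 0, 5), g2 = c(5, 1, 1))
#' colnames(m) <- c("a", "b", "c")
#' rank_transform(m)
#' @export
rank_transform <- function(expr) {
  expr <- validate_expression(expr)
  r <- t(apply(expr, 1L, rank, ties.method = "average"))
  if (ncol(expr) == 1L) r <- matrix(r, nrow = nrow(expr),
                                    dimnames = dimnames(expr))
  dimnames(r) <- dimnames(expr)
  r
}

#' Variance floor for residual variances
#' @noRd
sigma2_floor_default <- function(n) 1e-8 * n^2

# Precomputed quantities reused across many candidate orderings for one rank
# matrix: the orthonormal polynomial basis in positions 1..n and the per-gene
# total (centred) sums of squares, which are permutation-invariant.
#' @noRd
cost_context <- function(ranks, sigma2_floor = NULL) {
  n <- ncol(ranks)
  if (n < 5L)
    stop("cost fits need at least 5 cells per fitted unit ",
         "(cubic fit plus one residual degree of freedom); got ", n)
  if (is.null(sigma2_floor)) sigma2_floor <- sigma2_floor_default(n)
  Q <- stats::poly(seq_len(n), degree = 3L)    # orthonormal, orthogonal to 1
  ss_tot <- rowSums((ranks - rowMeans(ranks))^2)
  list(ranks = ranks, n = n, n_genes = nrow(ranks), Q = unclass(Q)[, 1:3],
       ss_tot = ss_tot, floor = sigma2_floor, logn = log(n))
}

# Evaluate total cost for a batch of orderings against one context.
# perms: list of integer permutations. Returns numeric vector of total costs.
#' @noRd
batch_cost <- function(ctx, perms) {
  n <- ctx$n
  k <- length(perms)
  # column d of candidate c is Q[, d] indexed at each cell's time position
  Qbig <- matrix(0, nrow = n, ncol = 3L * k)
  for (c in seq_len(k)) {
    tpos <- order(perms[[c]])                  # t value of each cell index
    Qbig[, (3L * c - 2L):(3L * c)] <- ctx$Q[tpos, ]
  }
  A <- ctx$ranks %*% Qbig                       # genes x (3k) projections
  out <- numeric(k)
  ss <- ctx$ss_tot
  for (c in seq_len(k)) {
    a2 <- A[, (3L * c - 2L):(3L * c), drop = FALSE]^2
    rss1 <- ss - a2[, 1L]
    rss2 <- rss1 - a2[, 2L]
    rss3 <- rss2 - a2[, 3L]
    s1 <- pmax(rss1 / n, ctx$floor)
    s2 <- pmax(rss2 / n, ctx$floor)
    s3 <- pmax(rss3 / n, ctx$floor)
    cj <- pmin(n * log(s1) + 1 * ctx$logn,
               n * log(s2) + 2 * ctx$logn,
               n * log(s3) + 3 * ctx$logn)
    out[c] <- sum(cj)
  }
  out
}

#' Cost of one gene's ranks under a candidate ordering
#'
#' Fits least squares of the gene's rank vector on pseudotime positions
#' 1..n (implied by `ordering`) restricted to polynomial degree d = 1, 2, 3,
#' and returns the fit minimising BIC_d = n*ln(sigma2) + d*ln(n), with the
#' residual variance floored at `sigma2_floor` so that perfect fits give a
#' large negative but finite BIC.  Fitting uses an orthogonal polynomial
#' basis internally; the reported coefficients are on centred, scaled time
#' s = (t - (n+1)/2)/n (residual variance and BIC are basis-invariant).
#'
#' @param ranks_row numeric vector of ranks for one gene (length n >= 5).
#' @param ordering integer permutation of 1..n; `ordering[k]` is the cell at
#'   position k.
#' @param sigma2_floor lower bound on the residual variance; default
#'   `1e-8 * n^2` (ranks have scale n).
#' @return a list with `degree`, `coefficients` (length 4, unused high terms
#'   zero, basis s = (t-(n+1)/2)/n), `resid_var`, and `bic` (= C_j).
#' @export
gene_cost <- function(ranks_row, ordering, sigma2_floor = NULL) {
  n <- length(ranks_row)
  if (n < 5L)
    stop("at least 5 cells are required per fitted unit (minimum cluster size 5)")
  ordering <- stopifnot_permutation(ordering)
  if (length(ordering) != n) stop("ordering length must match ranks_row")
  if (is.null(sigma2_floor)) sigma2_floor <- sigma2_floor_default(n)
  y <- ranks_row[ordering]                      # response ordered by position
  s <- (seq_len(n) - (n + 1) / 2) / n
  X <- cbind(1, s, s^2, s^3)
  logn <- log(n)
  best <- NULL
  for (d in 1:3) {
    fit <- stats::lm.fit(X[, seq_len(d + 1L), drop = FALSE], y)
    sigma2 <- max(mean(fit$residuals^2), sigma2_floor)
    bic <- n * log(sigma2) + d * logn
    if (is.null(best) || bic < best$bic) {
      beta <- numeric(4)
      beta[seq_len(d + 1L)] <- fit$coefficients
      best <- list(degree = d, coefficients = beta,
                   resid_var = sigma2, bic = bic)
    }
  }
  best
}

#' Total cost of an ordering over all genes
#'
#' Sums the per-gene minimum-BIC costs C_j for one candidate ordering.
#'
#' @param ranks rank matrix from [rank_transform()] (genes x cells).
#' @param ordering integer permutation of cell indices.
#' @param sigma2_floor residual-variance floor (see [gene_cost()]).
#' @return list with `total` (C) and `per_gene` (named vector of C_j).
#' @export
total_cost <- function(ranks, ordering, sigma2_floor = NULL) {
  ordering <- stopifnot_permutation(ordering)
  if (length(ordering) != ncol(ranks))
    stop("ordering length must equal the number of cells")
  ctx <- cost_context(ranks, sigma2_floor)
  tpos <- order(ordering)
  A <- ctx$ranks %*% ctx$Q[tpos, ]
  a2 <- A^2
  rss <- cbind(ctx$ss_tot - a2[, 1L],
               ctx$ss_tot - a2[, 1L] - a2[, 2L],
               ctx$ss_tot - a2[, 1L] - a2[, 2L] - a2[, 3L])
  sigma2 <- pmax(rss / ctx$n, ctx$floor)
  bic <- ctx$n * log(sigma2) +
    matrix(1:3 * ctx$logn, nrow(ranks), 3L, byrow = TRUE)
  per_gene <- apply(bic, 1L, min)
  names(per_gene) <- rownames(ranks)
  list(total = sum(per_gene), per_gene = per_gene)
}

#' Exhaustive-search optimal ordering (small n)
#'
#' Evaluates the total cost of every permutation of the cells and returns a
#' global minimiser.  Because the polynomial family is closed under time
#' reversal, the reverse of the returned ordering always ties.  Intended as
#' an oracle for validating the genetic algorithm on tiny instances.
#'
#' @param ranks rank matrix (genes x cells) with at most 9 cells.
#' @param sigma2_floor residual-variance floor.
#' @return list with `ordering` (a minimising permutation), `cost`, and
#'   `degenerate` (TRUE when all permutations tie, e.g. constant genes).
#' @export
argmin_bruteforce <- function(ranks, sigma2_floor = NULL) {
  n <- ncol(ranks)
  if (n > 9L) stop("exhaustive search supports at most 9 cells (n! growth)")
  ctx <- cost_context(ranks, sigma2_floor)
  perms <- all_permutations(n)
  costs <- batch_cost(ctx, perms)
  best <- which.min(costs)
  list(ordering = perms[[best]], cost = costs[best],
       degenerate = (max(costs) - min(costs)) < 1e-9 * max(1, abs(costs[best])))
}

#' @noRd
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      i <- i + 1L
      out[[i]] <- as.integer(append(p, n, after = pos - 1L))
    }
  }
  out
}
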