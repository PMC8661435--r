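# Accuracy metrics for estimated pseudotime.

#' Absolute Spearman correlation with a reference ordering
#'
#' Returns |Spearman rho| between an estimated pseudotime (ordering ranks or
#' any score vector) and a reference.  Because a trajectory's orientation is
#' arbitrary, the absolute value is reported; the metric is symmetric in its
#' arguments and invariant to reversing either.  When the reference is a
#' small set of ordered stage labels whose true order is unknown (e.g. cell
#' cycle stages), set `stage_permutable = TRUE` to report the maximum |rho|
#' over all orderings of the stage labels.
#'
#' @param est numeric pseudotime estimate (ranks or scores), one per cell.
#' @param ref reference pseudotime: numeric, or a factor/character vector of
#'   stage labels.
#' @param stage_permutable maximise over permutations of the stage-label
#'   order (only meaningful for a label reference with few levels).
#' @return absolute Spearman correlation in [0, 1].
#' @export
abs_spearman <- function(est, ref, stage_permutable = FALSE) {
  if (length(est) != length(ref))
    stop("est and ref must cover the same cells")
  if (is.factor(ref) || is.character(ref)) {
    f <- factor(ref)
    if (!stage_permutable) {
      return(abs(stats::cor(est, as.integer(f), method = "spearman")))
    }
    k <- nlevels(f)
    if (k > 7L) stop("too many stage levels to permute (max 7)")
    perms <- all_permutations(k)
    best <- 0
    for (p in perms) {
      rho <- abs(stats::cor(est, p[as.integer(f)], method = "spearman"))
      if (!is.na(rho) && rho > best) best <- rho
    }
    return(best)
  }
  abs(stats::cor(est, ref, method = "spearman"))
}

#' Count genes functionally related to an estimated pseudotime
#'
#' For each gene, fits the best rank-polynomial model (degree <= 3 by BIC,
#' as in the ordering cost) of the gene's expression ranks on the estimated
#' pseudotime and tests it against the intercept-only model with an F test.
#' Genes significant after Benjamini-Hochberg correction at level `alpha`
#' are counted.  Because the response is the within-gene rank vector, the
#' count is invariant to strictly monotone transforms of the expression
#' values.
#'
#' @param expr genes x cells expression matrix.
#' @param est estimated pseudotime: a permutation of cell indices (ordering)
#'   or a per-cell numeric score whose ranks define the ordering.
#' @param alpha significance level after BH correction (default 0.05).
#' @return integer count of significant genes.
#' @export
count_functional_genes <- function(expr, est, alpha = 0.05) {
  expr <- validate_expression(expr)
  n <- ncol(expr)
  if (n < 5L) stop("at least 5 cells are required")
  if (length(est) != n) stop("est must have one value per cell")
  ordering <- if (is_permutation(est, n)) as.integer(est)
              else order(est)
  ranks <- rank_transform(expr)
  ctx <- cost_context(ranks)
  tpos <- order(ordering)
  A <- ctx$ranks %*% ctx$Q[tpos, ]
  a2 <- A^2
  rss <- cbind(ctx$ss_tot - a2[, 1L],
               ctx$ss_tot - a2[, 1L] - a2[, 2L],
               ctx$ss_tot - a2[, 1L] - a2[, 2L] - a2[, 3L])
  sigma2 <- pmax(rss / n, ctx$floor)
  bic <- n * log(sigma2) +
    matrix(1:3 * ctx$logn, nrow(expr), 3L, byrow = TRUE)
  d <- max.col(-bic, ties.method = "first")          # best degree per gene
  rss_d <- rss[cbind(seq_len(nrow(expr)), d)]
  rss_d <- pmax(rss_d, 0)
  # F test of the selected polynomial against the intercept-only model
  df2 <- n - d - 1L
  const <- ctx$ss_tot <= 0
  fstat <- ((ctx$ss_tot - rss_d) / d) / (rss_d / df2)
  p <- stats::pf(fstat, d, df2, lower.tail = FALSE)
  p[const] <- 1                                       # constant genes: no signal
  p[is.na(p)] <- 0                                    # perfect fit, rss 0
  p[const] <- 1
  padj <- stats::p.adjust(p, method = "BH")
  sum(padj < alpha)
}
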