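# Gamma-Poisson trajectory simulator.
#
# Each cell receives a latent pseudotime u in [0,1] (equally spaced; cell
# order shuffled for storage).  For a trend-bearing gene the Gamma shape
# parameter follows the gene's trend curve in u, mapped into `shape_range`;
# the per-cell expression mean is drawn Gamma(shape, scale) and the read
# count Poisson with that mean, so counts are marginally negative binomial
# (overdispersed).  Technical zeros are then injected under one of three
# dropout regimes.

#' Simulation configuration
#'
#' @param n_cells,n_genes dimensions of the simulated count matrix.
#' @param trend_fractions proportions of genes following, in order:
#'   linear-increasing, linear-decreasing, quadratic, sinusoidal, and
#'   pseudotime-independent trends; must sum to 1.
#' @param gamma_scale scale parameter of the Gamma mean distribution.
#' @param shape_range range (low, high) into which each gene's trend curve is
#'   mapped to give the pseudotime-dependent Gamma shape.
#' @param dropout_scenario 1 (low rate, decreasing in mean expression),
#'   2 (low constant rate), or 3 (high constant rate); 0 disables dropout.
#' @param dropout_rate target overall dropout probability; defaults to
#'   0.05 for scenarios 1 and 2 and 0.40 for scenario 3.
#' @param seed integer seed; fixed seed gives a bit-identical dataset.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 200L, n_genes = 100L,
                       trend_fractions = c(linear_up = 0.2, linear_down = 0.2,
                                           quadratic = 0.2, sinusoidal = 0.2,
                                           independent = 0.2),
                       gamma_scale = 1, shape_range = c(1, 20),
                       dropout_scenario = 0L, dropout_rate = NULL,
                       seed = 1L) {
  if (abs(sum(trend_fractions) - 1) > 1e-8)
    stop("trend_fractions must sum to 1")
  if (length(shape_range) != 2L || shape_range[1L] >= shape_range[2L])
    stop("shape_range must be (low, high) with low < high")
  if (!dropout_scenario %in% 0:3) stop("dropout_scenario must be 0, 1, 2 or 3")
  if (is.null(dropout_rate))
    dropout_rate <- if (dropout_scenario == 3L) 0.40 else 0.05
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 trend_fractions = trend_fractions, gamma_scale = gamma_scale,
                 shape_range = shape_range,
                 dropout_scenario = as.integer(dropout_scenario),
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# Trend curves on u in [0,1], each returning values in [0,1].
#' @noRd
trend_curve <- function(label, phase = 0, level = 0.5, flip = FALSE) {
  switch(label,
         linear_up = function(u) u,
         linear_down = function(u) 1 - u,
         quadratic = if (flip) function(u) 1 - 4 * u * (1 - u)
                     else function(u) 4 * u * (1 - u),
         sinusoidal = function(u) (sin(2 * pi * u + phase) + 1) / 2,
         independent = function(u) rep(level, length(u)),
         stop("unknown trend label: ", label))
}

#' @noRd
assign_trends <- function(n_genes, fractions) {
  labels <- names(fractions)
  counts <- floor(fractions * n_genes)
  rem <- n_genes - sum(counts)
  if (rem > 0) {          # distribute the rounding remainder in label order
    counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  }
  rep(labels, counts)
}

#' Simulate a single pseudotime trajectory
#'
#' Generates a genes x cells count matrix whose trend-bearing genes follow
#' their trend curves in the latent pseudotime through the Gamma shape
#' parameter, applies the configured dropout regime, and returns the counts
#' together with the generating truth.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_truth` with elements `counts` (genes x cells
#'   integer matrix), `true_pseudotime` (integer rank 1..n per cell, named),
#'   `u` (latent pseudotime in [0,1] per cell), `trend_label` (per gene),
#'   `dropout_mask` (logical matrix, TRUE where a technical zero was
#'   injected), and `means` (the generating Gamma means before dropout).
#' @export
simulate_trajectory <- function(config = sim_config()) {
  n <- config$n_cells; ng <- config$n_genes
  with_seed(config$seed, {
    u_sorted <- seq(0, 1, length.out = n)
    shuffle <- sample.int(n)              # storage order of cells
    u <- u_sorted[order(shuffle)]         # u of stored cell k
    true_pt <- rank(u, ties.method = "first")
    trend <- assign_trends(ng, config$trend_fractions)
    lo <- config$shape_range[1L]; hi <- config$shape_range[2L]
    shape <- matrix(0, nrow = ng, ncol = n)
    for (j in seq_len(ng)) {
      f <- trend_curve(trend[j], phase = stats::runif(1, 0, 2 * pi),
                       level = stats::runif(1),
                       flip = stats::runif(1) < 0.5)
      shape[j, ] <- lo + f(u) * (hi - lo)
    }
    means <- matrix(stats::rgamma(ng * n, shape = shape,
                                  scale = config$gamma_scale),
                    nrow = ng, ncol = n)
    counts <- matrix(stats::rpois(ng * n, means), nrow = ng, ncol = n)
    rownames(counts) <- sprintf("gene%d", seq_len(ng))
    colnames(counts) <- sprintf("cell%d", seq_len(n))
    dimnames(means) <- dimnames(counts)
    if (config$dropout_scenario > 0L) {
      dd <- apply_dropout(counts, means, config$dropout_scenario,
                          rate = config$dropout_rate)
      counts <- dd$counts
      mask <- dd$mask
    } else {
      mask <- matrix(FALSE, ng, n, dimnames = dimnames(counts))
    }
    names(true_pt) <- colnames(counts)
    names(u) <- colnames(counts)
    structure(list(counts = counts, true_pseudotime = true_pt, u = u,
                   trend_label = stats::setNames(trend, rownames(counts)),
                   dropout_mask = mask, means = means),
              class = "sim_truth")
  })
}

#' Inject technical zeros (dropout)
#'
#' Scenario 1 draws dropout with probability decreasing in the generating
#' mean (logistic in log mean, centred so the overall rate is close to
#' `rate`); scenario 2 uses a constant low probability independent of the
#' mean; scenario 3 a constant high probability.  Masked entries are set to
#' zero.
#'
#' @param counts integer count matrix (genes x cells).
#' @param means generating mean matrix aligned with `counts` (used by
#'   scenario 1 only).
#' @param scenario 1, 2 or 3.
#' @param rate target overall dropout probability.
#' @param slope steepness of the scenario-1 mean dependence (on log1p mean).
#' @return list with zeroed `counts` and logical `mask` of injected zeros.
#' @export
apply_dropout <- function(counts, means, scenario, rate = NULL, slope = 1.5) {
  if (!scenario %in% 1:3) stop("unknown dropout scenario: ", scenario)
  if (is.null(rate)) rate <- if (scenario == 3L) 0.40 else 0.05
  if (rate <= 0) {
    return(list(counts = counts,
                mask = matrix(FALSE, nrow(counts), ncol(counts),
                              dimnames = dimnames(counts))))
  }
  if (scenario == 1L) {
    lm1 <- log1p(means)
    # centre the logistic at the median log-mean so the realised overall
    # rate stays near `rate` while remaining decreasing in the mean
    p <- stats::plogis(stats::qlogis(min(rate, 1 - 1e-12)) -
                         slope * (lm1 - stats::median(lm1)))
  } else {
    p <- matrix(rate, nrow(counts), ncol(counts))
  }
  mask <- matrix(stats::runif(length(counts)) < p,
                 nrow(counts), ncol(counts), dimnames = dimnames(counts))
  counts[mask] <- 0L
  list(counts = counts, mask = mask)
}

#' Simulate a branching (Y- or multi-fork) trajectory
#'
#' A stem trajectory forks into several branch trajectories.  Every gene's
#' Gamma shape follows its stem trend over the stem; past the fork each
#' branch interpolates linearly from the gene's stem-terminal shape to a
#' branch-specific random target, so branch starting states match the stem's
#' terminal state in expectation while the branches diverge.
#'
#' @param n_cells_stem number of stem cells.
#' @param n_cells_branch integer vector: cells per branch (>= 2 branches for
#'   a fork; one branch degenerates to a single trajectory).
#' @param n_genes number of genes.
#' @param config a [sim_config()] supplying trends, shape range, scale,
#'   dropout and seed (its `n_cells`/`n_genes` are ignored).
#' @return `sim_truth` list as in [simulate_trajectory()], plus `branch`
#'   (per-cell label: "stem" or "branch<b>") and `u` the within-segment
#'   pseudotime; `true_pseudotime` ranks cells along stem then branches.
#' @export
simulate_branching <- function(n_cells_stem, n_cells_branch, n_genes,
                               config = sim_config()) {
  if (length(n_cells_branch) < 1L) stop("at least one branch is required")
  with_seed(config$seed, {
    lo <- config$shape_range[1L]; hi <- config$shape_range[2L]
    trend <- assign_trends(n_genes, config$trend_fractions)
    stem_f <- vector("list", n_genes)
    for (j in seq_len(n_genes)) {
      stem_f[[j]] <- trend_curve(trend[j], phase = stats::runif(1, 0, 2 * pi),
                                 level = stats::runif(1),
                                 flip = stats::runif(1) < 0.5)
    }
    segs <- list(stem = n_cells_stem)
    for (b in seq_along(n_cells_branch))
      segs[[paste0("branch", b)]] <- n_cells_branch[b]
    shape_cols <- list(); branch_lab <- character(0); useg <- numeric(0)
    for (sname in names(segs)) {
      m <- segs[[sname]]
      uu <- seq(0, 1, length.out = m)
      S <- matrix(0, n_genes, m)
      if (sname == "stem") {
        for (j in seq_len(n_genes)) S[j, ] <- lo + stem_f[[j]](uu) * (hi - lo)
      } else {
        # branch: linear from the stem-terminal shape to a random target
        target <- stats::runif(n_genes, lo, hi)
        for (j in seq_len(n_genes)) {
          start <- lo + stem_f[[j]](1) * (hi - lo)
          S[j, ] <- start + uu * (target[j] - start)
        }
      }
      shape_cols[[sname]] <- S
      branch_lab <- c(branch_lab, rep(sname, m))
      useg <- c(useg, uu)
    }
    shape <- do.call(cbind, shape_cols)
    n <- ncol(shape)
    means <- matrix(stats::rgamma(n_genes * n, shape = shape,
                                  scale = config$gamma_scale),
                    nrow = n_genes)
    counts <- matrix(stats::rpois(n_genes * n, means), nrow = n_genes)
    rownames(counts) <- sprintf("gene%d", seq_len(n_genes))
    colnames(counts) <- sprintf("cell%d", seq_len(n))
    dimnames(means) <- dimnames(counts)
    if (config$dropout_scenario > 0L) {
      dd <- apply_dropout(counts, means, config$dropout_scenario,
                          rate = config$dropout_rate)
      counts <- dd$counts; mask <- dd$mask
    } else {
      mask <- matrix(FALSE, n_genes, n, dimnames = dimnames(counts))
    }
    # global pseudotime rank: stem first, then branches in order
    true_pt <- stats::setNames(seq_len(n), colnames(counts))
    structure(list(counts = counts, true_pseudotime = true_pt, u = useg,
                   trend_label = stats::setNames(trend, rownames(counts)),
                   dropout_mask = mask, means = means,
                   branch = stats::setNames(branch_lab, colnames(counts)),
                   shape = shape),
              class = "sim_truth")
  })
}
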