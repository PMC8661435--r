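# Shared fixtures and independent oracles used across test files.

# Small expression matrix with named dims
toy_expr <- function(values, n_genes, n_cells) {
  m <- matrix(values, nrow = n_genes, ncol = n_cells)
  rownames(m) <- sprintf("g%02d", seq_len(n_genes))
  colnames(m) <- sprintf("c%02d", seq_len(n_cells))
  m
}

# Independent OLS oracle: explicit design matrices on raw time 1..n,
# residual variances for d = 1..3, BIC per the printed formula, C_j = min.
oracle_gene_cost <- function(ranks_row, ordering, sigma2_floor = NULL) {
  n <- length(ranks_row)
  if (is.null(sigma2_floor)) sigma2_floor <- 1e-8 * n^2
  y <- ranks_row[ordering]
  tt <- seq_len(n)
  bics <- sapply(1:3, function(d) {
    X <- outer(tt, 0:d, "^")
    beta <- qr.solve(qr(X, LAPACK = TRUE), y)
    sigma2 <- max(mean((y - X %*% beta)^2), sigma2_floor)
    n * log(sigma2) + d * log(n)
  })
  min(bics)
}

oracle_total_cost <- function(ranks, ordering, sigma2_floor = NULL) {
  sum(apply(ranks, 1L, oracle_gene_cost, ordering = ordering,
            sigma2_floor = sigma2_floor))
}

# Brute-force minimum-weight bipartite matching between position sets p and q
# with |p - q| weights: enumerate all assignments, return the minimal total
# weight (used to certify the sorted-order matching).
oracle_min_matching_weight <- function(p, q) {
  perms <- gatraj_perms(length(q))
  best <- Inf
  for (pr in perms) {
    w <- sum(abs(p - q[pr]))
    if (w < best) best <- w
  }
  best
}

gatraj_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in gatraj_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- as.integer(append(sub, n, after = pos - 1L))
    }
  }
  out
}

# Monotone-trend simulation shorthand used by several files
sim_monotone <- function(n_cells, n_genes, seed, dropout_scenario = 0L) {
  simulate_trajectory(sim_config(
    n_cells = n_cells, n_genes = n_genes,
    trend_fractions = c(linear_up = 0.5, linear_down = 0.5, quadratic = 0,
                        sinusoidal = 0, independent = 0),
    dropout_scenario = dropout_scenario, seed = seed))
}

# fast GA config for tests
fast_ga <- function(seed, min_gen = 15L, max_gen = 60L) {
  ga_config(seed = seed, min_generations = min_gen, max_generations = max_gen)
}
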