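# Genetic algorithm over cell permutations.
#
# One generation: every member of the size-N population produces one
# inversion mutant (N -> 2N); the 2N pool is split at random into two halves
# and paired across halves for crossover, each pair yielding two offspring
# (2N -> 4N); the N lowest-cost individuals of the 4N pool survive.  Because
# the incumbent best is in the pool, the best cost never increases.

#' Genetic-algorithm configuration
#'
#' @param pop_size population size N; must be >= 4 and divisible by 4 so the
#'   mutation/crossover/selection bookkeeping (N -> 2N -> 4N -> N) is exact.
#'   The default 100 evaluates the cost on 4N = 400 candidate orderings per
#'   generation.
#' @param min_generations generations to run before the convergence test is
#'   applied (default 30).
#' @param max_generations hard cap on generations (default 200).
#' @param epsilon absolute convergence threshold on the best-cost improvement
#'   between consecutive generations; if `NULL` (default) it is set to
#'   `1e-6 * |best cost at generation 1|`.
#' @param poisson_lambda mean of the Poisson number of crossover cut points
#'   (default 2; draws of 0 copy the parents through).
#' @param seed integer seed controlling every random draw of the run.
#' @param pc_init also seed one member ordered by the first principal
#'   component of the rank matrix (default FALSE; initialisation is uniform
#'   random permutations).
#' @return a list of class `ga_config`.
#' @export
ga_config <- function(pop_size = 100L, min_generations = 30L,
                      max_generations = 200L, epsilon = NULL,
                      poisson_lambda = 2, seed = 1L, pc_init = FALSE) {
  pop_size <- as.integer(pop_size)
  if (pop_size < 4L || pop_size %% 4L != 0L)
    stop("pop_size must be >= 4 and divisible by 4")
  if (min_generations < 1L) stop("min_generations must be >= 1")
  structure(list(pop_size = pop_size,
                 min_generations = as.integer(min_generations),
                 max_generations = as.integer(max_generations),
                 epsilon = epsilon, poisson_lambda = poisson_lambda,
                 seed = as.integer(seed), pc_init = isTRUE(pc_init)),
            class = "ga_config")
}

#' Inversion mutation
#'
#' Picks two positions i <= j uniformly at random and reverses the segment
#' of the permutation between them; positions outside the segment are
#' untouched.  The input is not modified.
#'
#' @param x integer permutation.
#' @param i,j optional fixed cut positions (drawn uniformly when missing).
#' @return mutated permutation.
#' @export
mutate_inversion <- function(x, i = NULL, j = NULL) {
  n <- length(x)
  if (is.null(i) || is.null(j)) {
    ij <- sort(sample.int(n, 2L, replace = TRUE))
    i <- ij[1L]; j <- ij[2L]
  }
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  y <- x
  y[i:j] <- x[j:i]
  y
}

# Minimum-weight matching of two position sets under |p - q| cost.
# For points on a line with absolute-difference weights, matching in sorted
# order is an exact optimal assignment; ties resolve to lowest index.
#' @noRd
match_positions <- function(p, q) {
  op <- order(p); oq <- order(q)
  cbind(p = p[op], q = q[oq])
}

#' Poisson-cut crossover with bipartite matching repair
#'
#' Draws the number of cut points from a Poisson distribution, splits both
#' parents into equal-length fragments (the last fragment absorbs any
#' remainder), and builds each child by retaining alternate fragments of one
#' parent.  The vacated positions are refilled from the other parent: the
#' positional indices of the left-behind entries in both parents form the
#' two sides of a bipartite graph with edge weight |p - q|, a minimum-weight
#' matching is solved exactly, and the second parent's entries are copied in
#' along the matching.  Both children are valid permutations.
#'
#' @param parent1,parent2 integer permutations of the same cells.
#' @param lambda Poisson mean for the number of cut points (default 2).
#' @param n_cut optional fixed number of cut points (overrides the draw).
#' @return list of two offspring permutations.
#' @export
recombine <- function(parent1, parent2, lambda = 2, n_cut = NULL) {
  n <- length(parent1)
  if (length(parent2) != n) stop("parents must have the same length")
  if (is.null(n_cut)) n_cut <- stats::rpois(1L, lambda)
  k <- n_cut + 1L                       # fragments
  if (k >= n) k <- n
  len <- n %/% k
  frag_id <- pmin((seq_len(n) - 1L) %/% len + 1L, k)  # last absorbs remainder
  keep <- frag_id %% 2L == 1L           # alternate fragments, first retained
  list(crossover_child(parent1, parent2, keep),
       crossover_child(parent2, parent1, keep))
}

#' @noRd
crossover_child <- function(keeper, donor, keep) {
  if (all(keep)) return(keeper)
  child <- keeper
  missing_vals <- keeper[!keep]               # entries not retained
  p <- which(!keep)                           # vacated positions in keeper
  q <- which(donor %in% missing_vals)         # their positions in the donor
  m <- match_positions(p, q)
  child[m[, "p"]] <- donor[m[, "q"]]
  child
}

#' Quarter selection
#'
#' Keeps the N lowest-cost members of a 4N pool, ties broken by insertion
#' order (stable sort), so the population size is constant across
#' generations and the incumbent best always survives.
#'
#' @param members list of permutations (the pool).
#' @param costs numeric vector of evaluated costs aligned with `members`.
#' @param n_keep number N of survivors; `length(members)` must be `4 * n_keep`.
#' @param distinct prefer distinct permutations: duplicates of an already
#'   selected ordering are passed over while distinct lower-cost candidates
#'   remain, which preserves population diversity (the survivor set is
#'   topped up with duplicates only when fewer than N distinct orderings
#'   exist).  Default FALSE (plain truncation selection); [evolve()] selects
#'   with `distinct = TRUE`.
#' @return list with `members` and `costs` of the survivors.
#' @export
select_quarter <- function(members, costs, n_keep, distinct = FALSE) {
  if (length(members) != 4L * n_keep)
    stop("selection expects a pool of exactly 4N individuals")
  if (length(costs) != length(members))
    stop("costs must align with members")
  idx <- order(costs)                         # stable: ties keep pool order
  if (distinct) {
    key <- vapply(members[idx], paste, "", collapse = ",")
    first <- !duplicated(key)
    idx <- c(idx[first], idx[!first])
  }
  idx <- sort.int(idx[seq_len(n_keep)])       # survivors keep pool order
  idx <- idx[order(costs[idx])]
  list(members = members[idx], costs = costs[idx])
}

#' Pseudotime ordering by genetic algorithm
#'
#' Minimises the rank-polynomial BIC cost over permutations of the cells.
#' Starting from seeded uniform-random permutations, each generation applies
#' inversion mutation, Poisson-cut crossover with matching repair, and
#' quarter selection (preferring distinct orderings, see
#' [select_quarter()]), and stops once at least `min_generations` have run
#' and the best cost improved by less than `epsilon` over the previous
#' generation.  On very small instances (n <= 12 by default) a converged
#' population is re-seeded with fresh random permutations (keeping the
#' incumbent best) up to `restarts` times within the `max_generations`
#' budget, which counters premature convergence when the permutation space
#' is small enough for near-exact search.  The orientation of the result is
#' arbitrary: its reverse has identical cost.
#'
#' @param ranks rank matrix from [rank_transform()] (genes x cells, n >= 5).
#' @param config a [ga_config()].
#' @param sigma2_floor residual-variance floor (see [gene_cost()]).
#' @param restarts population re-seedings after convergence; `NULL` (default)
#'   uses 3 when n <= 12 and 0 otherwise.
#' @param trace if TRUE, attach the per-generation best-cost trace.
#' @return list with `ordering` (best permutation found), `cost`, `pseudotime`
#'   (integer rank of each cell along the trajectory, named by cell id),
#'   `generations` run, `low_signal` flag (near-flat cost distribution at
#'   termination), and optionally `trace`.
#' @export
evolve <- function(ranks, config = ga_config(), sigma2_floor = NULL,
                   restarts = NULL, trace = FALSE) {
  n <- ncol(ranks)
  if (n < 5L) stop("evolve needs at least 5 cells")
  ctx <- cost_context(ranks, sigma2_floor)
  N <- config$pop_size
  if (is.null(restarts)) restarts <- if (n <= 12L) 3L else 0L
  with_seed(config$seed, {
    init_pop <- function(keep = NULL) {
      pop <- replicate(N, sample.int(n), simplify = FALSE)
      if (!is.null(keep)) pop[[1L]] <- keep
      pop
    }
    pop <- init_pop()
    if (config$pc_init && nrow(ranks) > 1L) {
      pc1 <- stats::prcomp(t(ranks), rank. = 1L)$x[, 1L]
      pop[[1L]] <- order(pc1)
    }
    costs <- batch_cost(ctx, pop)
    eps <- config$epsilon
    if (is.null(eps)) eps <- 1e-6 * abs(min(costs))
    best_m <- pop[[which.min(costs)]]
    best_c <- min(costs)
    best_trace <- numeric(0)
    gen <- 0L; since_init <- 0L; used_restarts <- 0L
    repeat {
      gen <- gen + 1L
      since_init <- since_init + 1L
      mutants <- lapply(pop, mutate_inversion)
      pool2 <- c(pop, mutants)                       # 2N
      split <- sample.int(2L * N)                    # random bipartition
      half1 <- split[seq_len(N)]
      half2 <- split[N + seq_len(N)]
      offspring <- vector("list", 2L * N)
      for (p in seq_len(N)) {
        ch <- recombine(pool2[[half1[p]]], pool2[[half2[p]]],
                        lambda = config$poisson_lambda)
        offspring[[2L * p - 1L]] <- ch[[1L]]
        offspring[[2L * p]] <- ch[[2L]]
      }
      new_costs <- batch_cost(ctx, c(mutants, offspring))
      pool <- c(pop, mutants, offspring)             # 4N
      pool_costs <- c(costs, new_costs)
      sel <- select_quarter(pool, pool_costs, N, distinct = TRUE)
      prev_best <- min(costs)
      pop <- sel$members
      costs <- sel$costs
      if (costs[1L] < best_c) { best_c <- costs[1L]; best_m <- pop[[1L]] }
      best_trace[gen] <- best_c
      converged <- since_init >= config$min_generations &&
        prev_best - costs[1L] < eps
      if (gen >= config$max_generations) break
      if (converged) {
        if (used_restarts < restarts) {
          used_restarts <- used_restarts + 1L
          since_init <- 0L
          pop <- init_pop(keep = best_m)
          costs <- batch_cost(ctx, pop)
        } else break
      }
    }
    pt <- order(best_m)
    names(pt) <- colnames(ranks)[seq_len(n)]
    spread <- max(costs) - min(costs)
    out <- list(ordering = best_m, cost = best_c, pseudotime = pt,
                generations = gen,
                low_signal = spread < 1e-6 * max(1, abs(best_c)))
    if (trace) out$trace <- best_trace
    out
  })
}
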