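test_that("cluster-wise ordering recovers each half of a split trajectory", {
  st <- sim_monotone(60, 80, seed = 31)
  # two clusters = first and second half of the true pseudotime
  labels <- ifelse(st$true_pseudotime <= 30, 1L, 2L)
  names(labels) <- colnames(st$counts)
  paths <- order_all_clusters(st$counts, labels, fast_ga(7))
  for (p in paths) {
    truth <- st$true_pseudotime[p$cells]
    expect_gte(abs_spearman(seq_along(p$cells), truth), 0.9)
  }
  # a single cluster covering everything reduces to plain evolve
  one <- order_all_clusters(st$counts, setNames(rep(1L, 60), colnames(st$counts)),
                            fast_ga(7))
  expect_length(one, 1L)
  expect_setequal(one[[1]]$cells, colnames(st$counts))
})

test_that("undersized clusters are rejected by name", {
  st <- sim_monotone(12, 10, seed = 5)
  labels <- c(rep(1L, 8), rep(2L, 4))
  names(labels) <- colnames(st$counts)
  expect_error(order_all_clusters(st$counts, labels, fast_ga(1)), "2")
})

test_that("endpoint distance picks the junction joining adjacent trajectory ends", {
  # one long low-noise trajectory: expression tracks time with small jitter
  set.seed(41)
  n <- 80
  expr <- toy_expr(0, 20, n)
  for (g in 1:20) {
    slope <- sample(c(-2, 2), 1)
    expr[g, ] <- slope * seq_len(n) + rnorm(n, sd = 3)
  }
  # split into two consecutive paths, each in true time order
  path_x <- list(cluster_id = 1L, cells = colnames(expr)[1:40])
  path_y <- list(cluster_id = 2L, cells = colnames(expr)[41:80])
  d <- endpoint_distance(path_x, path_y, expr)
  # temporally adjacent ends: tail of x (t=40) meets head of y (t=41)
  expect_equal(d$winner, "xt_yh")
  # the smooth junction costs strictly less than the three mismatched ones
  expect_true(all(d$costs[names(d$costs) != "xt_yh"] > d$distance))
})

test_that("endpoint distance is symmetric over random path pairs", {
  st <- sim_monotone(60, 30, seed = 51)
  set.seed(52)
  for (i in 1:50) {
    cells <- sample(colnames(st$counts))
    m <- sample(8:30, 1); n <- sample(8:(60 - m), 1)
    px <- list(cluster_id = 1L, cells = cells[1:m])
    py <- list(cluster_id = 2L, cells = cells[m + (1:n)])
    dxy <- endpoint_distance(px, py, st$counts)$distance
    dyx <- endpoint_distance(py, px, st$counts)$distance
    expect_equal(dxy, dyx, tolerance = 1e-9)
  }
})

test_that("constant genes make all four junction costs tie", {
  flat <- toy_expr(5, 4, 24)
  px <- list(cluster_id = 1L, cells = colnames(flat)[1:12])
  py <- list(cluster_id = 2L, cells = colnames(flat)[13:24])
  d <- endpoint_distance(px, py, flat)
  expect_true(d$tie)
  expect_equal(d$distance, min(d$costs))
})

test_that("trees span clusters acyclically with k-1 joins", {
  st <- sim_monotone(90, 50, seed = 61)
  labels <- cut(st$true_pseudotime, 3, labels = FALSE)
  names(labels) <- colnames(st$counts)
  paths <- order_all_clusters(st$counts, labels, fast_ga(3))
  tree <- build_tree(paths, st$counts)
  expect_length(tree$joins, 2L)                     # k - 1 inter-cluster joins
  # acyclic over all nodes: |E| = |V| - 1 and connected
  nodes <- unique(c(tree$edges$from, tree$edges$to))
  expect_equal(nrow(tree$edges), length(nodes) - 1L)
  # single path: trivial tree
  single <- build_tree(paths[1], st$counts)
  expect_length(single$joins, 0L)
  expect_equal(nrow(single$edges), 1L)
})

test_that("a Y-shaped simulation yields one connected tree over all branches", {
  sb <- simulate_branching(40, c(30, 30), 80, sim_config(seed = 71))
  labels <- setNames(as.integer(factor(sb$branch, levels = c("stem", "branch1", "branch2"))),
                     colnames(sb$counts))
  paths <- order_all_clusters(sb$counts, labels, fast_ga(9))
  tree <- build_tree(paths, sb$counts)
  expect_length(tree$joins, 2L)                 # k - 1 inter-cluster joins
  # every cluster participates and the node graph is a tree
  join_clusters <- unlist(lapply(tree$joins, function(j) c(j$a, j$b)))
  expect_setequal(unique(join_clusters), 1:3)
  nodes <- unique(c(tree$edges$from, tree$edges$to))
  expect_equal(nrow(tree$edges), length(nodes) - 1L)
  # per-cell table covers every cell exactly once with branch labels
  cells <- lineage_cells(tree)
  expect_setequal(cells$cell_id, colnames(sb$counts))
  expect_equal(anyDuplicated(cells$cell_id), 0L)
})

test_that("flat junctions lose to informative ones across three discrete states", {
  # clusters 1 and 3 share one transcriptional state while cluster 2 is
  # distinct (a return-to-baseline chain): the 1-3 junction is trendless
  # noise, so the tree must run through cluster 2
  set.seed(91)
  n_per <- 24
  expr <- toy_expr(0, 20, 3 * n_per)
  for (g in 1:20) {
    lv <- if (g %% 2 == 0) c(0, 50, 0) else c(50, 0, 50)
    expr[g, ] <- rep(lv, each = n_per) + rnorm(3 * n_per, sd = 4)
  }
  labels <- setNames(rep(1:3, each = n_per), colnames(expr))
  paths <- order_all_clusters(expr, labels, fast_ga(17))
  tree <- build_tree(paths, expr)
  joins <- sapply(tree$joins, function(j) paste(sort(c(j$a, j$b)), collapse = "-"))
  expect_setequal(joins, c("1-2", "2-3"))
})

test_that("rooting orients pseudotime away from the root without changing topology", {
  st <- sim_monotone(40, 60, seed = 81)
  labels <- setNames(rep(1L, 40), colnames(st$counts))
  paths <- order_all_clusters(st$counts, labels, fast_ga(11))
  tree <- build_tree(paths, st$counts)
  first_cell <- paths[[1]]$cells[1]
  last_cell <- paths[[1]]$cells[40]
  r1 <- root_tree(tree, first_cell)
  expect_identical(r1$paths[[1]]$cells, paths[[1]]$cells)   # unchanged
  r2 <- root_tree(tree, last_cell)
  expect_identical(r2$paths[[1]]$cells, rev(paths[[1]]$cells))  # reversed
  expect_error(root_tree(tree, "nonexistent"), "root")

  # multi-cluster: rooted edges form the same undirected edge set, and
  # within-path ranks increase along every directed root-to-leaf walk
  labels3 <- cut(st$true_pseudotime, 2, labels = FALSE)
  names(labels3) <- colnames(st$counts)
  p3 <- order_all_clusters(st$counts, labels3, fast_ga(13))
  t3 <- build_tree(p3, st$counts)
  rt <- root_tree(t3, 1)
  undirected <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  expect_identical(undirected(rt$edges), undirected(t3$edges))
  expect_equal(rt$root, "1")
})
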