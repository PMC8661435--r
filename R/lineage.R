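# Branching lineage construction: order cells within each cluster, then join
# cluster paths into a tree through their termination points.
#
# Each cluster's internal ordering has two termination points (its first and
# last quarter-segments).  The distance between two paths is the minimum
# rank-polynomial cost over the four printed quarter-segment concatenations,
# evaluated on ranks recomputed over the union of the involved cells.  Paths
# are joined smallest-distance-first under Kruskal's no-cycle rule; when
# several clusters attach at one termination point a branching node is
# inserted there.

#' Order the cells of every cluster independently
#'
#' Runs [evolve()] per cluster on that cluster's own rank matrix (ranks are
#' recomputed within the cluster: ranks are only meaningful within the
#' fitted unit).  Deterministic for a fixed config seed; per-cluster seeds
#' are derived from it.
#'
#' @param expr genes x cells expression matrix.
#' @param clusters per-cell cluster labels (named by cell id, or aligned
#'   with columns), e.g. from [cluster_cells()].
#' @param config a [ga_config()]; its seed drives all clusters.
#' @return list of cluster paths, one per cluster id, each a list with
#'   `cluster_id`, `cells` (cell ids in trajectory order), `ordering`
#'   (permutation of within-cluster column indices), and `cost`.
#' @export
order_all_clusters <- function(expr, clusters, config = ga_config()) {
  expr <- validate_expression(expr)
  labels <- align_labels(clusters, colnames(expr))
  ids <- sort(unique(labels))
  sizes <- table(labels)
  small <- names(sizes)[sizes < 5L]
  if (length(small) > 0L)
    stop("clusters with fewer than 5 cells cannot be ordered: ",
         paste(small, collapse = ", "))
  seeds <- derive_seeds(config$seed, length(ids))
  paths <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    cells <- which(labels == ids[i])
    sub <- expr[, cells, drop = FALSE]
    rk <- rank_transform(sub)
    cfg <- config
    cfg$seed <- seeds[i]
    fit <- evolve(rk, cfg)
    paths[[i]] <- list(cluster_id = ids[i],
                       cells = colnames(sub)[fit$ordering],
                       ordering = fit$ordering,
                       cost = fit$cost)
  }
  names(paths) <- as.character(ids)
  paths
}

# The four junction concatenations between paths x (length m) and y
# (length n), built from quarter-length end segments:
#   hh: head-quarter of y reversed, then head-quarter of x
#   th: tail-quarter of y, then head-quarter of x
#   hh2: head-quarter of x reversed, then head-quarter of y (reversal of hh)
#   ht: tail-quarter of x, then head-quarter of y
# Names record which termination points (head/tail of each path) meet.
#' @noRd
junction_sequences <- function(x_cells, y_cells) {
  m <- length(x_cells); n <- length(y_cells)
  qx <- max(1L, m %/% 4L); qy <- max(1L, n %/% 4L)
  list(
    yh_xh = c(rev(y_cells[seq_len(qy)]), x_cells[seq_len(qx)]),
    yt_xh = c(y_cells[(n - qy + 1L):n], x_cells[seq_len(qx)]),
    xh_yh = c(rev(x_cells[seq_len(qx)]), y_cells[seq_len(qy)]),
    xt_yh = c(x_cells[(m - qx + 1L):m], y_cells[seq_len(qy)])
  )
}

# which endpoint of each path participates in each junction geometry
#' @noRd
junction_endpoints <- list(
  yh_xh = c(x = "head", y = "head"),
  yt_xh = c(x = "head", y = "tail"),
  xh_yh = c(x = "head", y = "head"),
  xt_yh = c(x = "tail", y = "head")
)

#' Distance between two cluster paths
#'
#' Evaluates the ordering cost of the four quarter-segment concatenations of
#' the two paths' termination ends and returns the minimum, together with
#' the winning junction geometry (which end of each path meets the other).
#' Ranks are recomputed on the union of the cells in each concatenation.
#' For concatenations shorter than 5 cells the cubic-fit minimum cannot be
#' met and the cost falls back to the degree-1 fit.
#'
#' @param path_x,path_y cluster paths from [order_all_clusters()].
#' @param expr the full genes x cells expression matrix.
#' @return list with `distance`, `winner` (junction name), `endpoint_x`,
#'   `endpoint_y` ("head"/"tail"), `costs` (all four), and `tie` flag
#'   (all four costs equal, e.g. constant genes).
#' @export
endpoint_distance <- function(path_x, path_y, expr) {
  if (length(path_x$cells) < 4L || length(path_y$cells) < 4L)
    stop("paths need at least 4 cells for quarter-segment distances")
  seqs <- junction_sequences(path_x$cells, path_y$cells)
  costs <- vapply(seqs, function(cells) concat_cost(expr, cells), 0)
  w <- which.min(costs)
  ends <- junction_endpoints[[names(seqs)[w]]]
  list(distance = costs[[w]], winner = names(seqs)[w],
       endpoint_x = unname(ends["x"]), endpoint_y = unname(ends["y"]),
       costs = costs,
       tie = (max(costs) - min(costs)) < 1e-9 * max(1, abs(costs[[w]])))
}

#' @noRd
concat_cost <- function(expr, cells) {
  sub <- expr[, cells, drop = FALSE]
  rk <- rank_transform(sub)
  n <- ncol(rk)
  if (n >= 5L) {
    return(total_cost(rk, seq_len(n))$total)
  }
  # short concatenation: degree-1 fit only
  floor2 <- sigma2_floor_default(n)
  s <- seq_len(n)
  tot <- 0
  for (j in seq_len(nrow(rk))) {
    fit <- stats::lm.fit(cbind(1, s), rk[j, ])
    sigma2 <- max(mean(fit$residuals^2), floor2)
    tot <- tot + n * log(sigma2) + log(n)
  }
  tot
}

#' Join cluster paths into a lineage tree
#'
#' Computes all pairwise endpoint distances and joins clusters in increasing
#' distance order, rejecting edges that would close a cycle (Kruskal), until
#' the clusters are spanned by k - 1 inter-cluster edges.  Nodes are the two
#' termination points of every path (`c<id>_head`, `c<id>_tail`) linked by
#' the path itself; when more than one cluster attaches to a single
#' termination point, a branching node (`bp_*`) is inserted at that point
#' with zero-length edges to each attaching path.  Distance ties break
#' lexicographically on the (cluster id, cluster id) pair for determinism.
#'
#' @param paths list of cluster paths from [order_all_clusters()].
#' @param expr the full genes x cells expression matrix.
#' @return list of class `lineage_tree`: `edges` (data.frame from, to,
#'   weight, type = path/join/branch), `paths`, `root` (NULL until
#'   [root_tree()]), and `joins` (the accepted inter-cluster junctions).
#' @export
build_tree <- function(paths, expr) {
  k <- length(paths)
  if (k < 1L) stop("at least one path is required")
  ids <- vapply(paths, function(p) as.character(p$cluster_id), "")
  node <- function(id, end) sprintf("c%s_%s", id, end)
  edges <- data.frame(from = node(ids, "head"), to = node(ids, "tail"),
                      weight = 0, type = "path", stringsAsFactors = FALSE)
  joins <- list()
  if (k > 1L) {
    cand <- list()
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        d <- endpoint_distance(paths[[a]], paths[[b]], expr)
        cand[[length(cand) + 1L]] <- list(a = a, b = b, d = d)
      }
    }
    ord <- order(vapply(cand, function(c) c$d$distance, 0),
                 vapply(cand, function(c) ids[c$a], ""),
                 vapply(cand, function(c) ids[c$b], ""))
    comp <- seq_len(k)                      # union-find over clusters
    for (ci in ord) {
      cn <- cand[[ci]]
      if (comp[cn$a] == comp[cn$b]) next    # would close a cycle
      comp[comp == comp[cn$b]] <- comp[cn$a]
      joins[[length(joins) + 1L]] <- cn
      if (length(joins) == k - 1L) break
    }
    # insert branching points where a termination point hosts > 1 join
    endpoint_of <- function(cn) c(node(ids[cn$a], cn$d$endpoint_x),
                                  node(ids[cn$b], cn$d$endpoint_y))
    eps <- table(unlist(lapply(joins, endpoint_of)))
    branch_at <- names(eps)[eps > 1L]
    for (cn in joins) {
      ep <- endpoint_of(cn)
      hub <- ep[ep %in% branch_at]
      if (length(hub) > 0L) {
        # route the join through a branching node at the shared endpoint
        bp <- paste0("bp_", hub[1L])
        if (!any(edges$from == hub[1L] & edges$to == bp)) {
          edges <- rbind(edges, data.frame(from = hub[1L], to = bp,
                                           weight = 0, type = "branch",
                                           stringsAsFactors = FALSE))
        }
        other <- setdiff(ep, hub[1L])
        if (length(other) == 0L) other <- ep[2L]   # both ends shared hubs
        edges <- rbind(edges, data.frame(from = bp, to = other[1L],
                                         weight = cn$d$distance,
                                         type = "join",
                                         stringsAsFactors = FALSE))
      } else {
        edges <- rbind(edges, data.frame(from = ep[1L], to = ep[2L],
                                         weight = cn$d$distance,
                                         type = "join",
                                         stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(edges = edges, paths = paths, root = NULL, joins = joins),
            class = "lineage_tree")
}

#' Root a lineage tree
#'
#' Orients every edge away from the chosen root (a cluster id or a cell id)
#' and flips within-cluster orderings where needed so that pseudotime
#' increases along every directed root-to-leaf walk.  A root cell anchors
#' the endpoint of its cluster's path it lies nearest to; a root cluster
#' anchors its free endpoint (one not used by an inter-cluster join, head on
#' ties).  Topology is unchanged: only edge directions and path orientations
#' move.
#'
#' @param tree a `lineage_tree` from [build_tree()].
#' @param root cluster id or cell id present in the tree.
#' @return the tree with `root` set, `edges` ordered parent -> child, and
#'   flipped `paths` where re-orientation was required.
#' @export
root_tree <- function(tree, root) {
  ids <- vapply(tree$paths, function(p) as.character(p$cluster_id), "")
  root <- as.character(root)
  root_end <- NULL
  if (!root %in% ids) {
    hit <- vapply(tree$paths, function(p) root %in% p$cells, NA)
    if (!any(hit)) stop("root '", root, "' is neither a cluster nor a cell id")
    p <- tree$paths[[which(hit)[1L]]]
    pos <- match(root, p$cells)
    root_end <- if (pos - 1L <= length(p$cells) - pos) "head" else "tail"
    root <- ids[which(hit)[1L]]
  }
  if (is.null(root_end)) {
    # endpoints of the root cluster used by accepted joins
    used <- character(0)
    for (cn in tree$joins) {
      if (ids[cn$a] == root) used <- c(used, cn$d$endpoint_x)
      if (ids[cn$b] == root) used <- c(used, cn$d$endpoint_y)
    }
    root_end <- if (!"head" %in% used) "head"
                else if (!"tail" %in% used) "tail" else "head"
  }
  root_node <- sprintf("c%s_%s", root, root_end)
  # undirected adjacency over nodes
  nodes <- unique(c(tree$edges$from, tree$edges$to))
  adj <- lapply(stats::setNames(nodes, nodes), function(x) character(0))
  for (e in seq_len(nrow(tree$edges))) {
    f <- tree$edges$from[e]; t <- tree$edges$to[e]
    adj[[f]] <- c(adj[[f]], t)
    adj[[t]] <- c(adj[[t]], f)
  }
  # BFS orientation away from the root node
  parent <- stats::setNames(rep(NA_character_, length(nodes)), nodes)
  depth <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  queue <- root_node; depth[root_node] <- 0L
  while (length(queue) > 0L) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (nb in adj[[cur]]) {
      if (is.na(depth[nb])) {
        depth[nb] <- depth[cur] + 1L
        parent[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  edges <- tree$edges
  for (e in seq_len(nrow(edges))) {
    if (!is.na(parent[edges$from[e]]) && parent[edges$from[e]] == edges$to[e]) {
      tmp <- edges$from[e]; edges$from[e] <- edges$to[e]; edges$to[e] <- tmp
    }
  }
  # flip paths whose tail is nearer the root than their head
  paths <- tree$paths
  for (i in seq_along(paths)) {
    id <- ids[i]
    h <- depth[sprintf("c%s_head", id)]
    t <- depth[sprintf("c%s_tail", id)]
    if (!is.na(h) && !is.na(t) && t < h) {
      paths[[i]]$cells <- rev(paths[[i]]$cells)
      paths[[i]]$ordering <- rev(paths[[i]]$ordering)
    }
  }
  tree$edges <- edges
  tree$paths <- paths
  tree$root <- root
  tree
}

#' Per-cell table of a lineage tree
#'
#' @param tree a `lineage_tree`.
#' @return data.frame with cell_id, cluster, within-cluster pseudotime rank,
#'   and branch id (the cluster id; one row per cell).
#' @export
lineage_cells <- function(tree) {
  do.call(rbind, lapply(tree$paths, function(p) {
    data.frame(cell_id = p$cells, cluster = p$cluster_id,
               pseudotime_rank = seq_along(p$cells),
               branch = as.character(p$cluster_id),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
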