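#' Weighted Newman-Girvan modularity of a partition
#'
#' Q = sum over communities c of [ w_in(c)/m - (d_w(c) / (2 m))^2 ], where m is
#' the total edge weight, w_in(c) the intra-community edge weight and d_w(c)
#' the summed weighted degree of c. The one-community partition scores 0.
#'
#' @param graph a `snapshot_graph` (see [window_correlation_graph()]).
#' @param membership integer community label per node, named by node (pixel)
#'   id, covering exactly the graph's nodes; or a `group_partition` from
#'   [louvain()].
#' @return Q in [-1, 1].
#' @export
modularity_q <- function(graph, membership) {
  stopifnot(inherits(graph, "snapshot_graph"))
  if (inherits(membership, "group_partition"))
    membership <- partition_membership(membership)
  if (length(graph$nodes) == 0L) return(0)
  lab <- membership[as.character(graph$nodes)]
  if (anyNA(lab))
    stop("membership does not cover all graph nodes", call. = FALSE)
  ed <- graph$edges
  m <- sum(ed$w)
  if (m == 0) return(0)
  ci <- lab[as.character(ed$i)]
  cj <- lab[as.character(ed$j)]
  w_in <- tapply(ed$w[ci == cj], ci[ci == cj], sum)
  deg <- tapply(c(ed$w, ed$w), c(ci, cj), sum)
  q <- sum(w_in) / m - sum((deg / (2 * m))^2)
  unname(q)
}

partition_membership <- function(part) {
  ids <- unlist(part$groups)
  mem <- rep(seq_along(part$groups), vapply(part$groups, length, integer(1)))
  names(mem) <- as.character(ids)
  mem
}

#' Louvain community detection on one snapshot
#'
#' Greedy modularity optimization: nodes are repeatedly moved to the
#' neighbouring community with the largest modularity gain (visiting order
#' drawn from `seed`; on ties, including zero best gain, a node stays where it
#' is), then communities are aggregated into supernodes and the procedure
#' repeats until no level improves Q. Edge weights (correlations) enter the
#' optimization as-is; set `binary = TRUE` to ignore them.
#'
#' @param graph a `snapshot_graph`.
#' @param seed integer seed controlling node visiting order.
#' @param binary if TRUE all edge weights are treated as 1.
#' @param restarts independent greedy runs with sub-seeds derived from
#'   `seed`; the partition with the highest Q is returned (first on ties).
#'   More restarts cost proportionally more time but escape poor visiting
#'   orders on small graphs.
#' @return A `group_partition`: list with `t`, `groups` (list of 0-based pixel
#'   id vectors), `Q`, and `level_q` (modularity after each aggregation level,
#'   nondecreasing).
#' @export
louvain <- function(graph, seed = 1, binary = FALSE, restarts = 5) {
  stopifnot(inherits(graph, "snapshot_graph"))
  best <- NULL
  for (r in seq_len(max(1, restarts))) {
    p <- louvain_core(graph, seed + (r - 1L) * 1009L, binary)
    if (is.null(best) || p$Q > best$Q + 1e-12) best <- p
  }
  best
}

louvain_core <- function(graph, seed, binary = FALSE) {
  nodes <- graph$nodes
  if (length(nodes) == 0L)
    return(structure(list(t = graph$t, groups = list(), Q = 0,
                          level_q = numeric(0)),
                     class = "group_partition"))
  id2idx <- seq_along(nodes); names(id2idx) <- as.character(nodes)
  ei <- id2idx[as.character(graph$edges$i)]
  ej <- id2idx[as.character(graph$edges$j)]
  ew <- if (binary) rep(1, nrow(graph$edges)) else graph$edges$w

  set.seed(seed)
  # current level's graph: edge arrays + self-loop weights per supernode
  n <- length(nodes)
  li <- ei; lj <- ej; lw <- ew; self <- numeric(n)
  node_map <- seq_len(n)       # original node -> current supernode
  level_q <- numeric(0)
  repeat {
    res <- louvain_one_level(n, li, lj, lw, self)
    # project onto original nodes and record Q
    node_map <- res$comm[node_map]
    memb <- stats::setNames(node_map, as.character(nodes))
    q <- modularity_q(graph, memb)
    if (length(level_q) && q <= level_q[length(level_q)] + 1e-12) break
    level_q <- c(level_q, q)
    if (!res$moved) break
    # aggregate
    keep <- sort(unique(res$comm))
    relab <- integer(max(keep)); relab[keep] <- seq_along(keep)
    node_map <- relab[node_map]
    comm <- relab[res$comm]
    n_new <- length(keep)
    agg_self <- numeric(n_new)
    ci <- comm[li]; cj <- comm[lj]
    intra <- ci == cj
    if (any(intra)) {
      t1 <- tapply(lw[intra], ci[intra], sum)
      agg_self[as.integer(names(t1))] <- t1
    }
    t2 <- tapply(self, comm, sum)
    agg_self[as.integer(names(t2))] <- agg_self[as.integer(names(t2))] + t2
    if (any(!intra)) {
      a <- pmin(ci[!intra], cj[!intra]); b <- pmax(ci[!intra], cj[!intra])
      key <- paste(a, b)
      wagg <- tapply(lw[!intra], key, sum)
      ab <- do.call(rbind, strsplit(names(wagg), " "))
      li <- as.integer(ab[, 1]); lj <- as.integer(ab[, 2])
      lw <- as.numeric(wagg)
    } else {
      li <- integer(0); lj <- integer(0); lw <- numeric(0)
    }
    self <- agg_self
    n <- n_new
  }
  # final refinement: single-node moves on the original graph, seeded from
  # the aggregated partition, to escape premature aggregation on tiny graphs
  n0 <- length(nodes)
  ref <- louvain_one_level(n0, ei, ej, ew, numeric(n0), init = node_map)
  q_ref <- modularity_q(graph, stats::setNames(ref$comm, as.character(nodes)))
  q_cur <- if (length(level_q)) level_q[length(level_q)] else
    modularity_q(graph, stats::setNames(node_map, as.character(nodes)))
  if (q_ref > q_cur + 1e-12) {
    node_map <- ref$comm
    level_q <- c(level_q, q_ref)
  }
  groups <- split(nodes, node_map)
  groups <- unname(groups[order(vapply(groups, min, numeric(1)))])
  structure(list(t = graph$t, groups = groups,
                 Q = if (length(level_q)) level_q[length(level_q)] else
                   modularity_q(graph, stats::setNames(node_map,
                                                       as.character(nodes))),
                 level_q = level_q),
            class = "group_partition")
}

# One local-move phase. Edges (li, lj, lw) on nodes 1..n plus self-loop
# weights; starts from `init` (singletons by default); returns final
# community per node and whether any move happened.
louvain_one_level <- function(n, li, lj, lw, self, init = seq_len(n)) {
  m2 <- 2 * sum(lw) + 2 * sum(self)       # 2m
  comm <- init
  # adjacency lists
  deg <- numeric(n)
  adj_n <- vector("list", n); adj_w <- vector("list", n)
  if (length(li)) {
    for (k in seq_along(li)) {
      a <- li[k]; b <- lj[k]; w <- lw[k]
      adj_n[[a]] <- c(adj_n[[a]], b); adj_w[[a]] <- c(adj_w[[a]], w)
      adj_n[[b]] <- c(adj_n[[b]], a); adj_w[[b]] <- c(adj_w[[b]], w)
      deg[a] <- deg[a] + w; deg[b] <- deg[b] + w
    }
  }
  deg <- deg + 2 * self
  tot <- numeric(max(comm))
  for (i in seq_len(n)) tot[comm[i]] <- tot[comm[i]] + deg[i]
  moved_any <- FALSE
  if (m2 == 0) return(list(comm = comm, moved = FALSE))
  order_ <- sample.int(n)
  repeat {
    moved <- FALSE
    for (i in order_) {
      nb <- adj_n[[i]]
      if (is.null(nb)) next
      wv <- adj_w[[i]]
      ci <- comm[i]
      wc <- tapply(wv, comm[nb], sum)     # weight from i to each community
      tot[ci] <- tot[ci] - deg[i]
      w_own <- if (as.character(ci) %in% names(wc)) wc[[as.character(ci)]] else 0
      gain_stay <- w_own - deg[i] * tot[ci] / m2
      cand <- as.integer(names(wc))
      gains <- as.numeric(wc) - deg[i] * tot[cand] / m2
      gains[cand == ci] <- gain_stay   # tot excludes i only for ci
      best <- which.max(gains)
      if (gains[best] > gain_stay + 1e-12 && cand[best] != ci) {
        comm[i] <- cand[best]
        tot[cand[best]] <- tot[cand[best]] + deg[i]
        moved <- TRUE; moved_any <- TRUE
      } else {
        tot[ci] <- tot[ci] + deg[i]
      }
    }
    if (!moved) break
  }
  list(comm = comm, moved = moved_any)
}

#' @export
print.group_partition <- function(x, ...) {
  cat(sprintf("group_partition: t=%s, %d groups, Q=%.4f\n",
              as.character(x$t), length(x$groups), x$Q))
  invisible(x)
}

#' Stability of Louvain over repeated seeded runs
#'
#' Runs [louvain()] `runs` times with distinct seeds and summarizes the spread
#' of the modularity values.
#'
#' @param graph a `snapshot_graph`.
#' @param runs number of runs (default 30, >= 2).
#' @param seeds optional explicit seeds (length `runs`).
#' @return List with `q` (per-run modularity), `sd_q`, `cv_q` (sd/mean;
#'   `NA` when the mean is 0).
#' @export
louvain_stability <- function(graph, runs = 30, seeds = seq_len(runs)) {
  if (runs < 2) stop("need at least 2 runs", call. = FALSE)
  stopifnot(length(seeds) == runs)
  q <- vapply(seeds, function(s) louvain(graph, seed = s)$Q, numeric(1))
  mu <- mean(q)
  list(q = q, sd_q = stats::sd(q),
       cv_q = if (abs(mu) < .Machine$double.eps) NA_real_ else stats::sd(q) / mu)
}
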