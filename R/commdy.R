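#' Temporal grouping: per-step partitions of observed individuals
#'
#' Collects the static communities of each snapshot (the "groups", e.g.
#' Louvain output) into the input structure for dynamic community inference.
#' Individuals unobserved at a step simply do not appear in that step's
#' groups.
#'
#' @param partitions list, one element per time step: either a
#'   `group_partition` (from [louvain()]) or a plain list of disjoint member
#'   id vectors.
#' @param times optional numeric step times (default: the partitions' `t`
#'   fields, else 1, 2, ...).
#' @return A `temporal_grouping`: list with `steps`, `groups` (per step, a
#'   list of integer member vectors), `individuals` (sorted union of ids) and
#'   `gidx` (steps x individuals matrix of group indices, NA = unobserved).
#' @export
temporal_grouping <- function(partitions, times = NULL) {
  glists <- lapply(partitions, function(p) {
    g <- if (inherits(p, "group_partition")) p$groups else p
    lapply(g, function(v) sort(as.integer(v)))
  })
  if (is.null(times)) {
    times <- vapply(seq_along(partitions), function(k) {
      p <- partitions[[k]]
      if (inherits(p, "group_partition") && !is.null(p$t)) as.numeric(p$t)
      else as.numeric(k)
    }, numeric(1))
    if (anyDuplicated(times)) times <- seq_along(partitions)
  }
  for (g in glists) {
    ids <- unlist(g)
    if (anyDuplicated(ids))
      stop("groups within one time step must be disjoint", call. = FALSE)
  }
  individuals <- sort(unique(unlist(glists)))
  nt <- length(glists); ni <- length(individuals)
  gidx <- matrix(NA_integer_, nt, ni,
                 dimnames = list(NULL, as.character(individuals)))
  for (t in seq_len(nt)) {
    for (k in seq_along(glists[[t]]))
      gidx[t, as.character(glists[[t]][[k]])] <- k
  }
  structure(list(steps = times, groups = glists, individuals = individuals,
                 gidx = gidx),
            class = "temporal_grouping")
}

#' @export
print.temporal_grouping <- function(x, ...) {
  cat(sprintf("temporal_grouping: %d steps, %d individuals, %.1f groups/step\n",
              length(x$steps), length(x$individuals),
              mean(vapply(x$groups, length, numeric(1)))))
  invisible(x)
}

#' Social-cost parameters
#'
#' Unit costs for the three charged events: switching home community,
#' visiting a foreign community, and being absent from a gathering of one's
#' own community. All three default to 1 (equal costs).
#'
#' @param switch,visit,absence nonnegative costs.
#' @return A `commdy_costs` list.
#' @export
commdy_costs <- function(switch = 1, visit = 1, absence = 1) {
  if (any(c(switch, visit, absence) < 0))
    stop("costs must be nonnegative", call. = FALSE)
  structure(list(switch = switch, visit = visit, absence = absence),
            class = "commdy_costs")
}

#' Total social cost of a dynamic coloring
#'
#' Recomputes from scratch the cost charged to a coloring of groups and
#' individuals: `switch` per change between an individual's consecutive
#' defined colors, `visit` per (individual, step) observed in a group of a
#' different color, and `absence` per (individual, step) unobserved while at
#' least one group of the individual's color gathers.
#'
#' @param grouping a [temporal_grouping()].
#' @param coloring a `dynamic_coloring` (see [commdy_infer()]), or a list with
#'   `group_color` (per step, integer color per group) and `individual_color`
#'   (steps x individuals matrix, NA where undefined).
#' @param costs a [commdy_costs()].
#' @return Total cost (single number).
#' @export
social_cost <- function(grouping, coloring, costs = commdy_costs()) {
  stopifnot(inherits(grouping, "temporal_grouping"))
  nt <- length(grouping$steps); ni <- length(grouping$individuals)
  gc <- coloring$group_color
  ic <- coloring$individual_color
  for (t in seq_len(nt)) {
    if (length(gc[[t]]) != length(grouping$groups[[t]]) || anyNA(gc[[t]]))
      stop("uncolored group at step ", t, call. = FALSE)
  }
  if (any(is.na(ic[!is.na(grouping$gidx)])))
    stop("observed individual without a color", call. = FALSE)
  total <- 0
  for (i in seq_len(ni)) {
    cols <- ic[, i]
    def <- which(!is.na(cols))
    if (length(def) >= 2)
      total <- total + costs$switch * sum(diff(cols[def]) != 0)
  }
  for (t in seq_len(nt)) {
    obs <- !is.na(grouping$gidx[t, ])
    if (any(obs)) {
      own_group_color <- gc[[t]][grouping$gidx[t, obs]]
      total <- total + costs$visit * sum(own_group_color != ic[t, obs])
    }
    gathered <- unique(gc[[t]])
    un <- !obs & !is.na(ic[t, ])
    if (any(un))
      total <- total + costs$absence * sum(ic[t, un] %in% gathered)
  }
  total
}

# ---- shared per-individual optimal coloring given fixed group colors ----
#
# Given group colors, the optimal colors of each individual are independent
# and found by dynamic programming over the palette (all group colors plus
# one "never-gathering" color). Colors may change only at observed steps
# (carried forward while unobserved); the lexicographically smallest optimal
# sequence is returned.
individual_dp <- function(grouping, gc, costs) {
  nt <- length(grouping$steps); ni <- length(grouping$individuals)
  palette_ <- sort(unique(unlist(gc)))
  phantom <- if (length(palette_)) max(palette_) + 1L else 1L
  palette_ <- c(palette_, phantom)
  np <- length(palette_)
  gathers <- matrix(FALSE, nt, np)
  for (t in seq_len(nt))
    gathers[t, match(unique(gc[[t]]), palette_)] <- TRUE
  ic <- matrix(NA_integer_, nt, ni,
               dimnames = list(NULL, as.character(grouping$individuals)))
  total <- 0
  for (i in seq_len(ni)) {
    gv <- grouping$gidx[, i]
    obs <- which(!is.na(gv))
    if (length(obs) == 0L) next
    tf <- obs[1L]
    own_gc <- rep(NA_integer_, nt)
    own_gc[obs] <- vapply(obs, function(t) gc[[t]][gv[t]], integer(1))
    # backward DP: B[t, c] = min cost of steps t..nt with color c at step t
    B <- matrix(0, nt, np)
    for (t in nt:tf) {
      step_cost <- if (!is.na(gv[t]))
        costs$visit * (palette_ != own_gc[t])
      else costs$absence * gathers[t, ]
      nxt <- if (t == nt) rep(0, np) else {
        if (!is.na(gv[t + 1L])) {
          mn <- min(B[t + 1L, ])
          pmin(B[t + 1L, ], mn + costs$switch)
        } else B[t + 1L, ]
      }
      B[t, ] <- step_cost + nxt
    }
    best <- min(B[tf, ])
    total <- total + best
    cur <- which(B[tf, ] == best)[1L]
    ic[tf, i] <- palette_[cur]
    if (tf < nt) for (t in (tf + 1L):nt) {
      if (!is.na(gv[t])) {
        cand_cost <- costs$switch * (seq_len(np) != cur) + B[t, ]
        cur <- which(cand_cost == min(cand_cost))[1L]
      }
      ic[t, i] <- palette_[cur]
    }
  }
  list(individual_color = ic, cost = total)
}

new_coloring <- function(grouping, gc, costs) {
  dp <- individual_dp(grouping, gc, costs)
  structure(list(steps = grouping$steps, individuals = grouping$individuals,
                 group_color = gc, individual_color = dp$individual_color,
                 total_cost = dp$cost, costs = costs),
            class = "dynamic_coloring")
}

#' @export
print.dynamic_coloring <- function(x, ...) {
  ncol_ <- length(unique(stats::na.omit(as.vector(x$individual_color))))
  cat(sprintf(
    "dynamic_coloring: %d steps, %d individuals, %d communities, cost %g\n",
    length(x$steps), length(x$individuals), ncol_, x$total_cost))
  invisible(x)
}

#' Exact dynamic community inference by exhaustive search
#'
#' Provably minimal social cost over all colorings with at most `max_colors`
#' colors, for small instances only. Group colorings are enumerated in
#' canonical (restricted-growth) order, so the reported coloring is the
#' lexicographically smallest optimum up to color renaming; individual colors
#' are then optimal by dynamic programming.
#'
#' @param grouping a [temporal_grouping()].
#' @param costs a [commdy_costs()].
#' @param max_colors color budget (default: number of groups at the widest
#'   step, plus one).
#' @param cap list of instance-size caps; larger instances are refused and
#'   should use [commdy_infer()].
#' @return A `dynamic_coloring` with minimal `total_cost`.
#' @export
commdy_exact <- function(grouping, costs = commdy_costs(), max_colors = NULL,
                         cap = list(individuals = 8L, steps = 5L,
                                    groups = 10L)) {
  stopifnot(inherits(grouping, "temporal_grouping"))
  nt <- length(grouping$steps)
  ngr <- vapply(grouping$groups, length, integer(1))
  if (length(grouping$individuals) > cap$individuals || nt > cap$steps ||
      sum(ngr) > cap$groups)
    stop("instance too large for exact search; use commdy_infer()",
         call. = FALSE)
  if (nt == 0L)
    return(new_coloring(grouping, list(), costs))
  if (is.null(max_colors)) max_colors <- max(ngr, 0L) + 1L
  steps_of <- rep(seq_len(nt), ngr)
  total_groups <- sum(ngr)
  best_cost <- Inf; best_gc <- NULL
  assign_ <- integer(total_groups)
  recurse <- function(k, used_max) {
    if (k > total_groups) {
      gc <- split(assign_, steps_of)
      gc <- lapply(seq_len(nt), function(t)
        if (ngr[t] > 0) unname(gc[[as.character(t)]]) else integer(0))
      cost <- individual_dp(grouping, gc, costs)$cost
      if (cost < best_cost) { best_cost <<- cost; best_gc <<- gc }
      return(invisible(NULL))
    }
    t <- steps_of[k]
    taken <- assign_[which(steps_of == t & seq_len(total_groups) < k)]
    for (col in seq_len(min(used_max + 1L, max_colors))) {
      if (col %in% taken) next
      assign_[k] <<- col
      recurse(k + 1L, max(used_max, col))
    }
  }
  recurse(1L, 0L)
  if (is.null(best_gc)) stop("color budget too small for one step",
                             call. = FALSE)
  out <- new_coloring(grouping, best_gc, costs)
  stopifnot(abs(out$total_cost - best_cost) < 1e-9)
  out
}

#' Dynamic community inference (deterministic heuristic)
#'
#' Links each step's groups to ongoing communities and assigns every
#' individual a community color so that the total social cost (switching +
#' visiting + absence) is low. The heuristic is a greedy forward pass that
#' matches groups to existing community colors by maximum-weight bipartite
#' matching on shared-member counts (a group opens a new community when its
#' best match shares fewer than `new_frac` of its members), followed by an
#' exact per-individual forward-backward color assignment given the group
#' colors. It is deterministic, never violates the one-color-per-group-
#' per-step constraint, and finds every zero-cost solution, but carries no
#' optimality guarantee on general instances.
#'
#' @param grouping a [temporal_grouping()].
#' @param costs a [commdy_costs()].
#' @param new_frac vector of matching thresholds tried as independent starts:
#'   in each forward pass, a group whose best overlap with existing
#'   communities is below this fraction of its size starts a new community.
#'   The default tries a balanced threshold (0.5), aggressive linking (0,
#'   any overlap qualifies) and no linking at all (2, every group starts
#'   fresh and the repair passes do the joining); the cheapest result wins.
#' @return A `dynamic_coloring`.
#' @export
commdy_infer <- function(grouping, costs = commdy_costs(),
                         new_frac = c(0.5, 0, 2)) {
  best <- NULL
  for (nf in new_frac) {
    cand <- commdy_infer_once(grouping, costs, nf)
    if (is.null(best) || cand$total_cost < best$total_cost - 1e-9)
      best <- cand
  }
  best
}

commdy_infer_once <- function(grouping, costs, new_frac) {
  stopifnot(inherits(grouping, "temporal_grouping"))
  nt <- length(grouping$steps); ni <- length(grouping$individuals)
  if (nt == 0L) return(new_coloring(grouping, list(), costs))
  cur <- rep(NA_integer_, ni)          # most recent community per individual
  next_color <- 1L
  gc <- vector("list", nt)
  for (t in seq_len(nt)) {
    grps <- grouping$groups[[t]]
    ng <- length(grps)
    gc[[t]] <- integer(ng)
    if (ng == 0L) next
    midx <- lapply(grps, function(v) match(v, grouping$individuals))
    ov <- lapply(midx, function(ix) {
      tab <- table(cur[ix], useNA = "no")
      if (length(tab)) stats::setNames(as.integer(tab),
                                       names(tab)) else integer(0)
    })
    assign_t <- match_groups(ov, vapply(midx, length, integer(1)), new_frac)
    for (k in seq_len(ng)) {
      col <- assign_t[k]
      if (is.na(col)) { col <- next_color; next_color <- next_color + 1L }
      gc[[t]][k] <- col
      cur[midx[[k]]] <- col
    }
    next_color <- max(next_color, max(gc[[t]]) + 1L)
  }
  out <- new_coloring(grouping, gc, costs)
  # repair passes: alternate optimal individual colors (DP) with per-step
  # group recoloring given those colors, until the cost stops improving
  for (pass in 1:10) {
    gc2 <- recolor_groups(grouping, out$individual_color, out$costs)
    cand <- new_coloring(grouping, gc2, costs)
    if (cand$total_cost < out$total_cost - 1e-9) out <- cand else break
  }
  out
}

# Reassign group colors at each step to minimize visit + absence cost given
# fixed individual colors (injective within the step; exact assignment for
# few groups, greedy otherwise).
recolor_groups <- function(grouping, ic, costs) {
  nt <- length(grouping$steps)
  fresh <- max(c(unlist(lapply(seq_len(nt), function(t) ic[t, ])), 0L),
               na.rm = TRUE) + 1L
  lapply(seq_len(nt), function(t) {
    grps <- grouping$groups[[t]]
    ng <- length(grps)
    if (ng == 0L) return(integer(0))
    obs <- !is.na(grouping$gidx[t, ])
    cand_cols <- sort(unique(stats::na.omit(ic[t, ])))
    # absence charge if a color gathers: unobserved holders of that color
    unobs_of <- vapply(cand_cols, function(c_)
      sum(!obs & !is.na(ic[t, ]) & ic[t, ] == c_), numeric(1))
    names(unobs_of) <- as.character(cand_cols)
    midx <- lapply(grps, function(v) match(v, grouping$individuals))
    cost_gc <- function(k, c_) {
      inside <- ic[t, midx[[k]]]
      costs$visit * sum(inside != c_) +
        costs$absence * unobs_of[[as.character(c_)]]
    }
    fresh_cost <- function(k) costs$visit * length(midx[[k]])
    if (ng <= 7L && length(cand_cols) <= 12L) {
      best_cost <- Inf; best <- NULL
      assign_ <- integer(ng)
      rec <- function(k, acc) {
        if (acc >= best_cost) return(invisible(NULL))
        if (k > ng) { best_cost <<- acc; best <<- assign_
                      return(invisible(NULL)) }
        taken <- assign_[seq_len(k - 1L)]
        for (c_ in cand_cols) {
          if (c_ %in% taken) next
          assign_[k] <<- c_
          rec(k + 1L, acc + cost_gc(k, c_))
        }
        assign_[k] <<- 0L              # 0 marks a fresh color
        rec(k + 1L, acc + fresh_cost(k))
      }
      rec(1L, 0)
      out <- best
    } else {
      out <- integer(ng); taken <- integer(0)
      for (k in order(-vapply(midx, length, integer(1)))) {
        avail <- setdiff(cand_cols, taken)
        cc <- vapply(avail, function(c_) cost_gc(k, c_), numeric(1))
        if (length(avail) && min(cc) <= fresh_cost(k)) {
          out[k] <- avail[which.min(cc)]
          taken <- c(taken, out[k])
        } else out[k] <- 0L
      }
    }
    for (k in seq_len(ng)) if (out[k] == 0L) {
      out[k] <- fresh
      fresh <<- fresh + 1L
    }
    out
  })
}

# Max-weight matching of this step's groups to existing community colors.
# ov: per group, named integer vector of overlaps with colors. Exact search
# when few groups, greedy otherwise; returns color per group (NA = new).
match_groups <- function(ov, sizes, new_frac) {
  ng <- length(ov)
  qualified <- lapply(seq_len(ng), function(k) {
    o <- ov[[k]]
    o[o >= new_frac * sizes[k] & o > 0]
  })
  if (all(vapply(qualified, length, integer(1)) == 0L))
    return(rep(NA_integer_, ng))
  if (ng <= 7L) {
    best_score <- -1; best <- rep(NA_integer_, ng)
    assign_ <- rep(NA_integer_, ng)
    recurse <- function(k, score, used) {
      remaining <- if (k > ng) 0 else
        sum(vapply(k:ng, function(j)
          if (length(qualified[[j]])) max(qualified[[j]]) else 0L, numeric(1)))
      if (score + remaining <= best_score) return(invisible(NULL))
      if (k > ng) {
        best_score <<- score; best <<- assign_
        return(invisible(NULL))
      }
      o <- qualified[[k]]
      ord <- order(-o, as.integer(names(o)))
      for (ix in ord) {
        col <- as.integer(names(o)[ix])
        if (col %in% used) next
        assign_[k] <<- col
        recurse(k + 1L, score + o[ix], c(used, col))
        assign_[k] <<- NA_integer_
      }
      recurse(k + 1L, score, used)   # group k opens a new community
    }
    recurse(1L, 0, integer(0))
    return(best)
  }
  # greedy: largest overlaps first
  cand <- do.call(rbind, lapply(seq_len(ng), function(k) {
    o <- qualified[[k]]
    if (!length(o)) return(NULL)
    data.frame(g = k, col = as.integer(names(o)), o = as.integer(o))
  }))
  out <- rep(NA_integer_, ng)
  if (is.null(cand)) return(out)
  cand <- cand[order(-cand$o, cand$g, cand$col), , drop = FALSE]
  used <- integer(0)
  for (r in seq_len(nrow(cand))) {
    g <- cand$g[r]; col <- cand$col[r]
    if (!is.na(out[g]) || col %in% used) next
    out[g] <- col; used <- c(used, col)
  }
  out
}

#' Rank communities by total occupancy
#'
#' Communities are ranked by the number of (individual, step) pairs carrying
#' their color, descending; ties broken by earliest first appearance. Used to
#' pick the top-k communities for the fixed rendering palette.
#'
#' @param coloring a `dynamic_coloring`.
#' @param k number of labels to return (default 20).
#' @return Integer vector of community labels, best first, at most `k` long.
#' @export
top_communities <- function(coloring, k = 20) {
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  ic <- coloring$individual_color
  nt <- nrow(ic)
  occ <- list(); first <- list()
  for (t in seq_len(nt)) {
    # occupancy counted while observed: steps where the individual's group
    # gathers with its color or it is observed at all
    obs_cols <- ic[t, !is.na(ic[t, ])]
    for (c_ in unique(c(obs_cols, unlist(coloring$group_color[t])))) {
      key <- as.character(c_)
      if (is.null(first[[key]])) first[[key]] <- t
    }
    if (length(obs_cols)) {
      tab <- table(obs_cols)
      for (nm in names(tab))
        occ[[nm]] <- (if (is.null(occ[[nm]])) 0L else occ[[nm]]) + tab[[nm]]
    }
  }
  if (!length(occ)) return(integer(0))
  labs <- as.integer(names(occ))
  counts <- as.integer(unlist(occ))
  firsts <- vapply(names(occ), function(nm)
    if (is.null(first[[nm]])) Inf else first[[nm]], numeric(1))
  ord <- order(-counts, firsts, labs)
  utils::head(labs[ord], k)
}

#' Check structural validity of a dynamic coloring
#'
#' Asserts that every group is colored, no two groups at one step share a
#' color, every observed individual has a color, and the recorded total cost
#' matches [social_cost()] recomputed from scratch.
#'
#' @param grouping a [temporal_grouping()].
#' @param coloring a `dynamic_coloring`.
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_coloring <- function(grouping, coloring) {
  for (t in seq_along(grouping$steps)) {
    cols <- coloring$group_color[[t]]
    if (length(cols) != length(grouping$groups[[t]]) || anyNA(cols))
      stop("uncolored group at step ", t, call. = FALSE)
    if (anyDuplicated(cols))
      stop("two groups share a color at step ", t, call. = FALSE)
  }
  sc <- social_cost(grouping, coloring, coloring$costs)
  if (abs(sc - coloring$total_cost) > 1e-9)
    stop("total_cost does not match recomputed social cost", call. = FALSE)
  invisible(TRUE)
}

#' Write a dynamic coloring as delimited tables
#'
#' @param coloring a `dynamic_coloring`.
#' @param path base path: writes `<path>_individuals.tsv`
#'   (t, pixel_id, community_label) over defined entries and
#'   `<path>_groups.tsv` (t, group_id, community_label).
#' @return Invisibly, the two paths.
#' @export
write_coloring <- function(coloring, path) {
  ic <- coloring$individual_color
  nt <- nrow(ic)
  rows <- do.call(rbind, lapply(seq_len(nt), function(t) {
    def <- which(!is.na(ic[t, ]))
    if (!length(def)) return(NULL)
    data.frame(t = coloring$steps[t],
               pixel_id = coloring$individuals[def],
               community_label = ic[t, def])
  }))
  grows <- do.call(rbind, lapply(seq_len(nt), function(t) {
    cols <- coloring$group_color[[t]]
    if (!length(cols)) return(NULL)
    data.frame(t = coloring$steps[t], group_id = seq_along(cols) - 1L,
               community_label = cols)
  }))
  p1 <- paste0(path, "_individuals.tsv"); p2 <- paste0(path, "_groups.tsv")
  utils::write.table(if (is.null(rows)) data.frame() else rows, p1,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(if (is.null(grows)) data.frame() else grows, p2,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}
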