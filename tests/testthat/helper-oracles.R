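# Independent oracles and fixture builders shared across the test files.
# Everything here is deliberately written straight from the definitions,
# with plain loops, and independently of the package's implementation paths.

snapshot_from_edges <- function(i, j, w = 1, t = 1L) {
  ed <- data.frame(i = as.integer(i), j = as.integer(j),
                   w = rep_len(w, length(i)))
  swap <- ed$i > ed$j
  tmp <- ed$i[swap]; ed$i[swap] <- ed$j[swap]; ed$j[swap] <- tmp
  ed <- ed[order(ed$i, ed$j), , drop = FALSE]
  rownames(ed) <- NULL
  structure(list(t = t, nodes = sort(unique(c(ed$i, ed$j))), edges = ed,
                 window = 50L, threshold = 0.7,
                 n_pixels = max(ed$j) + 1L),
            class = "snapshot_graph")
}

# all set partitions of 1..n as membership vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1L]] <<- prefix; return(invisible(NULL)) }
    for (c_ in seq_len(mx + 1L)) rec(c(prefix, c_), max(mx, c_))
  }
  rec(integer(0), 0L)
  out
}

# plain-loop weighted modularity, written from the formula
oracle_modularity <- function(graph, memb_vec) {
  # memb_vec indexed by position in graph$nodes
  ed <- graph$edges
  m <- sum(ed$w)
  if (m == 0) return(0)
  lab <- stats::setNames(memb_vec, as.character(graph$nodes))
  comms <- unique(memb_vec)
  q <- 0
  for (c_ in comms) {
    w_in <- 0; d_c <- 0
    for (r in seq_len(nrow(ed))) {
      ci <- lab[[as.character(ed$i[r])]]
      cj <- lab[[as.character(ed$j[r])]]
      if (ci == c_ && cj == c_) w_in <- w_in + ed$w[r]
      if (ci == c_) d_c <- d_c + ed$w[r]
      if (cj == c_) d_c <- d_c + ed$w[r]
    }
    q <- q + w_in / m - (d_c / (2 * m))^2
  }
  q
}

brute_force_best_q <- function(graph) {
  n <- length(graph$nodes)
  stopifnot(n <= 8)
  best <- -Inf
  for (p in all_partitions(n)) {
    q <- oracle_modularity(graph, p)
    if (q > best) best <- q
  }
  best
}

# fixture graphs of <= 8 nodes with clear community structure
fixture_graphs <- function() {
  list(
    two_triangles = snapshot_from_edges(c(0, 0, 1, 3, 3, 4),
                                        c(1, 2, 2, 4, 5, 5)),
    complete_k5 = {
      pr <- utils::combn(0:4, 2)
      snapshot_from_edges(pr[1, ], pr[2, ])
    },
    path4 = snapshot_from_edges(0:2, 1:3),
    star5 = snapshot_from_edges(rep(0, 4), 1:4),
    barbell = snapshot_from_edges(c(0, 0, 1, 2, 3, 3, 4),
                                  c(1, 2, 2, 3, 4, 5, 5)),
    two_squares = snapshot_from_edges(c(0, 1, 2, 0, 4, 5, 6, 4),
                                      c(1, 2, 3, 3, 5, 6, 7, 7)),
    weighted_pair = snapshot_from_edges(c(0, 1, 2, 0), c(1, 2, 3, 3),
                                        w = c(1, 0.2, 1, 0.2)),
    triangle_plus_edge = snapshot_from_edges(c(0, 0, 1, 3), c(1, 2, 2, 4))
  )
}

# ---- CommDy oracles ----------------------------------------------------

# literal transcription of the three cost terms
oracle_social_cost <- function(grouping, gc, ic, costs) {
  nt <- length(grouping$steps)
  inds <- grouping$individuals
  total <- 0
  for (ii in seq_along(inds)) {
    seen <- ic[!is.na(ic[, ii]), ii]
    if (length(seen) > 1)
      for (k in 2:length(seen))
        if (seen[k] != seen[k - 1]) total <- total + costs$switch
  }
  for (t in seq_len(nt)) {
    gathered <- unique(gc[[t]])
    for (ii in seq_along(inds)) {
      g <- grouping$gidx[t, ii]
      if (!is.na(g)) {
        if (gc[[t]][g] != ic[t, ii]) total <- total + costs$visit
      } else if (!is.na(ic[t, ii]) && ic[t, ii] %in% gathered) {
        total <- total + costs$absence
      }
    }
  }
  total
}

# exhaustive minimum over all colorings (tiny instances only): canonical
# group colorings x all carry-forward individual color sequences
oracle_min_cost <- function(grouping, costs, max_colors = NULL) {
  nt <- length(grouping$steps)
  ngr <- vapply(grouping$groups, length, integer(1))
  if (is.null(max_colors)) max_colors <- max(ngr, 0L) + 1L
  steps_of <- rep(seq_len(nt), ngr)
  total_groups <- sum(ngr)
  best <- Inf
  assign_ <- integer(total_groups)
  try_gc <- function() {
    gc <- lapply(seq_len(nt), function(t) assign_[steps_of == t])
    palette_ <- c(sort(unique(unlist(gc))), max(unlist(gc), 0L) + 1L)
    cost <- 0
    for (ii in seq_along(grouping$individuals)) {
      gv <- grouping$gidx[, ii]
      obs <- which(!is.na(gv))
      if (!length(obs)) next
      tf <- obs[1]
      # enumerate carry-forward sequences: a color choice per observed step
      nobs <- length(obs)
      combos <- as.matrix(expand.grid(rep(list(palette_), nobs)))
      best_i <- Inf
      for (r in seq_len(nrow(combos))) {
        icv <- rep(NA_integer_, nt)
        cur <- NA_integer_
        oi <- 0L
        for (t in tf:nt) {
          if (!is.na(gv[t])) { oi <- oi + 1L; cur <- combos[r, oi] }
          icv[t] <- cur
        }
        icm <- matrix(icv, nt, 1)
        sub <- grouping
        sub$gidx <- grouping$gidx[, ii, drop = FALSE]
        sub$individuals <- grouping$individuals[ii]
        c_i <- oracle_social_cost(sub, gc, icm, costs)
        if (c_i < best_i) best_i <- c_i
      }
      cost <- cost + best_i
    }
    if (cost < best) best <<- cost
  }
  rec <- function(k, used_max) {
    if (k > total_groups) { try_gc(); return(invisible(NULL)) }
    t <- steps_of[k]
    taken <- assign_[which(steps_of == t & seq_len(total_groups) < k)]
    for (col in seq_len(min(used_max + 1L, max_colors))) {
      if (col %in% taken) next
      assign_[k] <<- col
      rec(k + 1L, max(used_max, col))
    }
  }
  if (total_groups == 0L) return(0)
  rec(1L, 0L)
  best
}

# zero total cost iff co-grouping induces a time-consistent partition:
# within each connected component of the "ever co-grouped" relation, at every
# step either all members sit together in exactly one group or none appears.
oracle_zero_cost_possible <- function(grouping) {
  inds <- grouping$individuals
  ni <- length(inds)
  roots <- seq_len(ni)
  repeat {
    changed <- FALSE
    for (t in seq_along(grouping$steps))
      for (g in grouping$groups[[t]]) {
        ix <- match(g, inds)
        m <- min(roots[ix])
        for (cl in setdiff(unique(roots[ix]), m)) {
          roots[roots == cl] <- m
          changed <- TRUE
        }
      }
    if (!changed) break
  }
  for (comp in unique(roots)) {
    members <- which(roots == comp)
    for (t in seq_along(grouping$steps)) {
      present <- members[!is.na(grouping$gidx[t, members])]
      if (!length(present)) next
      if (length(present) < length(members)) return(FALSE)
      gset <- unique(grouping$gidx[t, present])
      if (length(gset) != 1L) return(FALSE)
      if (length(grouping$groups[[t]][[gset]]) != length(members))
        return(FALSE)
    }
  }
  TRUE
}

random_grouping <- function(seed, n_ind = 6, n_steps = 4, max_groups = 2,
                            p_obs = 0.8) {
  set.seed(seed)
  parts <- lapply(seq_len(n_steps), function(t) {
    obs <- which(stats::runif(n_ind) < p_obs)
    if (length(obs) == 0L) obs <- sample.int(n_ind, 1L)
    ng <- sample.int(max_groups, 1L)
    memb <- sample.int(ng, length(obs), replace = TRUE)
    gs <- split(obs, memb)
    unname(gs[vapply(gs, length, integer(1)) > 0])
  })
  temporal_grouping(parts)
}

# ---- literal Table-style metrics oracle --------------------------------

oracle_node_metrics <- function(coloring, grouping) {
  nt <- length(grouping$steps)
  inds <- grouping$individuals
  gc <- coloring$group_color
  ic <- coloring$individual_color
  status <- function(t, ii) {
    g <- grouping$gidx[t, ii]
    if (!is.na(g)) {
      if (gc[[t]][g] == ic[t, ii]) "member" else "visitor"
    } else if (!is.na(ic[t, ii]) && ic[t, ii] %in% unique(gc[[t]])) {
      "absent"
    } else "none"
  }
  st <- matrix("none", nt, length(inds))
  for (t in seq_len(nt)) for (ii in seq_along(inds))
    st[t, ii] <- status(t, ii)
  affil <- st == "member" | st == "absent"
  colors_all <- sort(unique(c(unlist(gc), stats::na.omit(as.vector(ic)))))
  exist_steps <- function(c_) which(vapply(seq_len(nt), function(t)
    (c_ %in% gc[[t]]) || any(!is.na(ic[t, ]) & ic[t, ] == c_), logical(1)))
  gather_steps <- function(c_) which(vapply(seq_len(nt), function(t)
    c_ %in% gc[[t]], logical(1)))
  csize <- function(c_, t) sum(affil[t, ] & !is.na(ic[t, ]) & ic[t, ] == c_)
  rows <- list()
  for (ii in seq_along(inds)) {
    obs <- which(!is.na(grouping$gidx[, ii]))
    if (!length(obs)) next
    OBS <- length(obs)
    cols <- ic[obs, ii]
    sw <- 0
    if (OBS > 1) for (k in 2:OBS) if (cols[k] != cols[k - 1]) sw <- sw + 1
    vis <- sum(st[, ii] == "visitor")
    ab <- sum(st[, ii] == "absent")
    # stays: consecutive observed steps with same home color
    runs <- c(); cur <- 1
    if (OBS > 1) {
      for (k in 2:OBS) {
        if (cols[k] == cols[k - 1]) cur <- cur + 1
        else { runs <- c(runs, cur); cur <- 1 }
      }
    }
    runs <- c(runs, cur)
    # homing
    homs <- c()
    for (t in obs) {
      if (t == 1 || is.na(ic[t - 1, ii])) next
      now <- setdiff(which(affil[t, ] & !is.na(ic[t, ]) &
                             ic[t, ] == ic[t, ii]), ii)
      if (!length(now)) next
      prev <- setdiff(which(affil[t - 1, ] & !is.na(ic[t - 1, ]) &
                              ic[t - 1, ] == ic[t - 1, ii]), ii)
      homs <- c(homs, length(intersect(now, prev)) / length(now))
    }
    # group sizes over member steps
    gsz <- c()
    for (t in which(st[, ii] == "member")) {
      g <- grouping$gidx[t, ii]
      in_g <- which(!is.na(grouping$gidx[t, ]) & grouping$gidx[t, ] == g)
      n_mem <- sum(st[t, in_g] == "member")
      n_abs <- sum(st[t, ] == "absent" & !is.na(ic[t, ]) &
                     ic[t, ] == ic[t, ii])
      gsz <- c(gsz, n_mem + n_abs)
    }
    aff_cols <- unique(ic[affil[, ii], ii])
    spans <- vapply(aff_cols, function(c_) {
      es <- exist_steps(c_); max(es) - min(es)
    }, numeric(1))
    csizes <- vapply(aff_cols, function(c_) {
      gs <- gather_steps(c_)
      if (!length(gs)) return(NA_real_)
      mean(vapply(gs, function(t) csize(c_, t), numeric(1)))
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      pixel_id = inds[ii], OBS = OBS, SW = sw / OBS, VIS = vis / OBS,
      ABS = ab / OBS, AS = mean(runs), MS = max(runs),
      HOM = if (length(homs)) mean(homs) else NA_real_,
      GS = if (length(gsz)) mean(gsz) else NA_real_,
      TS = if (length(spans)) mean(spans) else NA_real_,
      CS = if (all(is.na(csizes))) NA_real_ else mean(csizes, na.rm = TRUE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# random but structurally valid coloring for a grouping
random_coloring <- function(grouping, seed, n_colors = 4) {
  set.seed(seed)
  nt <- length(grouping$steps)
  gc <- lapply(seq_len(nt), function(t) {
    ng <- length(grouping$groups[[t]])
    if (ng == 0L) return(integer(0))
    sample.int(n_colors, ng)
  })
  ni <- length(grouping$individuals)
  ic <- matrix(NA_integer_, nt, ni,
               dimnames = list(NULL, as.character(grouping$individuals)))
  for (ii in seq_len(ni)) {
    cur <- NA_integer_
    for (t in seq_len(nt)) {
      if (!is.na(grouping$gidx[t, ii])) cur <- sample.int(n_colors + 1L, 1L)
      ic[t, ii] <- cur
    }
  }
  structure(list(steps = grouping$steps, individuals = grouping$individuals,
                 group_color = gc, individual_color = ic,
                 total_cost = NA_real_, costs = commdy_costs()),
            class = "dynamic_coloring")
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

partition_membership_vec <- function(part) {
  ids <- unlist(part$groups)
  mem <- rep(seq_along(part$groups), vapply(part$groups, length, integer(1)))
  stats::setNames(mem, as.character(ids))
}
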