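#' Per-individual dynamic community metrics
#'
#' Computes the ten interpretable node metrics from a dynamic coloring. For
#' each individual (pixel) and step, its status follows from the coloring:
#' a *member* is observed in a group of its own color, a *visitor* is observed
#' in a group of another color, and an individual is *absent* when it is
#' unobserved while at least one group of its color gathers.
#'
#' Metrics per individual:
#' \describe{
#'   \item{OBS}{number of steps observed.}
#'   \item{SW}{community switches divided by OBS.}
#'   \item{VIS}{visits divided by OBS.}
#'   \item{ABS}{absences divided by OBS.}
#'   \item{AS, MS}{average and maximum number of consecutive observed steps
#'     spent in the same home community (raw run lengths).}
#'   \item{HOM}{mean fraction of the individual's current community comembers
#'     (members and absents of its color) retained from the previous step,
#'     over observed steps that have a defined previous affiliation and at
#'     least one current comember.}
#'   \item{GS}{mean size of the groups the individual was a member of; group
#'     size counts the group's members plus the community's absents at that
#'     step, but not visitors.}
#'   \item{TS}{mean time span (last minus first step of existence, where
#'     existence means any group or carried individual color occurrence) of
#'     the communities the individual was affiliated with as member or
#'     absent.}
#'   \item{CS}{mean size (members + absents, not visitors, averaged over the
#'     community's gathering steps) of those same communities.}
#' }
#'
#' @param coloring a `dynamic_coloring` (see [commdy_infer()]).
#' @param grouping the [temporal_grouping()] the coloring was inferred from.
#' @return A data.frame with one row per individual ever observed: `pixel_id`
#'   and columns OBS, SW, VIS, ABS, AS, MS, HOM, GS, TS, CS.
#' @export
node_metrics <- function(coloring, grouping) {
  stopifnot(inherits(grouping, "temporal_grouping"))
  nt <- length(grouping$steps); ni <- length(grouping$individuals)
  ic <- coloring$individual_color
  gc <- coloring$group_color
  gidx <- grouping$gidx
  observed <- !is.na(gidx)

  # per (t, i): color of the group the individual sits in (NA if unobserved)
  own_gc <- matrix(NA_integer_, nt, ni)
  for (t in seq_len(nt)) {
    obs <- which(observed[t, ])
    if (length(obs)) own_gc[t, obs] <- gc[[t]][gidx[t, obs]]
  }
  gathers_at <- lapply(seq_len(nt), function(t) unique(gc[[t]]))
  member <- observed & own_gc == ic
  member[is.na(member)] <- FALSE
  visitor <- observed & own_gc != ic
  visitor[is.na(visitor)] <- FALSE
  absent <- matrix(FALSE, nt, ni)
  for (t in seq_len(nt)) {
    un <- !observed[t, ] & !is.na(ic[t, ])
    absent[t, un] <- ic[t, un] %in% gathers_at[[t]]
  }
  affiliated <- member | absent      # counted in community size

  # community sizes and spans
  all_colors <- sort(unique(c(unlist(gc), stats::na.omit(as.vector(ic)))))
  span_of <- comm_size <- stats::setNames(numeric(length(all_colors)),
                                          as.character(all_colors))
  for (c_ in all_colors) {
    key <- as.character(c_)
    occ_t <- which(vapply(seq_len(nt), function(t)
      c_ %in% gc[[t]] || any(!is.na(ic[t, ]) & ic[t, ] == c_), logical(1)))
    span_of[key] <- if (length(occ_t)) max(occ_t) - min(occ_t) else 0
    gath_t <- which(vapply(seq_len(nt), function(t)
      c_ %in% gathers_at[[t]], logical(1)))
    comm_size[key] <- if (length(gath_t))
      mean(vapply(gath_t, function(t)
        sum(affiliated[t, ] & ic[t, ] == c_, na.rm = TRUE), numeric(1)))
    else NA_real_
  }

  # affiliation sets per (t, color) for HOM and GS
  out <- lapply(seq_len(ni), function(i) {
    obs_t <- which(observed[, i])
    if (!length(obs_t)) return(NULL)
    OBS <- length(obs_t)
    cols <- ic[obs_t, i]
    SW <- sum(diff(cols) != 0) / OBS
    VIS <- sum(visitor[, i]) / OBS
    ABSn <- sum(absent[, i]) / OBS
    runs <- rle(cols)$lengths
    AS <- mean(runs); MS <- max(runs)
    # homing
    hom_vals <- numeric(0)
    for (t in obs_t) {
      if (t == 1L || is.na(ic[t - 1L, i])) next
      c_now <- ic[t, i]
      com_now <- which(affiliated[t, ] & ic[t, ] == c_now)
      com_now <- setdiff(com_now, i)
      if (!length(com_now)) next
      c_prev <- ic[t - 1L, i]
      com_prev <- which(affiliated[t - 1L, ] & ic[t - 1L, ] == c_prev)
      com_prev <- setdiff(com_prev, i)
      hom_vals <- c(hom_vals, length(intersect(com_now, com_prev)) /
                      length(com_now))
    }
    HOM <- if (length(hom_vals)) mean(hom_vals) else NA_real_
    # group size over member steps
    mem_t <- which(member[, i])
    GS <- if (length(mem_t)) mean(vapply(mem_t, function(t) {
      g <- gidx[t, i]
      in_group <- which(observed[t, ] & gidx[t, ] == g)
      n_members <- sum(member[t, in_group])
      n_abs <- sum(absent[t, ] & ic[t, ] == ic[t, i], na.rm = TRUE)
      n_members + n_abs
    }, numeric(1))) else NA_real_
    # communities affiliated with as member or absent
    aff_cols <- unique(ic[affiliated[, i], i])
    TS <- if (length(aff_cols)) mean(span_of[as.character(aff_cols)])
          else NA_real_
    CS <- if (length(aff_cols)) mean(comm_size[as.character(aff_cols)],
                                     na.rm = TRUE) else NA_real_
    data.frame(pixel_id = grouping$individuals[i], OBS = OBS, SW = SW,
               VIS = VIS, ABS = ABSn, AS = AS, MS = MS, HOM = HOM, GS = GS,
               TS = TS, CS = CS)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-activation summary of node metrics
#'
#' Averages each metric over individuals (pixels), and additionally reports
#' GS, CS, AS and MS normalized by the total number of activated pixels, the
#' convention used when comparing activations of different spatial extent.
#'
#' @param metrics data.frame from [node_metrics()].
#' @param n_active total number of pixels observed in at least one snapshot
#'   of the activation (default: the number of rows, i.e. all individuals
#'   ever observed).
#' @param reference optional named numeric vector of reference means (e.g. the
#'   mean summary of a control group); when given, `rel_<metric>` columns
#'   holding mean/reference are added for plotting parity across groups.
#' @return A one-row data.frame: means of the ten metrics, `n_active`, and
#'   `norm_GS`, `norm_CS`, `norm_AS`, `norm_MS`.
#' @export
summarize_activation <- function(metrics, n_active = nrow(metrics),
                                 reference = NULL) {
  if (is.null(metrics) || nrow(metrics) == 0L)
    stop("empty metrics table", call. = FALSE)
  if (n_active < 1) stop("n_active must be >= 1", call. = FALSE)
  cols <- c("OBS", "SW", "VIS", "ABS", "AS", "MS", "HOM", "GS", "TS", "CS")
  mu <- vapply(cols, function(cn) mean(metrics[[cn]], na.rm = TRUE),
               numeric(1))
  out <- as.data.frame(as.list(mu))
  out$n_active <- n_active
  for (cn in c("GS", "CS", "AS", "MS"))
    out[[paste0("norm_", cn)]] <- mu[[cn]] / n_active
  if (!is.null(reference)) {
    for (cn in intersect(names(reference), names(out)))
      out[[paste0("rel_", cn)]] <- out[[cn]] / reference[[cn]]
  }
  out
}
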