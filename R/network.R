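#' Convert a frame count to milliseconds
#'
#' @param n number of frames (>= 0).
#' @param fps frames per second (> 0).
#' @return Integer milliseconds, rounded to nearest.
#' @examples
#' frames_to_ms(25, 71)   # 352
#' frames_to_ms(200, 71)  # 2817
#' @export
frames_to_ms <- function(n, fps) {
  if (fps <= 0) stop("`fps` must be positive", call. = FALSE)
  if (any(n < 0)) stop("`n` must be nonnegative", call. = FALSE)
  as.integer(round(1000 * n / fps))
}

# pixel series matrix: frames x pixels, columns in row-major 0-based id order
pixel_matrix <- function(stack) {
  nf <- n_frames(stack); h <- frame_h(stack); w <- frame_w(stack)
  m <- matrix(0, nf, h * w)
  for (f in seq_len(nf)) m[f, ] <- as.numeric(t(stack$data[f, , ]))
  m
}

#' Thresholded correlation graph over one sliding window
#'
#' Edges connect pixel pairs whose Pearson correlation over the window
#' `[t0, t0 + W)` is at least `theta`; the correlation is kept as the edge
#' weight. Thresholding is one-sided: anticorrelated pairs carry no edge.
#' Pixels with zero variance in the window carry no edges. A pixel is
#' "observed" (a node) in the snapshot iff it has at least one
#' supra-threshold edge.
#'
#' @param stack an [image_stack] (or a frames x pixels numeric matrix).
#' @param t0 window start frame, 1-based.
#' @param W window length in frames (>= 3).
#' @param theta correlation cutoff in (0, 1].
#' @return A `snapshot_graph`: list with `t` (window start), `nodes` (0-based
#'   pixel ids with >= 1 edge), `edges` (data.frame i, j, w with i < j),
#'   `window`, `threshold`, `n_pixels`.
#' @export
window_correlation_graph <- function(stack, t0, W, theta) {
  m <- if (inherits(stack, "image_stack")) pixel_matrix(stack) else stack
  if (W < 3) stop("window must span at least 3 frames", call. = FALSE)
  if (theta <= 0 || theta > 1) stop("`theta` must be in (0, 1]", call. = FALSE)
  if (t0 < 1 || t0 + W - 1 > nrow(m))
    stop("window exceeds the stack", call. = FALSE)
  win <- m[t0:(t0 + W - 1L), , drop = FALSE]
  sds <- apply(win, 2, stats::sd)
  live <- which(sds > 0)
  ed <- data.frame(i = integer(0), j = integer(0), w = numeric(0))
  if (length(live) >= 2) {
    cc <- suppressWarnings(stats::cor(win[, live, drop = FALSE]))
    cc[lower.tri(cc, diag = TRUE)] <- NA
    hit <- which(cc >= theta, arr.ind = TRUE)
    if (nrow(hit)) {
      ed <- data.frame(i = live[hit[, 1]] - 1L, j = live[hit[, 2]] - 1L,
                       w = cc[hit])
      swap <- ed$i > ed$j
      tmp <- ed$i[swap]; ed$i[swap] <- ed$j[swap]; ed$j[swap] <- tmp
      ed <- ed[order(ed$i, ed$j), , drop = FALSE]
      rownames(ed) <- NULL
    }
  }
  structure(list(t = t0, nodes = sort(unique(c(ed$i, ed$j))), edges = ed,
                 window = as.integer(W), threshold = theta,
                 n_pixels = ncol(m)),
            class = "snapshot_graph")
}

#' @export
print.snapshot_graph <- function(x, ...) {
  cat(sprintf("snapshot_graph: t0=%d, %d nodes, %d edges (W=%d, theta=%g)\n",
              x$t, length(x$nodes), nrow(x$edges), x$window, x$threshold))
  invisible(x)
}

#' Build the sliding-window temporal network
#'
#' Computes [window_correlation_graph()] at window starts 1, 1+stride,
#' 1+2*stride, ... while the window fits in the stack.
#'
#' @param stack an [image_stack].
#' @param W window length in frames (default 50).
#' @param theta correlation cutoff (default 0.7).
#' @param stride frames advanced between snapshots (default 1).
#' @return A `temporal_network`: list with `snapshots`, `W`, `theta`,
#'   `stride`, `fps`, `dim` (height, width).
#' @export
build_temporal_network <- function(stack, W = 50, theta = 0.7, stride = 1) {
  stopifnot(inherits(stack, "image_stack"))
  if (stride < 1) stop("`stride` must be >= 1", call. = FALSE)
  m <- pixel_matrix(stack)
  starts <- seq(1L, nrow(m) - W + 1L, by = stride)
  snaps <- lapply(starts, function(t0)
    window_correlation_graph(m, t0, W, theta))
  structure(list(snapshots = snaps, W = as.integer(W), theta = theta,
                 stride = as.integer(stride), fps = stack$fps,
                 dim = c(frame_h(stack), frame_w(stack))),
            class = "temporal_network")
}

#' @export
print.temporal_network <- function(x, ...) {
  ne <- vapply(x$snapshots, function(s) nrow(s$edges), numeric(1))
  cat(sprintf(
    "temporal_network: %d snapshots (W=%d, theta=%g, stride=%d), %g edges/snapshot on average\n",
    length(x$snapshots), x$W, x$theta, x$stride, mean(ne)))
  invisible(x)
}

#' Mean degree per node of a temporal network
#'
#' Total edge endpoints over all snapshots divided by total node observations
#' (a node counts once per snapshot it appears in).
#'
#' @param net a `temporal_network`.
#' @return Mean degree (edges per observed node); 0 for an empty network.
#' @export
mean_degree <- function(net) {
  e <- sum(vapply(net$snapshots, function(s) nrow(s$edges), numeric(1)))
  n <- sum(vapply(net$snapshots, function(s) length(s$nodes), numeric(1)))
  if (n == 0) 0 else 2 * e / n
}

#' Frame index of the activation peak
#'
#' Index of the maximum of the spatially averaged series; ties broken by the
#' earliest frame.
#'
#' @param stack an [image_stack] (dF/F or raw).
#' @return 1-based frame index.
#' @export
find_peak <- function(stack) {
  s <- mean_series(stack)
  which.max(s)   # which.max takes the first maximum
}

#' Per-pixel degree map around a frame window
#'
#' For every pixel, the mean number of supra-threshold edges over the
#' snapshots whose correlation windows intersect `around_peak` (by default the
#' 100 frames surrounding the activation peak is a typical choice). The
#' normalized map divides by the image maximum.
#'
#' @param net a `temporal_network`.
#' @param around_peak integer vector of frame indices (1-based).
#' @return A `degree_map`: list with `raw` and `normalized` (height x width
#'   matrices) and `n_snapshots` used.
#' @export
degree_map <- function(net, around_peak) {
  stopifnot(inherits(net, "temporal_network"))
  lo <- min(around_peak); hi <- max(around_peak)
  use <- Filter(function(s) s$t <= hi && (s$t + s$window - 1L) >= lo,
                net$snapshots)
  if (length(use) == 0L)
    stop("no snapshots intersect the requested window", call. = FALSE)
  npx <- prod(net$dim)
  deg <- numeric(npx)
  for (s in use) {
    if (nrow(s$edges)) {
      tab <- table(c(s$edges$i, s$edges$j) + 1L)
      deg[as.integer(names(tab))] <- deg[as.integer(names(tab))] + tab
    }
  }
  raw <- deg / length(use)
  mx <- max(raw)
  norm <- if (mx > 0) raw / mx else raw
  structure(list(raw = matrix(raw, net$dim[1], net$dim[2], byrow = TRUE),
                 normalized = matrix(norm, net$dim[1], net$dim[2],
                                     byrow = TRUE),
                 n_snapshots = length(use)),
            class = "degree_map")
}

#' Export a temporal network as an edge-list table plus JSON header
#'
#' @param net a `temporal_network`.
#' @param path base path: writes `<path>.tsv` (t, i, j, weight) and
#'   `<path>.json` (W, theta, stride, fps, dim).
#' @return Invisibly, the two paths.
#' @export
write_temporal_network <- function(net, path) {
  rows <- do.call(rbind, lapply(net$snapshots, function(s)
    if (nrow(s$edges)) cbind(t = s$t, s$edges) else NULL))
  if (is.null(rows)) rows <- data.frame(t = integer(0), i = integer(0),
                                        j = integer(0), w = numeric(0))
  names(rows) <- c("t", "i", "j", "weight")
  p1 <- paste0(path, ".tsv"); p2 <- paste0(path, ".json")
  utils::write.table(rows, p1, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(W = net$W, theta = net$theta, stride = net$stride,
                            fps = net$fps, height = net$dim[1],
                            width = net$dim[2]),
                       p2, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2))
}

#' Read a temporal network written by [write_temporal_network()]
#'
#' @param path base path used when writing.
#' @return A `temporal_network`.
#' @export
read_temporal_network <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  rows <- utils::read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t")
  npx <- hdr$height * hdr$width
  snaps <- lapply(split(rows, rows$t), function(d) {
    ed <- data.frame(i = d$i, j = d$j, w = d$weight)
    structure(list(t = d$t[1], nodes = sort(unique(c(d$i, d$j))), edges = ed,
                   window = as.integer(hdr$W), threshold = hdr$theta,
                   n_pixels = npx),
              class = "snapshot_graph")
  })
  snaps <- snaps[order(vapply(snaps, function(s) s$t, numeric(1)))]
  structure(list(snapshots = unname(snaps), W = as.integer(hdr$W),
                 theta = hdr$theta, stride = as.integer(hdr$stride),
                 fps = hdr$fps, dim = c(hdr$height, hdr$width)),
            class = "temporal_network")
}
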