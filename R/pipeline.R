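#' Default pipeline configuration
#'
#' Flat, serializable list of every stage parameter. Defaults follow the
#' operating point established for cortical fluorescence data: a 50-frame
#' correlation window, threshold 0.7, stride 1, equal unit social costs,
#' 50-tree forests and a 20-color rendering palette.
#'
#' @param ... overrides of any default field.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    input_tiff = NULL,     # path to a multi-page TIFF, or NULL to simulate
    fps = 71,
    simulate = NULL,       # list of synth_spec() arguments
    bin_by = 1,
    roi_rows = NULL, roi_cols = NULL,
    baseline_frames = NULL,   # NULL = first 10% of frames
    W = 50, theta = 0.7, stride = 1,
    louvain_seed = 1,
    cost_switch = 1, cost_visit = 1, cost_absence = 1,
    n_trees = 50, classifier_seed = 1,
    palette_k = 20,
    render = FALSE,
    out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  validate_config(structure(cfg, class = "run_config"))
}

validate_config <- function(cfg) {
  if (cfg$theta <= 0 || cfg$theta > 1)
    stop("config: theta must be in (0, 1]", call. = FALSE)
  if (cfg$W < 3) stop("config: W must be >= 3", call. = FALSE)
  if (cfg$stride < 1) stop("config: stride must be >= 1", call. = FALSE)
  if (cfg$fps <= 0) stop("config: fps must be positive", call. = FALSE)
  if (any(c(cfg$cost_switch, cfg$cost_visit, cfg$cost_absence) < 0))
    stop("config: costs must be nonnegative", call. = FALSE)
  if (cfg$palette_k < 1) stop("config: palette_k must be >= 1", call. = FALSE)
  cfg
}

#' Write / read a run configuration (JSON round-trip)
#'
#' @param cfg a [run_config()].
#' @param path JSON file path.
#' @return `write_config` returns the path invisibly; `read_config` the
#'   validated `run_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Run the dynamic community analysis on one image stack
#'
#' The in-memory core of the pipeline: preprocessing (optional binning, ROI,
#' dF/F), sliding-window correlation network, per-snapshot Louvain groups,
#' social-cost dynamic community inference, and per-pixel metrics.
#'
#' @param stack an [image_stack] of raw intensities.
#' @param cfg a [run_config()].
#' @return List with `stack` (preprocessed), `network`, `partitions`,
#'   `grouping`, `coloring`, `metrics`, `summary`, `peak_frame`, `degree`.
#' @export
analyze_stack <- function(stack, cfg = run_config()) {
  if (cfg$bin_by > 1) stack <- bin_pixels(stack, cfg$bin_by)
  if (!is.null(cfg$roi_rows) || !is.null(cfg$roi_cols)) {
    rows <- if (is.null(cfg$roi_rows)) seq_len(dim(stack)[2]) else
      cfg$roi_rows[1]:cfg$roi_rows[2]
    cols <- if (is.null(cfg$roi_cols)) seq_len(dim(stack)[3]) else
      cfg$roi_cols[1]:cfg$roi_cols[2]
    stack <- crop_roi(stack, rows, cols)
  }
  stack <- dff(stack, cfg$baseline_frames)
  net <- build_temporal_network(stack, W = cfg$W, theta = cfg$theta,
                                stride = cfg$stride)
  partitions <- lapply(seq_along(net$snapshots), function(k)
    louvain(net$snapshots[[k]], seed = cfg$louvain_seed + k - 1L))
  grouping <- temporal_grouping(partitions)
  costs <- commdy_costs(cfg$cost_switch, cfg$cost_visit, cfg$cost_absence)
  coloring <- commdy_infer(grouping, costs)
  metrics <- node_metrics(coloring, grouping)
  # a fully disconnected network has no activated pixels and no communities
  summ <- if (!is.null(metrics) && nrow(metrics) > 0)
    summarize_activation(metrics) else NULL
  peak <- find_peak(stack)
  around <- max(1, peak - 50):min(n_frames(stack), peak + 49)
  degmap <- tryCatch(degree_map(net, around), error = function(e) NULL)
  list(stack = stack, network = net, partitions = partitions,
       grouping = grouping, coloring = coloring, metrics = metrics,
       summary = summ, peak_frame = peak, degree = degmap)
}

#' Run the full pipeline into an output directory
#'
#' Loads or simulates the movie per the configuration, runs [analyze_stack()],
#' and writes every stage output (edge lists, partitions, colorings, metric
#' tables, optional rendered maps) plus a JSON manifest with an md5 checksum
#' per file. Re-running the same configuration reproduces all outputs
#' bit-identically.
#'
#' @param cfg a [run_config()]; `cfg$out_dir` must be set.
#' @return The output directory path, invisibly; the analysis list is
#'   attached as attribute `"result"`.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  if (is.null(cfg$out_dir)) stop("config: out_dir not set", call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  stack <- stage("input", {
    if (!is.null(cfg$input_tiff)) load_stack(cfg$input_tiff, cfg$fps)
    else if (!is.null(cfg$simulate)) {
      spec <- do.call(synth_spec, cfg$simulate)
      generate_movie(spec)$stack
    } else stop("neither input_tiff nor simulate given")
  })
  res <- stage("analysis", analyze_stack(stack, cfg))
  files <- character(0)
  put <- function(paths) files <<- c(files, paths)
  stage("export", {
    put(write_temporal_network(res$network, file.path(cfg$out_dir, "network")))
    part_rows <- do.call(rbind, lapply(res$partitions, function(p) {
      if (!length(p$groups)) return(NULL)
      data.frame(t = p$t,
                 pixel_id = unlist(p$groups),
                 group_id = rep(seq_along(p$groups) - 1L,
                                vapply(p$groups, length, integer(1))),
                 Q = p$Q)
    }))
    pf <- file.path(cfg$out_dir, "partitions.tsv")
    utils::write.table(if (is.null(part_rows)) data.frame() else part_rows,
                       pf, sep = "\t", row.names = FALSE, quote = FALSE)
    put(pf)
    put(write_coloring(res$coloring, file.path(cfg$out_dir, "coloring")))
    mf <- file.path(cfg$out_dir, "node_metrics.tsv")
    utils::write.table(if (is.null(res$metrics)) data.frame() else
      res$metrics, mf, sep = "\t", row.names = FALSE, quote = FALSE)
    put(mf)
    sf <- file.path(cfg$out_dir, "activation_summary.tsv")
    utils::write.table(if (is.null(res$summary)) data.frame() else
      res$summary, sf, sep = "\t", row.names = FALSE, quote = FALSE)
    put(sf)
  })
  if (isTRUE(cfg$render)) stage("render", {
    put(render_maps(res$coloring, res$degree, k = cfg$palette_k,
                    dim = res$network$dim, dir = cfg$out_dir))
  })
  manifest <- list(config = unclass(cfg),
                   files = lapply(sort(files), function(f)
                     list(path = basename(f),
                          md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  out <- cfg$out_dir
  attr(out, "result") <- res
  invisible(out)
}

# fixed 20-color palette: label rank k always maps to the same color
community_palette <- function(k = 20) {
  base <- c("#E6194B", "#3CB44B", "#4363D8", "#FFE119", "#F58231",
            "#911EB4", "#42D4F4", "#F032E6", "#BFEF45", "#FABED4",
            "#469990", "#DCBEFF", "#9A6324", "#FFFAC8", "#800000",
            "#AAFFC3", "#808000", "#FFD8B1", "#000075", "#A9A9A9")
  rep_len(base, k)
}

#' Render community maps and a degree heat map as PNG files
#'
#' Colors each pixel by its community at each time step, using a fixed
#' palette over the top-k communities (others and background stay dark), and
#' writes a degree heat map. Palette order is fixed: the same ranked label
#' keeps its color across frames.
#'
#' @param coloring a `dynamic_coloring`.
#' @param degree a `degree_map` or NULL.
#' @param k palette size (default 20).
#' @param dim c(height, width) of the frame.
#' @param dir output directory.
#' @param steps which time steps to render (default: all).
#' @return Character vector of files written.
#' @export
render_maps <- function(coloring, degree, k = 20, dim, dir, steps = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  top <- top_communities(coloring, k)
  pal <- community_palette(length(top))
  rgb_ <- grDevices::col2rgb(pal) / 255
  h <- dim[1]; w <- dim[2]
  nt <- length(coloring$steps)
  if (is.null(steps)) steps <- seq_len(nt)
  files <- character(0)
  for (t in steps) {
    img <- array(0.05, c(h, w, 3))
    cols <- coloring$individual_color[t, ]
    def <- which(!is.na(cols))
    for (ix in def) {
      rank_ <- match(cols[ix], top)
      if (is.na(rank_)) next
      px <- coloring$individuals[ix]     # 0-based row-major
      r <- px %/% w + 1L; cc <- px %% w + 1L
      img[r, cc, ] <- rgb_[, rank_]
    }
    f <- file.path(dir, sprintf("community_t%04d.png", t))
    png::writePNG(img, f)
    files <- c(files, f)
  }
  if (!is.null(degree)) {
    nrm <- degree$normalized
    ramp <- grDevices::colorRamp(c("black", "darkred", "orange", "white"))
    rgbv <- ramp(as.vector(nrm)) / 255
    img <- array(0, c(h, w, 3))
    for (ch in 1:3) img[, , ch] <- matrix(rgbv[, ch], h, w)
    f <- file.path(dir, "degree_map.png")
    png::writePNG(img, f)
    files <- c(files, f)
  }
  files
}

#' Modal community label per pixel
#'
#' The community color each pixel carries most often (over defined steps);
#' handy for comparing an inferred coloring with planted ground truth.
#'
#' @param coloring a `dynamic_coloring`.
#' @param steps optional subset of step indices.
#' @return Named integer vector (names = pixel ids).
#' @export
pixel_modal_community <- function(coloring, steps = NULL) {
  ic <- coloring$individual_color
  if (!is.null(steps)) ic <- ic[steps, , drop = FALSE]
  out <- apply(ic, 2, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_integer_)
    tab <- table(v)
    as.integer(names(tab)[which.max(tab)])
  })
  stats::setNames(as.integer(out), colnames(ic))
}
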