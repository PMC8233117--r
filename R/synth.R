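#' Specification for a synthetic fluorescence movie
#'
#' Describes a movie with planted pixel communities whose membership may change
#' at epoch boundaries. Each community follows a latent time course; each pixel
#' mixes its community's latent with private noise at a tunable coupling, the
#' knob standing in for age or NMDA blockade in degradation experiments.
#'
#' The latent of community c is a standardized common waveform (paroxysmal
#' transient or sinusoid, see [paroxysmal_waveform()]) plus community-private
#' white noise of relative variance `latent_noise`, so that communities share
#' the event timing but remain statistically separable. Pixel series are
#' `baseline * (1 + amplitude * (sqrt(coupling) * z_c + sqrt(1-coupling) * e_p))
#' + noise_sd * w_p` with `e_p`, `w_p` independent standard Gaussian noise, so
#' `coupling` is the fraction of structured pixel variance carried by the
#' community latent and the expected within-community correlation at
#' `noise_sd = 0`. Pixels assigned community 0 are pure-noise background (an
#' "off-slice" margin).
#'
#' @param height,width frame size in pixels.
#' @param n_frames number of frames.
#' @param fps frames per second.
#' @param n_communities number of planted communities (>= 1).
#' @param community_map integer matrix (height x width) or a list of such
#'   matrices, one per epoch, with entries in 0..n_communities (0 = background
#'   noise pixel). Default: `n_communities` contiguous vertical stripes.
#' @param epoch_boundaries integer frame indices (1-based, strictly inside the
#'   movie) at which the planted membership switches to the next epoch's map.
#' @param waveform `"paroxysmal"` or `"oscillatory"`.
#' @param onset_frame frame (1-based) at which the paroxysmal activation
#'   starts; frames before it are baseline.
#' @param peak_time_ms milliseconds from onset to the paroxysmal peak.
#' @param decay_tau_s exponential decay time constant, seconds.
#' @param osc_freq_hz oscillation frequency for the oscillatory waveform.
#' @param coupling fraction in [0, 1] of structured pixel variance explained by
#'   the community latent.
#' @param latent_noise variance of the community-private latent component
#'   relative to the shared waveform (default 1; 0 makes all communities
#'   identical).
#' @param amplitude peak fractional fluorescence change of the structured
#'   signal (arbitrary units; activations have no absolute scale here).
#' @param baseline_level mean raw fluorescence, arbitrary units.
#' @param noise_sd additive measurement noise, fluorescence units.
#' @param seed integer RNG seed; identical specs generate identical movies.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(height = 12, width = 12, n_frames = 300, fps = 71,
                       n_communities = 3, community_map = NULL,
                       epoch_boundaries = integer(0),
                       waveform = c("paroxysmal", "oscillatory"),
                       onset_frame = 31, peak_time_ms = 150, decay_tau_s = 2,
                       osc_freq_hz = 3, coupling = 0.9, latent_noise = 1,
                       amplitude = 0.1, baseline_level = 100, noise_sd = 0.1,
                       seed = 1) {
  waveform <- match.arg(waveform)
  if (n_communities < 1) stop("need n_communities >= 1", call. = FALSE)
  if (coupling < 0 || coupling > 1)
    stop("`coupling` must be in [0, 1]", call. = FALSE)
  if (fps <= 0) stop("`fps` must be positive", call. = FALSE)
  if (is.null(community_map))
    community_map <- stripe_map(height, width, n_communities)
  if (!is.list(community_map)) community_map <- list(community_map)
  for (m in community_map) {
    if (!identical(dim(m), c(as.integer(height), as.integer(width))))
      stop("community_map shape does not match height x width", call. = FALSE)
    if (any(m < 0 | m > n_communities | m != round(m)))
      stop("community_map entries must be integers in 0..n_communities",
           call. = FALSE)
  }
  if (length(community_map) != length(epoch_boundaries) + 1L)
    stop("need one community_map per epoch (boundaries + 1)", call. = FALSE)
  if (length(epoch_boundaries) &&
      (any(epoch_boundaries <= 1L) || any(epoch_boundaries > n_frames) ||
       is.unsorted(epoch_boundaries, strictly = TRUE)))
    stop("epoch_boundaries must be strictly increasing frames in 2..n_frames",
         call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_frames = as.integer(n_frames), fps = fps,
                 n_communities = as.integer(n_communities),
                 community_map = community_map,
                 epoch_boundaries = as.integer(epoch_boundaries),
                 waveform = waveform, onset_frame = as.integer(onset_frame),
                 peak_time_ms = peak_time_ms, decay_tau_s = decay_tau_s,
                 osc_freq_hz = osc_freq_hz, coupling = coupling,
                 latent_noise = latent_noise, amplitude = amplitude,
                 baseline_level = baseline_level, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

stripe_map <- function(height, width, k) {
  cols <- sort(rep_len(seq_len(k), width))
  matrix(cols[col(matrix(0, height, width))], height, width)
}

#' Paroxysmal activation waveform
#'
#' Template time course of a paroxysmal depolarization: a linear rise from
#' baseline to a unit peak about 150 ms after onset, followed by a slow
#' exponential decline back toward baseline over seconds. The peak is snapped
#' to the frame grid, so the maximum sits exactly at the frame nearest
#' `peak_time_ms` after onset.
#'
#' @param peak_time_ms milliseconds from onset to peak (> 0).
#' @param decay_tau_s exponential decay time constant in seconds (> 0;
#'   `Inf` holds the peak value forever).
#' @param fps frames per second.
#' @param n_frames number of frames to generate, onset at frame 1.
#' @return Numeric vector of length `n_frames`, nonnegative, unit peak.
#' @examples
#' w <- paroxysmal_waveform(150, 2, fps = 71, n_frames = 400)
#' which.max(w) - 1  # frames after onset: round(0.150 * 71)
#' @export
paroxysmal_waveform <- function(peak_time_ms, decay_tau_s, fps, n_frames) {
  if (peak_time_ms <= 0 || decay_tau_s <= 0)
    stop("timing parameters must be positive", call. = FALSE)
  if (fps <= 0 || n_frames < 1)
    stop("need fps > 0 and n_frames >= 1", call. = FALSE)
  k_peak <- max(1L, as.integer(round(peak_time_ms / 1000 * fps)))
  t <- (seq_len(n_frames) - 1L) / fps        # seconds since onset
  t_peak <- k_peak / fps
  w <- ifelse(t <= t_peak, t / t_peak,
              if (is.finite(decay_tau_s)) exp(-(t - t_peak) / decay_tau_s)
              else 1)
  w
}

oscillatory_waveform <- function(freq_hz, fps, n_frames, phase = 0) {
  t <- (seq_len(n_frames) - 1L) / fps
  sin(2 * pi * freq_hz * t + phase)
}

#' Generate a synthetic movie with planted communities
#'
#' Realizes the model described in [synth_spec()]: one latent time course per
#' planted community, pixel series mixing the latent with private noise, and a
#' ground-truth label per (pixel, frame).
#'
#' @param spec a [synth_spec()].
#' @return A list with `stack` (an [image_stack]), and `truth`, a list holding
#'   `labels` (n_frames x n_pixels integer matrix of planted labels, columns in
#'   row-major 0-based pixel-id order, 0 = background), `onset_frames` and the
#'   epoch boundaries.
#' @export
generate_movie <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  nf <- spec$n_frames; h <- spec$height; w <- spec$width
  npx <- h * w; k <- spec$n_communities

  base_wave <- switch(spec$waveform,
    paroxysmal = {
      wv <- numeric(nf)
      if (spec$onset_frame <= nf) {
        post <- spec$onset_frame:nf
        wv[post] <- paroxysmal_waveform(spec$peak_time_ms, spec$decay_tau_s,
                                        spec$fps, length(post))
      }
      wv
    },
    oscillatory = oscillatory_waveform(spec$osc_freq_hz, spec$fps, nf))

  standardize <- function(x) {
    s <- stats::sd(x)
    if (s == 0) x * 0 else (x - mean(x)) / s
  }
  wz <- standardize(base_wave)
  # phase offsets decorrelate community latents; capped at a quarter cycle so
  # the tone survives in the spatial average instead of cancelling out
  phases <- (pi / 2) * (seq_len(k) - 1) / max(k - 1, 1)
  latents <- sapply(seq_len(k), function(c) {
    shared <- if (spec$waveform == "oscillatory")
      standardize(oscillatory_waveform(spec$osc_freq_hz, spec$fps, nf,
                                       phases[c]))
    else wz
    z <- shared + sqrt(spec$latent_noise) * stats::rnorm(nf)
    standardize(z)   # unit variance, like the pixel-private component
  })
  latents <- matrix(latents, nrow = nf)

  # planted label per (frame, pixel); community maps are epoch-wise
  bounds <- c(1L, spec$epoch_boundaries, nf + 1L)
  labels <- matrix(0L, nf, npx)
  for (e in seq_along(spec$community_map)) {
    fr <- bounds[e]:(bounds[e + 1L] - 1L)
    # row-major 0-based pixel order: transpose the height x width map
    lab <- as.integer(t(spec$community_map[[e]]))
    labels[fr, ] <- matrix(lab, length(fr), npx, byrow = TRUE)
  }

  a <- spec$amplitude * spec$baseline_level
  sig <- matrix(0, nf, npx)
  for (p in seq_len(npx)) {
    lab <- labels[, p]
    zc <- numeric(nf)
    on <- lab > 0L
    if (any(on)) zc[on] <- latents[cbind(which(on), lab[on])]
    sig[, p] <- a * (sqrt(spec$coupling) * zc +
                     sqrt(1 - spec$coupling) * stats::rnorm(nf))
  }
  raw <- spec$baseline_level + sig +
    matrix(stats::rnorm(nf * npx, sd = spec$noise_sd), nf, npx)
  raw[raw < 0] <- 0

  data <- array(0, c(nf, h, w))
  for (f in seq_len(nf))
    data[f, , ] <- matrix(raw[f, ], h, w, byrow = TRUE)  # row-major ids
  stack <- image_stack(data, spec$fps,
                       meta = list(source = "synthetic", seed = spec$seed))
  truth <- list(labels = labels,
                onset_frames = if (spec$waveform == "paroxysmal")
                  spec$onset_frame else integer(0),
                epoch_boundaries = spec$epoch_boundaries)
  list(stack = stack, truth = truth)
}

#' Write a generated movie with its ground truth
#'
#' Writes the stack as a multi-page TIFF, the planted labels as a delimited
#' table (pixel_id, frame, label) and the spec as a JSON sidecar.
#'
#' @param movie result of [generate_movie()].
#' @param spec the [synth_spec()] used.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_movie <- function(movie, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_tif <- file.path(dir, "movie.tif")
  p_lab <- file.path(dir, "ground_truth.tsv")
  p_json <- file.path(dir, "spec.json")
  write_stack(movie$stack, p_tif)
  lab <- movie$truth$labels
  df <- data.frame(pixel_id = rep(seq_len(ncol(lab)) - 1L, each = nrow(lab)),
                   frame = rep(seq_len(nrow(lab)) - 1L, ncol(lab)),
                   label = as.integer(lab))
  utils::write.table(df, p_lab, sep = "\t", row.names = FALSE, quote = FALSE)
  sp <- spec
  sp$community_map <- lapply(sp$community_map, function(m)
    apply(m, 1, identity, simplify = FALSE))
  class(sp) <- NULL
  jsonlite::write_json(sp, p_json, auto_unbox = TRUE, digits = NA)
  invisible(c(p_tif, p_lab, p_json))
}
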