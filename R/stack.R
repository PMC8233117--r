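#' Fluorescence image stack
#'
#' An `image_stack` holds a frames x height x width array of nonnegative
#' fluorescence intensities together with the acquisition frame rate and a
#' provenance record of the preprocessing steps applied so far.
#'
#' Pixel coordinates follow a row-major, 0-based convention with the origin at
#' the top-left corner: pixel id = row * width + col, rows and columns counted
#' from 0. All exported tables use these ids.
#'
#' @param data numeric array with dimensions (frames, height, width), or a
#'   matrix (taken as a single frame).
#' @param fps acquisition rate in frames per second; must be positive.
#' @param meta optional named list of provenance fields.
#' @return An object of class `image_stack` with elements `data`, `fps`,
#'   `meta` (including `meta$steps`, the ordered record of processing steps).
#' @examples
#' st <- image_stack(array(runif(4 * 3 * 3), c(4, 3, 3)), fps = 71)
#' dim(st$data)
#' @export
image_stack <- function(data, fps, meta = list()) {
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a frames x height x width array", call. = FALSE)
  if (dim(data)[1] < 1L) stop("stack needs at least one frame", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop("`fps` must be a single positive number", call. = FALSE)
  if (is.null(meta$steps)) meta$steps <- character(0)
  structure(list(data = data, fps = fps, meta = meta), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d frames of %d x %d pixels at %g fps\n",
              d[1], d[2], d[3], x$fps))
  if (length(x$meta$steps))
    cat("  steps: ", paste(x$meta$steps, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[1]
frame_h <- function(stack) dim(stack$data)[2]
frame_w <- function(stack) dim(stack$data)[3]

#' Read a multi-page TIFF as an image stack
#'
#' Each page becomes one frame. Pages must all have the same shape; multi-channel
#' pages are reduced to their first channel.
#'
#' @param path path to a multi-page TIFF file.
#' @param fps acquisition rate in frames per second.
#' @return An [image_stack].
#' @export
load_stack <- function(path, fps) {
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("not a readable TIFF: ", path,
                                             call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    p
  })
  shp <- dim(pages[[1L]])
  ok <- vapply(pages, function(p) identical(dim(p), shp), logical(1))
  if (!all(ok))
    stop("pages of differing shapes in '", path, "'", call. = FALSE)
  data <- array(0, c(length(pages), shp[1], shp[2]))
  for (k in seq_along(pages)) data[k, , ] <- pages[[k]]
  image_stack(data, fps, meta = list(source = path))
}

#' Write an image stack as a multi-page TIFF
#'
#' Intensities are rescaled to [0, 1] for storage (the TIFF writer's required
#' range); the scale used is returned invisibly.
#'
#' @param stack an [image_stack].
#' @param path output path.
#' @return Invisibly, the scale factor applied before writing.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  hi <- max(stack$data)
  scale <- if (hi > 0) hi else 1
  pages <- lapply(seq_len(n_frames(stack)),
                  function(k) stack$data[k, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(scale)
}

#' Spatially bin pixels
#'
#' Replaces each `by` x `by` block of pixels by its mean, mirroring hardware
#' binning. Trailing rows or columns that do not fill a complete block are
#' dropped, so the output is floor(height/by) x floor(width/by).
#'
#' @param stack an [image_stack].
#' @param by integer bin factor, at least 1.
#' @return A binned [image_stack].
#' @examples
#' st <- image_stack(array(1:8, c(2, 2, 2)), fps = 10)
#' bin_pixels(st, 2)$data
#' @export
bin_pixels <- function(stack, by) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.numeric(by) || length(by) != 1L || by < 1 || by != round(by))
    stop("`by` must be an integer >= 1", call. = FALSE)
  by <- as.integer(by)
  if (by == 1L) return(stack)
  h <- (frame_h(stack) %/% by) * by
  w <- (frame_w(stack) %/% by) * by
  if (h < by || w < by) stop("frame smaller than one bin", call. = FALSE)
  dat <- stack$data[, seq_len(h), seq_len(w), drop = FALSE]
  nf <- dim(dat)[1]
  # reshape so block members become the dimensions averaged over
  dim(dat) <- c(nf, by, h %/% by, by, w %/% by)
  out <- apply(dat, c(1, 3, 5), mean)
  meta <- stack$meta
  meta$steps <- c(meta$steps, sprintf("bin%dx%d", by, by))
  image_stack(out, stack$fps, meta)
}

#' Crop a region of interest
#'
#' Restricts the stack to a rectangular ROI. The original coordinates of the
#' ROI are recorded in `meta$roi` so that exported pixel ids can be traced
#' back to the full frame.
#'
#' @param stack an [image_stack].
#' @param rows,cols integer index vectors (1-based, contiguous) selecting the
#'   ROI within the current frame.
#' @return The cropped [image_stack].
#' @export
crop_roi <- function(stack, rows, cols) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(rows) == 0L || length(cols) == 0L)
    stop("empty ROI range", call. = FALSE)
  if (min(rows) < 1L || max(rows) > frame_h(stack) ||
      min(cols) < 1L || max(cols) > frame_w(stack))
    stop("ROI out of frame bounds", call. = FALSE)
  out <- stack$data[, rows, cols, drop = FALSE]
  meta <- stack$meta
  meta$steps <- c(meta$steps, "crop")
  # 0-based offsets of the ROI origin in the pre-crop frame
  meta$roi <- list(row0 = min(rows) - 1L, col0 = min(cols) - 1L,
                   height = length(rows), width = length(cols))
  image_stack(out, stack$fps, meta)
}

#' Relative fluorescence change (dF/F)
#'
#' Converts each pixel series to (F - F0) / F0 where F0 is that pixel's mean
#' over a baseline frame range. The step is recorded in the provenance and may
#' be applied only once per stack.
#'
#' @param stack an [image_stack] of raw intensities.
#' @param baseline integer vector of baseline frame indices (1-based). Default
#'   is the first 10\% of frames (at least one frame): both datasets this
#'   pipeline targets begin with a quiescent prefix.
#' @return An [image_stack] of dF/F values (no longer nonnegative).
#' @export
dff <- function(stack, baseline = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if ("dff" %in% stack$meta$steps)
    stop("dF/F already applied to this stack (see meta$steps)", call. = FALSE)
  nf <- n_frames(stack)
  if (is.null(baseline)) baseline <- seq_len(max(1L, floor(nf / 10)))
  if (length(baseline) == 0L || min(baseline) < 1L || max(baseline) > nf)
    stop("baseline range empty or outside the stack", call. = FALSE)
  f0 <- apply(stack$data[baseline, , , drop = FALSE], c(2, 3), mean)
  if (any(f0 <= 0)) {
    bad <- which(f0 <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "baseline mean <= 0 at pixel id %d (row %d, col %d)",
      (bad[1] - 1L) * frame_w(stack) + (bad[2] - 1L), bad[1] - 1L, bad[2] - 1L),
      call. = FALSE)
  }
  out <- stack$data
  for (k in seq_len(nf)) out[k, , ] <- out[k, , ] / f0 - 1
  meta <- stack$meta
  meta$steps <- c(meta$steps, "dff")
  meta$baseline <- range(baseline)
  structure(list(data = out, fps = stack$fps, meta = meta),
            class = "image_stack")
}

#' Spatially averaged pixel series
#'
#' @param stack an [image_stack].
#' @return Numeric vector: per-frame mean over all pixels.
#' @export
mean_series <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  apply(stack$data, 1, mean)
}
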