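#' Signal-to-noise ratio of a periodic series, in dB
#'
#' Ratio of the power of the fundamental — the largest non-DC component of the
#' periodogram — to the power of everything else after excluding DC, the
#' fundamental and its harmonics, following the convention of common
#' signal-processing `snr` routines. Each excluded component removes its bin
#' and one neighbouring bin on each side (spectral leakage guard).
#'
#' @param series numeric time series, length >= 16.
#' @param fps sampling rate in frames per second.
#' @param cap_db ceiling on the reported ratio: values at or above the cap
#'   (e.g. a noiseless sinusoid, where the residual power is numerical noise)
#'   are reported as `cap_db`. Default 100 dB.
#' @param n_harmonics number of harmonics of the fundamental excluded from the
#'   noise estimate (default 6).
#' @return SNR in decibels; `cap_db` when no noise power remains.
#' @examples
#' t <- seq(0, 20, by = 1 / 25)[-1]
#' snr_db(sin(2 * pi * 3 * t) + rnorm(length(t), sd = 0.5), fps = 25)
#' @export
snr_db <- function(series, fps, cap_db = 100, n_harmonics = 6) {
  if (length(series) < 16L) stop("series too short (< 16 samples)", call. = FALSE)
  if (fps <= 0) stop("`fps` must be positive", call. = FALSE)
  x <- series - mean(series)
  if (all(abs(x) < .Machine$double.eps * max(1, abs(mean(series))) * 8))
    stop("constant series has no fundamental", call. = FALSE)
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n          # periodogram, DC already removed
  nyq <- floor(n / 2) + 1L
  p <- p[2:nyq]                          # positive-frequency bins 1..nyq-1
  nb <- length(p)
  kf <- which.max(p)
  keep <- rep(TRUE, nb)
  exclude <- function(k) {
    idx <- intersect(seq.int(k - 1L, k + 1L), seq_len(nb))
    keep[idx] <<- FALSE
  }
  exclude(kf)
  p_sig <- sum(p[seq.int(max(1L, kf - 1L), min(nb, kf + 1L))])
  for (h in 2:(n_harmonics + 1L)) {
    kh <- kf * h
    if (kh > nb) break
    exclude(kh)
  }
  p_noise <- sum(p[keep])
  if (p_noise <= 0) return(cap_db)
  min(10 * log10(p_sig / p_noise), cap_db)
}

#' Dominant frequency of a series within a band
#'
#' Frequency of maximal spectral power density inside `band`, estimated with an
#' averaged (Welch-style) periodogram: the series is split into half-overlapping
#' Hann-windowed segments whose periodograms are averaged.
#'
#' @param series numeric time series.
#' @param fps sampling rate in frames per second.
#' @param band numeric length-2 vector of Hz, within (0, fps/2).
#' @param segment_length samples per segment (default: the largest power of two
#'   not exceeding length/2, at least 32, at most the series length).
#' @return Dominant frequency in Hz.
#' @export
dominant_frequency <- function(series, fps, band = c(0.5, fps / 2 * 0.99),
                               segment_length = NULL) {
  if (fps <= 0) stop("`fps` must be positive", call. = FALSE)
  if (length(band) != 2L || band[1] <= 0 || band[2] >= fps / 2 ||
      band[1] >= band[2])
    stop("`band` must lie within (0, fps/2)", call. = FALSE)
  n <- length(series)
  if (is.null(segment_length)) {
    segment_length <- 2^floor(log2(max(n %/% 2, 2)))
    segment_length <- min(max(segment_length, 32L), n)
  }
  sp <- welch_psd(series, fps, segment_length)
  in_band <- sp$freq >= band[1] & sp$freq <= band[2]
  if (!any(in_band)) stop("no spectral bins inside `band`", call. = FALSE)
  f <- sp$freq[in_band]
  f[which.max(sp$power[in_band])]
}

# Averaged periodogram over half-overlapping Hann-windowed segments.
welch_psd <- function(series, fps, segment_length) {
  n <- length(series)
  L <- min(as.integer(segment_length), n)
  step <- max(1L, L %/% 2L)
  starts <- seq(1L, n - L + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))
  acc <- numeric(L)
  for (s in starts) {
    seg <- series[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * win
    acc <- acc + Mod(stats::fft(seg))^2
  }
  acc <- acc / length(starts)
  nyq <- floor(L / 2) + 1L
  list(freq = (seq_len(nyq) - 1L) * fps / L, power = acc[seq_len(nyq)])
}
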