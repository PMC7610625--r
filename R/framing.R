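#' Trailing analysis windows on the controller frame grid
#'
#' Frame k (1-based) covers the half-open interval `((k-1)*frame_s,
#' k*frame_s]` and exposes the trailing `window_s` seconds ending at its
#' last sample — only past samples, as the real-time constraint demands.
#' Frames that begin before one full window has elapsed are flagged
#' warm-up and carry no valid features.
#'
#' @param x a [timeseries()] (or anything with `rate_hz`, `samples`).
#' @param frame_s controller update interval in seconds (default 0.1,
#'   i.e. the 10 Hz update rate).
#' @param window_s trailing analysis window length in seconds (default
#'   0.5; must be >= `frame_s`).
#' @return Object of class `frame_index`: data.frame with columns
#'   `frame`, `start`, `end` (1-based sample indices) and `warmup`;
#'   attributes `rate_hz`, `frame_s`, `window_s`, `window_n`.
#' @export
frame_signal <- function(x, frame_s = 0.1, window_s = 0.5) {
  if (window_s < frame_s)
    tl_stop("invalid-window", "window_s must be >= frame_s")
  rate <- x$rate_hz
  nsamp <- n_samples(x)
  wn <- as.integer(round(window_s * rate))
  if (wn > nsamp)
    tl_stop("signal-too-short", "window longer than signal")
  nf <- n_frames(nsamp / rate, frame_s)
  k <- seq_len(nf)
  end <- as.integer(round(k * frame_s * rate))
  start <- end - wn + 1L
  idx <- data.frame(frame = k, start = start, end = end, warmup = start < 1L)
  attr(idx, "rate_hz") <- rate
  attr(idx, "frame_s") <- frame_s
  attr(idx, "window_s") <- window_s
  attr(idx, "window_n") <- wn
  class(idx) <- c("frame_index", "data.frame")
  idx
}

#' Extract one frame's trailing window from a series
#'
#' @param x a [timeseries()].
#' @param frames a [frame_signal()] index.
#' @param k frame number (1-based).
#' @return Numeric matrix `n_channels x window_n` (zero columns if the
#'   frame is warm-up).
#' @export
frame_window <- function(x, frames, k) {
  row <- frames[k, ]
  if (row$warmup) return(x$samples[, 0, drop = FALSE])
  x$samples[, row$start:row$end, drop = FALSE]
}

#' Hann-tapered one-sided periodogram
#'
#' Power spectral density estimate of one window; the single estimator
#' shared by feature extraction, tremor-band labeling and evaluation so
#' that all band powers are commensurable.
#'
#' @param w numeric vector, one window of samples.
#' @param rate_hz sampling rate in Hz.
#' @return list with `freq` (Hz, from 0 to Nyquist) and `psd` (power per
#'   Hz, one-sided).
#' @export
periodogram <- function(w, rate_hz) {
  n <- length(w)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
  xw <- (w - mean(w)) * taper
  X <- fft(xw)
  nh <- floor(n / 2)
  p <- (Mod(X)^2) / (rate_hz * sum(taper^2))
  psd <- p[1:(nh + 1)]
  psd[2:nh] <- 2 * psd[2:nh]           # fold negative frequencies
  list(freq = seq(0, nh) * rate_hz / n, psd = psd)
}

#' Mean power in a frequency band
#'
#' @param pg output of [periodogram()] or [welch_psd()].
#' @param band numeric length-2, band edges in Hz (inclusive).
#' @return Mean PSD over the band's bins.
#' @export
band_power <- function(pg, band) {
  sel <- pg$freq >= band[1] & pg$freq <= band[2]
  if (!any(sel))
    tl_stop("band-out-of-range", "no spectral bins inside band")
  mean(pg$psd[sel])
}

#' Welch power spectral density
#'
#' Mean of Hann-tapered one-sided periodograms over overlapping segments.
#'
#' @param x numeric vector.
#' @param rate_hz sampling rate in Hz.
#' @param seg_s segment length in seconds (default 1).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list with `freq` and `psd`.
#' @export
welch_psd <- function(x, rate_hz, seg_s = 1, overlap = 0.5) {
  n <- length(x)
  nseg <- as.integer(round(seg_s * rate_hz))
  if (nseg > n) tl_stop("signal-too-short", "segment longer than signal")
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, n - nseg + 1L, by = step)
  acc <- NULL
  for (s in starts) {
    pg <- periodogram(x[s:(s + nseg - 1L)], rate_hz)
    acc <- if (is.null(acc)) pg$psd else acc + pg$psd
  }
  list(freq = pg$freq, psd = acc / length(starts))
}

#' Per-frame band power of a multichannel series
#'
#' Band power of each frame's trailing window, summed across channels
#' (for triaxial accelerometry this equals the band power of the 3-D
#' vector signal). Warm-up frames return `NA`.
#'
#' @param x a [timeseries()].
#' @param frames a [frame_signal()] index.
#' @param band numeric length-2 band in Hz (default the 3-7 Hz tremor
#'   band).
#' @return Numeric vector, one value per frame.
#' @export
frame_band_power <- function(x, frames, band = c(3, 7)) {
  out <- rep(NA_real_, nrow(frames))
  for (k in seq_len(nrow(frames))) {
    if (frames$warmup[k]) next
    w <- x$samples[, frames$start[k]:frames$end[k], drop = FALSE]
    tot <- 0
    for (ch in seq_len(nrow(w)))
      tot <- tot + band_power(periodogram(w[ch, ], x$rate_hz), band)
    out[k] <- tot
  }
  out
}
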