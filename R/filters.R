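#' Specification of the causal acquisition band-pass filter
#'
#' Mirrors the recording chain: a forward (causal, single-pass) 8th-order
#' Butterworth IIR band-pass at 0.5-500 Hz. The filter is always applied
#' forward-only so that output at time t depends only on samples up to t,
#' as required for real-time use; there is no zero-phase two-pass option.
#'
#' @param order overall band-pass order (must be even; default 8).
#' @param low_hz,high_hz band edges in Hz (defaults 0.5 and 500).
#' @return Object of class `filter_spec`.
#' @export
filter_spec <- function(order = 8, low_hz = 0.5, high_hz = 500) {
  if (order %% 2 != 0 || order < 2)
    tl_stop("filter-design-error", "order must be a positive even integer")
  if (!(low_hz > 0 && low_hz < high_hz))
    tl_stop("filter-design-error", "need 0 < low_hz < high_hz")
  structure(list(kind = "butterworth-bandpass", order = as.integer(order),
                 low_hz = low_hz, high_hz = high_hz, causal = TRUE),
            class = "filter_spec")
}

#' Butterworth band-pass design in second-order sections
#'
#' Designs the digital filter by the classical route: analog Butterworth
#' low-pass prototype poles, low-pass to band-pass transformation, bilinear
#' transform with frequency prewarping. Poles are grouped into conjugate
#' pairs (biquads) rather than expanded into one transfer function, which
#' keeps the design numerically stable even with a 0.5 Hz lower edge at
#' 2048 Hz sampling.
#'
#' @param low_hz,high_hz band edges in Hz.
#' @param order overall band-pass order (even); the analog prototype has
#'   order `order/2`.
#' @param rate_hz sampling rate in Hz.
#' @return Matrix with one row per biquad, columns `b0 b1 b2 a0 a1 a2`
#'   (`a0` always 1).
#' @export
butter_bandpass_sos <- function(low_hz, high_hz, order = 8, rate_hz = 2048) {
  if (order %% 2 != 0 || order < 2)
    tl_stop("filter-design-error", "order must be even and >= 2")
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < rate_hz / 2))
    tl_stop("filter-design-error",
            "band edges must satisfy 0 < low < high < rate/2")
  m <- order / 2                       # analog prototype order
  fs2 <- 2 * rate_hz
  # prewarped analog edge frequencies (rad/s)
  w1 <- fs2 * tan(pi * low_hz / rate_hz)
  w2 <- fs2 * tan(pi * high_hz / rate_hz)
  w0sq <- w1 * w2
  bw <- w2 - w1
  # prototype poles on the unit circle, left half-plane
  k <- seq_len(m)
  p_lp <- exp(1i * pi * (2 * k + m - 1) / (2 * m))
  # low-pass -> band-pass: each prototype pole yields two s-plane poles
  disc <- sqrt((bw * p_lp)^2 - 4 * w0sq + 0i)
  s_poles <- c((bw * p_lp + disc) / 2, (bw * p_lp - disc) / 2)
  # bilinear transform
  z_poles <- (fs2 + s_poles) / (fs2 - s_poles)
  if (any(Mod(z_poles) >= 1 - 1e-12))
    tl_stop("filter-design-error", "unstable design at the given rate")
  # group into conjugate pairs; real poles (possible for odd prototype
  # contributions) are paired among themselves
  pos <- z_poles[Im(z_poles) > 1e-10]
  realp <- Re(z_poles[abs(Im(z_poles)) <= 1e-10])
  sections <- list()
  for (p in pos)
    sections[[length(sections) + 1L]] <- c(1, -2 * Re(p), Mod(p)^2)
  if (length(realp) >= 2) {
    realp <- sort(realp)
    for (i in seq(1, length(realp) - 1, by = 2))
      sections[[length(sections) + 1L]] <-
        c(1, -(realp[i] + realp[i + 1]), realp[i] * realp[i + 1])
  }
  if (length(sections) != m)
    tl_stop("filter-design-error", "pole pairing failed")
  # order sections by pole radius (most damped first)
  rad <- vapply(sections, function(a) sqrt(max(a[3], 0)), 0)
  sections <- sections[order(rad)]
  # each section carries one zero at z=1 and one at z=-1: b = (1, 0, -1)
  sos <- t(vapply(sections, function(a) c(1, 0, -1, a), numeric(6)))
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  # normalize to unit gain at the (warped) center frequency
  f0 <- atan(sqrt(w0sq) / fs2) * rate_hz / pi  # analog center mapped to digital Hz
  h0 <- abs(sos_response(sos, f0, rate_hz))
  g <- (1 / h0)^(1 / m)
  sos[, 1:3] <- sos[, 1:3] * g
  sos
}

#' Butterworth high-pass design in second-order sections
#'
#' Used for the EMG/accelerometer envelope (movement labeling), where slow
#' drift and gravity must be removed before rectification.
#'
#' @param cut_hz corner frequency in Hz.
#' @param order filter order (even).
#' @param rate_hz sampling rate in Hz.
#' @return SOS coefficient matrix as in [butter_bandpass_sos()].
#' @export
butter_highpass_sos <- function(cut_hz, order = 4, rate_hz = 2048) {
  if (order %% 2 != 0 || order < 2)
    tl_stop("filter-design-error", "order must be even and >= 2")
  if (!(cut_hz > 0 && cut_hz < rate_hz / 2))
    tl_stop("filter-design-error", "cut_hz must lie in (0, rate/2)")
  m <- order / 2
  fs2 <- 2 * rate_hz
  wc <- fs2 * tan(pi * cut_hz / rate_hz)
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  s_poles <- wc / p_lp                  # LP -> HP: s -> wc / s
  z_poles <- (fs2 + s_poles) / (fs2 - s_poles)
  if (any(Mod(z_poles) >= 1 - 1e-12))
    tl_stop("filter-design-error", "unstable design at the given rate")
  pos <- z_poles[Im(z_poles) > 1e-10]
  sections <- lapply(pos, function(p) c(1, -2 * Re(p), Mod(p)^2))
  # zeros all at z = +1: b = (1, -2, 1)
  sos <- t(vapply(sections, function(a) c(1, -2, 1, a), numeric(6)))
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  hN <- abs(sos_response(sos, rate_hz / 2, rate_hz))
  g <- (1 / hN)^(1 / nrow(sos))
  sos[, 1:3] <- sos[, 1:3] * g
  sos
}

#' Frequency response of a second-order-section cascade
#'
#' Evaluates the transfer function on the unit circle; the analytic
#' reference for steady-state gain tests.
#'
#' @param sos SOS matrix (rows `b0 b1 b2 a0 a1 a2`).
#' @param f_hz frequencies at which to evaluate, in Hz.
#' @param rate_hz sampling rate in Hz.
#' @return Complex response, same length as `f_hz`.
#' @export
sos_response <- function(sos, f_hz, rate_hz) {
  z1 <- exp(-1i * 2 * pi * f_hz / rate_hz)
  h <- rep(1 + 0i, length(f_hz))
  for (i in seq_len(nrow(sos))) {
    co <- unname(sos[i, ])
    num <- co[1] + co[2] * z1 + co[3] * z1^2
    den <- co[4] + co[5] * z1 + co[6] * z1^2
    h <- h * num / den
  }
  h
}

new_sos_state <- function(sos) matrix(0, nrow = nrow(sos), ncol = 4)

#' Causal SOS filtering with carried state
#'
#' Filters a signal chunk through the biquad cascade, optionally resuming
#' from the state returned by a previous call; filtering a signal in chunks
#' is then sample-exact equal to filtering it whole. This is the streaming
#' primitive the real-time loop is built on.
#'
#' @param sos SOS matrix.
#' @param x numeric vector (one channel).
#' @param state state matrix from a previous call, or `NULL` to start from
#'   rest (zero initial conditions).
#' @return list with `y` (filtered chunk) and `state` (to pass to the next
#'   call).
#' @export
sos_filter_chunk <- function(sos, x, state = NULL) {
  if (is.null(state)) state <- new_sos_state(sos)
  y <- x
  for (i in seq_len(nrow(sos))) {
    b <- sos[i, 1:3]; a <- sos[i, 4:6]
    xin <- y
    y <- as.numeric(signal::filter(b, a, xin,
                                   init.x = state[i, 1:2],
                                   init.y = state[i, 3:4]))
    n <- length(xin)
    if (n >= 2) {
      state[i, ] <- c(xin[n - 1], xin[n], y[n - 1], y[n])
    } else if (n == 1) {
      state[i, ] <- c(state[i, 2], xin[1], state[i, 4], y[1])
    }
  }
  list(y = y, state = state)
}

#' Apply a SOS cascade to a whole vector
#' @inheritParams sos_filter_chunk
#' @return Filtered numeric vector.
#' @export
sos_filter <- function(sos, x) sos_filter_chunk(sos, x)$y

#' Bipolar montage from monopolar contacts
#'
#' Differences of adjacent channels (contact i minus contact i+1),
#' rejecting common-mode signal. Recordings made in differential bipolar
#' mode do not need this; it is provided for monopolar inputs.
#'
#' @param x a [timeseries()] with >= 2 channels.
#' @return A [timeseries()] with `n_channels - 1` channels labelled
#'   `"<a>-<b>"`.
#' @export
bipolar_montage <- function(x) {
  if (n_channels(x) < 2L)
    tl_stop("invalid-timeseries", "montage needs at least 2 channels")
  i <- seq_len(n_channels(x) - 1L)
  out <- x$samples[i, , drop = FALSE] - x$samples[i + 1L, , drop = FALSE]
  timeseries(out, x$rate_hz,
             paste0(x$channel_labels[i], "-", x$channel_labels[i + 1L]),
             x$units[i])
}

#' Causal band-pass filtering of a multichannel series
#'
#' Forward-only Butterworth band-pass in second-order sections, applied per
#' channel independently from zero initial conditions. The start-up
#' transient is excluded downstream via warm-up flags on the frame grid,
#' not by backward filtering, preserving causality.
#'
#' @param x a [timeseries()].
#' @param spec a [filter_spec()].
#' @return Filtered [timeseries()] with the same shape.
#' @export
bandpass_causal <- function(x, spec = filter_spec()) {
  if (!inherits(x, "timeseries"))
    tl_stop("invalid-timeseries", "x must be a timeseries")
  if (x$rate_hz <= 2 * spec$high_hz)
    tl_stop("filter-design-error",
            "sampling rate must exceed twice the upper band edge")
  sos <- butter_bandpass_sos(spec$low_hz, spec$high_hz, spec$order, x$rate_hz)
  out <- x$samples
  for (i in seq_len(nrow(out))) out[i, ] <- sos_filter(sos, out[i, ])
  timeseries(out, x$rate_hz, x$channel_labels, x$units)
}
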