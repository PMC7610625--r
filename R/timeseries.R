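#' Multichannel uniformly sampled time series
#'
#' The universal carrier for LFP, accelerometer and EMG signals. Samples are
#' stored channel-major (one row per channel). All channels share one
#' sampling rate and length.
#'
#' @param samples numeric matrix, `n_channels x n_samples`, or a numeric
#'   vector for a single channel.
#' @param rate_hz sampling rate in Hz (default 2048, the acquisition rate of
#'   the recording chain this package models).
#' @param channel_labels character vector of channel names; defaults to
#'   `"ch1"..`.
#' @param units character, one per channel (recycled if scalar); by
#'   convention `"uV"` for LFP/EMG and `"g"` for accelerometer channels.
#' @return An object of class `timeseries`.
#' @export
timeseries <- function(samples, rate_hz = 2048,
                       channel_labels = NULL, units = "uV") {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    tl_stop("invalid-timeseries", "samples must be a numeric matrix")
  if (anyNA(samples) || any(!is.finite(samples)))
    tl_stop("invalid-timeseries", "samples contain NA or non-finite values")
  if (!is_scalar_number(rate_hz) || rate_hz <= 0)
    tl_stop("invalid-timeseries", "rate_hz must be a positive number")
  nch <- nrow(samples)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nch))
  if (length(channel_labels) != nch)
    tl_stop("invalid-timeseries", "channel_labels length != n_channels")
  units <- rep_len(units, nch)
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, rate_hz = as.numeric(rate_hz),
         channel_labels = as.character(channel_labels), units = units),
    class = "timeseries"
  )
}

#' @export
print.timeseries <- function(x, ...) {
  cat(sprintf("<timeseries> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              n_channels(x), n_samples(x), x$rate_hz, ts_duration(x)))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname timeseries
#' @param x a `timeseries`.
#' @export
n_channels <- function(x) nrow(x$samples)

#' @rdname timeseries
#' @export
n_samples <- function(x) ncol(x$samples)

#' @rdname timeseries
#' @export
ts_duration <- function(x) n_samples(x) / x$rate_hz

#' Series of values on the controller frame grid
#'
#' One value per 100 ms controller update interval (frame k covers the
#' half-open interval `[k*frame_s, (k+1)*frame_s)` from session start).
#'
#' @param values numeric vector, one value per frame.
#' @param frame_s frame duration in seconds; 0.1 matches the 10 Hz decoder
#'   update rate.
#' @return Object of class `frameseries`.
#' @export
frameseries <- function(values, frame_s = 0.1) {
  if (!is.numeric(values))
    tl_stop("invalid-frameseries", "values must be numeric")
  if (!is_scalar_number(frame_s) || frame_s <= 0)
    tl_stop("invalid-frameseries", "frame_s must be positive")
  structure(list(values = as.numeric(values), frame_s = frame_s),
            class = "frameseries")
}

#' @export
print.frameseries <- function(x, ...) {
  cat(sprintf("<frameseries> %d frames @ %g s (%.1f s)\n",
              length(x$values), x$frame_s, length(x$values) * x$frame_s))
  invisible(x)
}

#' Number of whole frames spanned by a duration
#' @param duration_s duration in seconds.
#' @param frame_s frame length in seconds.
#' @export
n_frames <- function(duration_s, frame_s = 0.1) {
  # floor with a guard against representation error (e.g. 60/0.1)
  as.integer(floor(duration_s / frame_s + 1e-9))
}

#' Motor states distinguished by the protocol and the decoder
#'
#' `REST`: no voluntary movement, no tremor-provoking posture.
#' `MOVE`: self-paced voluntary movement (e.g. pegboard, pouring).
#' `POSTURE`: sustained tremor-provoking posture (arms raised).
#' @export
MOTOR_STATES <- c("REST", "MOVE", "POSTURE")

#' Block-structured session protocol
#'
#' @param blocks data.frame with columns `state` (one of
#'   [MOTOR_STATES]) and `duration_s` (positive seconds).
#' @param task which task the session exercises, `"movement"` or
#'   `"posture"`.
#' @return Object of class `session_protocol`.
#' @export
session_protocol <- function(blocks, task = c("movement", "posture")) {
  task <- match.arg(task)
  if (!is.data.frame(blocks) || !all(c("state", "duration_s") %in% names(blocks)))
    tl_stop("invalid-protocol", "blocks must have columns state, duration_s")
  if (!all(blocks$state %in% MOTOR_STATES))
    tl_stop("invalid-protocol", "unknown motor state in protocol")
  if (any(!is.finite(blocks$duration_s)) || any(blocks$duration_s <= 0))
    tl_stop("invalid-protocol", "block durations must be positive")
  structure(list(blocks = data.frame(state = as.character(blocks$state),
                                     duration_s = as.numeric(blocks$duration_s),
                                     stringsAsFactors = FALSE),
                 task = task),
            class = "session_protocol")
}

#' @rdname session_protocol
#' @param x a `session_protocol`.
#' @export
protocol_duration <- function(x) sum(x$blocks$duration_s)

#' Per-frame motor state implied by a protocol
#'
#' @param protocol a [session_protocol()].
#' @param frame_s frame length in seconds.
#' @return character vector of states, one per frame.
#' @export
protocol_states <- function(protocol, frame_s = 0.1) {
  nf <- n_frames(protocol_duration(protocol), frame_s)
  t_mid <- (seq_len(nf) - 0.5) * frame_s
  edges <- cumsum(protocol$blocks$duration_s)
  idx <- findInterval(t_mid, c(0, edges), rightmost.closed = FALSE,
                      left.open = TRUE)
  idx[idx > nrow(protocol$blocks)] <- nrow(protocol$blocks)
  protocol$blocks$state[idx]
}

#' Per-frame protocol block index
#'
#' Used to build leakage-free block-wise cross-validation folds.
#' @inheritParams protocol_states
#' @return integer vector, one block id per frame.
#' @export
protocol_block_index <- function(protocol, frame_s = 0.1) {
  nf <- n_frames(protocol_duration(protocol), frame_s)
  t_mid <- (seq_len(nf) - 0.5) * frame_s
  edges <- cumsum(protocol$blocks$duration_s)
  idx <- findInterval(t_mid, c(0, edges), left.open = TRUE)
  idx[idx > nrow(protocol$blocks)] <- nrow(protocol$blocks)
  as.integer(idx)
}

#' Aligned multimodal recording session
#'
#' Bundles bipolar LFP, triaxial accelerometer and EMG signals with the
#' stimulation amplitude trace (on the frame grid), optional ground-truth
#' motor states (synthetic sessions), and the protocol.
#'
#' @param lfp,accel,emg [timeseries()] objects (accel/emg may be `NULL` for
#'   deploy-mode sessions without label sources).
#' @param stim_trace [frameseries()] of stimulation amplitude in volts.
#' @param truth_states optional character vector of per-frame
#'   [MOTOR_STATES].
#' @param protocol optional [session_protocol()].
#' @param extras named list of auxiliary frame series (e.g. the generator's
#'   ground-truth tremor envelope).
#' @return Object of class `session_recording`.
#' @export
session_recording <- function(lfp, accel = NULL, emg = NULL,
                              stim_trace = NULL, truth_states = NULL,
                              protocol = NULL, extras = list()) {
  if (!inherits(lfp, "timeseries"))
    tl_stop("invalid-session", "lfp must be a timeseries")
  if (n_samples(lfp) == 0L)
    tl_stop("invalid-session", "zero-length session")
  dur <- ts_duration(lfp)
  frame_s <- if (is.null(stim_trace)) 0.1 else stim_trace$frame_s
  for (nm in c("accel", "emg")) {
    s <- get(nm)
    if (!is.null(s)) {
      if (!inherits(s, "timeseries"))
        tl_stop("invalid-session", paste(nm, "must be a timeseries"))
      if (abs(ts_duration(s) - dur) > frame_s)
        tl_stop("invalid-session",
                paste(nm, "duration differs from lfp by more than one frame"))
    }
  }
  nf <- n_frames(dur, frame_s)
  if (is.null(stim_trace)) stim_trace <- frameseries(numeric(nf), frame_s)
  if (length(stim_trace$values) != nf)
    tl_stop("invalid-session", "stim_trace length does not match duration")
  if (any(stim_trace$values < 0))
    tl_stop("invalid-session", "stim_trace amplitudes must be >= 0")
  if (!is.null(truth_states)) {
    truth_states <- as.character(truth_states)
    if (length(truth_states) != nf)
      tl_stop("invalid-session", "truth_states length does not match frames")
    if (!all(truth_states %in% MOTOR_STATES))
      tl_stop("invalid-session", "unknown state in truth_states")
  }
  structure(list(lfp = lfp, accel = accel, emg = emg,
                 stim_trace = stim_trace, truth_states = truth_states,
                 protocol = protocol, extras = extras),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %.1f s @ %g Hz\n",
              ts_duration(x$lfp), x$lfp$rate_hz))
  cat(sprintf("  lfp: %d ch | accel: %s | emg: %s | %d frames\n",
              n_channels(x$lfp),
              if (is.null(x$accel)) "none" else paste0(n_channels(x$accel), " ch"),
              if (is.null(x$emg)) "none" else paste0(n_channels(x$emg), " ch"),
              length(x$stim_trace$values)))
  if (!is.null(x$protocol))
    cat(sprintf("  protocol: %s, %d blocks\n", x$protocol$task,
                nrow(x$protocol$blocks)))
  invisible(x)
}
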