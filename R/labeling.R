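#' Exact 1-D two-means clustering
#'
#' Deterministic k=2 clustering of scalar values: sort, scan all split
#' points, minimize within-cluster sum of squares with prefix sums. Used
#' for data-driven label thresholds (no random restarts, no RNG).
#'
#' @param x numeric vector (length >= 2).
#' @return list with `centers` (sorted, length 2) and `threshold` (their
#'   midpoint).
#' @export
kmeans2_1d <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  i <- seq_len(n - 1)
  ssl <- cs2[i] - cs[i]^2 / i
  ssr <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i)
  k <- which.min(ssl + ssr)
  c1 <- cs[k] / k
  c2 <- (cs[n] - cs[k]) / (n - k)
  list(centers = c(c1, c2), threshold = (c1 + c2) / 2)
}

#' Apply hysteresis to a raw binary sequence
#'
#' A state flip requires `min_frames` consecutive frames on the other
#' side of threshold; shorter excursions are suppressed. 300 ms (3
#' frames) debounces envelope chatter around threshold.
#'
#' @param raw integer/logical vector of per-frame threshold crossings.
#' @param min_frames minimum run length to flip state.
#' @return Integer vector of debounced labels.
#' @export
apply_hysteresis <- function(raw, min_frames = 3L) {
  raw <- as.integer(raw)
  n <- length(raw)
  if (n == 0L) return(integer(0))
  out <- integer(n)
  state <- 0L
  run <- 0L
  for (k in seq_len(n)) {
    if (raw[k] != state) {
      run <- run + 1L
      if (run >= min_frames) {
        state <- raw[k]
        # the run that caused the flip is relabeled to the new state
        out[(k - run + 1L):k] <- state
        run <- 0L
        next
      }
    } else run <- 0L
    out[k] <- state
  }
  out
}

frame_rms_envelope <- function(x, frames, highpass_hz = 10) {
  sos <- butter_highpass_sos(highpass_hz, 4, x$rate_hz)
  env <- rep(NA_real_, nrow(frames))
  filt <- x$samples
  for (ch in seq_len(nrow(filt))) filt[ch, ] <- sos_filter(sos, filt[ch, ])
  filt <- abs(filt)
  for (k in seq_len(nrow(frames))) {
    if (frames$warmup[k]) next
    env[k] <- sqrt(mean(filt[, frames$start[k]:frames$end[k]]^2))
  }
  env
}

# A unimodal envelope is declared "no contrast" when the two 1-D k-means
# centers are closer than 1% of the observed range *or* closer than
# `min_log_contrast` log units (~ a 1.6x amplitude ratio): windowed RMS
# envelopes of pure noise cluster within a few percent on the log scale,
# far below any genuine rest/task contrast (log(1 + burst gain) >= 0.9
# at the weakest gains this model considers).
label_from_log_values <- function(logv, warmup, min_frames = 3L,
                                  contrast_frac = 0.01,
                                  min_log_contrast = 0.5) {
  ok <- !warmup & is.finite(logv)
  if (sum(ok) < 2L) tl_stop("no-frames", "too few frames to label")
  km <- kmeans2_1d(logv[ok])
  rng <- diff(range(logv[ok]))
  if (rng == 0 || diff(km$centers) < contrast_frac * rng ||
      diff(km$centers) < min_log_contrast) {
    tl_warn("no-contrast", "envelope is unimodal; returning all-zero labels")
    return(list(labels = integer(length(logv)), threshold = NA_real_))
  }
  raw <- as.integer(logv > km$threshold)
  raw[!ok] <- 0L
  list(labels = apply_hysteresis(raw, min_frames), threshold = km$threshold)
}

#' Per-frame binary labels on the controller frame grid
#'
#' @param labels integer vector in {0, 1}.
#' @param source `"accel"`, `"emg"` or `"truth"`.
#' @param task `"movement"`, `"posture"` or `"tremor"`.
#' @param threshold the data-driven threshold used (log scale), `NA` on
#'   the no-contrast path.
#' @param warmup logical per frame.
#' @return Object of class `label_series`.
#' @export
label_series <- function(labels, source, task, threshold = NA_real_,
                         warmup = NULL) {
  if (!all(labels %in% c(0L, 1L)))
    tl_stop("invalid-labels", "labels must be 0/1")
  structure(list(labels = as.integer(labels), source = source, task = task,
                 threshold = threshold,
                 warmup = if (is.null(warmup)) rep(FALSE, length(labels))
                          else warmup),
            class = "label_series")
}

#' Movement/posture labels from EMG (or accelerometer) activity
#'
#' Envelope = per-frame RMS of the 10 Hz high-passed, rectified signal;
#' threshold = midpoint of the two cluster centers of exact 2-means on
#' the log envelope; 300 ms hysteresis. Thresholding on the log scale
#' makes the labels invariant to overall signal gain.
#'
#' @param x a [timeseries()] (EMG preferred; accelerometer accepted).
#' @param frames a [frame_signal()] index on the source signal.
#' @param task `"movement"` or `"posture"`.
#' @param min_frames hysteresis run length (default 3 frames = 300 ms).
#' @return A [label_series()].
#' @export
movement_labels <- function(x, frames, task = "movement", min_frames = 3L) {
  env <- frame_rms_envelope(x, frames)
  lv <- log(pmax(env, 1e-300))
  res <- label_from_log_values(lv, frames$warmup, min_frames)
  label_series(res$labels, source = "emg", task = task,
               threshold = res$threshold, warmup = frames$warmup)
}

#' Tremor labels and continuous tremor-intensity target
#'
#' Per-frame 3-7 Hz band power of the accelerometer (periodogram of the
#' trailing window, summed across axes); binary label = power above the
#' 2-means threshold on log power with hysteresis; the continuous power
#' is returned as the regression target.
#'
#' @param accel triaxial accelerometer [timeseries()].
#' @param frames a [frame_signal()] index.
#' @param band tremor band in Hz.
#' @param min_frames hysteresis run length.
#' @return list with `labels` (a [label_series()]) and `target` (class
#'   `tremor_target`: nonnegative per-frame band power, `NA` in
#'   warm-up).
#' @export
tremor_labels <- function(accel, frames, band = c(3, 7), min_frames = 3L) {
  pow <- frame_band_power(accel, frames, band)
  lv <- log(pmax(pow, 1e-300))
  res <- label_from_log_values(lv, frames$warmup, min_frames)
  target <- structure(list(power = pow, frame_s = attr(frames, "frame_s")),
                      class = "tremor_target")
  list(labels = label_series(res$labels, source = "accel", task = "tremor",
                             threshold = res$threshold,
                             warmup = frames$warmup),
       target = target)
}

#' Binary labels from a session's ground-truth states
#'
#' @param session a synthetic [session_recording()] with `truth_states`.
#' @param task `"movement"` or `"posture"`; the matching state (MOVE or
#'   POSTURE) maps to 1. `"any"` maps both task states to 1.
#' @return A [label_series()] with source `"truth"`.
#' @export
truth_labels <- function(session, task = c("movement", "posture", "any")) {
  task <- match.arg(task)
  if (is.null(session$truth_states))
    tl_stop("no-truth", "session has no ground-truth states")
  st <- session$truth_states
  lab <- switch(task,
                movement = as.integer(st == "MOVE"),
                posture = as.integer(st == "POSTURE"),
                any = as.integer(st != "REST"))
  label_series(lab, source = "truth", task = task)
}
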