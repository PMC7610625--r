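#' Specification of the per-frame LFP feature set
#'
#' Twelve features per bipolar channel per 100 ms frame, computed on the
#' trailing analysis window: log mean periodogram power in eight bands
#' plus four time-domain statistics (RMS, line length, Hjorth mobility,
#' Hjorth complexity). The default bands cover the state-dependent
#' effects the decoder exploits — theta (posture), alpha, low/high beta
#' (movement/posture desynchronization), low gamma edge, gamma
#' (movement), and two high-frequency bands that carry stimulation
#' artifact and aliased energy (useful because models are trained per
#' stimulation state) — while avoiding 50 Hz mains and its first
#' harmonic.
#'
#' @param bands_hz list of 8 numeric length-2 band edges in Hz.
#' @param log_epsilon floor inside the log of band powers.
#' @return Object of class `feature_spec`.
#' @export
feature_spec <- function(bands_hz = list(c(3, 7), c(8, 12), c(13, 20),
                                         c(21, 30), c(31, 45), c(55, 95),
                                         c(105, 195), c(205, 395)),
                         log_epsilon = 1e-12) {
  if (length(bands_hz) != 8L)
    tl_stop("invalid-feature-spec", "exactly 8 bands are required")
  for (b in bands_hz)
    if (length(b) != 2 || b[1] <= 0 || b[2] <= b[1])
      tl_stop("invalid-feature-spec", "bands must be increasing positive pairs")
  structure(list(bands_hz = bands_hz,
                 time_features = c("rms", "line_length",
                                   "hjorth_mobility", "hjorth_complexity"),
                 log_epsilon = log_epsilon),
            class = "feature_spec")
}

feature_names <- function(spec, channel_labels) {
  base <- c(vapply(spec$bands_hz,
                   function(b) sprintf("bp%g_%g", b[1], b[2]), ""),
            spec$time_features)
  as.vector(vapply(channel_labels,
                   function(ch) paste0("f", base, "_", ch),
                   character(12)))
}

hjorth <- function(w) {
  v0 <- mean(w^2) - mean(w)^2
  d1 <- diff(w); d2 <- diff(d1)
  v1 <- mean(d1^2) - mean(d1)^2
  v2 <- mean(d2^2) - mean(d2)^2
  if (v0 <= 0 || v1 <= 0) return(c(0, 0))
  mob <- sqrt(v1 / v0)
  c(mob, sqrt(v2 / v1) / mob)
}

window_features <- function(w, rate_hz, spec) {
  pg <- periodogram(w, rate_hz)
  bp <- vapply(spec$bands_hz, function(b)
    log(spec$log_epsilon + band_power(pg, b)), 0)
  c(bp, sqrt(mean(w^2)), sum(abs(diff(w))), hjorth(w))
}

#' Extract the 12-per-channel feature matrix
#'
#' One row per frame, `12 * n_channels` columns (channels concatenated).
#' Warm-up frames are `NA` and flagged in the `warmup` attribute.
#'
#' @param x a [timeseries()] of (preprocessed) bipolar LFPs.
#' @param frames a [frame_signal()] index over `x`.
#' @param spec a [feature_spec()].
#' @return Object of class `feature_matrix`: numeric matrix with
#'   attributes `warmup` (logical per frame), `frame_s` and
#'   `feature_names` as column names.
#' @export
extract_features <- function(x, frames, spec = feature_spec()) {
  rate <- x$rate_hz
  for (b in spec$bands_hz)
    if (b[2] >= rate / 2)
      tl_stop("band-out-of-range", "feature band reaches Nyquist")
  nf <- nrow(frames)
  nch <- n_channels(x)
  out <- matrix(NA_real_, nf, 12L * nch)
  colnames(out) <- feature_names(spec, x$channel_labels)
  for (k in seq_len(nf)) {
    if (frames$warmup[k]) next
    sl <- frames$start[k]:frames$end[k]
    for (ch in seq_len(nch))
      out[k, ((ch - 1L) * 12L + 1L):(ch * 12L)] <-
        window_features(x$samples[ch, sl], rate, spec)
  }
  attr(out, "warmup") <- frames$warmup
  attr(out, "frame_s") <- attr(frames, "frame_s")
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Compute features for a single trailing window
#'
#' The incremental form used by the real-time loop: features for one
#' frame's window across channels.
#'
#' @param w numeric matrix `n_channels x window_n`.
#' @param rate_hz sampling rate.
#' @param spec a [feature_spec()].
#' @return Numeric vector of length `12 * n_channels`.
#' @export
extract_features_window <- function(w, rate_hz, spec = feature_spec()) {
  as.vector(vapply(seq_len(nrow(w)), function(ch)
    window_features(w[ch, ], rate_hz, spec), numeric(12)))
}

#' Write / read a feature matrix as TSV
#'
#' One row per frame with a `frame` column and the
#' `f<band|stat>_<channel>` feature columns; warm-up frames are written
#' with empty cells.
#'
#' @param features an [extract_features()] matrix.
#' @param path file path.
#' @export
write_features <- function(features, path) {
  df <- data.frame(frame = seq_len(nrow(features)), features,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "frame"), drop = FALSE])
  attr(m, "warmup") <- !stats::complete.cases(m)
  class(m) <- c("feature_matrix", class(m))
  m
}

#' Fit per-column normalization statistics
#'
#' Mean and standard deviation per feature column over non-warm-up
#' training frames. SDs are floored at `eps` so constant columns
#' normalize to zero rather than dividing by zero.
#'
#' @param features a [extract_features()] matrix (rows with `NA` are
#'   ignored).
#' @param eps SD floor.
#' @return Object of class `feature_norm` with `mean` and `sd`.
#' @export
fit_normalizer <- function(features, eps = 1e-12) {
  ok <- stats::complete.cases(features)
  if (sum(ok) < 2L) tl_stop("no-frames", "need >= 2 complete frames")
  m <- colMeans(features[ok, , drop = FALSE])
  s <- apply(features[ok, , drop = FALSE], 2, sd)
  s[!is.finite(s) | s < eps] <- eps
  structure(list(mean = m, sd = s), class = "feature_norm")
}

#' Apply normalization statistics to a feature matrix
#'
#' @param features feature matrix (or single feature vector).
#' @param norm a [fit_normalizer()] result.
#' @return Matrix (or vector) of z-scored features.
#' @export
apply_normalizer <- function(features, norm) {
  if (is.null(dim(features)))
    return((features - norm$mean) / norm$sd)
  out <- sweep(features, 2, norm$mean, "-")
  out <- sweep(out, 2, norm$sd, "/")
  # constant columns (SD floored): force exact zero, not tiny residue / eps
  const <- norm$sd <= 1e-12
  if (any(const)) {
    resid <- abs(sweep(features[, const, drop = FALSE], 2,
                       norm$mean[const], "-"))
    z <- out[, const, drop = FALSE]
    z[resid < 1e-9] <- 0
    out[, const] <- z
  }
  out
}
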