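#' Frame-wise confusion metrics
#'
#' Rates as percentages of frames: accuracy over all supplied frames,
#' TPR over truth-positive frames, FPR over truth-negative frames, and
#' FNR = 100 - TPR (an identity, not an independent count). Warm-up
#' frames should be excluded by the caller.
#'
#' @param detection 0/1 per-frame detections (or stimulation-on
#'   indicator).
#' @param truth 0/1 per-frame truth (a [label_series()] is accepted).
#' @return list with `accuracy`, `tpr`, `fpr`, `fnr` (percent).
#' @export
confusion_metrics <- function(detection, truth) {
  if (inherits(truth, "label_series")) truth <- truth$labels
  if (inherits(detection, "frameseries")) detection <- detection$values
  detection <- as.integer(detection > 0)
  truth <- as.integer(truth > 0)
  if (length(detection) != length(truth))
    tl_stop("grid-mismatch", "detection and truth differ in length")
  npos <- sum(truth == 1L)
  if (npos == 0L)
    tl_stop("no-positives", "no truth-positive frames; TPR/FNR undefined")
  tpr <- 100 * sum(detection == 1L & truth == 1L) / npos
  nneg <- sum(truth == 0L)
  fpr <- if (nneg == 0L) NA_real_
         else 100 * sum(detection == 1L & truth == 0L) / nneg
  list(accuracy = 100 * mean(detection == truth),
       tpr = tpr, fpr = fpr, fnr = 100 - tpr)
}

#' Durations of false-negative episodes
#'
#' Maximal runs of frames where the truth is positive but the detection
#' (stimulation) is off; these are the intervals when stimulation was
#' wrongly withheld during movement.
#'
#' @inheritParams confusion_metrics
#' @param frame_s frame duration in seconds.
#' @return Numeric vector of episode durations in seconds (possibly
#'   empty).
#' @export
fn_episodes <- function(detection, truth, frame_s = 0.1) {
  if (inherits(truth, "label_series")) truth <- truth$labels
  if (inherits(detection, "frameseries")) detection <- detection$values
  fn <- as.integer(truth > 0 & !(detection > 0))
  r <- rle(fn)
  r$lengths[r$values == 1L] * frame_s
}

#' Mean tremor-band power over selected frames
#'
#' Mean over the selected frames of the per-frame 3-7 Hz accelerometer
#' band power (same periodogram estimator as the feature and labeling
#' paths).
#'
#' @param accel triaxial accelerometer [timeseries()].
#' @param frames a [frame_signal()] index.
#' @param select logical or integer frame selection (default: all
#'   non-warm-up frames).
#' @param band band in Hz.
#' @return Scalar mean band power.
#' @export
tremor_power <- function(accel, frames, select = NULL, band = c(3, 7)) {
  pow <- frame_band_power(accel, frames, band)
  keep <- !frames$warmup
  if (!is.null(select)) {
    sel <- rep(FALSE, nrow(frames))
    sel[select] <- TRUE
    keep <- keep & sel
  }
  if (!any(keep)) tl_stop("no-frames", "no frames selected")
  mean(pow[keep])
}

#' Delivered-energy index of a closed-loop run
#'
#' `sum over frames of [state == on] * amplitude^2 * f_stim * (2 *
#' pulse_us * 1e-6) * frame_s` — proportional to the delivered electrical
#' energy for a fixed electrode impedance (the constant impedance factor
#' cancels in the A-DBS/C-DBS ratios that are reported).
#'
#' @param trace a [run_closed_loop()] result (or its `trace`
#'   data.frame).
#' @param stim a [stim_params()].
#' @param frame_s frame duration in seconds.
#' @return Nonnegative scalar index.
#' @export
energy_index <- function(trace, stim = stim_params(), frame_s = 0.1) {
  tr <- if (inherits(trace, "closed_loop_trace")) trace$trace else trace
  on <- tr$state == "on"
  sum(tr$amplitude_v[on]^2) * stim$freq_hz *
    (2 * stim$pulse_us * 1e-6) * frame_s
}

#' Percent tremor suppression relative to the unstimulated condition
#'
#' @param p_cond mean tremor power under the stimulated condition.
#' @param p_nodbs mean tremor power without stimulation.
#' @return `100 * (p_nodbs - p_cond) / p_nodbs`.
#' @export
suppression_pct <- function(p_cond, p_nodbs) {
  if (p_nodbs == 0)
    tl_stop("undefined-suppression", "no-DBS tremor power is zero")
  100 * (p_nodbs - p_cond) / p_nodbs
}

#' Trigger latency of a decoder at a matched true-positive rate
#'
#' Sweeps the decision threshold over the observed scores, picks the one
#' whose frame-wise TPR is closest to `matched_tpr` (ties favour the
#' lower threshold, i.e. the more sensitive setting), then measures per
#' trial the time from movement onset to the first supra-threshold
#' frame inside the trial. Negative latencies mean anticipation.
#'
#' @param scores per-frame decoder scores (`NA` allowed in warm-up).
#' @param truth 0/1 frames defining the decoder's own positive class
#'   (used for the TPR sweep).
#' @param trials data.frame with `onset` and `end` frame indices
#'   (1-based, inclusive), one row per movement trial.
#' @param matched_tpr target TPR as a fraction.
#' @param frame_s frame duration in seconds.
#' @param tol largest acceptable |TPR - matched_tpr|.
#' @return list with `threshold`, `tpr`, `latency_s` (per trial; `NA`
#'   when the trial has no detection) and `mean_latency_s`.
#' @export
trigger_latency <- function(scores, truth, trials, matched_tpr = 0.8,
                            frame_s = 0.1, tol = 0.1) {
  if (inherits(truth, "label_series")) truth <- truth$labels
  ok <- !is.na(scores)
  pos <- ok & truth > 0
  if (!any(pos)) tl_stop("no-positives", "no positive frames")
  cand <- sort(unique(scores[ok]))
  tprs <- vapply(cand, function(th) mean(scores[pos] > th), 0)
  gap <- abs(tprs - matched_tpr)
  if (min(gap) > tol)
    tl_stop("tpr-unreachable",
            sprintf("closest achievable TPR is %.2f from target",
                    min(gap) + matched_tpr * 0))
  best <- which(gap == min(gap))
  th <- cand[min(best)]                   # ties -> lower threshold
  lat <- rep(NA_real_, nrow(trials))
  for (i in seq_len(nrow(trials))) {
    win <- trials$onset[i]:trials$end[i]
    hit <- win[!is.na(scores[win]) & scores[win] > th]
    if (length(hit)) lat[i] <- (hit[1] - trials$onset[i]) * frame_s
  }
  list(threshold = th, tpr = tprs[min(best)], latency_s = lat,
       mean_latency_s = mean(lat, na.rm = TRUE))
}

#' Movement-decoder vs tremor-decoder anticipation comparison
#'
#' Both decoders are evaluated on the same sessions with thresholds
#' chosen to match their true-positive rates; the movement decoder is
#' expected to trigger earlier (anticipating tremor, which develops with
#' a delay after task onset).
#'
#' @param movement,tremor lists with `scores` and `truth` (each
#'   decoder's own positive class) on a common frame grid.
#' @param trials data.frame of `onset`/`end` frame indices of the task
#'   trials (>= 3 rows).
#' @param matched_tpr matched TPR (fraction).
#' @param frame_s frame duration.
#' @return list with per-decoder [trigger_latency()] results and the
#'   paired latency differences (movement - tremor) over trials where
#'   both decoders triggered.
#' @export
anticipation_latency <- function(movement, tremor, trials,
                                 matched_tpr = 0.8, frame_s = 0.1) {
  if (nrow(trials) < 3L)
    tl_stop("too-few-trials", "need >= 3 movement onsets")
  lm <- trigger_latency(movement$scores, movement$truth, trials,
                        matched_tpr, frame_s)
  lt <- trigger_latency(tremor$scores, tremor$truth, trials,
                        matched_tpr, frame_s)
  diffs <- lm$latency_s - lt$latency_s
  list(movement = lm, tremor = lt,
       paired_diff_s = diffs[!is.na(diffs)],
       mean_diff_s = mean(diffs, na.rm = TRUE))
}

#' Paired t test on per-session values
#'
#' Thin wrapper over [stats::t.test()] with the degenerate
#' (zero-variance-difference) case guarded.
#'
#' @param values_a,values_b equal-length numeric vectors (n >= 2).
#' @return list with `t`, `df`, `p`.
#' @export
paired_compare <- function(values_a, values_b) {
  if (length(values_a) != length(values_b) || length(values_a) < 2L)
    tl_stop("degenerate-pairs", "need equal-length vectors, n >= 2")
  d <- values_a - values_b
  if (sd(d) < 1e-12) {
    if (all(abs(d) < 1e-12)) return(list(t = 0, df = length(d) - 1, p = 1))
    tl_stop("degenerate-pairs", "differences have zero variance")
  }
  tt <- t.test(values_a, values_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Full metrics report for a three-condition closed-loop experiment
#'
#' Computes the decoding confusion rates of the adaptive run against
#' ground truth, false-negative episode durations, mean tremor power
#' per condition, percent suppression, delivered-energy indices and the
#' A-DBS/C-DBS energy ratio.
#'
#' @param nodbs,adbs,cdbs [run_closed_loop()] results on the same core
#'   (same seed and configuration, different controller modes).
#' @param truth_task which truth states count as positive (see
#'   [truth_labels()]).
#' @return list of class `metrics_report`.
#' @export
closed_loop_metrics <- function(nodbs, adbs, cdbs, truth_task = "any") {
  keep <- !adbs$trace$warmup
  truth <- truth_labels(adbs$session, truth_task)$labels
  conf <- confusion_metrics(as.integer(adbs$trace$state == "on")[keep],
                            truth[keep])
  fne <- fn_episodes(as.integer(adbs$trace$state == "on")[keep],
                     truth[keep])
  p <- vapply(list(nodbs = nodbs, adbs = adbs, cdbs = cdbs), function(r)
    mean(r$trace$tremor_power[!r$trace$warmup]), 0)
  e <- vapply(list(nodbs = nodbs, adbs = adbs, cdbs = cdbs), function(r)
    energy_index(r, r$stim), 0)
  structure(list(
    accuracy = conf$accuracy, tpr = conf$tpr, fpr = conf$fpr,
    fnr = conf$fnr,
    fn_episode_durations_s = fne,
    tremor_power = as.list(p),
    suppression_pct = list(adbs = suppression_pct(p[["adbs"]], p[["nodbs"]]),
                           cdbs = suppression_pct(p[["cdbs"]], p[["nodbs"]])),
    energy_index = as.list(e),
    energy_ratio_pct = 100 * e[["adbs"]] / e[["cdbs"]]),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Closed-loop evaluation\n")
  cat(sprintf("  accuracy %.2f%%  TPR %.2f%%  FPR %.2f%%  FNR %.2f%%\n",
              x$accuracy, x$tpr, x$fpr, x$fnr))
  if (length(x$fn_episode_durations_s))
    cat(sprintf("  mean FN episode %.3f s (n = %d)\n",
                mean(x$fn_episode_durations_s),
                length(x$fn_episode_durations_s)))
  cat(sprintf("  tremor suppression: A-DBS %.2f%%, C-DBS %.2f%%\n",
              x$suppression_pct$adbs, x$suppression_pct$cdbs))
  cat(sprintf("  delivered energy: A-DBS %.2f%% of C-DBS\n",
              x$energy_ratio_pct))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param report a [closed_loop_metrics()] result (or any list).
#' @param path output file.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
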