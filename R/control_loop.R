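#' Controller configuration
#'
#' The stimulation decision runs at the fixed 10 Hz update rate of the
#' frame grid. `mode` selects adaptive (decoder-triggered), continuous,
#' or no stimulation; the latter two ignore the decoder for actuation
#' (scores are still recorded when models are supplied).
#'
#' @param threshold decision threshold on the decoder score, in (0, 1).
#' @param initial_state stimulator state before the first frame.
#' @param mode `"adbs"`, `"cdbs"` or `"nodbs"`.
#' @return Object of class `controller_config`.
#' @export
controller_config <- function(threshold = 0.5,
                              initial_state = c("off", "on"),
                              mode = c("adbs", "cdbs", "nodbs")) {
  initial_state <- match.arg(initial_state)
  mode <- match.arg(mode)
  if (!(threshold > 0 && threshold < 1))
    tl_stop("invalid-controller", "threshold must lie in (0, 1)")
  structure(list(update_hz = 10, threshold = threshold,
                 initial_state = initial_state, mode = mode),
            class = "controller_config")
}

#' One step of the on/off stimulation controller
#'
#' The raw state-flipping rule: a positive detection switches (or keeps)
#' the stimulator on; a negative detection switches (or keeps) it off.
#' Pure function, no debounce.
#'
#' @param state current stimulator state, `"on"` or `"off"`.
#' @param detection 0/1 decoder detection for this frame.
#' @return The next stimulator state.
#' @export
controller_step <- function(state, detection) {
  if (detection == 1) "on" else "off"
}

#' Pick the decoder matching task and stimulator state
#'
#' In the closed loop the model is selected by the stimulator state at
#' the *previous* frame — the one-frame model-selection lag that is the
#' loop's only delay.
#'
#' @param models a `decoder_bundle` (or named list with
#'   `"<task>.<state>"` entries).
#' @param task `"movement"` or `"posture"`.
#' @param stim_state `"on"` or `"off"`.
#' @return The matching [train_decoder()] model.
#' @export
select_model <- function(models, task, stim_state) {
  key <- paste(task, stim_state, sep = ".")
  m <- models[[key]]
  if (is.null(m))
    tl_stop("incomplete-grid", paste("no model for cell", key))
  m
}

#' Run the closed-loop simulation
#'
#' The real-time loop: each 100 ms frame of signals is generated under
#' the stimulator state currently in force (stimulation artifact and
#' tremor-suppression dynamics included), filtered causally with carried
#' filter state, featurized from the trailing window, scored by the
#' decoder selected with the previous frame's stimulator state,
#' thresholded, and fed to the controller, whose new state takes effect
#' at the next frame. Deterministic end-to-end given `seed`.
#'
#' @param config a [sim_config()] (its `seed` is overridden by `seed`
#'   when given).
#' @param protocol a [session_protocol()].
#' @param stim a [stim_params()].
#' @param models a `decoder_bundle`; may be `NULL` in `"cdbs"` /
#'   `"nodbs"` modes (scores recorded as `NA`).
#' @param controller a [controller_config()].
#' @param seed integer seed, or `NULL` to use `config$seed`.
#' @param task decoded task; defaults to the protocol's task.
#' @param fspec [filter_spec()] for preprocessing.
#' @param featspec [feature_spec()].
#' @param window_s trailing analysis window (seconds).
#' @return Object of class `closed_loop_trace`: list with `trace` (one
#'   row per frame: `time_s`, `truth`, `score`, `detection`, `state`,
#'   `amplitude_v`, `tremor_power`) and the generated `session`.
#' @export
run_closed_loop <- function(config, protocol, stim = stim_params(),
                            models = NULL,
                            controller = controller_config(),
                            seed = NULL, task = NULL,
                            fspec = filter_spec(),
                            featspec = feature_spec(),
                            window_s = 0.5) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(task)) task <- protocol$task
  if (controller$mode == "adbs" && is.null(models))
    tl_stop("incomplete-grid", "adaptive mode requires a decoder bundle")

  core <- sim_core(config, protocol)
  eng <- sim_engine_new(core, config, stim)
  rate <- core$rate
  nf <- core$nf
  nch <- core$nch
  wn <- as.integer(round(window_s * rate))
  sos <- butter_bandpass_sos(fspec$low_hz, fspec$high_hz, fspec$order, rate)
  filt_state <- lapply(seq_len(nch), function(i) NULL)
  ring <- matrix(0, nch, wn)
  seen <- 0L                       # filtered samples accumulated so far

  lfp <- matrix(0, nch, core$n)
  accel <- matrix(0, 3, core$n)
  emg <- matrix(0, 1, core$n)
  amp_trace <- numeric(nf)
  score <- rep(NA_real_, nf)
  detection <- integer(nf)
  state_trace <- character(nf)
  a_env <- numeric(nf)

  state <- switch(controller$mode,
                  cdbs = "on", nodbs = "off", controller$initial_state)
  prev_state <- state               # stimulator state at the previous frame
  s0 <- 1L
  for (k in seq_len(nf)) {
    amp_k <- if (state == "on") stim$amplitude_v else 0
    stp <- sim_engine_step(eng, k, amp_k)
    eng <- stp$eng
    s1 <- eng$ends[k]
    lfp[, s0:s1] <- stp$lfp
    accel[, s0:s1] <- stp$accel
    emg[, s0:s1] <- stp$emg
    a_env[k] <- stp$a_end

    ns <- s1 - s0 + 1L
    for (ch in seq_len(nch)) {
      fc <- sos_filter_chunk(sos, stp$lfp[ch, ], filt_state[[ch]])
      filt_state[[ch]] <- fc$state
      if (ns >= wn) ring[ch, ] <- tail(fc$y, wn)
      else ring[ch, ] <- c(ring[ch, -(1:ns)], fc$y)
    }
    seen <- seen + ns

    warm <- seen < wn
    if (!warm && !is.null(models)) {
      model <- select_model(models, task, prev_state)
      fv <- extract_features_window(ring, rate, featspec)
      sc <- decoder_score(model, fv)
      score[k] <- sc
      if (controller$mode == "adbs")
        detection[k] <- as.integer(is.finite(sc) && sc > controller$threshold)
    }
    # warm-up frames are scored as no-detection by definition
    state_trace[k] <- state
    amp_trace[k] <- amp_k
    prev_state <- state
    state <- switch(controller$mode,
                    cdbs = "on", nodbs = "off",
                    controller_step(state, detection[k]))
    s0 <- s1 + 1L
  }

  session <- session_recording(
    lfp = timeseries(lfp, rate, paste0("LFP_", seq_len(nch)), "uV"),
    accel = timeseries(accel, rate, c("ACC_X", "ACC_Y", "ACC_Z"), "g"),
    emg = timeseries(emg, rate, "EMG_1", "uV"),
    stim_trace = frameseries(amp_trace, 0.1),
    truth_states = core$frame_states,
    protocol = protocol,
    extras = list(tremor_envelope = frameseries(a_env, 0.1)))

  frames <- frame_signal(session$accel, 0.1, window_s)
  tp <- frame_band_power(session$accel, frames, c(3, 7))
  trace <- data.frame(
    frame = seq_len(nf),
    time_s = (seq_len(nf) - 1) * 0.1,
    truth = core$frame_states,
    score = score,
    detection = detection,
    state = state_trace,
    amplitude_v = amp_trace,
    tremor_power = tp,
    warmup = frames$warmup)
  structure(list(trace = trace, session = session,
                 controller = controller, stim = stim, task = task),
            class = "closed_loop_trace")
}

#' @export
print.closed_loop_trace <- function(x, ...) {
  on_frac <- mean(x$trace$state == "on")
  cat(sprintf("<closed_loop_trace> %s, %d frames, stim on %.1f%% of frames\n",
              x$controller$mode, nrow(x$trace), 100 * on_frac))
  invisible(x)
}
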