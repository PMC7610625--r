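#' Stimulation waveform parameters
#'
#' Defaults follow the clinical settings this package models: 130 Hz
#' biphasic pulses of 60 us per phase with a 20 us interphase gap, and a
#' patient-range amplitude of 1-3 V (mean 1.95 V).
#'
#' @param freq_hz pulse repetition rate in Hz.
#' @param pulse_us width of each phase in microseconds.
#' @param gap_us interphase gap in microseconds.
#' @param amplitude_v stimulation amplitude in volts.
#' @return Object of class `stim_params`.
#' @export
stim_params <- function(freq_hz = 130, pulse_us = 60, gap_us = 20,
                        amplitude_v = 1.95) {
  if (freq_hz <= 0 || pulse_us < 0 || gap_us < 0 || amplitude_v < 0)
    tl_stop("invalid-stim", "invalid stimulation parameters")
  structure(list(freq_hz = freq_hz, pulse_us = pulse_us, gap_us = gap_us,
                 amplitude_v = amplitude_v), class = "stim_params")
}

#' Synthetic session configuration
#'
#' Parameters of the generative model for LFP/accelerometer/EMG sessions.
#' The signal model per bipolar LFP channel is 1/f^alpha background noise
#' plus band-limited oscillations (band-pass filtered white noise, so PSDs
#' show bands rather than lines) whose amplitudes are modulated by the
#' motor state: beta (13-30 Hz) attenuates during movement and posture,
#' theta (4-7 Hz) rises during posture, gamma (55-95 Hz) rises during
#' movement, and a tremor-frequency component follows the limb tremor
#' envelope. Limb tremor appears with a delay after task onset, grows with
#' a first-order time constant, and is multiplicatively suppressed toward
#' `1 - stim_suppression_fraction` of its unstimulated level (time constant
#' `stim_tau_s`) while stimulation is on. Amplitudes are in uV (LFP/EMG)
#' and g (accelerometer).
#'
#' @param seed integer RNG seed; identical (seed, config, protocol) give
#'   byte-identical sessions.
#' @param lfp_channels number of bipolar LFP channels.
#' @param rate_hz sampling rate (default 2048).
#' @param noise_exponent alpha of the 1/f^alpha LFP background.
#' @param background_rms_uv RMS of the LFP background noise.
#' @param beta_hz,beta_rest_rms_uv,beta_move_attenuation beta band, its
#'   resting RMS, and the fractional amplitude reduction during
#'   movement/posture (0..1).
#' @param theta_hz,theta_rest_rms_uv,theta_posture_gain theta band, resting
#'   RMS, and the multiplicative amplitude gain during posture (>= 1).
#' @param gamma_hz,gamma_rest_rms_uv,gamma_move_gain gamma band, resting
#'   RMS, and movement gain (>= 1).
#' @param tremor_hz tremor frequency (3-7 Hz).
#' @param tremor_band_halfwidth_hz half-width of the tremor oscillation
#'   band around `tremor_hz`.
#' @param tremor_onset_delay_s delay from task onset to tremor onset.
#' @param tremor_rise_tau_s first-order time constant of tremor growth and
#'   decay.
#' @param tremor_amp_g full-tremor accelerometer RMS amplitude.
#' @param lfp_tremor_rms_uv LFP tremor-frequency component RMS at full
#'   tremor.
#' @param stim_suppression_fraction steady-state fractional tremor
#'   suppression by stimulation (0..1; default 0.53, the continuous-DBS
#'   group mean this model reproduces).
#' @param stim_tau_s wash-in time constant: tremor amplitude decays
#'   toward its suppressed level with this constant while stimulation is
#'   on (thalamic stimulation arrests tremor within seconds).
#' @param stim_washout_tau_s wash-out time constant: tremor recovers
#'   toward its unstimulated level with this (slower) constant after
#'   stimulation stops — re-emergence takes tens of seconds, which is
#'   what lets intermittent stimulation match continuous suppression.
#' @param accel_noise_g accelerometer broadband noise RMS.
#' @param accel_move_g accelerometer RMS of the low-frequency voluntary
#'   movement component during MOVE blocks.
#' @param emg_noise_rms_uv EMG baseline (resting) RMS.
#' @param emg_burst_gain multiplicative EMG envelope gain during
#'   MOVE/POSTURE (> 0 means task EMG exceeds rest).
#' @param artifact_gain_uv_per_v recorded artifact amplitude scale, uV of
#'   pulse amplitude per volt of stimulation (free parameter; the artifact
#'   amplitude relative to LFP is not constrained by the data this model
#'   emulates).
#' @param artifact_front_end_hz cutoff of the 2-pole front-end response
#'   applied to the artifact path (electrode-tissue/amplifier
#'   charge-transfer dynamics); shapes the pulse train so the recorded
#'   artifact spectrum is dominated by the stimulation frequency while
#'   supra-Nyquist harmonics still fold into band.
#' @param snr_scale overall scale of the state-modulated LFP oscillations
#'   relative to background (1 = defaults; 0 removes all decodable
#'   signal).
#' @param env_tau_s smoothing time constant of motor-state envelopes
#'   (models gradual movement initiation/termination).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       lfp_channels = 3L,
                       rate_hz = 2048,
                       noise_exponent = 1,
                       background_rms_uv = 5,
                       beta_hz = c(13, 30),
                       beta_rest_rms_uv = 2,
                       beta_move_attenuation = 0.6,
                       theta_hz = c(4, 7),
                       theta_rest_rms_uv = 1,
                       theta_posture_gain = 2,
                       gamma_hz = c(55, 95),
                       gamma_rest_rms_uv = 0.5,
                       gamma_move_gain = 1.5,
                       tremor_hz = 5,
                       tremor_band_halfwidth_hz = 1,
                       tremor_onset_delay_s = 5,
                       tremor_rise_tau_s = 1.5,
                       tremor_amp_g = 0.1,
                       lfp_tremor_rms_uv = 4,
                       stim_suppression_fraction = 0.53,
                       stim_tau_s = 1.5,
                       stim_washout_tau_s = 15,
                       accel_noise_g = 0.01,
                       accel_move_g = 0.05,
                       emg_noise_rms_uv = 10,
                       emg_burst_gain = 2,
                       artifact_gain_uv_per_v = 2000,
                       artifact_front_end_hz = 100,
                       snr_scale = 1,
                       env_tau_s = 0.2) {
  cfg <- as.list(environment())
  if (!(tremor_hz >= 3 && tremor_hz <= 7))
    tl_stop("invalid-config", "tremor_hz must lie in [3, 7]")
  fr <- c(beta_move_attenuation, stim_suppression_fraction)
  if (any(fr < 0 | fr > 1))
    tl_stop("invalid-config", "fractions must lie in [0, 1]")
  if (theta_posture_gain < 1 || gamma_move_gain < 1)
    tl_stop("invalid-config", "state gains must be >= 1")
  if (tremor_onset_delay_s < 0 || tremor_rise_tau_s < 0 ||
      stim_tau_s < 0 || stim_washout_tau_s < 0)
    tl_stop("invalid-config", "delays and time constants must be >= 0")
  structure(cfg, class = "sim_config")
}

#' Build a block-structured task protocol
#'
#' Alternating rest/task blocks beginning and ending with rest. The first
#' and last rest blocks are half-length so that the task occupies exactly
#' `task_s / (task_s + rest_s)` of the session (with the 30 s / 30 s
#' defaults, tasks fill half the session, matching the roughly 50% task
#' occupancy of the protocol this generator emulates).
#'
#' @param task `"movement"` or `"posture"`.
#' @param n_blocks number of task blocks (6-8 movement / 8-10 posture
#'   blocks are typical).
#' @param task_s,rest_s block durations in seconds (default 30/30).
#' @return A [session_protocol()].
#' @export
make_protocol <- function(task = c("movement", "posture"), n_blocks,
                          task_s = 30, rest_s = 30) {
  task <- match.arg(task)
  if (n_blocks < 1 || task_s <= 0 || rest_s <= 0)
    tl_stop("invalid-protocol", "need n_blocks >= 1 and positive durations")
  state <- if (task == "movement") "MOVE" else "POSTURE"
  blocks <- data.frame(state = "REST", duration_s = rest_s / 2)
  for (b in seq_len(n_blocks)) {
    blocks <- rbind(blocks, data.frame(state = state, duration_s = task_s))
    blocks <- rbind(blocks, data.frame(
      state = "REST",
      duration_s = if (b == n_blocks) rest_s / 2 else rest_s))
  }
  session_protocol(blocks, task)
}

# --- stochastic primitives ---------------------------------------------

#' 1/f^alpha background noise, unit stationary RMS
#'
#' Causal synthesis: white noise convolved with the truncated impulse
#' response of the fractional integrator `(1 - z^-1)^(-alpha/2)`
#' (recurrence `h[k] = h[k-1] * (k - 1 + alpha/2) / k`), kernel length
#' fixed at 8192 samples so the generator is strictly causal and its
#' output over `[0, t]` depends only on noise drawn up to `t` — a
#' prerequisite for the closed-loop causality guarantees. The FFT is
#' used only as a fast linear-convolution engine. Normalized by the
#' kernel's analytic stationary gain, not the realization's sample SD.
#'
#' @param n number of samples.
#' @param alpha spectral exponent.
#' @keywords internal
one_over_f_noise <- function(n, alpha, kernel_len = 8192L) {
  k <- seq_len(kernel_len - 1L)
  h <- cumprod(c(1, (k - 1 + alpha / 2) / k))
  x <- rnorm(n)
  m <- stats::nextn(n + kernel_len, 2)
  y <- Re(fft(fft(c(x, numeric(m - n))) *
              fft(c(h, numeric(m - kernel_len))), inverse = TRUE)) / m
  y[seq_len(n)] / sqrt(sum(h^2))
}

# analytic stationary SD of unit white noise through a SOS cascade
sos_noise_gain <- function(sos, rate_hz, ngrid = 16384L) {
  f <- seq(0, rate_hz / 2, length.out = ngrid)
  sqrt(mean(Mod(sos_response(sos, f, rate_hz))^2))
}

#' Band-pass filtered white noise, unit stationary RMS
#'
#' Causal: a seeded white stream through the causal SOS band-pass,
#' scaled by the filter's analytic noise gain (realization-independent,
#' so a longer session extends a shorter one sample-for-sample).
#' @keywords internal
bandlimited_noise <- function(n, rate_hz, band, order = 4) {
  sos <- butter_bandpass_sos(band[1], band[2], order, rate_hz)
  sos_filter(sos, rnorm(n)) / sos_noise_gain(sos, rate_hz)
}

first_order_smooth <- function(x, tau_s, rate_hz, init = 0) {
  if (tau_s <= 0) return(x)
  beta <- exp(-1 / (tau_s * rate_hz))
  as.numeric(stats::filter((1 - beta) * x, beta, method = "recursive",
                           init = init))
}

# --- stimulation artifact ----------------------------------------------

FINE_OVERSAMPLE <- 25L   # fine grid = 25 x 2048 Hz = 51.2 kHz (>= 20x)

#' Biphasic pulse train evaluated at arbitrary times
#'
#' +1 during the leading phase, 0 during the interphase gap, -1 during the
#' trailing phase, repeating at the stimulation frequency.
#' @keywords internal
pulse_train_at <- function(t, stim) {
  period <- 1 / stim$freq_hz
  ph <- t %% period
  w <- stim$pulse_us * 1e-6
  g <- stim$gap_us * 1e-6
  out <- numeric(length(t))
  out[ph < w] <- 1
  out[ph >= w + g & ph < 2 * w + g] <- -1
  out
}

artifact_state_new <- function() list(y1 = 0, y2 = 0, quiet = TRUE)

# Artifact samples for sample range s0:s1 (1-based), gate constant per call.
# Synthesizes the pulse train on the fine grid, applies the 2-pole
# front-end (two cascaded first-order sections, DC gain 1), then decimates
# by taking every 25th fine sample -- no anti-alias filtering, so harmonic
# images above Nyquist fold into the recorded band.
artifact_chunk <- function(s0, s1, gate_uv, stim, fc_hz, rate_hz, state) {
  ns <- s1 - s0 + 1L
  if (gate_uv == 0 && state$quiet)
    return(list(y = numeric(ns), state = state))
  fine_rate <- FINE_OVERSAMPLE * rate_hz
  i0 <- (s0 - 1L) * FINE_OVERSAMPLE
  tf <- (i0 + seq_len(ns * FINE_OVERSAMPLE) - 1L) / fine_rate
  x <- gate_uv * pulse_train_at(tf, stim)
  beta <- exp(-2 * pi * fc_hz / fine_rate)
  y1 <- as.numeric(stats::filter((1 - beta) * x, beta,
                                 method = "recursive", init = state$y1))
  y2 <- as.numeric(stats::filter((1 - beta) * y1, beta,
                                 method = "recursive", init = state$y2))
  state$y1 <- y1[length(y1)]
  state$y2 <- y2[length(y2)]
  state$quiet <- gate_uv == 0 &&
    abs(state$y1) < 1e-12 && abs(state$y2) < 1e-12
  list(y = y2[seq(FINE_OVERSAMPLE, length(y2), by = FINE_OVERSAMPLE)],
       state = state)
}

#' Add the sampled stimulation artifact to an LFP series
#'
#' During stimulation-on frames, adds the 2048 Hz sampled image of the
#' biphasic pulse train. The train is synthesized on a 25x fine grid,
#' shaped by a 2-pole front-end response (see
#' [sim_config()]`$artifact_front_end_hz`), and decimated without
#' anti-alias filtering: harmonics of the pulse rate above the 1024 Hz
#' Nyquist frequency fold back to `|k*f_stim - 2048*round(k*f_stim/2048)|`
#' Hz, reproducing the aliased peaks seen in stimulated recordings.
#' Stimulation-off frames are unchanged; `artifact_gain = 0` is the
#' identity.
#'
#' @param lfp a [timeseries()] at 2048 Hz.
#' @param stim_on a [frameseries()]; nonzero values gate the artifact and
#'   scale it (interpreted as stimulation amplitude in volts).
#' @param stim a [stim_params()].
#' @param artifact_gain recorded amplitude in uV per volt of stimulation.
#' @param front_end_hz front-end cutoff in Hz.
#' @return A [timeseries()] with the artifact added to every channel.
#' @export
inject_stim_artifact <- function(lfp, stim_on, stim = stim_params(),
                                 artifact_gain = 50, front_end_hz = 100) {
  if (artifact_gain == 0) return(lfp)
  rate <- lfp$rate_hz
  n <- n_samples(lfp)
  frame_s <- stim_on$frame_s
  ends <- sample_frame_ends(n, rate, frame_s)
  art <- numeric(n)
  st <- artifact_state_new()
  s0 <- 1L
  for (k in seq_along(ends)) {
    amp <- if (k <= length(stim_on$values)) stim_on$values[k] else 0
    ch <- artifact_chunk(s0, ends[k], artifact_gain * amp, stim,
                         front_end_hz, rate, st)
    art[s0:ends[k]] <- ch$y
    st <- ch$state
    s0 <- ends[k] + 1L
  }
  if (s0 <= n) {
    ch <- artifact_chunk(s0, n, 0, stim, front_end_hz, rate, st)
    art[s0:n] <- ch$y
  }
  out <- lfp$samples + matrix(art, nrow = n_channels(lfp), ncol = n,
                              byrow = TRUE)
  timeseries(out, rate, lfp$channel_labels, lfp$units)
}

# frame-end sample indices for a signal of n samples
sample_frame_ends <- function(n, rate_hz, frame_s = 0.1) {
  nf <- n_frames(n / rate_hz, frame_s)
  as.integer(round(seq_len(nf) * frame_s * rate_hz))
}

# --- simulation core and engine ----------------------------------------

# All stimulation-independent stochastic material for one session,
# generated in one seeded pass so that closed-loop and fixed-schedule
# composition are sample-identical for identical stimulation sequences.
sim_core <- function(config, protocol) {
  rate <- config$rate_hz
  dur <- protocol_duration(protocol)
  n <- as.integer(round(dur * rate))
  nch <- config$lfp_channels
  frame_states <- protocol_states(protocol, 0.1)
  nf <- length(frame_states)

  # per-sample motor-state indicators, smoothed (gradual initiation)
  t_samp <- (seq_len(n) - 0.5) / rate
  edges <- cumsum(protocol$blocks$duration_s)
  bidx <- findInterval(t_samp, c(0, edges), left.open = TRUE)
  bidx[bidx > nrow(protocol$blocks)] <- nrow(protocol$blocks)
  st_samp <- protocol$blocks$state[bidx]
  task_env <- first_order_smooth(as.numeric(st_samp != "REST"),
                                 config$env_tau_s, rate)
  posture_env <- first_order_smooth(as.numeric(st_samp == "POSTURE"),
                                    config$env_tau_s, rate)
  move_env <- first_order_smooth(as.numeric(st_samp == "MOVE"),
                                 config$env_tau_s, rate)

  # per-frame time since task onset (for the tremor delay)
  is_task <- frame_states != "REST"
  t_since <- rep(Inf, nf)
  run <- 0
  for (k in seq_len(nf)) {
    if (is_task[k]) { t_since[k] <- run * 0.1; run <- run + 1 }
    else run <- 0
  }

  # each stochastic component draws from its own sub-seeded stream, so a
  # session over a longer protocol extends a shorter one sample-for-sample
  # (prefix stability -- the basis of the closed-loop causality audit)
  j <- 0L
  sub <- function(gen) {
    j <<- j + 1L
    s <- (as.numeric(config$seed) * 131 + j * 7919) %% 2147483647
    with_seed(as.integer(s), gen())
  }
  mk <- function(gen) t(vapply(seq_len(nch), function(i) sub(gen), numeric(n)))
  tband <- config$tremor_hz + c(-1, 1) * config$tremor_band_halfwidth_hz
  list(
    n = n, rate = rate, nf = nf, nch = nch,
    frame_states = frame_states, t_since_onset = t_since,
    task_env = task_env, posture_env = posture_env, move_env = move_env,
    background = mk(function() one_over_f_noise(n, config$noise_exponent)) *
      config$background_rms_uv,
    beta_osc = mk(function() bandlimited_noise(n, rate, config$beta_hz)),
    theta_osc = mk(function() bandlimited_noise(n, rate, config$theta_hz)),
    gamma_osc = mk(function() bandlimited_noise(n, rate, config$gamma_hz)),
    lfp_tremor_osc = mk(function() bandlimited_noise(n, rate, tband)),
    accel_noise = rbind(sub(function() rnorm(n)), sub(function() rnorm(n)),
                        sub(function() rnorm(n))) * config$accel_noise_g,
    tremor_carrier = sub(function() bandlimited_noise(n, rate, tband)),
    move_carrier = rbind(
      sub(function() bandlimited_noise(n, rate, c(0.5, 3))),
      sub(function() bandlimited_noise(n, rate, c(0.5, 3))),
      sub(function() bandlimited_noise(n, rate, c(0.5, 3)))),
    emg_carrier = sub(function() bandlimited_noise(n, rate, c(20, 450))),
    tremor_phase = sub(function() runif(1, 0, 2 * pi))
  )
}

TREMOR_AXIS_W <- c(1, 0.4, 0.2)  # tremor projects mostly on one axis

sim_engine_new <- function(core, config, stim) {
  list(core = core, config = config, stim = stim,
       e = 0, m = 1, prev_a = 0,
       art = artifact_state_new(),
       ends = as.integer(round(seq_len(core$nf) * 0.1 * core$rate)))
}

# advance the engine one frame; stim_amp_v is the stimulator amplitude
# held during this frame. Returns the sample chunk for the frame.
sim_engine_step <- function(eng, k, stim_amp_v) {
  cfg <- eng$config; core <- eng$core
  s1 <- eng$ends[k]
  s0 <- if (k == 1L) 1L else eng$ends[k - 1L] + 1L
  ns <- s1 - s0 + 1L
  idx <- s0:s1
  frame_s <- 0.1

  # tremor dynamics on the frame grid
  provoked <- core$frame_states[k] != "REST" &&
    core$t_since_onset[k] >= cfg$tremor_onset_delay_s
  e_target <- if (provoked) cfg$tremor_amp_g else 0
  ae <- if (cfg$tremor_rise_tau_s > 0) 1 - exp(-frame_s / cfg$tremor_rise_tau_s) else 1
  eng$e <- eng$e + ae * (e_target - eng$e)
  stim_on_now <- stim_amp_v > 0
  m_target <- 1 - cfg$stim_suppression_fraction * as.numeric(stim_on_now)
  m_tau <- if (stim_on_now) cfg$stim_tau_s else cfg$stim_washout_tau_s
  am <- if (m_tau > 0) 1 - exp(-frame_s / m_tau) else 1
  eng$m <- eng$m + am * (m_target - eng$m)
  a_end <- eng$e * eng$m
  a_samp <- eng$prev_a + (a_end - eng$prev_a) * seq_len(ns) / ns
  eng$prev_a <- a_end
  a_norm <- if (cfg$tremor_amp_g > 0) a_samp / cfg$tremor_amp_g else a_samp * 0

  # artifact (shared across bipolar channels)
  ch <- artifact_chunk(s0, s1, cfg$artifact_gain_uv_per_v * stim_amp_v,
                       eng$stim, cfg$artifact_front_end_hz, core$rate,
                       eng$art)
  eng$art <- ch$state

  beta_env <- cfg$beta_rest_rms_uv *
    (1 - cfg$beta_move_attenuation * core$task_env[idx])
  theta_env <- cfg$theta_rest_rms_uv *
    (1 + (cfg$theta_posture_gain - 1) * core$posture_env[idx])
  gamma_env <- cfg$gamma_rest_rms_uv *
    (1 + (cfg$gamma_move_gain - 1) * core$move_env[idx])
  osc <- cfg$snr_scale * (
    core$beta_osc[, idx, drop = FALSE] * rep(beta_env, each = core$nch) +
    core$theta_osc[, idx, drop = FALSE] * rep(theta_env, each = core$nch) +
    core$gamma_osc[, idx, drop = FALSE] * rep(gamma_env, each = core$nch) +
    core$lfp_tremor_osc[, idx, drop = FALSE] *
      rep(cfg$lfp_tremor_rms_uv * a_norm, each = core$nch))
  lfp <- core$background[, idx, drop = FALSE] + osc +
    matrix(ch$y, nrow = core$nch, ncol = ns, byrow = TRUE)

  accel <- core$accel_noise[, idx, drop = FALSE] +
    outer(TREMOR_AXIS_W, a_samp * core$tremor_carrier[idx]) +
    core$move_carrier[, idx, drop = FALSE] *
      rep(cfg$accel_move_g * core$move_env[idx], each = 3)

  t_idx <- (idx - 0.5) / core$rate
  tremor_mod <- 0.5 * (1 + sin(2 * pi * cfg$tremor_hz * t_idx +
                               core$tremor_phase))
  emg_env <- (1 + cfg$emg_burst_gain * core$task_env[idx]) *
    (1 + 0.5 * a_norm * tremor_mod)
  emg <- matrix(cfg$emg_noise_rms_uv * core$emg_carrier[idx] * emg_env,
                nrow = 1)

  list(eng = eng, lfp = lfp, accel = accel, emg = emg, a_end = a_end)
}

#' Generate a synthetic recording session
#'
#' Produces a fully aligned [session_recording()] with ground truth: LFP
#' channels with state-modulated oscillations and (when stimulation is on)
#' the aliased stimulation artifact; triaxial accelerometer with delayed
#' tremor and voluntary-movement components; EMG with task bursts and
#' tremor-frequency modulation. Deterministic given
#' `(config$seed, config, protocol)` and the stimulation sequence.
#'
#' @param config a [sim_config()].
#' @param protocol a [session_protocol()].
#' @param stim a [stim_params()].
#' @param stim_schedule either `NULL` (stimulation off throughout), a
#'   [frameseries()] of amplitudes in volts on the 100 ms grid, or the
#'   string `"on"` (continuous stimulation at `stim$amplitude_v`).
#' @return A [session_recording()]; `extras$tremor_envelope` carries the
#'   generator's ground-truth tremor amplitude per frame.
#' @export
generate_session <- function(config, protocol, stim = stim_params(),
                             stim_schedule = NULL) {
  core <- sim_core(config, protocol)
  nf <- core$nf
  amp <- if (is.null(stim_schedule)) numeric(nf)
  else if (identical(stim_schedule, "on")) rep(stim$amplitude_v, nf)
  else if (inherits(stim_schedule, "frameseries")) stim_schedule$values
  else tl_stop("schedule-mismatch", "unrecognized stim_schedule")
  if (length(amp) != nf)
    tl_stop("schedule-mismatch",
            sprintf("schedule has %d frames, protocol needs %d",
                    length(amp), nf))

  eng <- sim_engine_new(core, config, stim)
  nch <- core$nch
  lfp <- matrix(0, nch, core$n)
  accel <- matrix(0, 3, core$n)
  emg <- matrix(0, 1, core$n)
  a_env <- numeric(nf)
  s0 <- 1L
  for (k in seq_len(nf)) {
    stp <- sim_engine_step(eng, k, amp[k])
    eng <- stp$eng
    s1 <- eng$ends[k]
    lfp[, s0:s1] <- stp$lfp
    accel[, s0:s1] <- stp$accel
    emg[, s0:s1] <- stp$emg
    a_env[k] <- stp$a_end
    s0 <- s1 + 1L
  }
  session_recording(
    lfp = timeseries(lfp, core$rate, paste0("LFP_", seq_len(nch)), "uV"),
    accel = timeseries(accel, core$rate, c("ACC_X", "ACC_Y", "ACC_Z"), "g"),
    emg = timeseries(emg, core$rate, "EMG_1", "uV"),
    stim_trace = frameseries(amp, 0.1),
    truth_states = core$frame_states,
    protocol = protocol,
    extras = list(tremor_envelope = frameseries(a_env, 0.1))
  )
}
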