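# Shared fixtures, built once per test run and memoised across files.
# Sessions are deliberately small (2 LFP channels, 10 s blocks) so the
# whole suite stays fast; the methods vignette documents the scaled-down
# problem sizes.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

quick_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, lfp_channels = 2L, ...)
}

quick_protocol <- function(task = "posture", n_blocks = 3L,
                           task_s = 10, rest_s = 10) {
  make_protocol(task, n_blocks, task_s, rest_s)
}

# default posture session + derived objects used by several files
default_session <- function() {
  fixture("default_session",
          generate_session(quick_config(seed = 11L), quick_protocol()))
}

default_features <- function() {
  fixture("default_features", {
    ses <- default_session()
    fr <- frame_signal(ses$lfp)
    list(frames = fr,
         fm = extract_features(bandpass_causal(ses$lfp), fr),
         labels = movement_labels(ses$emg, frame_signal(ses$emg),
                                  task = "posture"),
         blocks = protocol_block_index(ses$protocol),
         truth = truth_labels(ses, "any"))
  })
}

# small trained posture decoder bundle (stim on + off cells) for the
# closed-loop tests; the movement cells reuse the posture models since
# single-task loops only consult their own task's cells
train_cell <- function(seed, stim_state, prot,
                       cfg_fun = quick_config, algorithm = "svm") {
  sched <- if (stim_state == "on") "on" else NULL
  ses <- generate_session(cfg_fun(seed), prot, stim_params(), sched)
  fr <- frame_signal(ses$lfp)
  fm <- extract_features(bandpass_causal(ses$lfp), fr)
  ml <- movement_labels(ses$emg, frame_signal(ses$emg), task = prot$task)
  train_decoder(fm, ml, prot$task, stim_state, algorithm,
                stim_frames = ses$stim_trace$values)
}

posture_bundle <- function() {
  fixture("posture_bundle", {
    prot <- quick_protocol("posture", 4L, 15, 15)
    m_off <- train_cell(21L, "off", prot)
    m_on <- train_cell(22L, "on", prot)
    structure(list("posture.off" = m_off, "posture.on" = m_on,
                   "movement.off" = m_off, "movement.on" = m_on),
              class = "decoder_bundle")
  })
}

# independent brute-force oracles --------------------------------------

# pair-counting AUC: (concordant + half ties) / (n1 * n0)
auc_paircount <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# direct DFT periodogram, written independently of the package path
direct_band_features <- function(w, rate, bands, eps = 1e-12) {
  n <- length(w)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
  xw <- (w - mean(w)) * taper
  kmax <- floor(n / 2)
  X <- vapply(0:kmax, function(k)
    sum(xw * exp(-2i * pi * k * seq(0, n - 1) / n)), complex(1))
  psd <- Mod(X)^2 / (rate * sum(taper^2))
  psd[2:kmax] <- 2 * psd[2:kmax]
  freq <- (0:kmax) * rate / n
  vapply(bands, function(b)
    log(eps + mean(psd[freq >= b[1] & freq <= b[2]])), 0)
}
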