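test_that("make_protocol builds alternating blocks with exact task fraction", {
  p <- make_protocol("movement", 6, 30, 30)
  expect_equal(sum(p$blocks$state == "MOVE"), 6L)
  expect_true(all(p$blocks$duration_s[p$blocks$state == "MOVE"] == 30))
  expect_equal(p$blocks$state[1], "REST")
  expect_equal(p$blocks$state[nrow(p$blocks)], "REST")
  p2 <- make_protocol("posture", 1, 10, 10)
  expect_equal(p2$blocks$state, c("REST", "POSTURE", "REST"))
  p3 <- make_protocol("posture", 8, 30, 30)
  task_frac <- sum(p3$blocks$duration_s[p3$blocks$state == "POSTURE"]) /
    protocol_duration(p3)
  expect_equal(task_frac, 0.5)
  expect_error(make_protocol("movement", 0, 30, 30),
               class = "invalid-protocol")
  expect_error(make_protocol("movement", 2, -1, 30),
               class = "invalid-protocol")
})

test_that("generation is deterministic given the seed", {
  prot <- quick_protocol("movement", 1L, 5, 5)
  a <- generate_session(quick_config(seed = 3L), prot)
  b <- generate_session(quick_config(seed = 3L), prot)
  expect_identical(a$lfp$samples, b$lfp$samples)
  expect_identical(a$accel$samples, b$accel$samples)
  expect_identical(a$emg$samples, b$emg$samples)
  c_ <- generate_session(quick_config(seed = 4L), prot)
  expect_false(identical(a$lfp$samples, c_$lfp$samples))
})

test_that("pure rest with stimulation off has no tremor above the noise floor", {
  prot <- session_protocol(data.frame(state = "REST", duration_s = 20),
                           "posture")
  ses <- generate_session(quick_config(seed = 6L), prot)
  expect_true(all(ses$extras$tremor_envelope$values == 0))
  expect_true(all(ses$truth_states == "REST"))
  fr <- frame_signal(ses$accel)
  pow <- frame_band_power(ses$accel, fr, c(3, 7))
  # white-noise floor: flat PSD of sd^2/nyquist per Hz per axis
  floor_psd <- 3 * quick_config()$accel_noise_g^2 / 1024
  expect_lt(mean(pow[!fr$warmup]), 3 * floor_psd)
})

test_that("LFP band powers move with motor state in the directions observed in patients", {
  ses <- default_session()                       # posture task
  fr <- frame_signal(ses$lfp)
  lfpf <- bandpass_causal(ses$lfp)
  ok <- !fr$warmup
  st <- ses$truth_states
  beta <- frame_band_power(lfpf, fr, c(13, 30))
  theta <- frame_band_power(lfpf, fr, c(4, 7))
  expect_lt(mean(beta[ok & st == "POSTURE"]), mean(beta[ok & st == "REST"]))
  expect_gt(mean(theta[ok & st == "POSTURE"]), mean(theta[ok & st == "REST"]))
  mses <- fixture("move_session",
                  generate_session(quick_config(seed = 12L),
                                   quick_protocol("movement")))
  mfr <- frame_signal(mses$lfp)
  mok <- !mfr$warmup
  mst <- mses$truth_states
  mlfpf <- bandpass_causal(mses$lfp)
  mbeta <- frame_band_power(mlfpf, mfr, c(13, 30))
  gamma <- frame_band_power(mlfpf, mfr, c(55, 95))
  expect_lt(mean(mbeta[mok & mst == "MOVE"]), mean(mbeta[mok & mst == "REST"]))
  expect_gt(mean(gamma[mok & mst == "MOVE"]), mean(gamma[mok & mst == "REST"]))
})

test_that("EMG envelope rises during task blocks whenever burst gain is positive", {
  for (gain in c(0.5, 2)) {
    ses <- generate_session(quick_config(seed = 9L, emg_burst_gain = gain),
                            quick_protocol("posture", 2L, 10, 10))
    fr <- frame_signal(ses$emg)
    env <- rep(NA_real_, nrow(fr))
    for (k in which(!fr$warmup))
      env[k] <- sqrt(mean(ses$emg$samples[1, fr$start[k]:fr$end[k]]^2))
    ok <- !fr$warmup
    st <- ses$truth_states
    expect_gt(mean(env[ok & st != "REST"]), mean(env[ok & st == "REST"]))
  }
})

test_that("continuous stimulation settles tremor at 1 - suppression within 2%", {
  cfg <- quick_config(seed = 15L)
  prot <- session_protocol(data.frame(state = c("REST", "POSTURE"),
                                      duration_s = c(5, 45)), "posture")
  off <- generate_session(cfg, prot)
  on <- generate_session(cfg, prot, stim_params(), "on")
  # steady state: late in the block, > 10 * stim_tau_s after stim onset
  late <- 420:500
  ratio <- mean(on$extras$tremor_envelope$values[late]) /
    mean(off$extras$tremor_envelope$values[late])
  expect_equal(ratio, 1 - cfg$stim_suppression_fraction, tolerance = 0.02)
})

test_that("mismatched stimulation schedules are rejected", {
  prot <- quick_protocol("posture", 1L, 5, 5)
  expect_error(generate_session(quick_config(), prot, stim_params(),
                                frameseries(numeric(7))),
               class = "schedule-mismatch")
})

test_that("zero artifact gain is the identity", {
  lfp <- timeseries(matrix(rnorm(2048 * 2), 1), 2048, "LFP_1")
  out <- inject_stim_artifact(lfp, frameseries(rep(1, 20)),
                              artifact_gain = 0)
  expect_identical(out$samples, lfp$samples)
})

test_that("artifact appears only during stimulation-on frames", {
  lfp <- timeseries(matrix(0, 1, 4 * 2048), 2048, "LFP_1")
  gate <- frameseries(rep(c(0, 1.95), each = 20))
  out <- inject_stim_artifact(lfp, gate, artifact_gain = 50)
  n_on_start <- round(2 * 2048)
  expect_true(all(out$samples[1, 1:n_on_start] == 0))
  expect_gt(max(abs(out$samples[1, (n_on_start + 1):(4 * 2048)])), 0.1)
})

test_that("stimulated LFP spectra peak at 130 Hz with fold-back aliases", {
  lfp <- timeseries(matrix(0, 1, 30 * 2048), 2048, "LFP_1")
  out <- inject_stim_artifact(lfp, frameseries(rep(1.95, 300)),
                              artifact_gain = 50)
  pg <- welch_psd(out$samples[1, ], 2048, seg_s = 1, overlap = 0.5)
  sel <- pg$freq > 100
  expect_equal(pg$freq[sel][which.max(pg$psd[sel])], 130)
  # supra-Nyquist harmonics fold to |2048 * round(k*130/2048) - k*130| Hz
  for (k in 8:15) {
    fa <- abs(2048 * round(k * 130 / 2048) - k * 130)
    i <- which.min(abs(pg$freq - fa))
    nb <- pg$psd[abs(pg$freq - fa) >= 3 & abs(pg$freq - fa) <= 10]
    expect_gt(pg$psd[i], 2 * median(nb))
  }
})

test_that("folded-line powers match the analytic harmonic amplitudes", {
  # oracle: the k-th harmonic of the biphasic doublet has amplitude
  # |G(f)| = w sinc(pi f w) * 2 sin(pi f (w + g)) shaped by the 2-pole
  # front end; after decimation its power appears at the folded
  # frequency. Measured line powers must match these analytic ratios.
  lfp <- timeseries(matrix(0, 1, 30 * 2048), 2048, "LFP_1")
  out <- inject_stim_artifact(lfp, frameseries(rep(1.95, 300)),
                              stim_params(), artifact_gain = 50,
                              front_end_hz = 100)
  pg <- welch_psd(out$samples[1, ], 2048, seg_s = 1, overlap = 0.5)
  w <- 60e-6; g <- 20e-6; fine <- 25 * 2048
  Gmag <- function(f) w * abs(sin(pi * f * w) / (pi * f * w)) *
    2 * abs(sin(pi * f * (w + g)))
  Hmag <- function(f) {
    b <- exp(-2 * pi * 100 / fine); om <- 2 * pi * f / fine
    ((1 - b) / Mod(1 - b * exp(-1i * om)))^2
  }
  k <- 8:14                      # k = 15 folds to 98 Hz, inside the
  fk <- 130 * k                  # front-end knee where background mixes in
  fa <- abs(2048 * round(fk / 2048) - fk)
  pred <- (Gmag(fk) * Hmag(fk))^2
  meas <- vapply(fa, function(f) pg$psd[which.min(abs(pg$freq - f))], 0)
  expect_equal(meas / meas[1], pred / pred[1], tolerance = 0.1)
})
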