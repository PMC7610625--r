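# a decoder_model whose score is a constant, built on the HELM backend
# (zero hidden weights, constant readout) -- used to make the loop's
# model-selection lag observable
constant_model <- function(score, task = "posture", stim_state = "off",
                           d = 24L) {
  fit <- list(W1 = matrix(0, d, 2), b1 = c(0, 0),
              W2 = matrix(0, 2, 2), b2 = c(0, 0),
              beta = matrix(c(score, 0, 0), ncol = 1))
  norm <- structure(list(mean = rep(0, d), sd = rep(1, d)),
                    class = "feature_norm")
  structure(list(task = task, stim_state = stim_state, algorithm = "helm",
                 fit = fit, norm = norm, decision_threshold = 0.5,
                 seed = 1L),
            class = "decoder_model")
}

test_that("controller truth table matches the on/off decision rule", {
  expect_equal(controller_step("off", 1), "on")
  expect_equal(controller_step("on", 0), "off")
  expect_equal(controller_step("on", 1), "on")
  expect_equal(controller_step("off", 0), "off")
})

test_that("select_model returns the (task, stim-state) cell or fails loudly", {
  b <- posture_bundle()
  m <- select_model(b, "posture", "on")
  expect_equal(m$stim_state, "on")
  expect_equal(select_model(b, "posture", "off")$stim_state, "off")
  expect_error(select_model(list("posture.off" = b$posture.off),
                            "posture", "on"),
               class = "incomplete-grid")
})

test_that("model selection uses the previous frame's stimulator state", {
  # off-state model always fires (score 0.9), on-state model never (0.1):
  # after warm-up the loop must cycle off,on,on,off with period 4, because
  # scoring frame k uses the state held at frame k-1
  nch <- 2L
  bundle <- structure(
    list("posture.off" = constant_model(0.9, stim_state = "off", d = 12 * nch),
         "posture.on" = constant_model(0.1, stim_state = "on", d = 12 * nch)),
    class = "decoder_bundle")
  prot <- session_protocol(data.frame(state = "REST", duration_s = 10),
                           "posture")
  res <- run_closed_loop(quick_config(seed = 33L), prot, models = bundle,
                         controller = controller_config(mode = "adbs"))
  tr <- res$trace
  active <- which(!is.na(tr$score))
  # reference simulation of the same rule
  state <- "off"; prev <- "off"
  exp_state <- character(0); exp_score <- numeric(0)
  for (k in active) {
    sc <- if (prev == "off") 0.9 else 0.1
    det <- as.integer(sc > 0.5)
    exp_state <- c(exp_state, state)
    exp_score <- c(exp_score, sc)
    prev <- state
    state <- controller_step(state, det)
  }
  expect_equal(tr$score[active], exp_score)
  expect_equal(tr$state[active], exp_state)
  # both models are actually exercised
  expect_true(any(tr$score[active] == 0.9) && any(tr$score[active] == 0.1))
})

test_that("continuous and no-stimulation modes pin the amplitude", {
  prot <- quick_protocol("posture", 1L, 5, 5)
  cfg <- quick_config(seed = 34L)
  cd <- run_closed_loop(cfg, prot, controller = controller_config(mode = "cdbs"))
  nd <- run_closed_loop(cfg, prot, controller = controller_config(mode = "nodbs"))
  expect_true(all(cd$trace$amplitude_v == stim_params()$amplitude_v))
  expect_true(all(nd$trace$amplitude_v == 0))
})

test_that("a never-reached threshold reproduces the no-DBS condition", {
  prot <- quick_protocol("posture", 1L, 10, 10)
  cfg <- quick_config(seed = 35L)
  b <- posture_bundle()
  hi <- run_closed_loop(cfg, prot, models = b,
                        controller = controller_config(threshold = 1 - 1e-9,
                                                       mode = "adbs"))
  nd <- run_closed_loop(cfg, prot, controller = controller_config(mode = "nodbs"))
  expect_true(all(hi$trace$amplitude_v == 0))
  expect_equal(hi$trace$tremor_power, nd$trace$tremor_power,
               tolerance = 1e-9)
})

test_that("adaptive stimulation concentrates on task frames", {
  prot <- quick_protocol("posture", 2L, 15, 15)
  b <- posture_bundle()
  res <- run_closed_loop(quick_config(seed = 36L), prot, models = b,
                         controller = controller_config(mode = "adbs"))
  tr <- res$trace[!res$trace$warmup, ]
  on_rest <- mean(tr$state[tr$truth == "REST"] == "on")
  on_task <- mean(tr$state[tr$truth != "REST"] == "on")
  expect_lt(on_rest, on_task)
})

test_that("energy ordering nodbs <= adbs <= cdbs holds for every seed and threshold", {
  prot <- quick_protocol("posture", 1L, 10, 10)
  b <- posture_bundle()
  for (seed in c(41L, 42L)) {
    for (th in c(0.3, 0.7)) {
      cfg <- quick_config(seed = seed)
      ad <- run_closed_loop(cfg, prot, models = b,
                            controller = controller_config(threshold = th,
                                                           mode = "adbs"))
      cd <- run_closed_loop(cfg, prot,
                            controller = controller_config(mode = "cdbs"))
      e <- c(0, energy_index(ad), energy_index(cd))
      expect_true(all(diff(e) >= 0))
    }
  }
})

test_that("stimulation-on fraction is nonincreasing in the threshold", {
  prot <- quick_protocol("posture", 1L, 10, 10)
  b <- posture_bundle()
  cfg <- quick_config(seed = 43L)
  fracs <- vapply(c(0.2, 0.5, 0.8), function(th) {
    r <- run_closed_loop(cfg, prot, models = b,
                         controller = controller_config(threshold = th,
                                                        mode = "adbs"))
    mean(r$trace$state == "on")
  }, 0)
  expect_true(all(diff(fracs) <= 0))
})

test_that("the loop is causal: a modified future leaves past trace rows unchanged", {
  b <- posture_bundle()
  p_short <- session_protocol(
    data.frame(state = c("REST", "POSTURE", "REST"),
               duration_s = c(5, 10, 10)), "posture")
  p_long <- session_protocol(
    data.frame(state = c("REST", "POSTURE", "REST", "POSTURE", "REST"),
               duration_s = c(5, 10, 5, 10, 5)), "posture")
  cfg <- quick_config(seed = 44L)
  r1 <- run_closed_loop(cfg, p_short, models = b,
                        controller = controller_config(mode = "adbs"))
  r2 <- run_closed_loop(cfg, p_long, models = b,
                        controller = controller_config(mode = "adbs"))
  # the protocols agree over the first 15 s (150 frames)
  past <- 1:150
  expect_equal(r1$trace$score[past], r2$trace$score[past], tolerance = 1e-9)
  expect_identical(r1$trace$detection[past], r2$trace$detection[past])
  expect_identical(r1$trace$state[past], r2$trace$state[past])
})

test_that("stimulator state changes only at frame boundaries", {
  prot <- quick_protocol("posture", 1L, 10, 10)
  b <- posture_bundle()
  r <- run_closed_loop(quick_config(seed = 45L), prot, models = b,
                       controller = controller_config(mode = "adbs"))
  # amplitudes in the trace are per-frame constants taking only two values
  expect_true(all(r$trace$amplitude_v %in% c(0, stim_params()$amplitude_v)))
  # and the session's sample-level stim trace matches the frame trace
  expect_identical(r$session$stim_trace$values, r$trace$amplitude_v)
})
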