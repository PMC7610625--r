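# two separable Gaussian classes with a block structure for CV
separable_data <- function(n_blocks = 10L, per_block = 40L, gap = 3,
                           seed = 16L, d = 6L) {
  set.seed(seed)
  lab <- rep(rep(c(0L, 1L), length.out = n_blocks), each = per_block)
  blocks <- rep(seq_len(n_blocks), each = per_block)
  X <- matrix(rnorm(length(lab) * d), ncol = d)
  X[, 1] <- X[, 1] + gap * lab
  colnames(X) <- paste0("f", seq_len(d))
  list(X = X, labels = label_series(lab, "truth", "movement"),
       blocks = blocks)
}

test_that("trapezoidal AUC equals brute-force pair counting", {
  expect_equal(roc_auc(c(0.1, 0.35, 0.4, 0.8), c(0, 1, 0, 1))$auc, 0.75)
  set.seed(17)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
    s <- round(runif(n), 2)                    # coarse scores force ties
    expect_equal(roc_auc(s, y)$auc, auc_paircount(s, y),
                 tolerance = 1e-9)
  }
})

test_that("ROC of a perfect scorer passes through (0,1) with AUC 1", {
  ra <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(ra$auc, 1)
  expect_true(any(ra$roc$fpr == 0 & ra$roc$tpr == 1))
  expect_true(all(diff(ra$roc$tpr) >= 0) && all(diff(ra$roc$fpr) >= 0))
})

test_that("AUC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(18)
  y <- rbinom(300, 1, 0.4)
  s <- rnorm(300) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(s, y)$auc, ref, tolerance = 1e-12)
})

test_that("linearly separable features give training AUC 1 for every algorithm", {
  d <- separable_data(gap = 10)
  for (alg in ALGORITHMS) {
    m <- train_decoder(d$X, d$labels, "movement", "off", alg)
    sc <- decoder_score(m, d$X)
    expect_equal(roc_auc(sc, d$labels$labels)$auc, 1,
                 tolerance = 1e-6, label = alg)
  }
})

test_that("training and scoring are deterministic given the seed", {
  d <- separable_data(gap = 1)
  for (alg in c("svm", "helm", "knn")) {
    m1 <- train_decoder(d$X, d$labels, "movement", "off", alg, seed = 5L)
    m2 <- train_decoder(d$X, d$labels, "movement", "off", alg, seed = 5L)
    expect_identical(decoder_score(m1, d$X), decoder_score(m2, d$X),
                     label = alg)
  }
})

test_that("single-class labels are rejected", {
  d <- separable_data()
  ones <- label_series(rep(1L, nrow(d$X)), "truth", "movement")
  expect_error(train_decoder(d$X, ones, "movement", "off", "svm"),
               class = "degenerate-labels")
})

test_that("label permutation yields chance-level cross-validated AUC", {
  d <- separable_data(n_blocks = 20L, per_block = 50L, gap = 3)
  y <- d$labels$labels
  set.seed(19)
  aucs <- vapply(1:20, function(i) {
    perm <- label_series(sample(y), "truth", "movement")
    cross_validate(d$X, perm, d$blocks, "movement", "off", "lda",
                   k = 5L)$auc
  }, 0)
  expect_true(all(aucs > 0.4 & aucs < 0.6))
})

test_that("block-wise CV requires enough task blocks and pools one ROC", {
  d <- separable_data(n_blocks = 10L, gap = 10)
  cv <- cross_validate(d$X, d$labels, d$blocks, "movement", "off", "svm",
                       k = 5L)
  expect_gt(cv$auc, 0.99)
  expect_equal(sort(unique(cv$fold)), 1:5)
  expect_equal(roc_auc(cv$scores, cv$labels)$auc, cv$auc)
  expect_error(cross_validate(d$X, d$labels, d$blocks, "movement", "off",
                              "svm", k = 8L),
               class = "too-few-blocks")
})

test_that("the stimulation-state firewall holds in training", {
  d <- separable_data()
  stim <- rep(c(0, 1.95), length.out = nrow(d$X))
  m_off <- train_decoder(d$X, d$labels, "movement", "off", "svm",
                         stim_frames = stim)
  m_on <- train_decoder(d$X, d$labels, "movement", "on", "svm",
                        stim_frames = stim)
  expect_true(all(stim[m_off$trained_on] == 0))
  expect_true(all(stim[m_on$trained_on] > 0))
})

test_that("algorithm comparison shares folds, flags the best, breaks ties by fixed order", {
  d <- separable_data(gap = 0.8)
  cmp <- compare_algorithms(d$X, d$labels, d$blocks, "movement", "off",
                            algorithms = c("svm", "lr", "lda"), k = 5L)
  expect_equal(nrow(cmp$table), 3L)
  expect_equal(sum(cmp$table$best), 1L)
  expect_equal(cmp$table$auc[cmp$table$best],
               max(cmp$table$auc))
  # duplicated algorithm gives identical AUCs; the tie goes to the first
  # entry in the fixed order
  cmp2 <- compare_algorithms(d$X, d$labels, d$blocks, "movement", "off",
                             algorithms = c("lda", "lda"), k = 5L)
  expect_equal(cmp2$table$auc[1], cmp2$table$auc[2])
  expect_true(cmp2$table$best[1])
  cmp1 <- compare_algorithms(d$X, d$labels, d$blocks, "movement", "off",
                             algorithms = "svm", k = 5L)
  expect_equal(nrow(cmp1$table), 1L)
  expect_true(cmp1$table$best)
})

test_that("every algorithm beats chance on generator-default features", {
  df <- default_features()
  cmp <- compare_algorithms(df$fm, df$labels, df$blocks, "posture", "off",
                            algorithms = ALGORITHMS, k = 3L)
  n1 <- sum(df$labels$labels == 1); n0 <- sum(df$labels$labels == 0)
  for (i in seq_len(nrow(cmp$table))) {
    a <- cmp$table$auc[i]
    # Hanley-McNeil standard error at the observed AUC
    q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
    se <- sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) +
                  (n0 - 1) * (q2 - a^2)) / (n1 * n0))
    expect_gt(a, 0.5 + 3 * se)
  }
})

test_that("select_models retrains the per-cell best and validates the grid", {
  d <- separable_data()
  cmp <- compare_algorithms(d$X, d$labels, d$blocks, "movement", "off",
                            algorithms = c("svm", "lda"), k = 5L)
  cell <- list(features = d$X, labels = d$labels, blocks = d$blocks,
               comparison = cmp)
  cells <- list("movement.off" = cell, "movement.on" = cell,
                "posture.off" = cell, "posture.on" = cell)
  bundle <- select_models(cells)
  expect_s3_class(bundle$movement.off, "decoder_model")
  expect_equal(bundle$posture.on$task, "posture")
  expect_equal(bundle$posture.on$stim_state, "on")
  expect_error(select_models(cells[1:3]), class = "incomplete-grid")
  bad <- cells
  bad$posture.on$comparison$table$auc <- NaN
  expect_error(select_models(bad), class = "incomplete-grid")
})

test_that("AUC shrinks to chance as generator effect sizes vanish and grows with SNR", {
  flat_cfg <- quick_config(seed = 23L, beta_move_attenuation = 0,
                           theta_posture_gain = 1, gamma_move_gain = 1,
                           lfp_tremor_rms_uv = 0)
  prot <- quick_protocol("posture", 5L, 10, 10)
  ses <- generate_session(flat_cfg, prot)
  fr <- frame_signal(ses$lfp)
  fm <- extract_features(bandpass_causal(ses$lfp), fr)
  tr <- truth_labels(ses, "any")
  tr$warmup <- fr$warmup
  blocks <- protocol_block_index(prot)
  auc_flat <- cross_validate(fm, tr, blocks, "posture", "off", "lda",
                             k = 5L)$auc
  expect_gt(auc_flat, 0.35)
  expect_lt(auc_flat, 0.65)
  weak <- generate_session(quick_config(seed = 23L, snr_scale = 0.15), prot)
  strong <- generate_session(quick_config(seed = 23L, snr_scale = 1), prot)
  auc_of <- function(ses) {
    fm <- extract_features(bandpass_causal(ses$lfp), frame_signal(ses$lfp))
    tr <- truth_labels(ses, "any"); tr$warmup <- fr$warmup
    cross_validate(fm, tr, blocks, "posture", "off", "lda", k = 5L)$auc
  }
  expect_gt(auc_of(strong), auc_of(weak) - 0.02)
})

test_that("SVR recovers a noisy single-feature intensity relation (held-out r >= 0.95)", {
  set.seed(24)
  n <- 400L
  X <- matrix(rnorm(n * 5), ncol = 5)
  colnames(X) <- paste0("f", 1:5)
  pow <- exp(1.2 * X[, 3] + rnorm(n, sd = 0.1))
  blocks <- rep(1:10, each = 40)
  res <- cv_intensity(X, pow, blocks, k = 5L)
  expect_gte(res$r, 0.95)
})

test_that("constant tremor targets are rejected", {
  set.seed(25)
  X <- matrix(rnorm(100), ncol = 2)
  expect_error(fit_intensity(X, rep(2, 50)), class = "degenerate-target")
})

test_that("LFP features predict generator tremor intensity above chance", {
  # longer posture blocks give tremor time to develop past its 5 s delay
  ses <- fixture("delay_session",
                 generate_session(quick_config(seed = 31L),
                                  quick_protocol("posture", 2L, 15, 10)))
  fr <- frame_signal(ses$lfp)
  fm <- extract_features(bandpass_causal(ses$lfp), fr)
  tg <- tremor_labels(ses$accel, frame_signal(ses$accel))$target
  blocks <- protocol_block_index(ses$protocol)
  res <- cv_intensity(fm, tg, blocks, k = 3L, n_perm = 39L, seed = 2L)
  expect_gt(res$r, 0)
  expect_lt(res$p_value, 0.05)
})
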