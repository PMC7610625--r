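#' Fixed algorithm order (also the tie-break order for model selection)
#' @export
ALGORITHMS <- c("svm", "lr", "lda", "nb", "dt", "knn", "helm")

#' ROC curve and area under it
#'
#' The ROC is traced over all distinct score thresholds (tied scores form
#' one diagonal step) and the AUC is its trapezoidal integral — exactly
#' the pair-counting probability (concordant + half ties) / (n1 * n0).
#'
#' @param scores numeric decoder outputs (higher = more positive).
#' @param labels 0/1 truth.
#' @return list with `roc` (data.frame `fpr`, `tpr`, monotone
#'   nondecreasing from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    tl_stop("degenerate-labels", "both classes required for ROC")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(rep(1L, length(y)), grp, sum)
  tp <- cumsum(tp_g); fp <- cumsum(n_g - tp_g)
  tpr <- c(0, tp / n1); fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# --- classifier backends ------------------------------------------------

fit_classifier <- function(algorithm, X, y, seed = 1L) {
  y <- factor(y, levels = c("0", "1"))
  switch(algorithm,
    svm = e1071::svm(X, y, kernel = "linear", cost = 1, scale = FALSE),
    lr = {
      d <- data.frame(.y = y, X, check.names = FALSE)
      suppressWarnings(glm(.y ~ ., data = d, family = binomial()))
    },
    lda = suppressWarnings(MASS::lda(X, grouping = y)),
    nb = e1071::naiveBayes(X, y),
    dt = {
      d <- data.frame(.y = y, X, check.names = TRUE)
      rpart::rpart(.y ~ ., data = d, method = "class")
    },
    knn = list(X = X, y = y, k = 5L),
    helm = fit_helm(X, as.numeric(y == "1"), seed = seed),
    tl_stop("unknown-algorithm", paste("unknown algorithm:", algorithm))
  )
}

score_classifier <- function(algorithm, fit, X) {
  switch(algorithm,
    svm = {
      dv <- attr(predict(fit, X, decision.values = TRUE),
                 "decision.values")
      nm <- colnames(dv)[1]
      v <- as.numeric(dv[, 1])
      # decision value is positive for the class named first in "a/b"
      if (startsWith(nm, "0")) v <- -v
      plogis(v)
    },
    lr = {
      d <- data.frame(X, check.names = FALSE)
      as.numeric(predict(fit, newdata = d, type = "response"))
    },
    lda = as.numeric(predict(fit, X)$posterior[, "1"]),
    nb = as.numeric(predict(fit, X, type = "raw")[, "1"]),
    dt = {
      d <- data.frame(X, check.names = TRUE)
      as.numeric(predict(fit, newdata = d, type = "prob")[, "1"])
    },
    knn = {
      pr <- class::knn(fit$X, X, fit$y, k = fit$k, prob = TRUE,
                       use.all = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    },
    helm = score_helm(fit, X)
  )
}

# hierarchical extreme learning machine: two random-projection tanh
# layers with a seeded ridge readout; deterministic given the seed.
fit_helm <- function(X, y01, h1 = 60L, h2 = 40L, lambda = 1e-2, seed = 1L) {
  d <- ncol(X)
  with_seed(seed, {
    W1 <- matrix(rnorm(d * h1, sd = 1 / sqrt(d)), d, h1)
    b1 <- rnorm(h1, sd = 0.1)
    W2 <- matrix(rnorm(h1 * h2, sd = 1 / sqrt(h1)), h1, h2)
    b2 <- rnorm(h2, sd = 0.1)
    H <- tanh(sweep(tanh(sweep(X %*% W1, 2, b1, "+")) %*% W2, 2, b2, "+"))
    H <- cbind(1, H)
    beta <- solve(crossprod(H) + lambda * diag(ncol(H)), crossprod(H, y01))
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, beta = beta)
  })
}

score_helm <- function(fit, X) {
  H <- tanh(sweep(tanh(sweep(X %*% fit$W1, 2, fit$b1, "+")) %*% fit$W2,
                  2, fit$b2, "+"))
  pmin(pmax(as.numeric(cbind(1, H) %*% fit$beta), 0), 1)
}

# --- decoder training ---------------------------------------------------

usable_frames <- function(features, labels, stim_frames, stim_state) {
  ok <- stats::complete.cases(features) & !labels$warmup
  if (!is.null(stim_frames)) {
    want_on <- stim_state == "on"
    ok <- ok & ((stim_frames > 0) == want_on)
  }
  ok
}

#' Train one (task, stimulation-state) decoder
#'
#' Fits the chosen classifier on frames whose stimulation state matches
#' `stim_state` (the stimulation-state firewall: an "off" model never
#' sees a stimulated frame). Normalization statistics are fitted on the
#' same training frames only.
#'
#' @param features a [extract_features()] matrix.
#' @param labels a [label_series()] on the same frame grid.
#' @param task `"movement"` or `"posture"`.
#' @param stim_state `"on"` or `"off"`.
#' @param algorithm one of [ALGORITHMS].
#' @param stim_frames per-frame stimulation amplitudes (or 0/1); `NULL`
#'   uses all frames (single-state sessions).
#' @param seed seed for seeded fitters (HELM).
#' @return Object of class `decoder_model` with a
#'   `decision_threshold` of 0.5.
#' @export
train_decoder <- function(features, labels, task, stim_state, algorithm,
                          stim_frames = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  stim_state <- match.arg(stim_state, c("on", "off"))
  if (length(labels$labels) != nrow(features))
    tl_stop("grid-mismatch", "features and labels differ in frame count")
  ok <- usable_frames(features, labels, stim_frames, stim_state)
  y <- labels$labels[ok]
  if (length(unique(y)) < 2L)
    tl_stop("degenerate-labels", "training labels contain a single class")
  norm <- fit_normalizer(features[ok, , drop = FALSE])
  X <- apply_normalizer(features[ok, , drop = FALSE], norm)
  fit <- fit_classifier(algorithm, X, y, seed = seed)
  structure(list(task = task, stim_state = stim_state,
                 algorithm = algorithm, fit = fit, norm = norm,
                 decision_threshold = 0.5, seed = seed,
                 trained_on = which(ok)),
            class = "decoder_model")
}

#' Score frames with a trained decoder
#'
#' @param model a [train_decoder()] model.
#' @param features feature matrix (or single feature vector).
#' @return Probability-like scores in \[0, 1\] (`NA` for incomplete
#'   frames).
#' @export
decoder_score <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  out <- rep(NA_real_, nrow(features))
  ok <- stats::complete.cases(features)
  if (any(ok)) {
    X <- apply_normalizer(features[ok, , drop = FALSE], model$norm)
    out[ok] <- score_classifier(model$algorithm, model$fit, X)
  }
  out
}

#' Block-wise cross-validation of one decoder configuration
#'
#' Folds are contiguous groups of protocol blocks — never frame-level
#' splits — so that autocorrelation between neighbouring frames cannot
#' leak across folds. Out-of-fold scores are pooled into a single
#' ROC/AUC.
#'
#' @inheritParams train_decoder
#' @param blocks integer per-frame protocol block index (see
#'   [protocol_block_index()]).
#' @param k number of folds.
#' @return Object of class `crossval_report`: `auc`, `roc`, pooled
#'   `scores`/`labels`, `fold` assignment per used frame, `class_balance`.
#' @export
cross_validate <- function(features, labels, blocks, task, stim_state,
                           algorithm, k = 5L, stim_frames = NULL,
                           seed = 1L) {
  ok <- usable_frames(features, labels, stim_frames, stim_state)
  y_all <- labels$labels
  # count task blocks among usable frames
  task_blocks <- unique(blocks[ok & y_all == 1L])
  if (length(task_blocks) < k)
    tl_stop("too-few-blocks",
            sprintf("%d task blocks < k = %d", length(task_blocks), k))
  ub <- unique(blocks[ok])
  grp <- as.integer(cut(match(blocks, ub), breaks = k, labels = FALSE))
  scores <- rep(NA_real_, length(y_all))
  fold_of <- rep(NA_integer_, length(y_all))
  for (f in seq_len(k)) {
    te <- ok & grp == f
    tr <- ok & grp != f
    if (!any(te)) next
    ytr <- y_all[tr]
    if (length(unique(ytr)) < 2L)
      tl_stop("degenerate-labels", "a training fold has a single class")
    norm <- fit_normalizer(features[tr, , drop = FALSE])
    Xtr <- apply_normalizer(features[tr, , drop = FALSE], norm)
    Xte <- apply_normalizer(features[te, , drop = FALSE], norm)
    fit <- fit_classifier(algorithm, Xtr, ytr, seed = seed)
    scores[te] <- score_classifier(algorithm, fit, Xte)
    fold_of[te] <- f
  }
  use <- !is.na(scores)
  ra <- roc_auc(scores[use], y_all[use])
  structure(list(auc = ra$auc, roc = ra$roc,
                 scores = scores[use], labels = y_all[use],
                 fold = fold_of[use], k = k, algorithm = algorithm,
                 task = task, stim_state = stim_state,
                 class_balance = mean(y_all[use])),
            class = "crossval_report")
}

#' @export
print.crossval_report <- function(x, ...) {
  cat(sprintf("<crossval_report> %s/%s %s: AUC = %.3f (%d frames, %.1f%% positive, %d folds)\n",
              x$task, x$stim_state, x$algorithm, x$auc, length(x$labels),
              100 * x$class_balance, x$k))
  invisible(x)
}

#' Compare classification algorithms on identical folds
#'
#' @inheritParams cross_validate
#' @param algorithms character vector of [ALGORITHMS] entries (>= 2, or
#'   1 for a single-row table).
#' @return list with `table` (data.frame `algorithm`, `auc`, `best`) and
#'   `reports` (per-algorithm [cross_validate()] outputs). Failures
#'   yield `NaN` AUC with a warning. Ties are broken by the fixed order
#'   in [ALGORITHMS].
#' @export
compare_algorithms <- function(features, labels, blocks, task, stim_state,
                               algorithms = ALGORITHMS, k = 5L,
                               stim_frames = NULL, seed = 1L) {
  algorithms <- match.arg(algorithms, ALGORITHMS, several.ok = TRUE)
  reports <- list()
  aucs <- numeric(length(algorithms))
  for (i in seq_along(algorithms)) {
    r <- tryCatch(
      cross_validate(features, labels, blocks, task, stim_state,
                     algorithms[i], k, stim_frames, seed),
      error = function(e) {
        tl_warn("algorithm-failed",
                sprintf("%s failed: %s", algorithms[i], conditionMessage(e)))
        NULL
      })
    reports[[algorithms[i]]] <- r
    aucs[i] <- if (is.null(r)) NaN else r$auc
  }
  rank_order <- match(algorithms, ALGORITHMS)
  best_auc <- suppressWarnings(max(aucs, na.rm = TRUE))
  cand <- which(is.finite(aucs) & aucs >= best_auc - 1e-12)
  best <- cand[which.min(rank_order[cand])]
  list(table = data.frame(algorithm = algorithms, auc = aucs,
                          best = seq_along(algorithms) == best),
       reports = reports)
}

#' Select and retrain the per-cell best decoders
#'
#' For each (task, stimulation-state) cell, the algorithm with the
#' highest cross-validated AUC is retrained on all of that cell's data.
#'
#' @param cells named list with entries `"movement.off"`,
#'   `"movement.on"`, `"posture.off"`, `"posture.on"`; each a list with
#'   `features`, `labels`, `blocks`, optional `stim_frames`, and
#'   `comparison` (a [compare_algorithms()] result).
#' @param seed training seed.
#' @return Named list of four [train_decoder()] models (class
#'   `decoder_bundle`).
#' @export
select_models <- function(cells, seed = 1L) {
  need <- c("movement.off", "movement.on", "posture.off", "posture.on")
  if (!all(need %in% names(cells)))
    tl_stop("incomplete-grid",
            paste("missing cells:",
                  paste(setdiff(need, names(cells)), collapse = ", ")))
  out <- list()
  for (nm in need) {
    cell <- cells[[nm]]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    tab <- cell$comparison$table
    if (all(!is.finite(tab$auc)))
      tl_stop("incomplete-grid", paste("no successful algorithm in", nm))
    alg <- tab$algorithm[tab$best][1]
    out[[nm]] <- train_decoder(cell$features, cell$labels,
                               task = parts[1], stim_state = parts[2],
                               algorithm = alg,
                               stim_frames = cell$stim_frames, seed = seed)
  }
  structure(out, class = "decoder_bundle")
}

# --- tremor-intensity regression ---------------------------------------

#' Fit the SVR tremor-intensity model
#'
#' Support-vector regression from LFP features to the log accelerometer
#' tremor-band power, fitted on stimulation-off frames only. Predictions
#' are exponentiated back to power and clipped at zero.
#'
#' @param features feature matrix.
#' @param target a `tremor_target` (from [tremor_labels()]) or numeric
#'   per-frame power vector.
#' @param stim_frames per-frame stimulation amplitudes; frames with
#'   nonzero stimulation are excluded.
#' @param kernel SVR kernel (default linear).
#' @return Object of class `intensity_model`.
#' @export
fit_intensity <- function(features, target, stim_frames = NULL,
                          kernel = "linear") {
  pow <- if (inherits(target, "tremor_target")) target$power else target
  ok <- stats::complete.cases(features) & is.finite(pow)
  if (!is.null(stim_frames)) ok <- ok & stim_frames == 0
  if (sum(ok) < 4L) tl_stop("no-frames", "too few frames for regression")
  y <- log(pmax(pow[ok], 1e-300))
  if (sd(y) < 1e-12)
    tl_stop("degenerate-target", "tremor target is constant")
  norm <- fit_normalizer(features[ok, , drop = FALSE])
  X <- apply_normalizer(features[ok, , drop = FALSE], norm)
  fit <- e1071::svm(X, y, type = "eps-regression", kernel = kernel,
                    cost = 1, scale = FALSE)
  structure(list(fit = fit, norm = norm, kernel = kernel),
            class = "intensity_model")
}

#' @rdname fit_intensity
#' @param model an `intensity_model`.
#' @return `predict_intensity`: nonnegative predicted tremor power per
#'   frame (`NA` for incomplete frames).
#' @export
predict_intensity <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  out <- rep(NA_real_, nrow(features))
  ok <- stats::complete.cases(features)
  if (any(ok)) {
    X <- apply_normalizer(features[ok, , drop = FALSE], model$norm)
    out[ok] <- pmax(exp(as.numeric(predict(model$fit, X))), 0)
  }
  out
}

#' Held-out evaluation of tremor-intensity regression
#'
#' Block-wise k-fold fit/predict; reports the Pearson correlation
#' between predicted and actual power on pooled held-out frames, with an
#' optional block-permutation null.
#'
#' The reported `r` is computed on the log-power scale on which the
#' model is fit: tremor band power is heavy-tailed (a handful of
#' full-tremor frames dominate the linear scale), so the log scale is
#' the one on which "tracking the tremor envelope" is measurable.
#' `r_power` on the raw power scale is also returned.
#'
#' @inheritParams fit_intensity
#' @param blocks per-frame protocol block index.
#' @param k folds.
#' @param n_perm if > 0, number of block permutations for the null
#'   distribution of r.
#' @param seed permutation seed.
#' @return list with `r`, `r_power`, `frames` and (when `n_perm > 0`)
#'   `p_value`.
#' @export
cv_intensity <- function(features, target, blocks, k = 5L,
                         stim_frames = NULL, kernel = "linear",
                         n_perm = 0L, seed = 1L) {
  pow <- if (inherits(target, "tremor_target")) target$power else target
  ok <- stats::complete.cases(features) & is.finite(pow)
  if (!is.null(stim_frames)) ok <- ok & stim_frames == 0
  ub <- unique(blocks[ok])
  if (length(ub) < k) tl_stop("too-few-blocks", "fewer blocks than folds")
  grp <- as.integer(cut(match(blocks, ub), breaks = k, labels = FALSE))
  run_cv <- function(pw, scale = c("log", "power")) {
    scale <- match.arg(scale)
    pred <- rep(NA_real_, length(pw))
    for (f in seq_len(k)) {
      tr <- ok & grp != f; te <- ok & grp == f
      if (!any(te)) next
      m <- fit_intensity(features[tr, , drop = FALSE], pw[tr],
                         kernel = kernel)
      pred[te] <- predict_intensity(m, features[te, , drop = FALSE])
    }
    use <- ok & !is.na(pred)
    if (scale == "log")
      cor(log(pmax(pred[use], 1e-300)), log(pmax(pw[use], 1e-300)))
    else cor(pred[use], pw[use])
  }
  r_obs <- run_cv(pow)
  out <- list(r = r_obs, r_power = run_cv(pow, "power"),
              frames = which(ok))
  if (n_perm > 0L) {
    r_null <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        perm <- sample(ub)
        # permute whole blocks of the target, keeping features fixed
        pw <- pow
        for (j in seq_along(ub))
          pw[ok & blocks == ub[j]] <-
            resample_block(pow, ok, blocks, perm[j],
                           sum(ok & blocks == ub[j]))
        run_cv(pw)
      }, 0)
    })
    out$p_value <- (1 + sum(r_null >= r_obs)) / (n_perm + 1)
    out$r_null <- r_null
  }
  out
}

# values of `pow` in block `b`, recycled/truncated to length n
resample_block <- function(pow, ok, blocks, b, n) {
  v <- pow[ok & blocks == b]
  rep_len(v, n)
}
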