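#' Binary classification metrics at original prevalence
#'
#' Confusion-matrix metrics at a probability threshold plus the AUC. All
#' values are proportions in \[0, 1\]; AUC is `NA` when the truth is
#' single-class.
#'
#' @param truth 0/1 (or logical/factor with positive level `"scratch"`).
#' @param prob Predicted positive-class probabilities.
#' @param threshold Call threshold, default 0.5.
#' @return One-row tibble: `prevalence`, `auc`, `accuracy`, `recall`,
#'   `specificity`, `f1`, `ppv`, `npv`, plus the raw counts.
#' @export
classification_metrics <- function(truth, prob, threshold = 0.5) {
  if (is.factor(truth) || is.character(truth)) truth <- truth == "scratch"
  y <- as.integer(as.logical(truth))
  call <- as.integer(prob >= threshold)
  tp <- sum(y == 1 & call == 1); fp <- sum(y == 0 & call == 1)
  fn <- sum(y == 1 & call == 0); tn <- sum(y == 0 & call == 0)
  n <- length(y)
  auc <- if (length(unique(y)) < 2L) NA_real_ else {
    as.numeric(pROC::auc(pROC::roc(y, prob, quiet = TRUE, direction = "<")))
  }
  rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  ppv <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  npv <- if (tn + fn == 0) NA_real_ else tn / (tn + fn)
  f1 <- if (is.na(rec) || is.na(ppv) || rec + ppv == 0) NA_real_ else
    2 * ppv * rec / (ppv + rec)
  tibble::tibble(prevalence = mean(y), auc = auc, accuracy = (tp + tn) / n,
                 recall = rec, specificity = spec, f1 = f1, ppv = ppv,
                 npv = npv, tp = tp, fp = fp, fn = fn, tn = tn)
}

feature_matrix_of <- function(features) {
  cols <- attr(features, "feature_cols")
  as.matrix(features[, cols, drop = FALSE])
}

xgb_fit <- function(x, y, nrounds = 60, max_depth = 6, eta = 0.2,
                    scale_pos_weight = 1, seed = 1L, watch = NULL,
                    early_stopping = NULL) {
  with_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(x, label = y)
    params <- list(objective = "binary:logistic", eval_metric = "auc",
                   max_depth = max_depth, eta = eta,
                   scale_pos_weight = scale_pos_weight, nthread = 1)
    if (is.null(watch)) {
      xgboost::xgb.train(params, dtrain, nrounds = nrounds, verbose = 0)
    } else {
      dval <- xgboost::xgb.DMatrix(watch$x, label = watch$y)
      xgboost::xgb.train(params, dtrain, nrounds = nrounds, verbose = 0,
                         evals = list(val = dval),
                         early_stopping_rounds = early_stopping)
    }
  })
}

#' Recursive feature elimination with a boosted-tree ranker
#'
#' Iteratively drops the lowest-importance features (tree gain importance),
#' recording the validation AUC at each feature-set size, until `target_k`
#' features remain. An internal seeded 80/20 row split supplies the
#' validation AUC curve (the elbow plot used to pick the deployed sizes).
#'
#' @param x Numeric feature matrix (or `ns_features` tibble).
#' @param y 0/1 labels (or the tibble's `label` column is used).
#' @param target_k Number of features to keep (paper-style defaults: 16 for
#'   accelerometer-only, 18 for both sensors).
#' @param step How many features to drop per iteration (default 1, the
#'   classical schedule; larger steps trade resolution of the curve for
#'   speed).
#' @param seed RNG seed for the split and fits.
#' @param nrounds Boosting rounds per refit.
#' @return List: `selected` (character), `ranking` (all features, most
#'   important last dropped first), `curve` (tibble `n_features`, `auc`).
#' @export
recursive_feature_elimination <- function(x, y = NULL, target_k = 16, step = 1,
                                          seed = 1L, nrounds = 60) {
  if (inherits(x, "ns_features")) {
    y <- as.numeric(x$label == "scratch")
    x <- feature_matrix_of(x)
  }
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) ns_abort("need two classes", "ns_error_degenerate")
  if (target_k > ncol(x)) ns_abort("target_k exceeds feature count", "ns_error_k")
  feats <- colnames(x)
  dropped <- character(0)
  curve_n <- integer(0); curve_auc <- numeric(0)
  idx <- with_seed(seed, sample.int(nrow(x)))
  n_tr <- max(2L, floor(0.8 * nrow(x)))
  tr <- idx[seq_len(n_tr)]; va <- idx[-seq_len(n_tr)]
  if (length(unique(y[va])) < 2L || length(unique(y[tr])) < 2L) {
    # degenerate random split: stratify instead
    pos <- which(y == 1); neg <- which(y == 0)
    tr <- c(pos[-1], neg[-1]); va <- c(pos[1], neg[1])
  }
  repeat {
    fit <- xgb_fit(x[tr, feats, drop = FALSE], y[tr], nrounds = nrounds,
                   seed = seed)
    pv <- stats::predict(fit, xgboost::xgb.DMatrix(x[va, feats, drop = FALSE]))
    auc <- if (length(unique(y[va])) < 2L) NA_real_ else
      as.numeric(pROC::auc(pROC::roc(y[va], pv, quiet = TRUE, direction = "<")))
    curve_n <- c(curve_n, length(feats)); curve_auc <- c(curve_auc, auc)
    if (length(feats) <= target_k) break
    imp <- xgboost::xgb.importance(model = fit)
    gain <- stats::setNames(rep(0, length(feats)), feats)
    gain[imp$Feature] <- imp$Gain
    k_drop <- min(max(1L, step), length(feats) - target_k)
    drop_now <- names(sort(gain))[seq_len(k_drop)]
    dropped <- c(dropped, drop_now)
    feats <- setdiff(feats, drop_now)
  }
  # final importance ordering of the survivors
  fit <- xgb_fit(x[tr, feats, drop = FALSE], y[tr], nrounds = nrounds, seed = seed)
  imp <- xgboost::xgb.importance(model = fit)
  gain <- stats::setNames(rep(0, length(feats)), feats)
  gain[imp$Feature] <- imp$Gain
  ranking <- c(names(sort(gain, decreasing = TRUE)), rev(dropped))
  list(selected = feats, ranking = ranking,
       curve = tibble::tibble(n_features = curve_n, auc = curve_auc))
}

#' Train the boosted-tree top layer of the ensemble
#'
#' Randomly splits the training windows 8-2 into train and validation sets,
#' uses the validation set for early stopping, and tunes tree depth and the
#' positive-class weight (`scale_pos_weight`, which balances the training set
#' only -- evaluation is always at original prevalence) over a small grid by
#' validation AUC. A degenerate split (single-class validation set) is
#' re-drawn with the next seed.
#'
#' @param features A `ns_features` tibble with labels (training subjects
#'   only), typically after [derive_dl_features()].
#' @param selected Character vector of feature columns to use.
#' @param seed RNG seed.
#' @param depth_grid,pos_weight_grid Hyperparameter grids; `NULL` weight grid
#'   means `c(1, n_neg/n_pos)`.
#' @param nrounds,early_stopping Boosting schedule.
#' @return A `ns_booster` list: `booster`, `selected`, `params`,
#'   `val_fraction`, `seed`.
#' @export
train_ensemble <- function(features, selected, seed = 1L,
                           depth_grid = c(4, 6, 8), pos_weight_grid = NULL,
                           nrounds = 300, early_stopping = 25) {
  y <- as.numeric(features$label == "scratch")
  if (length(unique(y)) < 2L) ns_abort("need two classes", "ns_error_degenerate")
  x <- as.matrix(features[, selected, drop = FALSE])
  n <- nrow(x)
  sd_try <- seed
  for (try in 1:20) {
    idx <- with_seed(sd_try, sample.int(n))
    n_tr <- floor(0.8 * n)
    tr <- idx[seq_len(n_tr)]; va <- idx[-seq_len(n_tr)]
    if (length(unique(y[tr])) == 2L && length(unique(y[va])) == 2L) break
    sd_try <- sd_try + 1L
  }
  if (is.null(pos_weight_grid)) {
    pos_weight_grid <- unique(c(1, sum(y[tr] == 0) / max(1, sum(y[tr] == 1))))
  }
  best <- NULL
  for (d in depth_grid) {
    for (w in pos_weight_grid) {
      fit <- xgb_fit(x[tr, , drop = FALSE], y[tr], nrounds = nrounds,
                     max_depth = d, eta = 0.1, scale_pos_weight = w,
                     seed = sd_try,
                     watch = list(x = x[va, , drop = FALSE], y = y[va]),
                     early_stopping = early_stopping)
      sc <- as.numeric(xgboost::xgb.attr(fit, "best_score"))
      if (is.null(best) || sc > best$score) {
        best <- list(score = sc, fit = fit, depth = d, weight = w)
      }
    }
  }
  structure(list(booster = best$fit, selected = selected,
                 params = list(max_depth = best$depth,
                               scale_pos_weight = best$weight,
                               val_auc = best$score),
                 val_fraction = length(va) / n, seed = sd_try,
                 val_index = sort(va)),
            class = "ns_booster")
}

#' Train the full ensembled scratch classifier
#'
#' The complete training recipe on labeled windows from two or more training
#' subjects: train the convolutional and recurrent extractors, append their
#' ten penultimate features to the interpretable matrix, select features by
#' recursive elimination, and fit the boosted top layer with an 8-2
#' train/validation split and positive-class weighting.
#'
#' @param windows Labeled `ns_windows` (training subjects only).
#' @param sensors `"accel"` or `"both"`.
#' @param target_k Features kept by RFE (default 16 accel, 18 both).
#' @param seed RNG seed threaded through every stage.
#' @param epochs Extractor training epochs.
#' @param rfe_step Features dropped per RFE iteration.
#' @param features Optional precomputed interpretable `ns_features` for these
#'   windows (avoids recomputation).
#' @return A `ns_model`: extractors, booster, `selected`, `threshold`,
#'   `sensors`, RFE curve.
#' @export
train_scratch_model <- function(windows, sensors = c("accel", "both"),
                                target_k = NULL, seed = 1L, epochs = 12,
                                rfe_step = 25, features = NULL) {
  sensors <- match.arg(sensors)
  if (is.null(target_k)) target_k <- if (sensors == "accel") 16L else 18L
  if (is.null(features)) features <- assemble_features(windows, sensors)
  extractors <- list(
    conv = train_extractor("conv", windows, sensors, epochs = epochs,
                           seed = seed),
    recurrent = train_extractor("recurrent", windows, sensors, epochs = epochs,
                                seed = seed + 1L))
  feats <- derive_dl_features(extractors, features, windows)
  rfe <- recursive_feature_elimination(feats, target_k = target_k,
                                       step = rfe_step, seed = seed)
  booster <- train_ensemble(feats, rfe$selected, seed = seed)
  structure(list(extractors = extractors, booster = booster,
                 selected = rfe$selected, rfe_curve = rfe$curve,
                 sensors = sensors, threshold = 0.5, seed = seed),
            class = "ns_model")
}

#' Predict scratch probabilities for windows
#'
#' @param object A `ns_model`.
#' @param windows A `ns_windows` set.
#' @param features Optional precomputed interpretable features for `windows`.
#' @param ... Unused.
#' @return Tibble: window metadata plus `prob` and `call` (threshold stored in
#'   the model).
#' @export
predict.ns_model <- function(object, windows, features = NULL, ...) {
  if (nrow(windows) == 0L) {
    return(tibble::tibble(hand = character(), start_s = numeric(),
                          prob = numeric(), call = logical()))
  }
  if (is.null(features)) features <- assemble_features(windows, object$sensors)
  feats <- derive_dl_features(object$extractors, features, windows)
  x <- as.matrix(feats[, object$selected, drop = FALSE])
  prob <- stats::predict(object$booster$booster, xgboost::xgb.DMatrix(x))
  out <- tibble::as_tibble(windows[, intersect(c("subject", "night", "hand",
                                                 "start_s", "label"),
                                               names(windows))])
  out$prob <- as.numeric(prob)
  out$call <- out$prob >= object$threshold
  out
}

#' Leave-one-subject-out evaluation of the scratch classifier
#'
#' One fold per subject: the held-out subject's windows touch neither
#' extractor training, feature selection, nor early stopping; feature
#' selection is re-run within each fold; metrics are computed on the held-out
#' subject at original prevalence. Folds whose held-out subject has no
#' positive windows report `NA` AUC and are excluded from the AUC summary
#' with a warning.
#'
#' @param windows Labeled `ns_windows` with a `subject` column (>= 2
#'   subjects).
#' @param sensors `"accel"` or `"both"`.
#' @param target_k,seed,epochs,rfe_step Passed to [train_scratch_model()].
#' @return A `ns_loso` list: `folds` (per-fold metric tibble with train/test
#'   subject bookkeeping), `summary` (mean and SD per metric), `sensors`.
#' @export
evaluate_loso <- function(windows, sensors = c("accel", "both"),
                          target_k = NULL, seed = 1L, epochs = 12,
                          rfe_step = 25) {
  sensors <- match.arg(sensors)
  if (!"subject" %in% names(windows)) {
    ns_abort("windows need a 'subject' column", "ns_error_schema")
  }
  subjects <- unique(windows$subject)
  if (length(subjects) < 2L) {
    ns_abort("leave-one-subject-out needs >= 2 subjects", "ns_error_degenerate")
  }
  all_feats <- assemble_features(windows, sensors)
  folds <- list()
  for (i in seq_along(subjects)) {
    held <- subjects[i]
    tr_idx <- which(windows$subject != held)
    te_idx <- which(windows$subject == held)
    w_tr <- windows[tr_idx, ]
    class(w_tr) <- class(windows)
    attr(w_tr, "rate_hz") <- attr(windows, "rate_hz")
    f_tr <- all_feats[tr_idx, ]
    class(f_tr) <- class(all_feats)
    attr(f_tr, "feature_cols") <- attr(all_feats, "feature_cols")
    mdl <- train_scratch_model(w_tr, sensors, target_k = target_k,
                               seed = seed + i, epochs = epochs,
                               rfe_step = rfe_step, features = f_tr)
    w_te <- windows[te_idx, ]
    class(w_te) <- class(windows)
    attr(w_te, "rate_hz") <- attr(windows, "rate_hz")
    f_te <- all_feats[te_idx, ]
    class(f_te) <- class(all_feats)
    attr(f_te, "feature_cols") <- attr(all_feats, "feature_cols")
    pr <- predict(mdl, w_te, features = f_te)
    met <- classification_metrics(windows$label[te_idx], pr$prob)
    met$subject <- held
    met$n_train_subjects <- length(unique(w_tr$subject))
    met$held_out_in_train <- held %in% w_tr$subject
    folds[[i]] <- met
  }
  folds <- dplyr::bind_rows(folds)
  if (any(is.na(folds$auc))) {
    warning("fold(s) without positive windows excluded from AUC summary",
            call. = FALSE)
  }
  metric_cols <- c("prevalence", "auc", "accuracy", "recall", "specificity",
                   "f1", "ppv", "npv")
  summ <- tibble::tibble(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(folds[[m]], na.rm = TRUE), 1),
    sd = vapply(metric_cols, function(m) stats::sd(folds[[m]], na.rm = TRUE), 1))
  structure(list(folds = folds, summary = summ, sensors = sensors, seed = seed),
            class = "ns_loso")
}
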