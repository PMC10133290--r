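test_that("extractors expose a 5-unit penultimate layer and train to fit", {
  w <- mini_windows()
  conv <- train_extractor("conv", w, "accel", epochs = 10, seed = 1)
  expect_equal(conv$penultimate_dim, 5L)
  emb <- extract_embedding(conv, w[1:7, ])
  expect_equal(dim(emb), c(7L, 5L))
  acc <- mean((nightscratch:::extractor_predict(conv, w) > 0.5) ==
                (w$label == "scratch"))
  expect_gt(acc, 0.9)                    # easy synthetic data, 10 epochs
  rnn <- train_extractor("recurrent", w, "accel", epochs = 10, seed = 1)
  expect_equal(ncol(extract_embedding(rnn, w[1:3, ])), 5L)
  acc2 <- mean((nightscratch:::extractor_predict(rnn, w) > 0.5) ==
                 (w$label == "scratch"))
  expect_gt(acc2, 0.9)
  # same seed, same training data -> identical loss trajectory
  conv2 <- train_extractor("conv", w, "accel", epochs = 10, seed = 1)
  expect_identical(conv$loss, conv2$loss)
  # single-class training set is refused
  pos <- w[w$label == "scratch", ]
  class(pos) <- class(w)
  expect_error(train_extractor("conv", pos, "accel", seed = 1),
               class = "ns_error_degenerate")
})

test_that("learned features extend the matrix to 348 / 686 columns", {
  w <- mini_windows()
  f <- assemble_features(w, "accel")
  mdl <- mini_model()
  full <- derive_dl_features(mdl$extractors, f, w)
  expect_equal(length(attr(full, "feature_cols")), 348)
  expect_true(all(paste0("dl_conv_", 1:5) %in% names(full)))
  expect_true(all(paste0("dl_rnn_", 1:5) %in% names(full)))
  expect_error(extract_embedding(structure(list(), class = "list"), w),
               class = "ns_error_schema")
  # both-sensor path reaches 686
  wb <- mini_windows_both()[1:10, ]
  class(wb) <- class(mini_windows_both())
  attr(wb, "rate_hz") <- 20
  fb <- assemble_features(wb, "both")
  exb <- list(conv = train_extractor("conv", mini_windows_both(), "both",
                                     epochs = 2, seed = 1),
              recurrent = train_extractor("recurrent", mini_windows_both(),
                                          "both", epochs = 2, seed = 2))
  fullb <- derive_dl_features(exb, fb, wb)
  expect_equal(length(attr(fullb, "feature_cols")), 686)
})

test_that("recursive elimination ranks planted informative features on top", {
  set.seed(70)
  n <- 400
  x <- matrix(rnorm(n * 55), n, 55,
              dimnames = list(NULL, c(paste0("inf", 1:5), paste0("noise", 1:50))))
  y <- as.numeric(x[, 1] + x[, 2] - x[, 3] + 0.8 * x[, 4] + 0.8 * x[, 5] +
                    rnorm(n, 0, 0.5) > 0)
  rfe <- recursive_feature_elimination(x, y, target_k = 5, step = 5, seed = 1)
  expect_true(all(paste0("inf", 1:5) %in% rfe$ranking[1:10]))
  expect_equal(length(rfe$selected), 5)
  expect_true(all(diff(rfe$curve$n_features) < 0))
  # k = n_features: the ranking covers every feature, nothing is dropped
  rfe_all <- recursive_feature_elimination(x, y, target_k = 55, seed = 1)
  expect_equal(sort(rfe_all$ranking), sort(colnames(x)))
  expect_equal(length(rfe_all$selected), 55)
  expect_error(recursive_feature_elimination(x, y, target_k = 100),
               class = "ns_error_k")
})

test_that("the boosted top layer holds out 20% for early stopping", {
  w <- mini_windows()
  f <- assemble_features(w, "accel")
  mdl <- mini_model()
  full <- derive_dl_features(mdl$extractors, f, w)
  boost <- train_ensemble(full, mdl$selected, seed = 3)
  expect_equal(boost$val_fraction, 0.2, tolerance = 1.5 / nrow(w))
  boost2 <- train_ensemble(full, mdl$selected, seed = 3)
  x <- as.matrix(full[, mdl$selected])
  p1 <- predict(boost$booster, xgboost::xgb.DMatrix(x))
  p2 <- predict(boost2$booster, xgboost::xgb.DMatrix(x))
  expect_identical(p1, p2)                       # same seed, same model
})

test_that("classification metrics match hand-computed confusion counts", {
  # TP = 3, FP = 1, FN = 1, TN = 15
  truth <- c(rep(1, 4), rep(0, 16))
  prob <- c(0.9, 0.8, 0.7, 0.2, 0.6, rep(0.1, 15))
  m <- classification_metrics(truth, prob)
  expect_equal(m$tp, 3); expect_equal(m$fp, 1)
  expect_equal(m$fn, 1); expect_equal(m$tn, 15)
  expect_equal(m$recall, 0.75)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$specificity, 0.9375)
  expect_equal(m$f1, 0.75)
  expect_equal(m$accuracy, (3 + 15) / 20)
  expect_equal(m$f1, 2 * m$ppv * m$recall / (m$ppv + m$recall))
  # perfectly separable -> AUC 1
  expect_equal(classification_metrics(truth[1:8], c(1, 1, 1, 1, 0, 0, 0, 0) *
                                        0.9 + 0.05)$auc, 1)
})

test_that("LOSO produces one clean fold per subject without leakage", {
  w <- mini_windows()
  loso <- get_fixture("mini_loso", function() {
    evaluate_loso(mini_windows(), "accel", seed = 1, epochs = 6,
                  rfe_step = 60)
  })
  expect_equal(nrow(loso$folds), length(unique(w$subject)))
  expect_setequal(loso$folds$subject, unique(w$subject))
  expect_true(all(!loso$folds$held_out_in_train))
  expect_true(all(loso$folds$n_train_subjects ==
                    length(unique(w$subject)) - 1))
  met <- loso$folds[, c("prevalence", "auc", "accuracy", "recall",
                        "specificity", "f1", "ppv", "npv")]
  expect_true(all(as.matrix(met) >= 0 & as.matrix(met) <= 1, na.rm = TRUE))
  # metric identities per fold
  expect_equal(loso$folds$accuracy,
               (loso$folds$tp + loso$folds$tn) /
                 (loso$folds$tp + loso$folds$fp + loso$folds$fn +
                    loso$folds$tn))
  expect_equal(glance(loso)$metric,
               c("prevalence", "auc", "accuracy", "recall", "specificity",
                 "f1", "ppv", "npv"))
  # a single subject is refused
  one <- w[w$subject == w$subject[1], ]
  class(one) <- class(w)
  expect_error(evaluate_loso(one, "accel"), class = "ns_error_degenerate")
})

test_that("tidiers return tidy shapes", {
  mdl <- mini_model()
  td <- tidy(mdl)
  expect_true(all(c("feature", "gain") %in% names(td)))
  expect_equal(nrow(td), length(mdl$selected))
  gl <- glance(mdl)
  expect_equal(gl$n_selected, 16)
  loso <- get_fixture("mini_loso", function() stop("built above"))
  lt <- tidy(loso)
  expect_true(all(c("subject", "metric", "value") %in% names(lt)))
})
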