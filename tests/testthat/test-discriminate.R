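test_that("detection rate implements the strict lower-bound rule", {
  m <- cmat(0, 1, 10)
  m[1, 1:7] <- 6L
  expect_equal(unname(detection_rate(m, m = 5)), 0.7)
  m2 <- cmat(1:20, 2, 10)
  expect_equal(unname(detection_rate(m2, m = 0)), c(1, 1))
  expect_equal(unname(detection_rate(m2, m = 10000L)), c(0, 0))
})

test_that("feature selection is strict and errors when empty", {
  m <- cmat(0, 2, 10)
  m[1, 1:5] <- 3L   # d = 0.5
  m[2, 1:9] <- 3L   # d = 0.9
  expect_equal(select_features(m, t = 0.5, m = 0), "g002")
  m3 <- cmat(5, 3, 4)
  expect_setequal(select_features(m3, t = 0, m = 0), rownames(m3))
  expect_error(select_features(m, t = 0.95, m = 0), "lower t")
})

test_that("rank normalization follows descending, average-tie, min-max rules", {
  # within-sample descending ranks
  m <- matrix(c(5, 2, 9), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  sc <- rank_normalize(cbind(m, s2 = c(1, 2, 3)))
  ranks_s1 <- rank(-m[, 1], ties.method = "average")
  expect_equal(unname(ranks_s1), c(2, 3, 1))
  # average ranks for ties
  mt <- matrix(c(4, 4, 7), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  rt <- rank(-mt[, 1], ties.method = "average")
  expect_equal(unname(rt), c(2.5, 2.5, 1))
  # per-gene min-max over two samples maps ranks to 0 and 1
  m2 <- matrix(c(10, 1, 5,
                 1, 10, 5), 3, 2,
               dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  sc2 <- rank_normalize(m2)
  expect_equal(unname(sc2$features[, "a"]), c(0, 1))
  expect_equal(unname(sc2$features[, "b"]), c(1, 0))
  # constant-rank gene maps to 0.5
  expect_equal(unname(sc2$features[, "c"]), c(0.5, 0.5))
  expect_true(all(sc2$features >= 0 & sc2$features <= 1))
  expect_error(rank_normalize(m2[1, , drop = FALSE]), "2 genes")
})

test_that("rank features are invariant to increasing per-sample transforms", {
  set.seed(41)
  m <- matrix(rpois(200, 50), 20, 10,
              dimnames = list(sprintf("g%03d", 1:20), paste0("s", 1:10)))
  f1 <- rank_normalize(m)$features
  m2 <- m
  m2[, 1:5] <- m2[, 1:5] * 7L          # per-sample scaling
  m3 <- log1p(m2) + 2                  # global monotone transform
  expect_identical(f1, rank_normalize(m2)$features)
  expect_identical(f1, rank_normalize(m3)$features)
})

test_that("rank scaling fitted on train clips held-out samples to [0, 1]", {
  set.seed(42)
  m <- matrix(rpois(300, 40), 30, 10,
              dimnames = list(sprintf("g%03d", 1:30), paste0("s", 1:10)))
  sc <- rank_normalize(m[, 1:6], fit_samples = colnames(m)[1:6])
  new_f <- rank_transform(sc, m[, 7:10])
  expect_true(all(new_f >= 0 & new_f <= 1))
  expect_equal(colnames(new_f), sc$gene_ids)
  # transforming the fit samples reproduces the fitted features
  expect_equal(rank_transform(sc, m[, 1:6]), sc$features)
})

test_that("stratified splits have the right sizes and are deterministic", {
  labels <- factor(rep(c("control", "PD"), c(58, 58)))
  sp <- split_train_test(labels, 81, 35, seed = 3)
  expect_length(sp$train, 81)
  expect_length(sp$test, 35)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_train_test(labels, 81, 35, seed = 3))
  # class proportions preserved within one sample
  frac_train <- mean(labels[sp$train] == "PD")
  expect_lt(abs(frac_train - 0.5), 1 / 35)
  expect_error(split_train_test(labels, 80, 35, seed = 1), "equal")
})

test_that("the stage regressor recovers a deterministic stage signal", {
  set.seed(44)
  n <- 200
  X <- matrix(runif(n * 20), n, 20,
              dimnames = list(NULL, sprintf("f%02d", 1:20)))
  stage <- 2 * X[, 1] + X[, 2] - X[, 3] + 0.5 * X[, 4] * X[, 5]
  tr <- 1:150; te <- 151:200
  rg <- fit_stage_regressor(X[tr, ], stage[tr], seed = 1)
  pred <- predict(rg, data = as.data.frame(X[te, ]))$predictions
  expect_gte(cor(pred, stage[te], method = "spearman"), 0.8)
  # null control: permuted targets carry no held-out signal
  rg0 <- fit_stage_regressor(X[tr, ], sample(stage[tr]), seed = 1)
  pred0 <- predict(rg0, data = as.data.frame(X[te, ]))$predictions
  expect_lte(abs(cor(pred0, stage[te], method = "spearman")), 0.3)
  # determinism
  rg2 <- fit_stage_regressor(X[tr, ], stage[tr], seed = 1)
  expect_identical(pred, predict(rg2,
                                 data = as.data.frame(X[te, ]))$predictions)
  expect_warning(fit_stage_regressor(X[tr, ], rep(1, 150), seed = 1),
                 "constant")
})

test_that("the classifier recovers a deterministic label signal", {
  set.seed(45)
  n <- 200
  X <- matrix(runif(n * 20), n, 20,
              dimnames = list(NULL, sprintf("f%02d", 1:20)))
  labels <- factor(ifelse(X[, 1] > 0.5, "PD", "control"),
                   levels = c("control", "PD"))
  tr <- 1:150; te <- 151:200
  cl <- fit_classifier(X[tr, ], labels[tr], seed = 2)
  prob <- predict(cl, data = as.data.frame(X[te, ]))$predictions[, "PD"]
  expect_true(all(prob >= 0 & prob <= 1))
  expect_gte(auc_score(labels[te], prob), 0.95)
  # label-permuted null
  cl0 <- fit_classifier(X[tr, ], sample(labels[tr]), seed = 2)
  prob0 <- predict(cl0, data = as.data.frame(X[te, ]))$predictions[, "PD"]
  auc0 <- auc_score(labels[te], prob0)
  expect_gte(auc0, 0.35)
  expect_lte(auc0, 0.65)
  expect_error(fit_classifier(X[tr, ], rep("PD", 150), seed = 1),
               "single class")
})

test_that("the stacked model is deterministic given data and seed", {
  fx <- ml_fixture(seed = 46, n_genes = 150, n_per_group = 15)
  tr <- fx$split$train; te <- fx$split$test
  m1 <- fit_stacked_model(fx$counts[, tr], fx$meta[tr, ], seed = 5,
                          oof_folds = 5)
  m2 <- fit_stacked_model(fx$counts[, tr], fx$meta[tr, ], seed = 5,
                          oof_folds = 5)
  p1 <- predict(m1, fx$counts[, te], fx$meta[te, ])
  p2 <- predict(m2, fx$counts[, te], fx$meta[te, ])
  expect_identical(p1, p2)
  expect_true(all(p1$prob_pd >= 0 & p1$prob_pd <= 1))
  # ablation model has no stage prediction
  m0 <- fit_stacked_model(fx$counts[, tr], fx$meta[tr, ], seed = 5,
                          oof_folds = 5, use_regressor = FALSE)
  p0 <- predict(m0, fx$counts[, te], fx$meta[te, ])
  expect_true(all(is.na(p0$predicted_stage)))
})

test_that("confusion metrics match the worked example and degenerate cases", {
  # TP=10, FP=2, FN=3, TN=20
  labels <- factor(rep(c("PD", "control"), c(13, 22)),
                   levels = c("control", "PD"))
  probs <- c(rep(0.9, 10), rep(0.1, 3), rep(0.9, 2), rep(0.1, 20))
  cm <- confusion_metrics(labels, probs)
  expect_equal(cm$tp, 10); expect_equal(cm$fp, 2)
  expect_equal(cm$fn, 3); expect_equal(cm$tn, 20)
  expect_equal(cm$sensitivity, 10 / 13, tolerance = 1e-12)
  expect_equal(cm$specificity, 20 / 22, tolerance = 1e-12)
  expect_equal(cm$precision, 10 / 12, tolerance = 1e-12)
  expect_equal(cm$f1, 0.8, tolerance = 1e-12)
  # perfect scores
  lab2 <- factor(c("PD", "PD", "control", "control"),
                 levels = c("control", "PD"))
  cm2 <- confusion_metrics(lab2, c(1, 1, 0, 0))
  expect_equal(unlist(cm2[c("sensitivity", "specificity", "f1")]),
               c(sensitivity = 1, specificity = 1, f1 = 1))
  expect_equal(auc_score(lab2, c(1, 1, 0, 0)), 1)
})

test_that("AUC agrees with an independent Mann-Whitney computation", {
  set.seed(47)
  for (i in 1:10) {
    labels <- factor(sample(rep(c("control", "PD"), c(12, 8))),
                     levels = c("control", "PD"))
    scores <- round(runif(20), 2)  # rounding forces ties
    expect_equal(auc_score(labels, scores), brute_auc(labels, scores),
                 tolerance = 1e-12)
  }
  expect_error(auc_score(factor(rep("PD", 4), levels = c("control", "PD")),
                         runif(4)), "single class")
})

test_that("random-search tuning is deterministic and avoids fatal thresholds", {
  fx <- ml_fixture(seed = 48, n_genes = 120, n_per_group = 15)
  tr <- fx$split$train
  # degenerate space of size 1 returns that point
  space1 <- lapply(default_search_space(), function(v) v[1])
  tn1 <- tune_hyperparameters(fx$counts[, tr], fx$meta[tr, ],
                              search_space = space1, n_trials = 2,
                              seed = 9, n_folds = 3, oof_folds = 3)
  expect_identical(tn1$best, space1)
  # a threshold that removes every gene scores worse than a sane one
  space2 <- list(t = c(0.9, 1.0), m = 0L, n_estimators = 50L,
                 max_depth = 0L, max_features = 0.5,
                 min_samples_leaf = 1L, min_samples_split = 2L)
  tn2 <- tune_hyperparameters(fx$counts[, tr], fx$meta[tr, ],
                              search_space = space2, n_trials = 6,
                              seed = 10, n_folds = 3, oof_folds = 3)
  expect_equal(tn2$best$t, 0.9)
  tn3 <- tune_hyperparameters(fx$counts[, tr], fx$meta[tr, ],
                              search_space = space2, n_trials = 6,
                              seed = 10, n_folds = 3, oof_folds = 3)
  expect_identical(tn2$best, tn3$best)
  expect_identical(tn2$trials$cv_auc, tn3$trials$cv_auc)
})
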