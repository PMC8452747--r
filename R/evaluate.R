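#' ROC AUC of PD probabilities
#'
#' Trapezoidal area under the receiver operating characteristic curve, with
#' "PD" as the positive class and higher probabilities indicating PD.
#'
#' @param labels Factor or character with values "control"/"PD".
#' @param probs Numeric scores in \[0, 1\].
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(labels, probs) {
  labels <- factor(labels, levels = c("control", "PD"))
  if (nlevels(droplevels(labels)) < 2) {
    stop("AUC undefined: labels contain a single class", call. = FALSE)
  }
  as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = probs,
    levels = c("control", "PD"), direction = "<", quiet = TRUE
  )))
}

#' Confusion-matrix metrics at a probability threshold
#'
#' Classifies a sample as PD when its probability is >= `threshold`
#' (default 0.5) and reports sensitivity, specificity, precision, and the
#' F1 score (the harmonic mean of sensitivity and precision), plus the raw
#' confusion counts.
#'
#' @inheritParams auc_score
#' @param threshold Operating point on the probability scale.
#' @return Named list: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `precision`, `f1`.
#' @export
confusion_metrics <- function(labels, probs, threshold = 0.5) {
  labels <- factor(labels, levels = c("control", "PD"))
  pred_pd <- probs >= threshold
  tp <- sum(pred_pd & labels == "PD")
  fp <- sum(pred_pd & labels == "control")
  tn <- sum(!pred_pd & labels == "control")
  fn <- sum(!pred_pd & labels == "PD")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0) {
    2 * sens * prec / (sens + prec)
  } else NA_real_
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = sens, specificity = spec,
       precision = prec, f1 = f1)
}

# ROC curve points (1 - specificity, sensitivity) from pROC.
roc_points <- function(labels, probs) {
  labels <- factor(labels, levels = c("control", "PD"))
  r <- pROC::roc(response = labels, predictor = probs,
                 levels = c("control", "PD"), direction = "<",
                 quiet = TRUE)
  data.frame(fpr = rev(1 - r$specificities),
             tpr = rev(r$sensitivities))
}

#' Multi-seed evaluation of the stacked model on held-out data
#'
#' Trains the stacked model `n_seeds` times with different seeds on the
#' training samples, scores the disjoint test samples each time, and
#' reports per-seed and aggregate (mean and SD) AUC, sensitivity,
#' specificity, precision, and F1 at probability threshold 0.5, together
#' with confusion counts and ROC points. The ablation without the H&Y
#' stage regressor is evaluated alongside for comparison.
#'
#' @param counts_train,meta_train Training data (post-QC).
#' @param counts_test,meta_test Held-out test data (same gene panel,
#'   disjoint samples).
#' @param hyperparams See [default_hyperparams()].
#' @param n_seeds Number of training repetitions (default 5).
#' @param seed Base seed; repetition i uses `seed + i - 1`.
#' @param with_ablation Also evaluate the model without the stage
#'   regressor.
#' @param oof_folds Folds for the out-of-fold stage feature.
#' @return List of class `ssl_eval` with `per_seed` (`data.frame`: model,
#'   seed, auc, sensitivity, specificity, precision, f1, tp, fp, tn, fn,
#'   regressor_spearman), `aggregate` (mean and SD per model and metric),
#'   and `roc` (per-seed ROC points for the stacked model).
#' @export
evaluate_stacked <- function(counts_train, meta_train,
                             counts_test, meta_test,
                             hyperparams = default_hyperparams(),
                             n_seeds = 5L, seed = 1L,
                             with_ablation = TRUE, oof_folds = 10L) {
  if (length(intersect(colnames(counts_train), colnames(counts_test)))) {
    stop("train and test samples must be disjoint", call. = FALSE)
  }
  labels_test <- factor(
    meta_test$group[match(colnames(counts_test), meta_test$sample_id)],
    levels = c("control", "PD")
  )
  if (nlevels(droplevels(labels_test)) < 2) {
    stop("AUC undefined: test set contains a single class", call. = FALSE)
  }
  variants <- if (with_ablation) c(TRUE, FALSE) else TRUE
  rows <- list()
  roc <- list()
  for (use_reg in variants) {
    model_name <- if (use_reg) "stacked" else "no_regressor"
    for (i in seq_len(n_seeds)) {
      s <- seed + i - 1L
      fit <- fit_stacked_model(counts_train, meta_train, hyperparams,
                               seed = s, oof_folds = oof_folds,
                               use_regressor = use_reg)
      pred <- predict(fit, counts_test, meta_test)
      cm <- confusion_metrics(labels_test, pred$prob_pd)
      rho <- NA_real_
      if (use_reg) {
        stages_test <- as.numeric(
          meta_test$hy_stage[match(colnames(counts_test),
                                   meta_test$sample_id)]
        )
        stages_test[is.na(stages_test)] <- 0
        rho <- if (stats::sd(stages_test) > 0) {
          suppressWarnings(stats::cor(stages_test, pred$predicted_stage,
                                      method = "spearman"))
        } else NA_real_
        roc[[length(roc) + 1L]] <- cbind(seed = s,
                                         roc_points(labels_test,
                                                    pred$prob_pd))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model = model_name, seed = s,
        auc = auc_score(labels_test, pred$prob_pd),
        sensitivity = cm$sensitivity, specificity = cm$specificity,
        precision = cm$precision, f1 = cm$f1,
        tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
        regressor_spearman = rho,
        stringsAsFactors = FALSE
      )
    }
  }
  per_seed <- do.call(rbind, rows)
  metrics <- c("auc", "sensitivity", "specificity", "precision", "f1")
  agg <- do.call(rbind, lapply(split(per_seed, per_seed$model),
                               function(d) {
    data.frame(model = d$model[1],
               metric = metrics,
               mean = vapply(metrics, function(m) mean(d[[m]]), numeric(1)),
               sd = vapply(metrics, function(m) stats::sd(d[[m]]),
                           numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  structure(list(per_seed = per_seed, aggregate = agg,
                 roc = do.call(rbind, roc)),
            class = "ssl_eval")
}

#' @export
print.ssl_eval <- function(x, ...) {
  cat("Stacked-model evaluation over",
      length(unique(x$per_seed$seed)), "seeds\n")
  agg <- x$aggregate
  for (m in unique(agg$model)) {
    cat("  ", m, ":\n", sep = "")
    d <- agg[agg$model == m, ]
    for (i in seq_len(nrow(d))) {
      cat(sprintf("    %-12s %.3f +/- %.3f\n",
                  d$metric[i], d$mean[i], d$sd[i]))
    }
  }
  invisible(x)
}
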