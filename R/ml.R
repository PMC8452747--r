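#' Per-gene detection rate
#'
#' The machine-learning feature filter's statistic: for gene g,
#' `d_g = N_{g,m} / N`, where `N_{g,m}` is the number of samples whose read
#' count of g is strictly larger than the lower bound `m`, and `N` is the
#' number of samples.
#'
#' @param counts Gene x sample matrix of non-negative integer read counts.
#' @param m Read-count lower bound (>= 0).
#' @return Named numeric vector of detection rates in \[0, 1\].
#' @export
detection_rate <- function(counts, m = 0L) {
  check_count_matrix(counts)
  if (m < 0) stop("m must be >= 0", call. = FALSE)
  rowMeans(counts > m)
}

#' Select genes by detection rate
#'
#' Keeps genes whose detection rate is strictly greater than the threshold
#' `t`, in stable input order.
#'
#' @inheritParams detection_rate
#' @param t Detection-rate threshold in \[0, 1\].
#' @return Character vector of selected gene IDs.
#' @export
select_features <- function(counts, t = 0.9, m = 0L) {
  if (t < 0 || t > 1) stop("t must be in [0, 1]", call. = FALSE)
  d <- detection_rate(counts, m)
  sel <- names(d)[d > t]
  if (length(sel) == 0) {
    stop("no gene exceeds detection rate t = ", t,
         "; lower t or m", call. = FALSE)
  }
  sel
}

#' Rank-normalize expression into [0, 1] features
#'
#' Two-step feature construction for the tree models. Step 1, per sample:
#' genes are ranked by descending expression (rank 1 = highest; ties get
#' average ranks), which makes the features invariant to any strictly
#' increasing per-sample transform (library size, monotone normalization).
#' Step 2, per gene: ranks are min-max scaled to \[0, 1\] using the minimum
#' and maximum observed on `fit_samples` only; other samples are scaled with
#' the fitted min/max and clipped to \[0, 1\]. Genes whose rank is constant
#' across the fit samples map to 0.5.
#'
#' @param x Gene x sample expression matrix (raw or normalized counts;
#'   within-sample ranks are identical either way) with >= 2 genes.
#' @param fit_samples Character vector of sample IDs on which the per-gene
#'   min/max is fitted (the training samples). Defaults to all samples.
#' @return List of class `ssl_rank_scaler` with `features` (sample x gene
#'   matrix in \[0, 1\] for the samples of `x`), `rank_min`, `rank_max`,
#'   and `gene_ids`.
#' @export
rank_normalize <- function(x, fit_samples = colnames(x)) {
  if (!is.matrix(x) || nrow(x) < 2) {
    stop("rank normalization needs at least 2 genes", call. = FALSE)
  }
  if (length(fit_samples) == 0 || !all(fit_samples %in% colnames(x))) {
    stop("fit_samples must be a non-empty subset of the samples",
         call. = FALSE)
  }
  ranks <- apply(x, 2, function(col) rank(-col, ties.method = "average"))
  fit <- ranks[, fit_samples, drop = FALSE]
  rmin <- apply(fit, 1, min)
  rmax <- apply(fit, 1, max)
  scaler <- structure(list(rank_min = rmin, rank_max = rmax,
                           gene_ids = rownames(x)),
                      class = "ssl_rank_scaler")
  scaler$features <- rank_apply(scaler, ranks)
  scaler
}

# Scale a gene x sample rank matrix with a fitted scaler; returns
# sample x gene features clipped to [0, 1].
rank_apply <- function(scaler, ranks) {
  denom <- scaler$rank_max - scaler$rank_min
  scaled <- (ranks - scaler$rank_min) / ifelse(denom > 0, denom, 1)
  scaled[denom == 0, ] <- 0.5
  t(pmin(pmax(scaled, 0), 1))
}

#' Transform new samples with a fitted rank scaler
#'
#' @param scaler `ssl_rank_scaler` from [rank_normalize()].
#' @param x Gene x sample expression matrix containing at least the
#'   scaler's genes.
#' @return Sample x gene feature matrix in \[0, 1\].
#' @export
rank_transform <- function(scaler, x) {
  if (!all(scaler$gene_ids %in% rownames(x))) {
    stop("new data lacks genes present in the fitted scaler", call. = FALSE)
  }
  x <- x[scaler$gene_ids, , drop = FALSE]
  ranks <- apply(x, 2, function(col) rank(-col, ties.method = "average"))
  rank_apply(scaler, ranks)
}

#' Default ERT hyperparameters
#'
#' One parameter set shared by the stage regressor and the classifier:
#' detection-rate threshold `t` and read-count lower bound `m` for the
#' feature filter, and the five extremely-randomized-trees controls
#' (number of estimators, maximum depth with 0 = unlimited, fraction of
#' features tried per split, minimum samples per leaf, minimum samples to
#' split a node).
#'
#' @return Named list of hyperparameters.
#' @export
default_hyperparams <- function() {
  list(t = 0.9, m = 1L,
       n_estimators = 300L, max_depth = 0L, max_features = 0.3,
       min_samples_leaf = 1L, min_samples_split = 2L)
}

# Translate shared hyperparameters into ranger() arguments.
ert_args <- function(hp, n_features, seed) {
  list(
    num.trees = as.integer(hp$n_estimators),
    mtry = max(1L, min(n_features,
                       as.integer(floor(hp$max_features * n_features)))),
    max.depth = as.integer(hp$max_depth),
    min.node.size = as.integer(hp$min_samples_split),
    min.bucket = as.integer(hp$min_samples_leaf),
    splitrule = "extratrees",
    num.random.splits = 1L,
    replace = FALSE,
    sample.fraction = 1,
    seed = as.integer(seed),
    num.threads = 1L,
    verbose = FALSE
  )
}

#' Fit the H&Y stage regressor
#'
#' Extremely-randomized-trees regression ensemble (random split thresholds,
#' no bootstrap) mapping rank-normalized features to a continuous Hoehn &
#' Yahr stage prediction. Controls carry stage 0 so every training sample
#' has a target.
#'
#' @param features Sample x feature numeric matrix or data.frame.
#' @param stages Numeric H&Y stages, one per training sample.
#' @param hyperparams See [default_hyperparams()].
#' @param seed Integer seed (ensemble is deterministic given it).
#' @return A fitted `ranger` regression object.
#' @export
fit_stage_regressor <- function(features, stages,
                                hyperparams = default_hyperparams(),
                                seed = 1L) {
  if (length(stages) != nrow(features)) {
    stop("stages must have one value per training sample", call. = FALSE)
  }
  if (stats::sd(stages) == 0) {
    warning("constant stage target; the regressor predicts the constant",
            call. = FALSE)
  }
  df <- as.data.frame(features)
  df$.stage <- as.numeric(stages)
  args <- c(list(formula = .stage ~ ., data = df),
            ert_args(hyperparams, ncol(features), seed))
  do.call(ranger::ranger, args)
}

#' Fit the disease classifier
#'
#' Extremely-randomized-trees probability classifier on the rank-normalized
#' expression features, age, sex, and (in the stacked model) the predicted
#' H&Y stage.
#'
#' @inheritParams fit_stage_regressor
#' @param labels Factor or character with levels "control" and "PD".
#' @return A fitted `ranger` probability forest.
#' @export
fit_classifier <- function(features, labels,
                           hyperparams = default_hyperparams(),
                           seed = 1L) {
  labels <- factor(labels, levels = c("control", "PD"))
  if (nlevels(droplevels(labels)) < 2) {
    stop("training labels contain a single class", call. = FALSE)
  }
  df <- as.data.frame(features)
  df$.label <- labels
  args <- c(list(formula = .label ~ ., data = df, probability = TRUE),
            ert_args(hyperparams, ncol(features), seed))
  do.call(ranger::ranger, args)
}

# Assemble the sample x feature matrix: rank-scaled genes + age + sex
# (sex encoded 1 = male, 0 = female).
build_features <- function(gene_features, meta) {
  meta <- meta[match(rownames(gene_features), meta$sample_id), ]
  cbind(gene_features,
        age = as.numeric(meta$age),
        sex = as.numeric(meta$sex == "M"))
}

#' Fit the stacked discrimination model
#'
#' The full training procedure: (1) genes passing the detection-rate filter
#' on the training samples are selected; (2) expression is rank-normalized
#' with the per-gene min/max fitted on training samples; (3) an H&Y stage
#' regressor is fitted on the training features; (4) the classifier is
#' trained on the same features plus a predicted-stage column. To keep the
#' classifier from learning the regressor's in-sample optimism, the
#' predicted-stage column for training is built from K-fold out-of-fold
#' regressor predictions; at prediction time the full-train regressor
#' supplies the stage feature.
#'
#' @param counts Gene x sample training count matrix (post-QC).
#' @param meta Training metadata with `sample_id`, `group`, `sex`, `age`,
#'   `hy_stage` columns (controls' stage 0).
#' @param hyperparams See [default_hyperparams()].
#' @param seed Integer seed controlling folds and both ensembles.
#' @param oof_folds Folds for the out-of-fold stage predictions.
#' @param use_regressor If `FALSE`, fit the ablation without the
#'   predicted-stage feature.
#' @return List of class `ssl_stacked` with the fitted pieces.
#' @export
fit_stacked_model <- function(counts, meta,
                              hyperparams = default_hyperparams(),
                              seed = 1L, oof_folds = 10L,
                              use_regressor = TRUE) {
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  stopifnot(!anyNA(meta$sample_id))
  genes <- select_features(counts, hyperparams$t, hyperparams$m)
  scaler <- rank_normalize(counts[genes, , drop = FALSE])
  feats <- build_features(scaler$features, meta)
  labels <- factor(meta$group, levels = c("control", "PD"))
  stages <- as.numeric(meta$hy_stage)
  stages[is.na(stages)] <- 0

  regressor <- NULL
  oof_stage <- NULL
  if (use_regressor) {
    regressor <- fit_stage_regressor(feats, stages, hyperparams, seed)
    k <- min(oof_folds, nrow(feats))
    folds <- make_folds(labels, k, seed)
    oof_stage <- numeric(nrow(feats))
    for (f in seq_len(k)) {
      tr <- folds != f
      rg <- fit_stage_regressor(feats[tr, , drop = FALSE], stages[tr],
                                hyperparams, seed + f)
      oof_stage[!tr] <- stats::predict(
        rg, data = as.data.frame(feats[!tr, , drop = FALSE])
      )$predictions
    }
  }

  clf_feats <- if (use_regressor) {
    cbind(feats, predicted_stage = oof_stage)
  } else feats
  classifier <- fit_classifier(clf_feats, labels, hyperparams, seed)

  structure(list(
    hyperparams = hyperparams,
    selected_genes = genes,
    scaler = scaler,
    regressor = regressor,
    classifier = classifier,
    use_regressor = use_regressor,
    seed = seed
  ), class = "ssl_stacked")
}

#' Predict PD probability (and stage) for new samples
#'
#' @param object Fitted `ssl_stacked` model.
#' @param counts Gene x sample count matrix containing the model's genes.
#' @param meta Metadata for the new samples (`sample_id`, `sex`, `age`).
#' @param ... Unused.
#' @return `data.frame` with `sample_id`, `predicted_stage` (NA for the
#'   ablation model), `prob_pd`.
#' @export
predict.ssl_stacked <- function(object, counts, meta, ...) {
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  gene_feats <- rank_transform(object$scaler,
                               counts[object$selected_genes, , drop = FALSE])
  feats <- build_features(gene_feats, meta)
  stage_hat <- rep(NA_real_, nrow(feats))
  clf_feats <- feats
  if (object$use_regressor) {
    stage_hat <- stats::predict(
      object$regressor, data = as.data.frame(feats)
    )$predictions
    clf_feats <- cbind(feats, predicted_stage = stage_hat)
  }
  pr <- stats::predict(object$classifier,
                       data = as.data.frame(clf_feats))$predictions
  data.frame(sample_id = colnames(counts),
             predicted_stage = stage_hat,
             prob_pd = pr[, "PD"],
             row.names = NULL, stringsAsFactors = FALSE)
}

# Stratified fold assignment: returns a fold index per sample, balanced
# within each level of `strata`.
make_folds <- function(strata, k, seed) {
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  folds <- integer(length(strata))
  for (lev in unique(strata)) {
    idx <- which(strata == lev)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Stratified train/test split
#'
#' Splits samples into disjoint train and test sets of the requested sizes,
#' preserving class proportions to within one sample, seeded.
#'
#' @param labels Factor or character class label per sample.
#' @param train_size,test_size Integers summing to `length(labels)`.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, train_size, test_size, seed = 1L) {
  n <- length(labels)
  if (train_size + test_size != n) {
    stop("train_size + test_size must equal the number of samples",
         call. = FALSE)
  }
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  labels <- as.factor(labels)
  prop <- train_size / n
  # largest-remainder allocation of training slots across classes
  cls <- table(labels)
  raw <- as.numeric(cls) * prop
  base <- floor(raw)
  rem <- train_size - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  train <- integer(0)
  for (i in seq_along(cls)) {
    idx <- which(labels == names(cls)[i])
    train <- c(train, sample(idx, base[i]))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Default hyperparameter search space
#'
#' Candidate values for the seeded random search of
#' [tune_hyperparameters()]: the detection-rate threshold `t`, the
#' read-count lower bound `m`, and the five tree-ensemble controls.
#'
#' @return Named list of candidate vectors.
#' @export
default_search_space <- function() {
  list(
    t = c(0.8, 0.9, 0.95),
    m = c(0L, 1L, 5L),
    n_estimators = c(100L, 300L),
    max_depth = c(0L, 5L, 10L),
    max_features = c(0.1, 0.3, 1.0),
    min_samples_leaf = c(1L, 2L, 5L),
    min_samples_split = c(2L, 5L, 10L)
  )
}

#' Seeded random-search hyperparameter selection
#'
#' Draws `n_trials` parameter sets from the search space and scores each by
#' stratified K-fold cross-validated AUC of the whole stacked pipeline —
#' the detection filter, rank scaler, regressor, and classifier are all
#' re-fitted inside every fold, so no held-out fold leaks into feature
#' selection or scaling. Deterministic given the seed.
#'
#' @param counts,meta Training data (post-QC).
#' @param search_space Named list of candidate vectors; see
#'   [default_search_space()].
#' @param n_trials Number of random draws (>= 1).
#' @param seed Integer seed.
#' @param n_folds Cross-validation folds (the study used tenfold).
#' @param oof_folds Inner folds for the stacked out-of-fold stage feature.
#' @return List with `best` (chosen hyperparameter list), `best_auc`, and
#'   `trials` (a `data.frame` of every draw and its mean CV AUC).
#' @export
tune_hyperparameters <- function(counts, meta,
                                 search_space = default_search_space(),
                                 n_trials = 20L, seed = 1L,
                                 n_folds = 10L, oof_folds = 5L) {
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  labels <- factor(meta$group, levels = c("control", "PD"))
  if (nlevels(droplevels(labels)) < 2) {
    stop("training data needs both classes", call. = FALSE)
  }
  rng <- local_rng(seed)
  draws <- lapply(seq_len(n_trials), function(i) {
    lapply(search_space, function(v) v[sample.int(length(v), 1)])
  })
  rng()

  folds <- make_folds(labels, min(n_folds, min(table(labels))), seed + 1L)
  k <- max(folds)
  score_one <- function(hp, trial) {
    aucs <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      fit <- try(fit_stacked_model(counts[, tr, drop = FALSE], meta[tr, ],
                                   hyperparams = hp,
                                   seed = seed + 100L * trial + f,
                                   oof_folds = oof_folds), silent = TRUE)
      if (inherits(fit, "try-error")) return(NA_real_)
      pred <- predict(fit, counts[, !tr, drop = FALSE], meta[!tr, ])
      if (length(unique(labels[!tr])) < 2) return(NA_real_)
      auc_score(labels[!tr], pred$prob_pd)
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }
  scores <- vapply(seq_along(draws),
                   function(i) score_one(draws[[i]], i), numeric(1))
  best_i <- which.max(scores)
  trials <- cbind(do.call(rbind, lapply(draws, as.data.frame)),
                  cv_auc = scores)
  list(best = draws[[best_i]], best_auc = scores[best_i], trials = trials)
}
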