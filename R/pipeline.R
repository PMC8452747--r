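#' Build a pipeline configuration
#'
#' Assembles (and validates) the configuration driving [run_pipeline()]. By
#' default the pipeline simulates a two-cohort study; point `counts_path` /
#' `meta_path` at TSV files (dialect of [write_counts_tsv()] /
#' [write_meta_tsv()]) to run on real data instead.
#'
#' @param output_dir Directory for artifacts (created if needed).
#' @param seed Global seed; each stage derives its own seed from it
#'   (`seed + stage index`) so stages are independently reproducible.
#' @param simulate Logical; generate data with [simulate_two_cohorts()].
#' @param sim Named list of overrides for the simulator (e.g. `n_genes`,
#'   `log2fc`, `stage_slope`).
#' @param counts_path,meta_path Input TSVs when `simulate = FALSE`.
#' @param min_targets_detected,min_presence,detect_min QC thresholds, see
#'   [qc_filter()].
#' @param pca_n_top,pca_n_components PCA settings, see
#'   [pca_top_variance()].
#' @param fdr_strict,fdr_exploratory DEG thresholds (0.05 / 0.25).
#' @param train_fraction Fraction of combined samples used for training
#'   (the study split 81 of 116).
#' @param n_trials Random-search trials; 0 uses [default_hyperparams()]
#'   without tuning.
#' @param n_seeds Training repetitions in the final evaluation.
#' @param hyperparams Hyperparameters used when `n_trials = 0`.
#' @return List of class `ssl_pipeline_config`.
#' @export
pipeline_config <- function(output_dir = "ssl_run",
                            seed = 1L,
                            simulate = TRUE,
                            sim = list(),
                            counts_path = NULL,
                            meta_path = NULL,
                            min_targets_detected = 0.20,
                            min_presence = 0.90,
                            detect_min = 1L,
                            pca_n_top = 1000L,
                            pca_n_components = 3L,
                            fdr_strict = 0.05,
                            fdr_exploratory = 0.25,
                            train_fraction = 81 / 116,
                            n_trials = 0L,
                            n_seeds = 5L,
                            hyperparams = default_hyperparams()) {
  cfg <- list(output_dir = output_dir, seed = as.integer(seed),
              simulate = isTRUE(simulate), sim = sim,
              counts_path = counts_path, meta_path = meta_path,
              min_targets_detected = min_targets_detected,
              min_presence = min_presence, detect_min = detect_min,
              pca_n_top = as.integer(pca_n_top),
              pca_n_components = as.integer(pca_n_components),
              fdr_strict = fdr_strict, fdr_exploratory = fdr_exploratory,
              train_fraction = train_fraction,
              n_trials = as.integer(n_trials),
              n_seeds = as.integer(n_seeds),
              hyperparams = hyperparams)
  if (!cfg$simulate &&
      (is.null(cfg$counts_path) || is.null(cfg$meta_path))) {
    stop("counts_path and meta_path are required when simulate = FALSE",
         call. = FALSE)
  }
  stopifnot(cfg$train_fraction > 0, cfg$train_fraction < 1,
            cfg$n_seeds >= 1)
  class(cfg) <- "ssl_pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()].
#' @return `ssl_pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full SSL-RNA analysis pipeline
#'
#' Orchestrates every stage end to end: data simulation (or loading),
#' per-cohort QC, normalization, PCA and differential expression,
#' cross-cohort DEG overlap, covariate checks (age balance, levodopa-dose
#' correlation), combined-cohort QC, stratified train/test split, optional
#' hyperparameter tuning, and multi-seed evaluation of the stacked
#' discrimination model. Every artifact is written under
#' `config$output_dir` and checksummed into `manifest.json`; re-running
#' with the same config reproduces byte-identical artifacts.
#'
#' @param config `ssl_pipeline_config` (or path to a YAML file).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "ssl_pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  result <- list(config = config)

  run_stage <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      stop("pipeline failed at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }

  # --- data -----------------------------------------------------------
  data <- run_stage("data", {
    if (config$simulate) {
      do.call(simulate_two_cohorts,
              c(list(seed = config$seed), config$sim))
    } else {
      counts <- read_counts_tsv(config$counts_path)
      meta <- read_meta_tsv(config$meta_path)
      split_meta <- split(meta, meta$cohort)
      cohorts <- lapply(split_meta, function(m) {
        list(counts = counts[, m$sample_id, drop = FALSE], meta = m)
      })
      c(stats::setNames(cohorts, names(split_meta)),
        list(combined = list(counts = counts, meta = meta)))
    }
  })
  cohort_names <- setdiff(names(data), "combined")

  # --- per-cohort QC, normalization, PCA, DE --------------------------
  de_tables <- list()
  degs <- list()
  for (cn in cohort_names) {
    local_counts <- data[[cn]]$counts
    local_meta <- data[[cn]]$meta
    qc <- run_stage(paste0("qc_", cn), {
      qc_filter(local_counts, config$min_targets_detected,
                config$min_presence, config$detect_min)
    })
    write_json_file(qc$report, file.path(out, paste0("qc_", cn, ".json")))
    norm <- run_stage(paste0("normalize_", cn), {
      sf <- size_factors(qc$counts)
      list(sf = sf, vst = vst_transform(qc$counts, sf))
    })
    utils::write.table(
      data.frame(sample_id = names(norm$sf), size_factor = norm$sf),
      file.path(out, paste0("size_factors_", cn, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    pca <- run_stage(paste0("pca_", cn), {
      pca_top_variance(norm$vst,
                       n_top = min(config$pca_n_top, nrow(norm$vst)),
                       n_components = min(config$pca_n_components,
                                          ncol(norm$vst) - 1L))
    })
    utils::write.table(
      data.frame(sample_id = rownames(pca$scores), pca$scores),
      file.path(out, paste0("pca_scores_", cn, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    de <- run_stage(paste0("de_", cn), {
      grp <- local_meta$group[match(colnames(qc$counts),
                                    local_meta$sample_id)]
      suppressWarnings(
        nb_lrt(qc$counts, norm$sf,
               factor(grp, levels = c("control", "PD")))
      )
    })
    utils::write.table(de, file.path(out, paste0("de_", cn, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    de_tables[[cn]] <- de
    degs[[cn]] <- list(
      strict = call_degs(de, config$fdr_strict),
      exploratory = call_degs(de, config$fdr_exploratory)
    )
    for (lev in names(degs[[cn]])) {
      writeLines(sort(unlist(degs[[cn]][[lev]])),
                 file.path(out, paste0("degs_", cn, "_", lev, ".txt")))
    }
    # age balance between groups within the cohort
    ages <- split(local_meta$age, local_meta$group)
    if (all(lengths(ages) >= 2)) {
      bal <- age_balance_ttest(ages[[1]], ages[[2]])
      write_json_file(bal, file.path(out, paste0("age_balance_", cn,
                                                 ".json")))
      result[[paste0("age_balance_", cn)]] <- bal
    }
  }
  result$de <- de_tables
  result$degs <- degs

  # --- cross-cohort DEG overlap ---------------------------------------
  if (length(cohort_names) >= 2) {
    overlap <- run_stage("overlap", {
      a <- unlist(degs[[1]]$exploratory)
      b <- unlist(degs[[2]]$exploratory)
      universe <- intersect(de_tables[[1]]$gene_id,
                            de_tables[[2]]$gene_id)
      overlap_fisher(intersect(a, universe), intersect(b, universe),
                     universe)
    })
    write_json_file(overlap, file.path(out, "deg_overlap.json"))
    result$overlap <- overlap
  }

  # --- combined-cohort machine learning -------------------------------
  ml <- run_stage("ml_qc", {
    qc_filter(data$combined$counts, config$min_targets_detected,
              config$min_presence, config$detect_min)
  })
  meta_all <- data$combined$meta
  meta_all <- meta_all[match(colnames(ml$counts), meta_all$sample_id), ]
  # levodopa-dose correlation screen among medicated cases
  dose_screen <- run_stage("dose_screen", {
    cases <- meta_all$group == "PD" & !is.na(meta_all$ldopa_dose) &
      meta_all$ldopa_dose > 0
    if (sum(cases) >= 4 &&
        stats::sd(meta_all$ldopa_dose[cases]) > 0) {
      expr <- vst_transform(ml$counts[, cases, drop = FALSE])
      covariate_correlation_screen(expr, meta_all$ldopa_dose[cases])
    } else NULL
  })
  if (!is.null(dose_screen)) {
    utils::write.table(dose_screen,
                       file.path(out, "dose_correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    result$dose_screen <- dose_screen
  }

  split <- run_stage("split", {
    labels <- factor(meta_all$group, levels = c("control", "PD"))
    n <- length(labels)
    n_train <- round(config$train_fraction * n)
    split_train_test(labels, n_train, n - n_train,
                     seed = config$seed + 1L)
  })
  counts_train <- ml$counts[, split$train, drop = FALSE]
  counts_test <- ml$counts[, split$test, drop = FALSE]
  meta_train <- meta_all[split$train, ]
  meta_test <- meta_all[split$test, ]

  hp <- config$hyperparams
  if (config$n_trials > 0) {
    tuned <- run_stage("tune", {
      tune_hyperparameters(counts_train, meta_train,
                           n_trials = config$n_trials,
                           seed = config$seed + 2L)
    })
    hp <- tuned$best
    write_json_file(list(best = tuned$best, best_auc = tuned$best_auc),
                    file.path(out, "tuning.json"))
    result$tuning <- tuned
  }

  eval_report <- run_stage("evaluate", {
    evaluate_stacked(counts_train, meta_train, counts_test, meta_test,
                     hyperparams = hp, n_seeds = config$n_seeds,
                     seed = config$seed + 3L)
  })
  write_json_file(
    list(per_seed = eval_report$per_seed,
         aggregate = eval_report$aggregate),
    file.path(out, "eval_report.json")
  )
  utils::write.table(eval_report$roc, file.path(out, "roc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  result$eval <- eval_report

  # --- manifest -------------------------------------------------------
  manifest <- run_stage("manifest", {
    files <- sort(setdiff(list.files(out), "manifest.json"))
    sums <- as.list(tools::md5sum(file.path(out, files)))
    names(sums) <- files
    list(seed = config$seed,
         config = unclass(config)[setdiff(names(config), "output_dir")],
         checksums = sums)
  })
  write_json_file(manifest, file.path(out, "manifest.json"))
  result$manifest <- manifest
  invisible(result)
}
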