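#' Simulation configuration for an SSL-RNA-like cohort
#'
#' Builds and validates the parameter set for [simulate_cohort()]. The
#' defaults emulate a targeted-panel sebum RNA study arm: negative-binomial
#' counts with a global dispersion, log-normal library sizes, a planted set of
#' up- and down-regulated genes whose effect grows with Hoehn & Yahr (H&Y)
#' motor stage, and a subset of low-quality samples with heavy gene dropout
#' (the "Targets Detected" QC failure mode).
#'
#' @param n_controls,n_cases Number of control and case (PD) samples.
#' @param n_genes Number of panel genes.
#' @param baseline_mean_log_range Length-2 numeric, bounds of the natural-log
#'   baseline gene mean; gene means are drawn log-uniformly between
#'   `exp(min)` and `exp(max)`.
#' @param dispersion Global negative-binomial dispersion `alpha`
#'   (variance = mu + alpha * mu^2).
#' @param library_size_cv Coefficient of variation of the log-normal
#'   per-sample library-size factors (mean 1).
#' @param n_up_genes,n_down_genes Number of genes planted up-/down-regulated
#'   in cases.
#' @param log2fc Baseline planted case-vs-control effect, in log2 units
#'   (up-genes multiplied by `2^log2fc`, down-genes divided).
#' @param stage_slope Additional log2 effect per H&Y stage unit, so a stage-2
#'   case expresses an up-gene at `2^(log2fc + 2 * stage_slope)` times the
#'   control mean.
#' @param stage_distribution Probability vector over H&Y stages 0, 1, 2 for
#'   cases (controls are always stage 0). The default matches the observed
#'   early-PD composition of a medicated male cohort: 2/50, 20/50, 28/50.
#' @param quality_fraction_low Fraction of samples simulated as low-quality.
#' @param dropout_rate_low Probability that a gene's count is zeroed in a
#'   low-quality sample (applied independently per gene, after NB sampling).
#'   The default 0.9 leaves such samples with roughly 10% of genes
#'   detected, below the 20% Targets-Detected QC threshold — the failure
#'   mode the generator emulates.
#' @param female_fraction Fraction of samples drawn female (applied to both
#'   groups independently).
#' @param age_mean,age_sd Normal age distribution (years), truncated to
#'   \[35, 95\] and rounded.
#' @param cohort_id Label written into the sample metadata.
#' @param seed Integer seed; identical configs give bit-identical cohorts.
#'
#' @return A validated list of class `ssl_sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_controls = 50L,
                       n_cases = 50L,
                       n_genes = 2000L,
                       baseline_mean_log_range = c(log(5), log(500)),
                       dispersion = 0.1,
                       library_size_cv = 0.3,
                       n_up_genes = 25L,
                       n_down_genes = 25L,
                       log2fc = 1,
                       stage_slope = 0.25,
                       stage_distribution = c(0.04, 0.40, 0.56),
                       quality_fraction_low = 0.1,
                       dropout_rate_low = 0.9,
                       female_fraction = 0,
                       age_mean = 65,
                       age_sd = 10,
                       cohort_id = "cohort1",
                       seed = 1L) {
  cfg <- list(
    n_controls = as.integer(n_controls), n_cases = as.integer(n_cases),
    n_genes = as.integer(n_genes),
    baseline_mean_log_range = as.numeric(baseline_mean_log_range),
    dispersion = dispersion, library_size_cv = library_size_cv,
    n_up_genes = as.integer(n_up_genes),
    n_down_genes = as.integer(n_down_genes),
    log2fc = log2fc, stage_slope = stage_slope,
    stage_distribution = as.numeric(stage_distribution),
    quality_fraction_low = quality_fraction_low,
    dropout_rate_low = dropout_rate_low,
    female_fraction = female_fraction,
    age_mean = age_mean, age_sd = age_sd,
    cohort_id = as.character(cohort_id), seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "ssl_sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop("invalid sim_config field '", field, "': ", why, call. = FALSE)
  }
  chk(cfg$n_controls >= 1, "n_controls", "must be >= 1")
  chk(cfg$n_cases >= 1, "n_cases", "must be >= 1")
  chk(cfg$n_genes >= 1, "n_genes", "must be >= 1")
  chk(length(cfg$baseline_mean_log_range) == 2 &&
        diff(cfg$baseline_mean_log_range) >= 0,
      "baseline_mean_log_range", "must be a non-decreasing pair")
  chk(cfg$dispersion > 0, "dispersion", "must be > 0")
  chk(cfg$library_size_cv >= 0, "library_size_cv", "must be >= 0")
  chk(cfg$n_up_genes >= 0, "n_up_genes", "must be >= 0")
  chk(cfg$n_down_genes >= 0, "n_down_genes", "must be >= 0")
  chk(cfg$n_up_genes + cfg$n_down_genes <= cfg$n_genes,
      "n_up_genes", "n_up_genes + n_down_genes must be <= n_genes")
  chk(cfg$log2fc >= 0, "log2fc", "must be >= 0")
  chk(length(cfg$stage_distribution) == 3 &&
        all(cfg$stage_distribution >= 0) &&
        abs(sum(cfg$stage_distribution) - 1) < 1e-8,
      "stage_distribution", "must be 3 non-negative probabilities summing to 1")
  chk(cfg$quality_fraction_low >= 0 && cfg$quality_fraction_low <= 1,
      "quality_fraction_low", "must be in [0, 1]")
  chk(cfg$dropout_rate_low >= 0 && cfg$dropout_rate_low <= 1,
      "dropout_rate_low", "must be in [0, 1]")
  chk(cfg$female_fraction >= 0 && cfg$female_fraction <= 1,
      "female_fraction", "must be in [0, 1]")
  invisible(cfg)
}

#' Simulate one SSL-RNA-like cohort with ground truth
#'
#' Draws a gene-by-sample negative-binomial read-count matrix with planted
#' case/control differential expression, H&Y-stage-dependent effect sizes,
#' log-normal library-size variation, and a subset of low-quality samples in
#' which genes are independently zeroed (emulating samples that would fail a
#' "Targets Detected" QC screen). Controls carry H&Y stage 0; case stages are
#' drawn from `stage_distribution`. Case levodopa dose is loosely tied to
#' stage so that dose-correlation screens have a realistic confounder.
#'
#' @param config An [sim_config()] object.
#' @param planted Optional list with integer vectors `up_idx` and `down_idx`
#'   fixing which genes carry the planted signal (used to share signal genes
#'   across cohorts); defaults to a random draw.
#' @return A list with components:
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples, with dimnames.}
#'     \item{meta}{`data.frame` with columns `sample_id`, `cohort`, `group`
#'       ("control"/"PD"), `sex` ("F"/"M"), `age`, `hy_stage`, `ldopa_dose`.}
#'     \item{truth}{list with `up_gene_ids`, `down_gene_ids`,
#'       `low_quality_sample_ids`, `true_stages` (named numeric).}
#'   }
#' @examples
#' sim <- simulate_cohort(sim_config(n_controls = 5, n_cases = 5,
#'                                   n_genes = 50, seed = 1))
#' dim(sim$counts)
#' @export
simulate_cohort <- function(config, planted = NULL) {
  if (!inherits(config, "ssl_sim_config")) {
    config <- do.call(sim_config, config)
  }
  validate_sim_config(config)
  cfg <- config
  n <- cfg$n_controls + cfg$n_cases

  rng <- local_rng(cfg$seed)
  on.exit(rng(), add = TRUE)

  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
  sample_ids <- sprintf("%s_s%03d", cfg$cohort_id, seq_len(n))
  group <- rep(c("control", "PD"), c(cfg$n_controls, cfg$n_cases))

  # baseline mean expression, log-uniform across the configured range
  log_mu0 <- stats::runif(cfg$n_genes,
                          cfg$baseline_mean_log_range[1],
                          cfg$baseline_mean_log_range[2])

  # planted signal genes
  if (is.null(planted)) {
    de_idx <- if (cfg$n_up_genes + cfg$n_down_genes > 0) {
      sample(cfg$n_genes, cfg$n_up_genes + cfg$n_down_genes)
    } else integer(0)
    up_idx <- de_idx[seq_len(cfg$n_up_genes)]
    down_idx <- de_idx[cfg$n_up_genes + seq_len(cfg$n_down_genes)]
  } else {
    up_idx <- planted$up_idx
    down_idx <- planted$down_idx
    stopifnot(length(intersect(up_idx, down_idx)) == 0,
              all(c(up_idx, down_idx) %in% seq_len(cfg$n_genes)))
  }

  # H&Y stage: controls 0; cases from stage_distribution over {0,1,2}
  stage <- numeric(n)
  stage[group == "PD"] <- sample(0:2, cfg$n_cases, replace = TRUE,
                                 prob = cfg$stage_distribution)

  # library sizes: log-normal, mean 1, stated CV
  if (cfg$library_size_cv > 0) {
    sig2 <- log(1 + cfg$library_size_cv^2)
    libsize <- stats::rlnorm(n, meanlog = -sig2 / 2, sdlog = sqrt(sig2))
  } else {
    libsize <- rep(1, n)
  }

  # per-sample log2 effect applied to planted genes before NB sampling
  eff <- ifelse(group == "PD", cfg$log2fc + cfg$stage_slope * stage, 0)

  log_mu <- matrix(log_mu0, cfg$n_genes, n)
  if (length(up_idx)) {
    log_mu[up_idx, ] <- log_mu[up_idx, ] +
      matrix(log(2) * eff, length(up_idx), n, byrow = TRUE)
  }
  if (length(down_idx)) {
    log_mu[down_idx, ] <- log_mu[down_idx, ] -
      matrix(log(2) * eff, length(down_idx), n, byrow = TRUE)
  }
  mu <- exp(sweep(log_mu, 2, log(libsize), "+"))

  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / cfg$dispersion),
                   cfg$n_genes, n,
                   dimnames = list(gene_ids, sample_ids))

  # low-quality samples: independent per-gene zeroing after sampling
  n_low <- round(cfg$quality_fraction_low * n)
  low_idx <- if (n_low > 0) sort(sample(n, n_low)) else integer(0)
  for (j in low_idx) {
    drop <- stats::runif(cfg$n_genes) < cfg$dropout_rate_low
    counts[drop, j] <- 0L
  }

  sex <- ifelse(stats::runif(n) < cfg$female_fraction, "F", "M")
  age <- round(pmin(95, pmax(35, stats::rnorm(n, cfg$age_mean, cfg$age_sd))))
  # levodopa dose (mg/day): stage-dependent for medicated cases, 0 otherwise
  dose <- ifelse(group == "PD",
                 pmax(0, round(150 * stage + stats::rnorm(n, 0, 50))),
                 0)

  meta <- data.frame(
    sample_id = sample_ids,
    cohort = cfg$cohort_id,
    group = group,
    sex = sex,
    age = as.numeric(age),
    hy_stage = stage,
    ldopa_dose = as.numeric(dose),
    stringsAsFactors = FALSE
  )

  truth <- list(
    up_gene_ids = gene_ids[sort(up_idx)],
    down_gene_ids = gene_ids[sort(down_idx)],
    low_quality_sample_ids = sample_ids[low_idx],
    true_stages = stats::setNames(stage, sample_ids)
  )

  list(counts = counts, meta = meta, truth = truth)
}

#' Simulate a two-cohort SSL-RNA study
#'
#' Convenience wrapper that generates two cohorts mirroring a double-cohort
#' study design — a small mixed-sex de novo cohort (15 + 15) and a larger
#' all-male medicated cohort (50 + 50) — with shared planted gene sets and a
#' shared gene panel, then returns them separately and combined.
#'
#' @param seed Integer seed.
#' @param n_genes Number of shared panel genes.
#' @param ... Overrides passed to both cohorts' [sim_config()] (e.g.
#'   `log2fc`, `stage_slope`, `dropout_rate_low`).
#' @return List with `cohort1`, `cohort2` (each as [simulate_cohort()]
#'   output), and `combined` (`counts`, `meta` across both cohorts; the
#'   planted gene sets of cohort 1 are the shared truth).
#' @export
simulate_two_cohorts <- function(seed = 1L, n_genes = 2000L, ...) {
  dots <- list(...)
  base1 <- list(n_controls = 15L, n_cases = 15L, n_genes = n_genes,
                female_fraction = 0.6, cohort_id = "cohort1",
                seed = seed)
  base2 <- list(n_controls = 50L, n_cases = 50L, n_genes = n_genes,
                female_fraction = 0, cohort_id = "cohort2",
                seed = seed + 1L)
  c1 <- simulate_cohort(do.call(sim_config, utils::modifyList(base1, dots)))
  # cohort 2 carries the same planted gene sets so cross-cohort DEG overlap
  # and combined-cohort machine learning see a shared biological signal
  gene_ids <- rownames(c1$counts)
  c2 <- simulate_cohort(
    do.call(sim_config, utils::modifyList(base2, dots)),
    planted = list(up_idx = match(c1$truth$up_gene_ids, gene_ids),
                   down_idx = match(c1$truth$down_gene_ids, gene_ids))
  )
  combined_counts <- cbind(c1$counts, c2$counts)
  combined_meta <- rbind(c1$meta, c2$meta)
  list(cohort1 = c1, cohort2 = c2,
       combined = list(counts = combined_counts, meta = combined_meta))
}

# Scoped RNG: seeds deterministically, restores the caller's RNG state.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
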