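grp2 <- function(n) factor(rep(c("control", "PD"), each = n),
                           levels = c("control", "PD"))

test_that("NB fits agree with an independent GLM implementation", {
  skip_if_not_installed("MASS")
  set.seed(31)
  for (mu in c(30, 120)) {
    y <- rnbinom(40, mu = mu, size = 8)
    x <- rep(0:1, each = 20)
    cm <- matrix(y, 1, 40,
                 dimnames = list("g1", sprintf("s%03d", 1:40)))
    de <- suppressWarnings(
      nb_lrt(cm, setNames(rep(1, 40), colnames(cm)), grp2(20))
    )
    ref <- MASS::glm.nb(y ~ x)
    # with a saturated two-group design the mean MLEs are the group means,
    # independent of the dispersion convention
    expect_equal(de$log2_fold_change, unname(coef(ref)[2]) / log(2),
                 tolerance = 1e-6)
    # dispersion estimates use different adjustments but the same scale
    expect_equal(de$dispersion, 1 / ref$theta, tolerance = 0.5)
  }
})

test_that("a gene with identical counts everywhere gives stat 0, p 1", {
  cm <- cmat(5, 2, 10)
  de <- suppressWarnings(
    nb_lrt(cm, setNames(rep(1, 10), colnames(cm)), grp2(5))
  )
  expect_equal(de$lrt_stat, c(0, 0), tolerance = 1e-8)
  expect_equal(de$p_value, c(1, 1))
})

test_that("the test is invariant to sample order and label swap", {
  set.seed(32)
  cm <- cmat(rnbinom(200, mu = 50, size = 10), 10, 20)
  sf <- setNames(rep(1, 20), colnames(cm))
  g <- grp2(10)
  de <- suppressWarnings(nb_lrt(cm, sf, g))
  perm <- sample(20)
  de_p <- suppressWarnings(nb_lrt(cm[, perm], sf[perm], g[perm]))
  expect_equal(de$p_value, de_p$p_value, tolerance = 1e-8)
  expect_equal(de$log2_fold_change, de_p$log2_fold_change,
               tolerance = 1e-8)
  # swapping which level is the case flips the sign only
  g_sw <- factor(as.character(g), levels = c("PD", "control"))
  de_sw <- suppressWarnings(nb_lrt(cm, sf, g_sw))
  expect_equal(de$log2_fold_change, -de_sw$log2_fold_change,
               tolerance = 1e-6)
  expect_equal(de$p_value, de_sw$p_value, tolerance = 1e-6)
})

test_that("BH adjustment matches the worked example and brute force", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.73), 0.73)
  set.seed(33)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-14)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("DEG calls use a strict FDR threshold and the sign rule", {
  res <- data.frame(
    gene_id = c("a", "b", "c"),
    log2_fold_change = c(1.2, -0.5, 0.8),
    fdr = c(0.25, 0.01, 0.24),
    stringsAsFactors = FALSE
  )
  d <- call_degs(res, 0.25)
  expect_equal(d$up, "c")       # fdr 0.25 excluded at threshold 0.25
  expect_equal(d$down, "b")     # negative fold change
})

test_that("Fisher overlap matches hypergeometric enumeration", {
  universe <- sprintf("u%02d", 1:20)
  a <- universe[1:5]
  res <- overlap_fisher(a, a, universe)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-10)
  expect_equal(res$n_overlap, 5)
  # overlap exactly at expectation is not enriched
  universe2 <- sprintf("v%02d", 1:20)
  a2 <- universe2[1:10]
  b2 <- universe2[c(1:5, 11:15)]  # |A||B|/N = 5 = observed overlap
  expect_gte(overlap_fisher(a2, b2, universe2)$p_value, 0.5)
  # degenerate empty set
  res0 <- overlap_fisher(character(0), a, universe)
  expect_equal(res0$odds_ratio, 0)
  expect_equal(res0$p_value, 1)
  expect_error(overlap_fisher(a, a, character(0)), "empty")
})

test_that("covariate screen recovers perfect monotone relations", {
  cov <- c(1, 3, 2, 7, 5, 4)
  x <- rbind(pos = cov, neg = -cov, noise = c(2, 2, 9, 1, 4, 4))
  colnames(x) <- paste0("s", 1:6)
  res <- covariate_correlation_screen(x, cov)
  expect_equal(res$rho[res$gene_id == "pos"], 1)
  expect_equal(res$rho[res$gene_id == "neg"], -1)
  expect_error(covariate_correlation_screen(x, rep(2, 6)), "constant")
  expect_error(covariate_correlation_screen(x[, 1:3], cov[1:3]),
               "4 samples")
})

test_that("independent genes yield ~5% raw rejections in the screen", {
  set.seed(34)
  x <- matrix(rnorm(500 * 30), 500, 30,
              dimnames = list(sprintf("g%03d", 1:500), NULL))
  res <- covariate_correlation_screen(x, rnorm(30))
  expect_lt(abs(mean(res$p_value < 0.05) - 0.05), 0.03)
})

test_that("age balance t-test matches symmetry and separation expectations", {
  expect_equal(age_balance_ttest(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  r <- age_balance_ttest(c(0, 0, 0, 0) + c(1e-3, -1e-3, 2e-3, -2e-3),
                         c(10, 10, 10, 10) + c(1e-3, -1e-3, 2e-3, -2e-3))
  expect_lt(r$p_value, 1e-10)
  # cross-check against the closed-form pooled t
  a <- c(60, 65, 70); b <- c(62, 66, 73)
  r2 <- age_balance_ttest(a, b)
  sp <- sqrt(((2) * var(a) + (2) * var(b)) / 4)
  t_manual <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(r2$t, t_manual, tolerance = 1e-12)
  expect_error(age_balance_ttest(1, c(1, 2)), "at least 2")
})

test_that("planted fold changes are recovered with correct direction", {
  sim <- simulate_cohort(sim_config(
    n_controls = 30, n_cases = 30, n_genes = 300,
    n_up_genes = 15, n_down_genes = 15, log2fc = 2, stage_slope = 0,
    quality_fraction_low = 0, seed = 35
  ))
  qc <- qc_filter(sim$counts)
  de <- suppressWarnings(nb_lrt(qc$counts, groups = factor(
    sim$meta$group[match(colnames(qc$counts), sim$meta$sample_id)],
    levels = c("control", "PD")
  )))
  calls <- call_degs(de, 0.05)
  up_found <- intersect(calls$up, sim$truth$up_gene_ids)
  down_found <- intersect(calls$down, sim$truth$down_gene_ids)
  expect_gt(length(up_found) / length(sim$truth$up_gene_ids), 0.8)
  expect_gt(length(down_found) / length(sim$truth$down_gene_ids), 0.8)
  # direction column is consistent with the fold-change sign
  expect_true(all((de$log2_fold_change > 0) == (de$direction == "up")))
})
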