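# Small fixture builders and independent oracles used across test files.

# Count matrix with auto gene/sample names.
cmat <- function(x, nrow, ncol) {
  matrix(as.integer(x), nrow, ncol,
         dimnames = list(sprintf("g%03d", seq_len(nrow)),
                         sprintf("s%03d", seq_len(ncol))))
}

# Independent brute-force Benjamini-Hochberg step-up (no p.adjust).
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Independent brute-force median-of-ratios size factors.
brute_size_factors <- function(m) {
  ref <- apply(m, 1, function(r) all(r > 0))
  gm <- exp(rowMeans(log(m[ref, , drop = FALSE])))
  apply(m[ref, , drop = FALSE], 2, function(col) median(col / gm))
}

# Independent Mann-Whitney AUC.
brute_auc <- function(labels, scores) {
  pos <- scores[labels == "PD"]
  neg <- scores[labels == "control"]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Two-cohort simulated study, QC'd and split, shared by the ML tests.
ml_fixture <- function(seed = 7, n_genes = 400, n_per_group = 25, ...) {
  sim <- simulate_two_cohorts(seed = seed, n_genes = n_genes,
                              n_controls = n_per_group,
                              n_cases = n_per_group, ...)
  qc <- qc_filter(sim$combined$counts)
  meta <- sim$combined$meta
  meta <- meta[meta$sample_id %in% colnames(qc$counts), ]
  labels <- factor(meta$group, levels = c("control", "PD"))
  n <- length(labels)
  n_train <- round(81 / 116 * n)
  sp <- split_train_test(labels, n_train, n - n_train, seed = seed + 1)
  list(counts = qc$counts, meta = meta, labels = labels, split = sp,
       truth = sim$cohort1$truth)
}
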