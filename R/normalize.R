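#' Median-of-ratios size factors
#'
#' Computes one positive scaling constant per sample by the median-of-ratios
#' method: reference genes are those with a positive count in every sample;
#' each sample's factor is the median over reference genes of
#' `count[g, j] / geometric_mean_over_samples(count[g, ])`. Dividing counts
#' by these factors removes library-size differences.
#'
#' @param counts Gene x sample matrix of non-negative integer read counts.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  check_count_matrix(counts)
  ref <- rowSums(counts == 0) == 0
  if (!any(ref)) {
    stop("no gene has positive counts in every sample; ",
         "apply gene-presence filtering before normalization", call. = FALSE)
  }
  refc <- counts[ref, , drop = FALSE]
  geomean <- exp(rowMeans(log(refc)))
  sf <- apply(refc, 2, function(col) stats::median(col / geomean))
  stats::setNames(sf, colnames(counts))
}

#' Normalized counts
#'
#' Divides each sample's counts by its size factor.
#'
#' @inheritParams size_factors
#' @param factors Size factors from [size_factors()]; computed if omitted.
#' @return Real-valued matrix of normalized counts.
#' @export
normalize_counts <- function(counts, factors = NULL) {
  if (is.null(factors)) factors <- size_factors(counts)
  factors <- check_size_factors(factors, counts)
  sweep(counts, 2, factors, "/")
}

#' Variance-stabilizing transform of normalized counts
#'
#' Applies `log2(count / s_j + 1)`: a monotone transform of the normalized
#' counts that compresses the mean-variance relationship of overdispersed
#' counts before PCA and heatmap display. Count 0 maps to 0 for any size
#' factor, and scaling all counts and all factors by the same constant
#' leaves the output unchanged.
#'
#' @inheritParams normalize_counts
#' @return Real-valued matrix, same dimnames as `counts`.
#' @export
vst_transform <- function(counts, factors = NULL) {
  log2(normalize_counts(counts, factors) + 1)
}

#' Gene-wise z-scores
#'
#' Centers and scales each gene (row) to mean 0, sample standard deviation 1
#' (divisor n - 1), the convention used for expression heatmaps. Constant
#' genes map to an all-zero row.
#'
#' @param x Real-valued gene x sample matrix with >= 2 samples.
#' @return Matrix of z-scores with the same dimnames.
#' @export
zscore_by_gene <- function(x) {
  if (!is.matrix(x) || ncol(x) < 2) {
    stop("zscore_by_gene needs a matrix with at least 2 samples",
         call. = FALSE)
  }
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' PCA on the top-variance genes
#'
#' Selects the `n_top` genes with the highest row variance (ties broken by
#' gene ID order), centers each gene, and runs principal component analysis
#' on the samples. Each component's sign is fixed so that its
#' largest-magnitude gene loading is positive, making scores reproducible
#' across runs and platforms.
#'
#' @param x Real-valued gene x sample matrix (typically [vst_transform()]
#'   output).
#' @param n_top Number of top-variance genes to keep (<= number of genes).
#' @param n_components Number of components to return
#'   (<= `min(n samples, n_top)`).
#' @return List of class `ssl_pca` with `selected_gene_ids`, `scores`
#'   (sample x component matrix, columns `PC1..PCk`), `loadings`
#'   (gene x component), and `explained_variance` (fractions, non-increasing).
#' @export
pca_top_variance <- function(x, n_top = 1000L, n_components = 3L) {
  if (!is.matrix(x) || is.null(rownames(x))) {
    stop("x must be a matrix with gene row names", call. = FALSE)
  }
  if (n_top < 1 || n_top > nrow(x)) {
    stop("n_top must be between 1 and the number of genes", call. = FALSE)
  }
  if (n_components < 1 || n_components > min(ncol(x), n_top)) {
    stop("n_components must be between 1 and min(#samples, n_top)",
         call. = FALSE)
  }
  v <- apply(x, 1, stats::var)
  sel <- order(-v, rownames(x))[seq_len(n_top)]
  xs <- x[sel, , drop = FALSE]
  pc <- stats::prcomp(t(xs), center = TRUE, scale. = FALSE)
  k <- n_components
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    selected_gene_ids = rownames(xs),
    scores = scores,
    loadings = loadings,
    explained_variance = ev[seq_len(k)]
  ), class = "ssl_pca")
}

check_size_factors <- function(factors, counts) {
  if (is.null(names(factors)) ||
      !setequal(names(factors), colnames(counts)) ||
      any(!is.finite(factors)) || any(factors <= 0)) {
    stop("size factors must be positive and named for every sample",
         call. = FALSE)
  }
  invisible(factors[colnames(counts)])
}
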