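#' Per-sample "Targets Detected" fraction
#'
#' The sample-level QC metric of targeted RNA-seq panels: the fraction of
#' panel genes detected in each sample. A gene counts as detected when its
#' read count is at least `detect_min` (default 1, i.e. any non-zero count).
#'
#' @param counts Gene x sample matrix of non-negative integer read counts
#'   with gene row names and sample column names.
#' @param detect_min Minimum read count for a gene to count as detected
#'   (>= 1).
#' @return Named numeric vector, one fraction in \[0, 1\] per sample.
#' @export
targets_detected <- function(counts, detect_min = 1L) {
  check_count_matrix(counts)
  if (detect_min < 1) stop("detect_min must be >= 1", call. = FALSE)
  colMeans(counts >= detect_min)
}

#' Drop samples failing the Targets-Detected screen
#'
#' Retains exactly the samples whose Targets-Detected fraction is strictly
#' greater than `min_targets_detected` (the study convention "greater than
#' 20%" is a strict inequality).
#'
#' @inheritParams targets_detected
#' @param min_targets_detected Threshold fraction in \[0, 1\]; default 0.20.
#' @return List with `counts` (filtered matrix) and `report` (a
#'   [qc_report()]-style list recording kept/dropped samples and their
#'   fractions).
#' @export
filter_samples <- function(counts, min_targets_detected = 0.20,
                           detect_min = 1L) {
  check_count_matrix(counts)
  if (min_targets_detected < 0 || min_targets_detected > 1) {
    stop("min_targets_detected must be in [0, 1]", call. = FALSE)
  }
  td <- targets_detected(counts, detect_min)
  keep <- td > min_targets_detected
  if (!any(keep)) {
    stop("empty after QC: no sample exceeds Targets Detected > ",
         min_targets_detected, call. = FALSE)
  }
  report <- list(
    metric = "targets_detected",
    threshold = min_targets_detected,
    detect_min = detect_min,
    targets_detected = as.list(td),
    samples_kept = colnames(counts)[keep],
    samples_dropped = colnames(counts)[!keep]
  )
  list(counts = counts[, keep, drop = FALSE], report = report)
}

#' Drop genes failing the presence screen
#'
#' Retains genes with non-zero read counts in strictly more than
#' `min_presence` of the samples ("more than 90%" is a strict inequality).
#' Run after [filter_samples()] so presence is computed on the retained
#' samples only.
#'
#' @inheritParams targets_detected
#' @param min_presence Threshold fraction in \[0, 1\]; default 0.90.
#' @return List with `counts` and `report` (gene presence fractions,
#'   kept/dropped gene lists).
#' @export
filter_genes <- function(counts, min_presence = 0.90) {
  check_count_matrix(counts)
  if (min_presence < 0 || min_presence > 1) {
    stop("min_presence must be in [0, 1]", call. = FALSE)
  }
  presence <- rowMeans(counts > 0)
  keep <- presence > min_presence
  if (!any(keep)) {
    stop("empty after QC: no gene is present in more than ",
         min_presence * 100, "% of samples", call. = FALSE)
  }
  report <- list(
    metric = "gene_presence",
    threshold = min_presence,
    gene_presence = as.list(presence),
    genes_kept = rownames(counts)[keep],
    genes_dropped = rownames(counts)[!keep]
  )
  list(counts = counts[keep, , drop = FALSE], report = report)
}

#' Full data-cleaning pass: sample filter, then gene filter
#'
#' Applies the two QC rules in the study's order — first drop low-quality
#' samples (Targets Detected > `min_targets_detected`), then drop sparsely
#' detected genes (presence > `min_presence`, recomputed on the retained
#' samples).
#'
#' @inheritParams filter_samples
#' @inheritParams filter_genes
#' @return List with `counts` (cleaned matrix) and `report` combining both
#'   stage reports plus the thresholds used.
#' @export
qc_filter <- function(counts, min_targets_detected = 0.20,
                      min_presence = 0.90, detect_min = 1L) {
  s <- filter_samples(counts, min_targets_detected, detect_min)
  g <- filter_genes(s$counts, min_presence)
  list(
    counts = g$counts,
    report = list(
      thresholds = list(min_targets_detected = min_targets_detected,
                        min_presence = min_presence,
                        detect_min = detect_min),
      sample_filter = s$report,
      gene_filter = g$report
    )
  )
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || length(counts) == 0) {
    stop("counts must be a non-empty matrix", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("counts has duplicated gene or sample IDs", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative and NA-free", call. = FALSE)
  }
  if (any(counts != round(counts))) {
    stop("counts must be integral read counts", call. = FALSE)
  }
  invisible(counts)
}
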