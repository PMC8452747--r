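#' Read and write the count-matrix and metadata TSV dialects
#'
#' Count matrices are TSV with genes as rows: the first column (`gene_id`)
#' holds gene IDs and the remaining columns are samples. Sample metadata is
#' TSV with header `sample_id, cohort, group, sex, age, hy_stage,
#' ldopa_dose`.
#'
#' @param counts Gene x sample integer matrix with dimnames.
#' @param path File path.
#' @return `read_counts_tsv()` returns the matrix; `read_meta_tsv()` the
#'   metadata `data.frame`; the writers return `path` invisibly.
#' @name ssl_io
NULL

#' @rdname ssl_io
#' @export
write_counts_tsv <- function(counts, path) {
  check_count_matrix(counts)
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ssl_io
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (colnames(df)[1] != "gene_id") {
    stop("count TSV must have 'gene_id' as its first column", call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  check_count_matrix(m)
  m
}

#' @rdname ssl_io
#' @param meta Sample metadata `data.frame`.
#' @export
write_meta_tsv <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname ssl_io
#' @export
read_meta_tsv <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% colnames(meta))) {
    stop("metadata TSV must contain columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  meta
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
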