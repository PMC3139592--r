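#' Construct an expression experiment
#'
#' Bundles a linear-scale gene-by-sample intensity matrix with its sample
#' sheet (condition, replicate and batch per sample).  Intensities are
#' expected on the linear (non-log) scale of probe-level summarisation.
#'
#' @param matrix Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids), all values non-negative.
#' @param sample_sheet Data frame with columns `sample_id`, `condition`,
#'   `replicate`, `batch`; one row per matrix column, same order not required.
#' @return An `expression_experiment`.
#' @export
expression_experiment <- function(matrix, sample_sheet) {
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop_zftf("matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(matrix)))
    stop_zftf("duplicate gene ids in matrix")
  need <- c("sample_id", "condition", "replicate", "batch")
  if (!all(need %in% names(sample_sheet)))
    stop_zftf("sample sheet must have columns %s", paste(need, collapse = ", "))
  if (!setequal(sample_sheet$sample_id, colnames(matrix)) ||
      nrow(sample_sheet) != ncol(matrix))
    stop_zftf("sample sheet ids must match matrix columns exactly")
  if (any(!is.finite(matrix)) || any(matrix < 0))
    stop_zftf("intensities must be finite and non-negative")
  sample_sheet <- sample_sheet[match(colnames(matrix), sample_sheet$sample_id), ]
  rownames(sample_sheet) <- NULL
  structure(list(matrix = matrix, sample_sheet = sample_sheet),
            class = "expression_experiment")
}

#' @export
print.expression_experiment <- function(x, ...) {
  cat(sprintf("Expression experiment: %d genes x %d samples\n",
              nrow(x$matrix), ncol(x$matrix)))
  cat("  conditions:", paste(unique(x$sample_sheet$condition), collapse = ", "), "\n")
  cat("  batches:", paste(unique(x$sample_sheet$batch), collapse = ", "), "\n")
  invisible(x)
}

#' Write an expression experiment to TSV files
#'
#' The matrix is written genes-as-rows with a leading `gene_id` column; the
#' sample sheet is written as a separate TSV.  Values are printed with 15
#' significant digits so a write/read round trip is value-identical at that
#' precision.
#'
#' @param exp An `expression_experiment`.
#' @param matrix_path,samples_path Output paths.
#' @export
write_expression <- function(exp, matrix_path, samples_path) {
  stopifnot(inherits(exp, "expression_experiment"))
  df <- data.frame(gene_id = rownames(exp$matrix),
                   format(exp$matrix, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(exp$sample_sheet, samples_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, samples_path))
}

#' Read an expression experiment from TSV files
#'
#' @param matrix_path TSV with a `gene_id` first column then one column per
#'   sample.
#' @param samples_path Sample-sheet TSV with columns `sample_id`,
#'   `condition`, `replicate`, `batch`.
#' @return An `expression_experiment`.
#' @export
read_expression <- function(matrix_path, samples_path) {
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id")
    stop_zftf("matrix TSV must start with a 'gene_id' column")
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab$gene_id
  storage.mode(mat) <- "double"
  sheet <- utils::read.delim(samples_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  expression_experiment(mat, sheet)
}
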