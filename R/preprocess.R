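#' Processed expression matrix with a transform log
#'
#' A thin container for a genes-by-samples matrix moving through the
#' preprocessing pipeline.  Every operation appends a named entry (step +
#' parameters) to `transform_log`, so any processed matrix can be replayed
#' from its source experiment.
#'
#' @param matrix Numeric matrix with gene rownames and sample colnames.
#' @param sample_sheet Per-sample data frame (carried along for clustering).
#' @param transform_log List of applied steps.
#' @return A `processed_matrix`.
#' @export
processed_matrix <- function(matrix, sample_sheet = NULL,
                             transform_log = list()) {
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop_zftf("matrix must have rownames and colnames")
  structure(list(matrix = matrix, sample_sheet = sample_sheet,
                 transform_log = transform_log),
            class = "processed_matrix")
}

#' @export
print.processed_matrix <- function(x, ...) {
  cat(sprintf("Processed matrix: %d genes x %d samples\n",
              nrow(x$matrix), ncol(x$matrix)))
  steps <- vapply(x$transform_log, function(s) s$step, "")
  cat("  transform log:", if (length(steps)) paste(steps, collapse = " -> ")
                          else "(none)", "\n")
  invisible(x)
}

as_processed <- function(x) {
  if (inherits(x, "processed_matrix")) return(x)
  if (inherits(x, "expression_experiment"))
    return(processed_matrix(x$matrix, x$sample_sheet))
  if (is.matrix(x)) return(processed_matrix(x))
  stop_zftf("cannot interpret object of class '%s' as a matrix", class(x)[1])
}

log_step <- function(pm, step, ...) {
  pm$transform_log <- c(pm$transform_log, list(list(step = step,
                                                    params = list(...))))
  pm
}

trimmed_mean <- function(x, trim_fraction) {
  n <- length(x)
  g <- floor(n * trim_fraction / 2)
  s <- sort(x)
  mean(s[(g + 1L):(n - g)])
}

#' Scale each sample so its trimmed mean hits a common target
#'
#' Rescales every column so that its trimmed mean equals `target` (the
#' scaling convention of linear-scale probe-summarised intensities: the 2%
#' trimmed mean of each sample is set to 100).  "2% trimmed" is interpreted
#' as removing 1% of values from each tail, with `floor(n * 0.01)` values
#' dropped per tail.
#'
#' @param exp An `expression_experiment`, `processed_matrix` or matrix.
#' @param trim_fraction Total trimmed mass (default 0.02; half per tail).
#' @param target Target trimmed mean (default 100).
#' @return A `processed_matrix`.
#' @export
trimmed_mean_normalize <- function(exp, trim_fraction = 0.02, target = 100) {
  pm <- as_processed(exp)
  if (any(pm$matrix < 0)) stop_zftf("intensities must be non-negative")
  tm <- apply(pm$matrix, 2, trimmed_mean, trim_fraction = trim_fraction)
  if (any(tm <= 0))
    stop_zftf("sample(s) with non-positive trimmed mean: %s",
              paste(colnames(pm$matrix)[tm <= 0], collapse = ", "))
  pm$matrix <- sweep(pm$matrix, 2, target / tm, `*`)
  log_step(pm, "trimmed_mean_normalize", trim_fraction = trim_fraction,
           target = target)
}

#' Mean-shift batch correction on a per-gene basis
#'
#' For each gene and each batch N other than the first, the difference
#' between the gene's average expression in the first batch and its average
#' in batch N is added to every batch-N value.  Afterwards all per-gene batch
#' means are equal, and within-batch contrasts are exactly unchanged.  The
#' "first" batch is the batch of the first sample in the sample sheet.
#'
#' @param pm A `processed_matrix` (with a sample sheet carrying `batch`), or
#'   a matrix plus an explicit `batches` vector.
#' @param batches Optional character/factor vector of batch labels, one per
#'   column (overrides the sample sheet).
#' @return A `processed_matrix`.
#' @export
batch_correct <- function(pm, batches = NULL) {
  pm <- as_processed(pm)
  if (is.null(batches)) {
    if (is.null(pm$sample_sheet) || is.null(pm$sample_sheet$batch))
      stop_zftf("no batch assignment available")
    batches <- pm$sample_sheet$batch
  }
  if (length(batches) != ncol(pm$matrix))
    stop_zftf("batches must have one entry per sample")
  batches <- as.character(batches)
  levels <- unique(batches)      # first batch = first appearance order
  idx1 <- which(batches == levels[1])
  m1 <- rowMeans(pm$matrix[, idx1, drop = FALSE])
  for (b in levels[-1]) {
    idx <- which(batches == b)
    if (length(idx) == 0L) stop_zftf("batch '%s' has no samples", b)
    mb <- rowMeans(pm$matrix[, idx, drop = FALSE])
    pm$matrix[, idx] <- pm$matrix[, idx, drop = FALSE] + (m1 - mb)
  }
  log_step(pm, "batch_correct", first_batch = levels[1],
           n_batches = length(levels))
}

#' Keep the k most variable genes
#'
#' Retains exactly `k` rows, those with the largest sample standard
#' deviation across samples; ties at the boundary are broken by row-id
#' lexicographic order, and the surviving rows keep their original relative
#' order.
#'
#' @param pm A `processed_matrix` or matrix.
#' @param k Number of rows to retain (default 2500).
#' @return A `processed_matrix` with `k` rows.
#' @export
variance_filter <- function(pm, k = 2500) {
  pm <- as_processed(pm)
  n <- nrow(pm$matrix)
  if (k > n) stop_zftf("k = %d exceeds the %d available rows", k, n)
  sds <- apply(pm$matrix, 1, stats::sd)
  ord <- order(-sds, rownames(pm$matrix), method = "radix")
  keep <- sort(ord[seq_len(k)])          # preserve original row order
  pm$matrix <- pm$matrix[keep, , drop = FALSE]
  log_step(pm, "variance_filter", k = k, sd_convention = "sample")
}

#' Tukey median polish
#'
#' Iteratively sweeps row and column medians out of the matrix until the sum
#' of absolute residuals changes by less than `tol` (relative) or `max_iter`
#' is reached, replacing the matrix by the residuals.  Row, column and
#' overall effects are kept alongside the result.
#'
#' @param pm A `processed_matrix` or matrix (finite entries).
#' @param max_iter Maximum sweep iterations (default 20).
#' @param tol Relative convergence tolerance (default 1e-6).
#' @return A `processed_matrix` whose `matrix` holds the residuals, with a
#'   `medpolish` element (list: `overall`, `row`, `col`).
#' @export
median_polish <- function(pm, max_iter = 20L, tol = 1e-6) {
  pm <- as_processed(pm)
  if (any(!is.finite(pm$matrix))) stop_zftf("matrix has non-finite entries")
  fit <- stats::medpolish(pm$matrix, eps = tol, maxiter = max_iter,
                          trace.iter = FALSE, na.rm = FALSE)
  res <- fit$residuals
  dimnames(res) <- dimnames(pm$matrix)
  pm$matrix <- res
  pm$medpolish <- list(overall = fit$overall,
                       row = stats::setNames(fit$row, rownames(res)),
                       col = stats::setNames(fit$col, colnames(res)))
  log_step(pm, "median_polish", max_iter = max_iter, tol = tol)
}

#' Scale each row to mean 0, standard deviation 1
#'
#' Uses the population (divide-by-n) standard deviation.  Constant rows
#' cannot be scaled: by default they raise an error naming the offending
#' rows; with `drop_constant = TRUE` they are removed with a warning.
#'
#' @param pm A `processed_matrix` or matrix.
#' @param drop_constant Drop unscalable constant rows instead of erroring.
#' @return A `processed_matrix`.
#' @export
row_scale <- function(pm, drop_constant = FALSE) {
  pm <- as_processed(pm)
  m <- rowMeans(pm$matrix)
  s <- sqrt(rowMeans((pm$matrix - m)^2))
  const <- s == 0
  if (any(const)) {
    ids <- rownames(pm$matrix)[const]
    if (!drop_constant)
      stop_zftf("constant row(s) cannot be scaled: %s",
                paste(utils::head(ids, 5), collapse = ", "))
    warning(sprintf("dropping %d constant row(s)", sum(const)), call. = FALSE)
    pm$matrix <- pm$matrix[!const, , drop = FALSE]
    m <- m[!const]; s <- s[!const]
  }
  pm$matrix <- (pm$matrix - m) / s
  log_step(pm, "row_scale", sd_convention = "population",
           dropped_constant = if (any(const)) sum(const) else 0L)
}

#' Run the full preprocessing pipeline
#'
#' Convenience composition of the five preprocessing stages in their
#' analysis order: trimmed-mean scaling, per-gene mean-shift batch
#' correction, top-k variance filtering, median polish, and row
#' standardisation.  An optional `log2` transform (default off) can be
#' inserted after batch correction; the downstream stages otherwise operate
#' on linear-scale values.
#'
#' @param exp An `expression_experiment`.
#' @param k Variance-filter size (default 2500).
#' @param trim_fraction,target Trimmed-mean scaling parameters.
#' @param log2_transform Insert a log2(x + 1) transform after batch
#'   correction (default FALSE).
#' @return A `processed_matrix` ready for clustering.
#' @export
preprocess_pipeline <- function(exp, k = 2500, trim_fraction = 0.02,
                                target = 100, log2_transform = FALSE) {
  pm <- trimmed_mean_normalize(exp, trim_fraction = trim_fraction,
                               target = target)
  pm <- batch_correct(pm)
  if (log2_transform) {
    pm$matrix <- log2(pmax(pm$matrix, 0) + 1)
    pm <- log_step(pm, "log2_transform", offset = 1)
  }
  pm <- variance_filter(pm, k = k)
  pm <- median_polish(pm)
  row_scale(pm)
}

#' Replay a transform log against a source experiment
#'
#' Re-executes the recorded preprocessing steps on a fresh copy of the
#' source experiment; used to verify that a processed matrix is exactly
#' reproducible from its log.
#'
#' @param exp The source `expression_experiment`.
#' @param transform_log A `transform_log` from a `processed_matrix`.
#' @return A `processed_matrix`.
#' @export
replay_transforms <- function(exp, transform_log) {
  pm <- as_processed(exp)
  for (entry in transform_log) {
    p <- entry$params
    pm <- switch(entry$step,
      trimmed_mean_normalize = trimmed_mean_normalize(pm,
        trim_fraction = p$trim_fraction, target = p$target),
      batch_correct = batch_correct(pm),
      log2_transform = {
        pm$matrix <- log2(pmax(pm$matrix, 0) + 1)
        log_step(pm, "log2_transform", offset = 1)
      },
      variance_filter = variance_filter(pm, k = p$k),
      median_polish = median_polish(pm, max_iter = p$max_iter, tol = p$tol),
      row_scale = row_scale(pm),
      stop_zftf("unknown transform step '%s'", entry$step))
  }
  pm
}
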