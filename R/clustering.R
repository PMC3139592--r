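#' Correlation distance between gene profiles
#'
#' Pairwise distance `d_ij = 1 - Pearson(row_i, row_j)`, the standard
#' dissimilarity for co-expression clustering; range \[0, 2\], zero on the
#' diagonal.
#'
#' @param mat A `processed_matrix` or numeric matrix (genes in rows).
#' @return Symmetric numeric matrix of distances.
#' @export
correlation_distance_matrix <- function(mat) {
  x <- if (inherits(mat, "processed_matrix")) mat$matrix else mat
  if (ncol(x) < 2L) stop_zftf("need at least 2 samples per gene")
  s <- apply(x, 1, stats::sd)
  if (any(s == 0))
    stop_zftf("constant row(s) have undefined correlation: %s",
              paste(utils::head(rownames(x)[s == 0], 5), collapse = ", "))
  d <- 1 - stats::cor(t(x))
  diag(d) <- 0
  d[d < 0] <- 0              # clip tiny negative rounding of perfect correlation
  (d + t(d)) / 2
}

#' Average-linkage agglomerative clustering
#'
#' UPGMA: at every step the two clusters with the smallest mean cross-pair
#' distance are merged, the inter-cluster distance being the arithmetic mean
#' of all cross-pair distances.
#'
#' @param dist Symmetric distance matrix (e.g. from
#'   [correlation_distance_matrix()]) or a `dist` object.
#' @return An [stats::hclust] tree.
#' @export
average_linkage_cluster <- function(dist) {
  if (is.matrix(dist)) {
    if (nrow(dist) < 2L) stop_zftf("need at least 2 items to cluster")
    dist <- stats::as.dist(dist)
  }
  stats::hclust(dist, method = "average")
}

direction_call <- function(delta, tau) {
  ifelse(delta > tau, "up", ifelse(delta < -tau, "down", "none"))
}

make_tag <- function(calls, conditions) {
  up <- conditions[calls == "up"]
  down <- conditions[calls == "down"]
  if (length(down) == length(conditions) && length(conditions) > 0) return("common-down")
  if (length(up) == length(conditions) && length(conditions) > 0) return("common-up")
  if (length(up) && length(down)) return("mixed")
  if (length(up) == 1L) return(paste0("unique-up:", up))
  if (length(up) > 1L) return(paste0("shared-up:", paste(up, collapse = "+")))
  if (length(down) == 1L) return(paste0("unique-down:", down))
  if (length(down) > 1L) return(paste0("shared-down:", paste(down, collapse = "+")))
  "none"
}

#' Cut a gene dendrogram and label clusters by regulation direction
#'
#' The tree is cut either at a fixed height (default: correlation-distance
#' 0.16, i.e. clusters whose genes correlate at about 0.84 or better -- a
#' formalisation of tight, visually boxable co-expression modules) or into a
#' fixed number of clusters.  For every cluster of at least `min_size` genes
#' and every treatment condition, the cluster's mean scaled expression in
#' that condition minus its mean in the control condition is computed; the
#' condition is called "up" if the difference exceeds `tau`, "down" if below
#' `-tau`, "none" otherwise.  A cluster down in every treatment condition is
#' tagged `"common-down"` (the shared resistance-signature pattern); clusters
#' up in one or several conditions get `"unique-up:<cond>"` /
#' `"shared-up:<c1+c2+...>"` tags.  Clusters smaller than `min_size` are
#' tagged `"small"` and receive no direction calls.
#'
#' @param hc An `hclust` tree over the rows of `pm`.
#' @param pm The row-scaled `processed_matrix` the tree was built from (must
#'   carry a sample sheet with `condition`).
#' @param height Cut height (used when `n_clusters` is NULL; default 0.16).
#' @param n_clusters Optional number of clusters (overrides `height`).
#' @param tau Direction-call threshold in scaled-expression units
#'   (default 0.5).
#' @param min_size Minimum cluster size for labelling (default 20).
#' @param control Name of the control condition (default "control").
#' @return A `cluster_result`: `hclust`, `leaf_order`, `memberships`
#'   (named integer vector gene -> cluster), `labels` (one row per cluster:
#'   id, size, per-condition calls, tag), and the parameters used.
#' @export
cut_and_label <- function(hc, pm, height = 0.16, n_clusters = NULL,
                          tau = 0.5, min_size = 20, control = "control") {
  stopifnot(inherits(hc, "hclust"), inherits(pm, "processed_matrix"))
  if (tau <= 0) stop_zftf("tau must be positive")
  sheet <- pm$sample_sheet
  if (is.null(sheet)) stop_zftf("processed matrix has no sample sheet")
  if (!control %in% sheet$condition)
    stop_zftf("control condition '%s' missing from sample sheet", control)
  x <- pm$matrix
  if (!identical(sort(hc$labels), sort(rownames(x))))
    stop_zftf("dendrogram leaves do not match matrix rows")
  x <- x[hc$labels, , drop = FALSE]
  memberships <- if (!is.null(n_clusters)) stats::cutree(hc, k = n_clusters)
                 else stats::cutree(hc, h = height)
  conditions <- setdiff(unique(sheet$condition), control)
  ctrl_idx <- which(sheet$condition == control)
  cl_ids <- sort(unique(memberships))
  rows <- lapply(cl_ids, function(cl) {
    genes <- names(memberships)[memberships == cl]
    size <- length(genes)
    calls <- rep(NA_character_, length(conditions))
    tag <- "small"
    if (size >= min_size) {
      ctrl_mean <- mean(x[genes, ctrl_idx, drop = FALSE])
      delta <- vapply(conditions, function(cond) {
        idx <- which(sheet$condition == cond)
        mean(x[genes, idx, drop = FALSE]) - ctrl_mean
      }, 0)
      calls <- direction_call(delta, tau)
      tag <- make_tag(calls, conditions)
    }
    out <- data.frame(cluster = cl, size = size, tag = tag,
                      stringsAsFactors = FALSE)
    for (j in seq_along(conditions)) out[[paste0("call_", conditions[j])]] <- calls[j]
    out
  })
  labels <- do.call(rbind, rows)
  structure(list(hclust = hc, leaf_order = hc$labels[hc$order],
                 memberships = memberships, labels = labels,
                 conditions = conditions, control = control,
                 params = list(height = if (is.null(n_clusters)) height else NA,
                               n_clusters = n_clusters, tau = tau,
                               min_size = min_size)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Cluster result: %d genes in %d clusters (%d labelled)\n",
              length(x$memberships), nrow(x$labels),
              sum(x$labels$tag != "small")))
  lab <- x$labels[x$labels$tag != "small", c("cluster", "size", "tag")]
  if (nrow(lab)) print(lab, row.names = FALSE)
  invisible(x)
}

#' Genes belonging to clusters carrying a given tag
#'
#' @param result A `cluster_result`.
#' @param tag Tag to select (e.g. `"common-down"`).
#' @return Character vector of gene ids.
#' @export
cluster_genes <- function(result, tag = "common-down") {
  stopifnot(inherits(result, "cluster_result"))
  cls <- result$labels$cluster[result$labels$tag == tag]
  names(result$memberships)[result$memberships %in% cls]
}

#' Write cluster memberships as a TSV
#'
#' @param result A `cluster_result`.
#' @param path Output path.
#' @export
write_memberships <- function(result, path) {
  tags <- result$labels$tag[match(result$memberships, result$labels$cluster)]
  df <- data.frame(gene_id = names(result$memberships),
                   cluster = unname(result$memberships), tag = tags)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a gene dendrogram in Newick format
#'
#' Leaf names are gene ids; branch lengths are the height differences
#' between nested merges.
#'
#' @param hc An `hclust` tree.
#' @param path Output path.
#' @export
write_newick <- function(hc, path) {
  build <- function(i, parent_h) {
    if (i < 0) {   # leaf
      sprintf("%s:%.12g", hc$labels[-i], parent_h)
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%.12g", build(hc$merge[i, 1], h), build(hc$merge[i, 2], h),
              parent_h - h)
    }
  }
  n <- length(hc$height)
  txt <- paste0(sprintf("(%s,%s);",
                        build(hc$merge[n, 1], hc$height[n]),
                        build(hc$merge[n, 2], hc$height[n])))
  writeLines(txt, path)
  invisible(path)
}

#' Project a reference gene ordering onto an external dataset
#'
#' Restricts the external matrix to the reference gene list, independently
#' median-polishes and row-scales it, and reorders its rows to the reference
#' dendrogram's leaf order (genes absent from the external data are kept as
#' masked all-NA rows, preserving the ordering).  For every labelled
#' reference cluster with an unambiguous overall direction (a "common-down"
#' or any "up" tag), the per-gene external contrast (mean over all external
#' treatment samples minus mean over external controls) is computed and the
#' agreement score is the fraction of cluster genes whose contrast sign
#' matches the reference direction; about 0.5 for unrelated data, near 1 for
#' shared regulation.
#'
#' @param reference A `cluster_result` from the reference dataset.
#' @param external An `expression_experiment` (or `processed_matrix`) sharing
#'   the reference gene-id namespace, with a `condition` column including
#'   `control`.
#' @param control External control condition name (default "control").
#' @param min_present Minimum fraction of reference genes that must be
#'   present in the external data (default 0.5).
#' @return A `projection_result`: `matrix` (external, processed, reference
#'   leaf order, masked rows NA), `agreement` (per labelled cluster),
#'   `missing_genes`.
#' @export
project_external <- function(reference, external, control = "control",
                             min_present = 0.5) {
  stopifnot(inherits(reference, "cluster_result"))
  pm <- as_processed(external)
  sheet <- pm$sample_sheet
  if (is.null(sheet)) stop_zftf("external data has no sample sheet")
  if (!control %in% sheet$condition)
    stop_zftf("external control condition '%s' not found", control)
  ref_genes <- reference$leaf_order
  present <- ref_genes[ref_genes %in% rownames(pm$matrix)]
  if (length(present) / length(ref_genes) < min_present)
    stop_zftf("only %d/%d reference genes present in external data",
              length(present), length(ref_genes))
  sub <- processed_matrix(pm$matrix[present, , drop = FALSE], sheet,
                          pm$transform_log)
  sub <- median_polish(sub)
  sub <- row_scale(sub, drop_constant = TRUE)
  kept <- rownames(sub$matrix)
  out <- matrix(NA_real_, nrow = length(ref_genes), ncol = ncol(sub$matrix),
                dimnames = list(ref_genes, colnames(sub$matrix)))
  out[kept, ] <- sub$matrix
  treat_idx <- which(sheet$condition != control)
  ctrl_idx <- which(sheet$condition == control)
  contrast <- rowMeans(sub$matrix[, treat_idx, drop = FALSE]) -
              rowMeans(sub$matrix[, ctrl_idx, drop = FALSE])
  lab <- reference$labels
  agreement <- vapply(seq_len(nrow(lab)), function(i) {
    tag <- lab$tag[i]
    dir <- if (grepl("down", tag)) -1 else if (grepl("up", tag)) 1 else NA_real_
    if (is.na(dir)) return(NA_real_)
    genes <- names(reference$memberships)[reference$memberships == lab$cluster[i]]
    genes <- intersect(genes, kept)
    if (!length(genes)) return(NA_real_)
    mean(sign(contrast[genes]) == dir)
  }, 0)
  structure(list(matrix = out,
                 agreement = data.frame(cluster = lab$cluster, size = lab$size,
                                        tag = lab$tag, agreement = agreement),
                 missing_genes = setdiff(ref_genes, kept)),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("Projection: %d genes (%d masked), %d external samples\n",
              nrow(x$matrix), length(x$missing_genes), ncol(x$matrix)))
  ag <- x$agreement[!is.na(x$agreement$agreement), ]
  if (nrow(ag)) print(ag, row.names = FALSE)
  invisible(x)
}
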