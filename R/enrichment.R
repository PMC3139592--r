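#' Construct a gene-set database
#'
#' @param sets Named list: each element a character vector of member gene
#'   ids.  Names must be unique and members non-empty.
#' @param descriptions Optional character vector of per-set descriptions.
#' @param provenance Optional character notes on where the sets came from.
#' @return A `gene_set_db`.
#' @export
gene_set_db <- function(sets, descriptions = NULL, provenance = character()) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop_zftf("all gene sets must be named")
  if (anyDuplicated(names(sets)))
    stop_zftf("duplicate set name(s): %s",
              paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  if (any(lengths(sets) == 0L)) stop_zftf("empty gene set(s) not allowed")
  sets <- lapply(sets, unique)
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(list(sets = sets,
                 descriptions = stats::setNames(descriptions, names(sets)),
                 provenance = provenance),
            class = "gene_set_db")
}

#' @export
print.gene_set_db <- function(x, ...) {
  cat(sprintf("Gene-set database: %d sets (sizes %d-%d)\n", length(x$sets),
              min(lengths(x$sets)), max(lengths(x$sets))))
  if (length(x$provenance)) cat("  provenance:", paste(x$provenance, collapse = "; "), "\n")
  invisible(x)
}

#' Read a gene-set database from a GMT file
#'
#' GMT is tab-separated: set name, description, then member gene ids.
#'
#' @param path GMT file path.
#' @return A `gene_set_db` (descriptions are not retained by the reader).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  gene_set_db(sets, provenance = sprintf("read from %s", basename(path)))
}

#' Write a gene-set database to a GMT file
#'
#' @param db A `gene_set_db`.
#' @param path Output path.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "gene_set_db"))
  lines <- vapply(names(db$sets), function(nm) {
    paste(c(nm, db$descriptions[[nm]], db$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Merge two gene-set databases
#'
#' Concatenates the sets of both databases (e.g. a base collection augmented
#' with study-specific signatures), refusing name collisions and recording
#' the provenance of each source.
#'
#' @param base,extra `gene_set_db` objects.
#' @return A combined `gene_set_db`.
#' @export
augment_database <- function(base, extra) {
  stopifnot(inherits(base, "gene_set_db"), inherits(extra, "gene_set_db"))
  clash <- intersect(names(base$sets), names(extra$sets))
  if (length(clash))
    stop_zftf("set name collision between databases: %s",
              paste(clash, collapse = ", "))
  gene_set_db(c(base$sets, extra$sets),
              c(unname(base$descriptions), unname(extra$descriptions)),
              provenance = c(base$provenance, extra$provenance,
                             sprintf("augmented: %d + %d sets",
                                     length(base$sets), length(extra$sets))))
}

#' Upper-tail hypergeometric overlap probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, S, n)`: the probability that a
#' cluster of `n` genes and a gene set of `S` genes, both drawn at random
#' from a universe of `N` genes, share at least `k` members.
#'
#' @param N Universe size.
#' @param S Set size within the universe.
#' @param n Cluster size.
#' @param k Observed overlap.
#' @return The raw over-representation p-value.
#' @export
hypergeometric_tail <- function(N, S, n, k) {
  ok <- function(v) length(v) == 1L && is.finite(v) && v == round(v)
  if (!ok(N) || !ok(S) || !ok(n) || !ok(k))
    stop_zftf("N, S, n, k must be single integers")
  if (S < 0 || n < 0 || S > N || n > N)
    stop_zftf("need 0 <= S, n <= N (got N=%d S=%d n=%d)", N, S, n)
  if (k < 0 || k > min(S, n))
    stop_zftf("need 0 <= k <= min(S, n) (got k=%d)", k)
  if (k == 0) return(1)
  stats::phyper(k - 1, S, N - S, n, lower.tail = FALSE)
}

#' Holm step-down family-wise error adjustment
#'
#' @param pvals Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric())
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop_zftf("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "holm")
}

#' Hypergeometric enrichment of a gene cluster against a set database
#'
#' Every set is first intersected with the universe; the overlap of the
#' cluster with each intersected set is tested with the upper-tail
#' hypergeometric probability, and the p-values of all sets tested for this
#' cluster (one Holm family per cluster) are Holm-adjusted.  Sets that are
#' empty after universe intersection are reported with p = 1 and flagged.
#'
#' @param cluster_genes Character vector of cluster member gene ids (must be
#'   a subset of the universe).
#' @param db A `gene_set_db`.
#' @param universe Character vector of all assayable gene ids.
#' @param cluster_id Identifier used in the output (default "cluster").
#' @param min_overlap Sets with smaller overlap are still tested; the value
#'   is only recorded in the output flag (default 1).
#' @return Data frame (`enrichment_table`) with one row per set: `cluster`,
#'   `set`, `N`, `S`, `n`, `k`, `p_raw`, `p_holm`, `flag`; sorted by
#'   adjusted then raw p.
#' @export
run_enrichment <- function(cluster_genes, db, universe,
                           cluster_id = "cluster", min_overlap = 1) {
  stopifnot(inherits(db, "gene_set_db"))
  universe <- unique(universe)
  if (!length(universe)) stop_zftf("empty universe")
  if (!length(db$sets)) stop_zftf("empty gene-set database")
  cluster_genes <- unique(cluster_genes)
  out_of_univ <- setdiff(cluster_genes, universe)
  if (length(out_of_univ))
    stop_zftf("%d cluster gene(s) outside the universe", length(out_of_univ))
  N <- length(universe)
  n <- length(cluster_genes)
  rows <- lapply(names(db$sets), function(nm) {
    members <- intersect(db$sets[[nm]], universe)
    S <- length(members)
    k <- length(intersect(members, cluster_genes))
    p <- if (S == 0) 1 else hypergeometric_tail(N, S, n, k)
    flag <- if (S == 0) "empty_after_universe_intersection"
            else if (k < min_overlap) "below_min_overlap" else ""
    data.frame(cluster = cluster_id, set = nm, N = N, S = S, n = n, k = k,
               p_raw = p, flag = flag, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_holm <- holm_adjust(tab$p_raw)
  tab <- tab[order(tab$p_holm, tab$p_raw, tab$set),
             c("cluster", "set", "N", "S", "n", "k", "p_raw", "p_holm", "flag")]
  rownames(tab) <- NULL
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

#' Enrichment of every labelled cluster in a clustering result
#'
#' Runs [run_enrichment()] once per labelled (non-"small") cluster, each with
#' its own Holm family.
#'
#' @param result A `cluster_result`.
#' @param db A `gene_set_db`.
#' @param universe Gene universe (default: all clustered genes).
#' @param ... Passed to [run_enrichment()].
#' @return A combined `enrichment_table`.
#' @export
enrich_clusters <- function(result, db, universe = names(result$memberships),
                            ...) {
  stopifnot(inherits(result, "cluster_result"))
  lab <- result$labels[result$labels$tag != "small", , drop = FALSE]
  tabs <- lapply(seq_len(nrow(lab)), function(i) {
    genes <- names(result$memberships)[result$memberships == lab$cluster[i]]
    run_enrichment(genes, db, universe,
                   cluster_id = sprintf("cluster_%d", lab$cluster[i]), ...)
  })
  out <- do.call(rbind, tabs)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Collapse probe-level rows to one row per gene
#'
#' When several probe-set rows map to the same gene, the row with the
#' highest sample standard deviation represents the gene (a common
#' convention for membership-based enrichment).
#'
#' @param mat Numeric matrix with probe rownames.
#' @param probe_to_gene Named character vector mapping probe id -> gene id.
#' @return Matrix with one row per gene (rownames = gene ids).
#' @export
collapse_probes <- function(mat, probe_to_gene) {
  probes <- intersect(rownames(mat), names(probe_to_gene))
  if (!length(probes)) stop_zftf("no probes matched the mapping")
  mat <- mat[probes, , drop = FALSE]
  genes <- probe_to_gene[probes]
  sds <- apply(mat, 1, stats::sd)
  keep <- vapply(split(seq_along(probes), genes), function(idx) {
    idx[order(-sds[idx], probes[idx])[1]]
  }, 0L)
  out <- mat[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  out
}
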