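#' Expand an IUPAC-degenerate DNA string to all concrete sequences
#'
#' @param pattern IUPAC string.
#' @param max_expand Guard against combinatorial blow-up; expansion larger
#'   than this errors.
#' @return Character vector of concrete A/C/G/T strings (no duplicates).
#' @export
expand_iupac <- function(pattern, max_expand = 1e6) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_MAP))
  if (length(bad))
    stop_zftf("pattern '%s' contains non-IUPAC code(s): %s", pattern,
              paste(unique(bad), collapse = ","))
  opts <- lapply(chars, function(ch) strsplit(IUPAC_MAP[[ch]], "")[[1]])
  ndeg <- prod(lengths(opts))
  if (ndeg > max_expand)
    stop_zftf("expansion of '%s' has %g sequences (> max_expand = %g)",
              pattern, ndeg, max_expand)
  grid <- expand.grid(rev(opts), stringsAsFactors = FALSE)[, rev(seq_along(opts)), drop = FALSE]
  unique(do.call(paste0, grid))
}

#' Predict the DNA target site(s) of a finger array
#'
#' Each finger recognises a 3-bp subsite, so an L-finger array recognises a
#' 3L-bp composite site.  Zinc-finger arrays bind DNA antiparallel: under the
#' default convention the first (N-terminal) finger F1 contacts the 3'-most
#' triplet of the site, so the site read 5' to 3' is
#' `subsite(FL) ... subsite(F1)`.  The `orientation` flag flips the reported
#' reading convention to the complementary strand (F1 at the 5' end), which
#' yields exactly the reverse complement of the default site set.  Fingers
#' with alternative subsites contribute one degenerate site per subsite
#' combination; expanded concrete sites are de-duplicated after IUPAC
#' expansion.
#'
#' @param array A `zf_finger_array`.
#' @param orientation `"F1-3prime"` (default) or `"F1-5prime"`.
#' @param expand Whether to compute the concrete expanded site set.
#' @param max_expand Expansion guard passed to [expand_iupac()].
#' @return A `predicted_sites` list: `array_id`, `orientation`,
#'   `iupac_sites` (one degenerate string per subsite combination),
#'   `expanded_sites` (unique concrete sequences), `site_length`.
#' @examples
#' cat25 <- load_catalog()
#' cl7 <- finger_array(cat25, c("LZF15", "LZF23", "LZF10", "LZF20"), "7")
#' predict_sites(cl7)$site_length  # 12
#' @export
predict_sites <- function(array, orientation = c("F1-3prime", "F1-5prime"),
                          expand = TRUE, max_expand = 1e6) {
  stopifnot(inherits(array, "zf_finger_array"))
  orientation <- match.arg(orientation)
  if (any(lengths(array$subsites) < 1L))
    stop_zftf("every finger must have at least one subsite")
  # default convention: 5'->3' site is subsite(FL) ... subsite(F1)
  blocks <- rev(array$subsites)
  grid <- expand.grid(rev(blocks), stringsAsFactors = FALSE)[, rev(seq_along(blocks)), drop = FALSE]
  iupac <- unique(do.call(paste0, grid))
  if (orientation == "F1-5prime") iupac <- unique(dna_revcomp(iupac))
  expanded <- NULL
  if (expand) {
    expanded <- unique(unlist(lapply(iupac, expand_iupac, max_expand = max_expand),
                              use.names = FALSE))
  }
  structure(list(array_id = array$clone_id, orientation = orientation,
                 iupac_sites = iupac, expanded_sites = expanded,
                 site_length = 3L * length(array$fingers)),
            class = "predicted_sites")
}

#' @export
print.predicted_sites <- function(x, ...) {
  cat(sprintf("Predicted sites for array '%s' (%s): %d bp\n",
              x$array_id, x$orientation, x$site_length))
  cat("  degenerate site(s):", paste(x$iupac_sites, collapse = " | "), "\n")
  if (!is.null(x$expanded_sites))
    cat(sprintf("  %d distinct concrete sites\n", length(x$expanded_sites)))
  invisible(x)
}

# reverse complement that preserves IUPAC degeneracy codes
dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read DNA sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return A `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Scan sequences for exact occurrences of predicted binding sites
#'
#' Every exact occurrence of any expanded concrete site is reported with
#' 0-based half-open coordinates.  With `both_strands = TRUE`, occurrences of
#' the reverse complement on the forward strand are reported with strand
#' `"-"` (start still given on the forward strand).  `N` bases in the subject
#' sequence never match.
#'
#' @param seqs Named character vector of DNA sequences or a
#'   `Biostrings::DNAStringSet` (e.g. from [read_fasta()]).
#' @param sites A `predicted_sites` object (or character vector of concrete
#'   equal-length sites).
#' @param both_strands Scan the reverse strand as well (default TRUE).
#' @return Data frame with columns `sequence_id`, `start`, `end`, `strand`,
#'   `matched_site`, sorted by (sequence_id, start, strand).  `matched_site`
#'   is the site in its predicted orientation (for `-` hits it equals the
#'   reverse complement of the forward-strand subsequence).
#' @export
scan_sequence <- function(seqs, sites, both_strands = TRUE) {
  if (inherits(sites, "predicted_sites")) {
    if (is.null(sites$expanded_sites))
      stop_zftf("predicted_sites was built with expand = FALSE")
    sites <- sites$expanded_sites
  }
  empty <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      matched_site = character(), stringsAsFactors = FALSE)
  if (length(sites) == 0L) return(empty)
  if (length(unique(nchar(sites))) != 1L)
    stop_zftf("all sites must have equal length")
  if (is.character(seqs)) {
    if (is.null(names(seqs)))
      names(seqs) <- sprintf("seq%d", seq_along(seqs))
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  stopifnot(inherits(seqs, "XStringSet"))
  for (i in seq_along(seqs)) {
    letters <- unique(strsplit(as.character(seqs[[i]]), "")[[1]])
    bad <- setdiff(letters, c("A", "C", "G", "T", "N"))
    if (length(bad))
      stop_zftf("sequence '%s' contains invalid character(s): %s",
                names(seqs)[i], paste(bad, collapse = ","))
  }
  w <- nchar(sites[1])
  scan_one_strand <- function(patterns, strand) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(patterns))
    res <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
      if (Biostrings::nchar(seqs[[i]]) < w) { res[[i]] <- empty; next }
      m <- Biostrings::matchPDict(pd, seqs[[i]])
      st <- Biostrings::startIndex(m)
      n_per <- vapply(st, function(v) if (is.null(v)) 0L else length(v), 0L)
      if (sum(n_per) == 0L) { res[[i]] <- empty; next }
      starts <- unlist(st[n_per > 0L], use.names = FALSE)
      res[[i]] <- data.frame(
        sequence_id = names(seqs)[i],
        start = starts - 1L,              # 0-based half-open
        end = starts - 1L + w,
        strand = strand,
        # indexing the original sites keeps minus hits in site orientation
        # (the reverse complement of the forward-strand subsequence)
        matched_site = rep(sites[n_per > 0L], n_per[n_per > 0L]),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, res)
  }
  hits <- scan_one_strand(sites, "+")
  if (both_strands) {
    minus <- scan_one_strand(dna_revcomp(sites), "-")
    if (nrow(minus)) hits <- rbind(hits, minus)
  }
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  hits <- hits[order(hits$sequence_id, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write site hits as a BED6 file
#'
#' Coordinates are 0-based half-open, as produced by [scan_sequence()].
#'
#' @param hits Data frame from [scan_sequence()].
#' @param path Output file path.
#' @export
write_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$sequence_id, chromStart = hits$start,
                    chromEnd = hits$end, name = hits$matched_site,
                    score = 0L, strand = hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
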