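#' Load a zinc-finger catalog from a TSV file
#'
#' The catalog is a three-column tab-separated table: `name` (unique finger
#' identifier), `subsites` (one or more 3-bp IUPAC triplets, comma-separated
#' when a finger recognises alternative subsites), and `aa_sequence` (the
#' finger's amino-acid sequence).  The packaged default catalog contains the
#' 25 fingers used to assemble the combinatorial four-finger ZF-TF library.
#'
#' @param path Path to the catalog TSV.  Defaults to the packaged 25-finger
#'   catalog.
#' @return A `zf_catalog`: a data frame with columns `name`,
#'   `subsites` (list column of character triplets) and `aa_sequence`.
#' @examples
#' cat25 <- load_catalog()
#' nrow(cat25)  # 25
#' @export
load_catalog <- function(path = system.file("extdata", "zf_catalog.tsv",
                                            package = "zftfscreen")) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("name", "subsites", "aa_sequence")
  if (!all(need %in% names(raw)))
    stop_zftf("catalog TSV must have columns %s", paste(need, collapse = ", "))
  subsites <- lapply(strsplit(raw$subsites, ","), function(x) toupper(trimws(x)))
  for (i in seq_len(nrow(raw))) {
    validate_finger(raw$name[i], subsites[[i]], raw$aa_sequence[i], row = i)
  }
  dup <- raw$name[duplicated(raw$name)]
  if (length(dup))
    stop_zftf("duplicate finger name(s) in catalog: %s",
              paste(unique(dup), collapse = ", "))
  out <- data.frame(name = raw$name, aa_sequence = raw$aa_sequence,
                    stringsAsFactors = FALSE)
  out$subsites <- subsites
  out <- out[, c("name", "subsites", "aa_sequence")]
  class(out) <- c("zf_catalog", "data.frame")
  out
}

validate_finger <- function(name, subsites, aa_sequence, row = NA) {
  where <- if (is.na(row)) sprintf("finger '%s'", name)
           else sprintf("catalog row %d ('%s')", row, name)
  if (!nzchar(name)) stop_zftf("%s: empty name", where)
  if (length(subsites) < 1L) stop_zftf("%s: no subsites", where)
  for (s in subsites) {
    if (nchar(s) != 3L)
      stop_zftf("%s: subsite '%s' is not a 3-bp triplet", where, s)
    bad <- setdiff(strsplit(s, "")[[1]], names(IUPAC_MAP))
    if (length(bad))
      stop_zftf("%s: subsite '%s' contains non-IUPAC code(s) %s",
                where, s, paste(bad, collapse = ","))
  }
  if (!nzchar(aa_sequence)) stop_zftf("%s: empty amino-acid sequence", where)
  badaa <- setdiff(strsplit(toupper(aa_sequence), "")[[1]], AA_LETTERS)
  if (length(badaa))
    stop_zftf("%s: amino-acid sequence contains invalid letter(s) %s",
              where, paste(badaa, collapse = ","))
  invisible(TRUE)
}

#' @export
print.zf_catalog <- function(x, ...) {
  cat(sprintf("Zinc-finger catalog: %d fingers\n", nrow(x)))
  show <- data.frame(name = x$name,
                     subsites = vapply(x$subsites, paste, "", collapse = ","),
                     aa_sequence = x$aa_sequence)
  print(utils::head(show, 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Assemble a finger array (an ordered multi-finger protein) from a catalog
#'
#' Position `i` of `fingers` is finger F`i` of the protein, counted from the
#' protein's first (N-terminal) finger.
#'
#' @param catalog A `zf_catalog`.
#' @param fingers Character vector of finger names, in order F1..FL.
#' @param clone_id Optional identifier for the array.
#' @return A `zf_finger_array` with resolved subsites.
#' @export
finger_array <- function(catalog, fingers, clone_id = NULL) {
  stopifnot(inherits(catalog, "zf_catalog"))
  if (length(fingers) < 1L) stop_zftf("a finger array needs at least 1 finger")
  idx <- match(fingers, catalog$name)
  if (anyNA(idx))
    stop_zftf("finger(s) not in catalog: %s",
              paste(fingers[is.na(idx)], collapse = ", "))
  structure(
    list(clone_id = clone_id %||% paste(fingers, collapse = "-"),
         fingers = fingers,
         subsites = catalog$subsites[idx]),
    class = "zf_finger_array")
}

#' @export
print.zf_finger_array <- function(x, ...) {
  cat(sprintf("ZF-TF array '%s': %s\n", x$clone_id,
              paste(x$fingers, collapse = " - ")))
  invisible(x)
}

#' Enumerate the combinatorial ZF-TF library over a catalog
#'
#' A library of arrays of `length` fingers drawn (with repetition across
#' positions) from the catalog has `nrow(catalog)^length` members.  The size
#' is returned without materialising arrays; `$next_array()` iterates over the
#' members one at a time in lexicographic catalog order (position 1 varying
#' slowest), so even the full 25^4 = 390,625-member four-finger library can be
#' streamed in constant memory.
#'
#' @param catalog A `zf_catalog`.
#' @param length Number of finger positions per array (default 4).
#' @return A `zf_library` list with elements `size` (numeric), `length`,
#'   `catalog`, `next_array()` (returns the next `zf_finger_array` or `NULL`
#'   when exhausted) and `reset()`.
#' @examples
#' lib <- enumerate_library(load_catalog(), 4)
#' lib$size  # 390625
#' @export
enumerate_library <- function(catalog, length = 4L) {
  stopifnot(inherits(catalog, "zf_catalog"))
  if (nrow(catalog) < 1L) stop_zftf("catalog is empty")
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop_zftf("array length must be >= 1")
  n <- nrow(catalog)
  size <- n^length
  state <- new.env(parent = emptyenv())
  state$counter <- 0
  next_array <- function() {
    if (state$counter >= size) return(NULL)
    i <- state$counter
    state$counter <- i + 1
    # mixed-radix digits, position 1 most significant
    digits <- integer(length)
    for (p in length:1) {
      digits[p] <- i %% n
      i <- i %/% n
    }
    finger_array(catalog, catalog$name[digits + 1L],
                 clone_id = sprintf("lib_%d", state$counter))
  }
  structure(list(size = size, length = length, catalog = catalog,
                 next_array = next_array,
                 reset = function() { state$counter <- 0; invisible(NULL) }),
            class = "zf_library")
}

#' @export
print.zf_library <- function(x, ...) {
  cat(sprintf("Combinatorial ZF-TF library: %d fingers ^ %d positions = %s arrays\n",
              nrow(x$catalog), x$length, format(x$size, big.mark = ",")))
  invisible(x)
}

#' Materialise (part of) an enumerated library
#'
#' @param library A `zf_library`.
#' @param n Maximum number of arrays to collect (default: all; be careful with
#'   large libraries).
#' @return List of `zf_finger_array`.
#' @export
collect_arrays <- function(library, n = library$size) {
  stopifnot(inherits(library, "zf_library"))
  library$reset()
  out <- vector("list", min(n, library$size))
  for (i in seq_along(out)) out[[i]] <- library$next_array()
  library$reset()
  out
}

#' Collapse duplicated finger arrays
#'
#' Arrays identical in their ordered finger composition are collapsed to one
#' representative (the first seen), with a multiplicity count -- the in-silico
#' analogue of deduplicating clones rescued from a selection screen.
#'
#' @param arrays List of `zf_finger_array`.
#' @return A list with `unique` (list of representative arrays, first-seen
#'   order) and `counts` (integer multiplicities, named by composition).
#' @export
deduplicate_arrays <- function(arrays) {
  stopifnot(is.list(arrays))
  keys <- vapply(arrays, function(a) paste(a$fingers, collapse = "|"), "")
  first <- !duplicated(keys)
  counts <- table(factor(keys, levels = keys[first]))
  list(unique = arrays[first],
       counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Load the six fulvestrant-resistance ZF-TF arrays
#'
#' Reads the packaged table of the six four-finger arrays recovered from the
#' resistance screen (clones 7, 19, 64, 70, 83 and 115) and resolves them
#' against a catalog.
#'
#' @param catalog A `zf_catalog` (default: packaged 25-finger catalog).
#' @param path Path to the clone table TSV.
#' @return Named list of `zf_finger_array`.
#' @export
load_resistance_clones <- function(catalog = load_catalog(),
                                   path = system.file("extdata",
                                                      "resistance_clones.tsv",
                                                      package = "zftfscreen")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  out <- lapply(seq_len(nrow(tab)), function(i) {
    finger_array(catalog,
                 unlist(tab[i, c("finger1", "finger2", "finger3", "finger4")],
                        use.names = FALSE),
                 clone_id = tab$clone_id[i])
  })
  names(out) <- tab$clone_id
  out
}
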