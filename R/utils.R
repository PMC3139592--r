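#' @keywords internal
"_PACKAGE"

# IUPAC nucleotide degeneracy map (standard); used for subsite validation and
# expansion of degenerate binding sites.
IUPAC_MAP <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_zftf <- function(...) stop(sprintf(...), call. = FALSE)

#' Derive independent sub-seeds from one master seed
#'
#' A single user-facing seed is fanned out into named per-component seeds so
#' that adding a downstream random stage never perturbs the draws of an
#' earlier one.  All derived seeds stay below 2^31.
#'
#' @param seed Integer master seed.
#' @param names Character vector of component names.
#' @return Named integer vector of sub-seeds.
#' @export
fanout_seeds <- function(seed, names) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(names))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  out <- sample.int(.Machine$integer.max - 1L, length(names))
  names(out) <- names
  out
}

# run expr under a local RNG stream seeded with `seed`, restoring global state
with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# population (divide-by-n) standard deviation
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}
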