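#' Per-sample metagene score of a gene signature
#'
#' The metagene is the unweighted mean expression of the signature genes
#' present in the matrix (e.g. the 72-gene common down-regulated resistance
#' signature), computed per sample.
#'
#' @param mat Numeric matrix, genes in rows, samples in columns.
#' @param signature Character vector of signature gene ids.
#' @return Named numeric vector of metagene values with attributes
#'   `genes_used` (count) and `genes_missing`.
#' @export
compute_metagene <- function(mat, signature) {
  signature <- unique(signature)
  if (!length(signature)) stop_zftf("empty signature")
  present <- intersect(signature, rownames(mat))
  if (!length(present))
    stop_zftf("none of the %d signature genes are in the matrix",
              length(signature))
  missing <- setdiff(signature, present)
  if (length(missing))
    message(sprintf("metagene: %d/%d signature genes missing from matrix",
                    length(missing), length(signature)))
  out <- colMeans(mat[present, , drop = FALSE])
  attr(out, "genes_used") <- length(present)
  attr(out, "genes_missing") <- missing
  out
}

#' Median-split stratification of metagene values
#'
#' Samples strictly below the median metagene are labelled
#' `"fulvestrant-resistant"` (the signature genes are down-regulated in the
#' resistant state, so a low metagene marks resistance); samples at or above
#' the median are `"fulvestrant-sensitive"`.  The median is the standard
#' mid-point convention for even n.
#'
#' @param metagene Named numeric vector of metagene values (>= 2 samples).
#' @return Named character vector of stratum labels.
#' @export
stratify_by_median <- function(metagene) {
  if (length(metagene) < 2L) stop_zftf("need at least 2 samples to stratify")
  if (length(unique(metagene)) == 1L)
    stop_zftf("all metagene values identical; no median split possible")
  med <- stats::median(metagene)
  out <- ifelse(metagene < med, "fulvestrant-resistant", "fulvestrant-sensitive")
  names(out) <- names(metagene)
  out
}

#' Kaplan-Meier product-limit survival curve
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return A `km_curve` data frame: `time` (distinct event/censoring times),
#'   `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) stop_zftf("negative follow-up time")
  if (!all(event %in% c(0, 1))) stop_zftf("event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km A `km_curve`.
#' @param t Times at which to evaluate the step function.
#' @return Survival probabilities (1 before the first event).
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(tt) {
    idx <- which(km$time <= tt)
    if (!length(idx)) 1 else km$surv[max(idx)]
  }, 0)
}

#' One-sided two-group log-rank test
#'
#' Standard log-rank observed-minus-expected statistic with the hypergeometric
#' variance (ties handled by the multi-event variance term).  The one-sided
#' p-value is the upper normal tail of `z = (O_w - E_w) / sqrt(V)` where `w`
#' is the group hypothesised to fare worse, so p < 0.5 exactly when the
#' observed direction matches the hypothesis.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param group Two-level grouping vector.
#' @param worse The level hypothesised to have worse survival.
#' @return A `logrank_result` list: `z`, `chisq`, `p_one_sided`,
#'   `p_two_sided`, `worse`, `observed`, `expected` (per group), `n`.
#' @export
logrank_one_sided <- function(time, event, group, worse) {
  group <- as.character(group)
  levels <- unique(group)
  if (length(levels) != 2L) stop_zftf("log-rank needs exactly 2 groups")
  if (!worse %in% levels)
    stop_zftf("hypothesised-worse group '%s' not among groups (%s)", worse,
              paste(levels, collapse = ", "))
  if (sum(event) == 0) stop_zftf("no events observed")
  if (any(table(group) == 0L)) stop_zftf("empty group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  gnames <- sub("^group=", "", names(sd$n))
  iw <- match(worse, gnames)
  O <- sd$obs; E <- sd$exp
  V <- sd$var[iw, iw]
  z <- (O[iw] - E[iw]) / sqrt(V)
  structure(list(z = unname(z), chisq = unname(z^2),
                 p_one_sided = stats::pnorm(z, lower.tail = FALSE),
                 p_two_sided = stats::pchisq(z^2, df = 1, lower.tail = FALSE),
                 worse = worse,
                 observed = stats::setNames(as.vector(O), gnames),
                 expected = stats::setNames(as.vector(E), gnames),
                 n = stats::setNames(as.vector(sd$n), gnames)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("One-sided log-rank ('%s' hypothesised worse)\n", x$worse))
  cat(sprintf("  z = %.4f, one-sided p = %.4g, two-sided p = %.4g\n",
              x$z, x$p_one_sided, x$p_two_sided))
  tab <- data.frame(n = x$n, observed = x$observed, expected = x$expected)
  print(tab)
  invisible(x)
}

pick_endpoint <- function(clinical, endpoint = c("auto", "dmfs", "drfs", "generic")) {
  endpoint <- match.arg(endpoint)
  has <- function(p) all(paste0(p, c("_time", "_event")) %in% names(clinical))
  chosen <- switch(endpoint,
    auto = if (has("dmfs")) "dmfs" else if (has("drfs")) "drfs" else "generic",
    dmfs = { if (!has("dmfs")) stop_zftf("dmfs columns not present"); "dmfs" },
    drfs = { if (!has("drfs")) stop_zftf("drfs columns not present"); "drfs" },
    generic = "generic")
  if (chosen == "generic") {
    if (!all(c("time", "event") %in% names(clinical)))
      stop_zftf("clinical table needs time/event columns")
    list(endpoint = "generic", time = clinical$time, event = clinical$event)
  } else {
    list(endpoint = chosen,
         time = clinical[[paste0(chosen, "_time")]],
         event = clinical[[paste0(chosen, "_event")]])
  }
}

#' Metagene survival stratification end-to-end
#'
#' Computes the signature metagene per patient, splits the cohort at the
#' median (below-median = "fulvestrant-resistant"), estimates a Kaplan-Meier
#' curve per stratum, and tests the pre-specified hypothesis that the
#' resistant-metagene stratum fares worse with a one-sided log-rank test.
#' When the clinical table carries both a distant-metastasis-free and a
#' death-from-relapse-free endpoint, the distant-metastasis-free one is
#' preferred (`endpoint = "auto"`).
#'
#' @param mat Expression matrix, genes in rows, patients in columns.
#' @param clinical Data frame with `sample_id` plus either `time`/`event` or
#'   `dmfs_time`/`dmfs_event` and/or `drfs_time`/`drfs_event`.
#' @param signature Character vector of signature gene ids.
#' @param endpoint `"auto"` (default), `"dmfs"`, `"drfs"` or `"generic"`.
#' @return A `prognosis_result`: `strata` (per-patient table), `km` (list of
#'   `km_curve` per stratum), `logrank` (`logrank_result`), `endpoint`,
#'   `n_dropped` (unmatched samples).
#' @export
run_prognosis <- function(mat, clinical, signature, endpoint = "auto") {
  common <- intersect(colnames(mat), clinical$sample_id)
  n_dropped <- (ncol(mat) - length(common)) +
               (nrow(clinical) - length(common))
  if (length(common) < 2L)
    stop_zftf("fewer than 2 samples shared between expression and clinical data")
  if (n_dropped > 0)
    message(sprintf("prognosis: dropped %d unmatched sample(s)", n_dropped))
  mat <- mat[, common, drop = FALSE]
  clinical <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  ep <- pick_endpoint(clinical, endpoint)
  metagene <- compute_metagene(mat, signature)
  stratum <- stratify_by_median(metagene)
  strata <- data.frame(sample_id = common, metagene = unname(metagene),
                       stratum = unname(stratum), time = ep$time,
                       event = ep$event, stringsAsFactors = FALSE)
  km <- lapply(split(strata, strata$stratum),
               function(d) km_estimate(d$time, d$event))
  lr <- logrank_one_sided(strata$time, strata$event, strata$stratum,
                          worse = "fulvestrant-resistant")
  structure(list(strata = strata, km = km, logrank = lr,
                 endpoint = ep$endpoint, n_dropped = n_dropped,
                 genes_used = attr(metagene, "genes_used")),
            class = "prognosis_result")
}

#' @export
print.prognosis_result <- function(x, ...) {
  cat(sprintf("Prognosis (endpoint: %s, %d signature genes)\n",
              x$endpoint, x$genes_used))
  print(table(x$strata$stratum))
  print(x$logrank)
  invisible(x)
}
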