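# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive each quantity from first principles and stay
# independent of the package code paths they check.

# naive O(n^3) UPGMA: inter-cluster distance re-averaged over all cross pairs
# of the ORIGINAL distance matrix at every step; returns sorted merge heights
oracle_upgma_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best) { best <- dij; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  sort(heights)
}

# exact hypergeometric upper tail P(X >= k) as a finite sum of binomial
# coefficients (exact in double precision for N <= 25)
oracle_hyper_tail <- function(N, S, n, k) {
  js <- k:min(S, n)
  sum(choose(S, js) * choose(N - S, n - js)) / choose(N, n)
}

# brute-force enumeration of every possible n-subset of the universe
oracle_hyper_enum <- function(N, S, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= S) >= k)
}

# hand product-limit estimator over distinct event times
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts)); s <- 1
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

# hand two-group log-rank O/E/V table (ties via multi-event hypergeometric
# variance); returns z for group A = first level of `group`
oracle_logrank_z <- function(time, event, group, a_level) {
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n_a <- sum(at_risk & group == a_level)
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & group == a_level)
    O <- O + d_a
    E <- E + d * n_a / n_tot
    if (n_tot > 1)
      V <- V + d * (n_a / n_tot) * (1 - n_a / n_tot) * (n_tot - d) / (n_tot - 1)
  }
  (O - E) / sqrt(V)
}

# naive per-position sliding-window scan for exact site occurrences
oracle_scan <- function(seq, sites, both_strands = TRUE) {
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  w <- nchar(sites[1])
  hits <- data.frame(start = integer(), strand = character(),
                     site = character())
  for (p in seq_len(nchar(seq) - w + 1)) {
    sub <- substr(seq, p, p + w - 1)
    for (s in sites) {
      if (sub == s)
        hits <- rbind(hits, data.frame(start = p - 1L, strand = "+", site = s))
      if (both_strands && sub == revcomp(s))
        hits <- rbind(hits, data.frame(start = p - 1L, strand = "-", site = s))
    }
  }
  hits
}

# small helper: a clean experiment with a single planted module, no batch
# artefacts -- used by labelling and enrichment tests
tiny_module_experiment <- function(seed = 1, direction = "up",
                                   conditions = c("A", "B", "C"),
                                   target = "A", n_genes = 300,
                                   module_size = 40) {
  dirs <- stats::setNames(rep("none", length(conditions)), conditions)
  dirs[target] <- direction
  mods <- list(module_spec("sig", module_size, dirs))
  des <- experiment_design(n_genes, conditions, replicates = 4,
                           n_batches = 1, batch_effect_sd = 0)
  generate_expression_experiment(des, mods, seed = seed)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
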