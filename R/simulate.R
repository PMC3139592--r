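#' Specify a planted gene module
#'
#' A module is a block of genes that move together: per treatment condition
#' it is shifted up, down, or not at all relative to control, by
#' `effect_size` log2 units.
#'
#' @param module_id Identifier.
#' @param size Number of genes (>= 1).
#' @param directions Named character vector over treatment conditions with
#'   values in `"up"`, `"down"`, `"none"`; at least one non-"none".
#' @param effect_size Mean log2 shift (default 1.5).
#' @return A `module_spec`.
#' @export
module_spec <- function(module_id, size, directions, effect_size = 1.5) {
  if (size < 1) stop_zftf("module size must be >= 1")
  if (!all(directions %in% c("up", "down", "none")))
    stop_zftf("directions must be 'up', 'down' or 'none'")
  if (all(directions == "none"))
    stop_zftf("module '%s' has no non-'none' direction", module_id)
  if (is.null(names(directions)))
    stop_zftf("directions must be named by condition")
  structure(list(module_id = module_id, size = as.integer(size),
                 directions = directions, effect_size = effect_size),
            class = "module_spec")
}

#' Describe a synthetic expression experiment
#'
#' @param n_genes Total gene count.
#' @param conditions Character vector of treatment condition labels.
#' @param control Control condition label (default "control").
#' @param replicates Replicate infections per condition (default 2).
#' @param n_batches Number of profiling batches (default 4).  When
#'   `n_batches == 2 * replicates` each replicate's samples are split across
#'   its own pair of batches; otherwise samples are assigned round-robin.
#' @param noise_sd Multiplicative (log2-scale) noise standard deviation.
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baseline intensity
#'   distribution on the log2 scale.
#' @param batch_effect_sd Standard deviation of the additive per-(gene,
#'   batch) offset on the linear intensity scale.
#' @param min_intensity Lower floor keeping intensities strictly positive
#'   after additive batch offsets.
#' @return An `experiment_design`.
#' @export
experiment_design <- function(n_genes, conditions, control = "control",
                              replicates = 2L, n_batches = 4L,
                              noise_sd = 0.15, baseline_log2_mean = 7,
                              baseline_log2_sd = 1.2, batch_effect_sd = 2,
                              min_intensity = 0.0625) {
  if (n_genes < 1) stop_zftf("n_genes must be >= 1")
  if (control %in% conditions)
    stop_zftf("control label must not appear among treatment conditions")
  structure(list(n_genes = as.integer(n_genes), conditions = conditions,
                 control = control, replicates = as.integer(replicates),
                 n_batches = as.integer(n_batches), noise_sd = noise_sd,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 batch_effect_sd = batch_effect_sd,
                 min_intensity = min_intensity),
            class = "experiment_design")
}

#' The default six-condition resistance-screen emulation
#'
#' Control plus six ZF-TF conditions, two replicate infections profiled in
#' four batches, and five planted modules: one up-regulated in three of the
#' six conditions, three up-regulated each in a single condition, and one
#' 72-gene module down-regulated in all six (the common resistance
#' signature).  Module sizes are 230/225/135/123/72.  The matrix is
#' generated at the working dimension of the clustering analysis (2,500
#' genes, the size of the variance-filtered probe-set panel).
#'
#' @param effect_size Planted log2 effect (default 1.5).
#' @return List with `design` (`experiment_design`) and `modules`
#'   (list of `module_spec`).
#' @export
resistance_screen_preset <- function(effect_size = 1.5) {
  conds <- c("ZF7", "ZF19", "ZF64", "ZF70", "ZF83", "ZF115")
  dirs <- function(up = character(), down = character()) {
    d <- stats::setNames(rep("none", length(conds)), conds)
    d[up] <- "up"; d[down] <- "down"
    d
  }
  modules <- list(
    module_spec("m1", 230, dirs(up = c("ZF7", "ZF19", "ZF70")), effect_size),
    module_spec("m2", 225, dirs(up = "ZF64"), effect_size),
    module_spec("m3", 135, dirs(up = "ZF83"), effect_size),
    module_spec("m4", 123, dirs(up = "ZF115"), effect_size),
    module_spec("m5", 72, dirs(down = conds), effect_size))
  list(design = experiment_design(2500L, conds), modules = modules)
}

#' External-cohort analogue sharing the planted signature
#'
#' Emulates an independent dataset of pre-existing resistant clones plus
#' control: four resistant-clone conditions, the shared down-regulated
#' signature module planted in all four, and a subset of the up-regulated
#' modules planted in some clones.  Gene identifiers coincide with the
#' [resistance_screen_preset()] universe, so the reference clustering can be
#' projected directly.
#'
#' @param effect_size Planted log2 effect (default 1.5).
#' @return List with `design` and `modules`.
#' @export
external_mimic_preset <- function(effect_size = 1.5) {
  conds <- c("cloneA", "cloneB", "cloneC", "cloneD")
  dirs <- function(up = character(), down = character()) {
    d <- stats::setNames(rep("none", length(conds)), conds)
    d[up] <- "up"; d[down] <- "down"
    d
  }
  modules <- list(
    module_spec("m1", 230, dirs(up = c("cloneA", "cloneB", "cloneC")), effect_size),
    module_spec("m3", 135, dirs(up = "cloneB"), effect_size),
    module_spec("m4", 123, dirs(up = "cloneC"), effect_size),
    module_spec("m5", 72, dirs(down = conds), effect_size))
  # same gene universe; m5 occupies the same rows as in the reference preset
  list(design = experiment_design(2500L, conds, n_batches = 1L,
                                  batch_effect_sd = 0),
       modules = modules)
}

# gene ids are deterministic blocks: modules occupy fixed rows of the
# universe keyed by module_id, so presets sharing module ids share genes.
module_gene_map <- function(n_genes, modules) {
  all_ids <- sprintf("g%05d", seq_len(n_genes))
  # blocks reserved in the order of the full preset so subsets stay aligned
  reserved <- list(m1 = 1:230, m2 = 231:455, m3 = 456:590, m4 = 591:713,
                   m5 = 714:785)
  mids <- vapply(modules, `[[`, "", "module_id")
  sizes <- vapply(modules, function(m) m$size, 0L)
  use_reserved <- all(mids %in% names(reserved)) &&
    n_genes >= max(unlist(reserved)) &&
    all(sizes == lengths(reserved[mids]))
  assign <- stats::setNames(rep(NA_character_, n_genes), all_ids)
  offset <- 0L
  for (m in modules) {
    idx <- if (use_reserved) reserved[[m$module_id]]
           else { i <- (offset + 1L):(offset + m$size); offset <- offset + m$size; i }
    if (max(idx) > n_genes) stop_zftf("module genes exceed n_genes")
    assign[idx] <- m$module_id
  }
  list(gene_ids = all_ids, module_of = assign)
}

#' Generate a synthetic expression experiment with planted modules
#'
#' Intensities are built on the log2 scale as baseline + planted condition
#' effect + Gaussian noise, exponentiated to the linear scale (log-normal
#' multiplicative noise), after which a constant per-(gene, batch) offset is
#' added on the linear scale (the additive batch artefact the mean-shift
#' correction removes exactly).  The same master seed always produces the
#' identical experiment; the seed is fanned out into independent substreams
#' per component.
#'
#' @param design An `experiment_design`.
#' @param modules List of `module_spec`.
#' @param seed Integer master seed.
#' @return List with `experiment` (`expression_experiment`) and `truth`
#'   (gene -> module assignment, module list, design, seed).
#' @export
generate_expression_experiment <- function(design, modules, seed = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  total <- sum(vapply(modules, function(m) m$size, 0L))
  if (total > design$n_genes)
    stop_zftf("module sizes (%d) exceed n_genes (%d)", total, design$n_genes)
  map <- module_gene_map(design$n_genes, modules)
  gene_ids <- map$gene_ids
  conds_all <- c(design$control, design$conditions)
  sheet <- expand.grid(condition = conds_all,
                       replicate = seq_len(design$replicates),
                       stringsAsFactors = FALSE)
  sheet <- sheet[order(sheet$replicate, match(sheet$condition, conds_all)), ]
  sheet$sample_id <- sprintf("%s_r%d", sheet$condition, sheet$replicate)
  nb <- design$n_batches
  if (nb == 2L * design$replicates) {
    per_rep <- 2L
    ci <- match(sheet$condition, conds_all)
    sheet$batch <- sprintf("b%d", (sheet$replicate - 1L) * per_rep +
                                  ((ci - 1L) %% per_rep) + 1L)
  } else {
    sheet$batch <- sprintf("b%d", ((seq_len(nrow(sheet)) - 1L) %% nb) + 1L)
  }
  sheet <- sheet[, c("sample_id", "condition", "replicate", "batch")]
  rownames(sheet) <- NULL
  n_s <- nrow(sheet)

  seeds <- fanout_seeds(seed, c("baseline", "noise", "batch"))
  baseline <- with_seed(seeds["baseline"],
                        stats::rnorm(design$n_genes, design$baseline_log2_mean,
                                     design$baseline_log2_sd))
  effect <- matrix(0, design$n_genes, n_s,
                   dimnames = list(gene_ids, sheet$sample_id))
  for (m in modules) {
    rows <- which(map$module_of == m$module_id)
    for (cond in names(m$directions)) {
      dirn <- m$directions[[cond]]
      if (dirn == "none") next
      cols <- which(sheet$condition == cond)
      effect[rows, cols] <- effect[rows, cols] +
        (if (dirn == "up") m$effect_size else -m$effect_size)
    }
  }
  noise <- with_seed(seeds["noise"],
                     matrix(stats::rnorm(design$n_genes * n_s, 0,
                                         design$noise_sd),
                            design$n_genes, n_s))
  lin <- 2^(baseline + effect + noise)
  if (design$batch_effect_sd > 0) {
    batches <- unique(sheet$batch)
    delta <- with_seed(seeds["batch"],
                       matrix(stats::rnorm(design$n_genes * length(batches), 0,
                                           design$batch_effect_sd),
                              design$n_genes, length(batches),
                              dimnames = list(NULL, batches)))
    lin <- lin + delta[, sheet$batch, drop = FALSE]
    lin <- pmax(lin, design$min_intensity)
  }
  dimnames(lin) <- list(gene_ids, sheet$sample_id)
  truth <- list(module_of = map$module_of, modules = modules,
                design = design, seed = seed,
                module_genes = lapply(stats::setNames(modules,
                    vapply(modules, `[[`, "", "module_id")),
                  function(m) gene_ids[which(map$module_of == m$module_id)]))
  list(experiment = expression_experiment(lin, sheet), truth = truth)
}

#' Generate a gene-set database with known enrichments
#'
#' For each planted module one "true" set is built that draws
#' `overlap_fraction` of its members from the module (the remainder from the
#' rest of the universe); decoy sets are drawn uniformly from the universe.
#'
#' @param truth Ground truth from [generate_expression_experiment()].
#' @param n_decoy_sets Number of decoy sets (default 50).
#' @param set_size_range Decoy set size range (default c(20, 200)).
#' @param overlap_fraction Fraction of each true set drawn from its module
#'   (default 0.8).
#' @param seed Integer seed.
#' @return A `gene_set_db`; true sets are named `true_<module_id>`.
#' @export
generate_gene_set_db <- function(truth, n_decoy_sets = 50,
                                 set_size_range = c(20, 200),
                                 overlap_fraction = 0.8, seed = 1L) {
  universe <- names(truth$module_of)
  if (max(set_size_range) > length(universe))
    stop_zftf("set sizes exceed universe size")
  seeds <- fanout_seeds(seed, c("true", "decoy"))
  sets <- list(); desc <- character()
  with_seed(seeds["true"], {
    for (mid in names(truth$module_genes)) {
      mod <- truth$module_genes[[mid]]
      n_in <- round(overlap_fraction * length(mod))
      inside <- sample(mod, n_in)
      outside <- sample(setdiff(universe, mod), length(mod) - n_in)
      sets[[paste0("true_", mid)]] <- c(inside, outside)
      desc <- c(desc, sprintf("planted: %d/%d genes from module %s",
                              n_in, length(mod), mid))
    }
  })
  with_seed(seeds["decoy"], {
    sizes <- seq(set_size_range[1], set_size_range[2])
    for (i in seq_len(n_decoy_sets)) {
      sz <- sizes[sample.int(length(sizes), 1)]
      sets[[sprintf("decoy_%03d", i)]] <- sample(universe, sz)
      desc <- c(desc, "decoy: uniform draw from universe")
    }
  })
  gene_set_db(sets, desc, provenance = sprintf("synthetic (seed %d)", seed))
}

#' Generate a survival cohort whose hazard tracks a signature metagene
#'
#' Signature-gene expression is drawn either bimodally (two latent patient
#' groups separated by `separation` units on the signature genes) or
#' continuously (a latent per-patient factor loading on every signature
#' gene).  Event times are exponential; patients in the low-metagene half
#' have their hazard multiplied by `hazard_ratio`.  Censoring times are
#' uniform on (0, c), with c calibrated so the expected censoring fraction
#' equals `censoring_rate`.
#'
#' @param n_patients Cohort size.
#' @param signature_genes Character vector of signature gene ids.
#' @param hazard_ratio Hazard multiplier for the low-metagene group (> 0).
#' @param censoring_rate Expected fraction censored (default 0.3).
#' @param seed Integer seed.
#' @param distribution `"bimodal"` (default) or `"continuous"` metagene.
#' @param n_noise_genes Extra unrelated genes added to the matrix.
#' @param base_hazard Baseline exponential event rate (default 0.1 per time
#'   unit).
#' @param separation Group separation for the bimodal metagene (default 2).
#' @return List with `matrix` (genes x patients), `clinical` (sample_id,
#'   time, event), `truth` (latent group and true stratum per patient).
#' @export
generate_survival_cohort <- function(n_patients, signature_genes,
                                     hazard_ratio, censoring_rate = 0.3,
                                     seed = 1L,
                                     distribution = c("bimodal", "continuous"),
                                     n_noise_genes = 0, base_hazard = 0.1,
                                     separation = 2) {
  if (hazard_ratio <= 0) stop_zftf("hazard_ratio must be > 0")
  distribution <- match.arg(distribution)
  signature_genes <- unique(signature_genes)
  ids <- sprintf("pt%04d", seq_len(n_patients))
  seeds <- fanout_seeds(seed, c("expr", "event", "censor"))
  ng <- length(signature_genes)
  expr <- with_seed(seeds["expr"], {
    if (distribution == "bimodal") {
      grp <- sample(c(0L, 1L), n_patients, replace = TRUE)  # 1 = low metagene
      mu <- ifelse(grp == 1L, -separation / 2, separation / 2)
      x <- matrix(stats::rnorm(ng * n_patients, rep(mu, each = ng), 1),
                  ng, n_patients)
    } else {
      u <- stats::rnorm(n_patients)
      grp <- as.integer(u < 0)
      x <- matrix(rep(u, each = ng) + stats::rnorm(ng * n_patients), ng,
                  n_patients)
    }
    noise <- if (n_noise_genes > 0)
      matrix(stats::rnorm(n_noise_genes * n_patients), n_noise_genes,
             n_patients)
    else NULL
    list(x = x, grp = grp, noise = noise)
  })
  mat <- rbind(expr$x, expr$noise)
  rownames(mat) <- c(signature_genes,
                     if (n_noise_genes > 0) sprintf("noise%05d", seq_len(n_noise_genes)))
  colnames(mat) <- ids
  rate <- base_hazard * hazard_ratio^expr$grp
  t_event <- with_seed(seeds["event"], stats::rexp(n_patients, rate))
  if (censoring_rate <= 0) {
    time <- t_event; event <- rep(1L, n_patients)
  } else {
    # expected censor fraction for C ~ U(0, c), T ~ Exp(lambda):
    # P(C < T) = (1 - exp(-lambda c)) / (lambda c); average over groups
    p0 <- mean(expr$grp == 0L)
    cens_frac <- function(cc) {
      f <- function(l) (1 - exp(-l * cc)) / (l * cc)
      p0 * f(base_hazard) + (1 - p0) * f(base_hazard * hazard_ratio)
    }
    cmax <- stats::uniroot(function(cc) cens_frac(cc) - censoring_rate,
                           lower = 1e-8, upper = 1e8, tol = 1e-10)$root
    cens <- with_seed(seeds["censor"], stats::runif(n_patients, 0, cmax))
    event <- as.integer(t_event <= cens)
    time <- pmin(t_event, cens)
  }
  clinical <- data.frame(sample_id = ids, time = time, event = event,
                         stringsAsFactors = FALSE)
  truth <- list(group = stats::setNames(expr$grp, ids),
                true_stratum = stats::setNames(
                  ifelse(expr$grp == 1L, "fulvestrant-resistant",
                         "fulvestrant-sensitive"), ids),
                hazard_ratio = hazard_ratio, seed = seed)
  list(matrix = mat, clinical = clinical, truth = truth)
}

#' Write all synthetic inputs of a simulated study to a directory
#'
#' Produces the full file bundle a pipeline run needs: expression matrix
#' TSV, sample sheet TSV, gene-set GMT, clinical TSV, and a ground-truth
#' JSON.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed.
#' @param preset Preset list (default [resistance_screen_preset()]).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulated_study <- function(dir, seed = 1L, preset = resistance_screen_preset()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- fanout_seeds(seed, c("expr", "gmt", "surv"))
  sim <- generate_expression_experiment(preset$design, preset$modules,
                                        seed = seeds["expr"])
  db <- generate_gene_set_db(sim$truth, seed = seeds["gmt"])
  cohort <- generate_survival_cohort(300, sim$truth$module_genes$m5,
                                     hazard_ratio = 3, seed = seeds["surv"])
  paths <- c(matrix = file.path(dir, "expression.tsv"),
             samples = file.path(dir, "samples.tsv"),
             gmt = file.path(dir, "gene_sets.gmt"),
             clinical = file.path(dir, "clinical.tsv"),
             surv_matrix = file.path(dir, "cohort_expression.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  write_expression(sim$experiment, paths["matrix"], paths["samples"])
  write_gmt(db, paths["gmt"])
  utils::write.table(cohort$clinical, paths["clinical"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cm <- data.frame(gene_id = rownames(cohort$matrix), cohort$matrix,
                   check.names = FALSE)
  utils::write.table(cm, paths["surv_matrix"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed,
         module_genes = sim$truth$module_genes,
         survival_group = as.list(cohort$truth$group)),
    paths["truth"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
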