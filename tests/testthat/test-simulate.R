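test_that("generator is deterministic in the master seed", {
  preset <- resistance_screen_preset()
  a <- generate_expression_experiment(preset$design, preset$modules, seed = 40)
  b <- generate_expression_experiment(preset$design, preset$modules, seed = 40)
  c2 <- generate_expression_experiment(preset$design, preset$modules, seed = 41)
  expect_identical(a$experiment$matrix, b$experiment$matrix)
  expect_false(identical(a$experiment$matrix, c2$experiment$matrix))
  expect_true(all(a$experiment$matrix > 0))
})

test_that("zero noise and zero effects give constant genes", {
  des <- experiment_design(50, c("A", "B"), replicates = 2, n_batches = 1,
                           noise_sd = 0, batch_effect_sd = 0)
  mods <- list(module_spec("m", 10, c(A = "up", B = "none"), effect_size = 0))
  sim <- generate_expression_experiment(des, mods, seed = 42)
  expect_true(all(apply(sim$experiment$matrix, 1,
                        function(x) max(x) - min(x)) == 0))
})

test_that("resistance-screen preset encodes the published study structure", {
  preset <- resistance_screen_preset()
  sim <- generate_expression_experiment(preset$design, preset$modules, seed = 43)
  sheet <- sim$experiment$sample_sheet
  expect_equal(nrow(sheet), 14)                       # control + 6, 2 infections
  expect_equal(length(unique(sheet$condition)), 7)
  expect_equal(length(unique(sheet$batch)), 4)
  expect_equal(as.vector(table(sheet$condition)), rep(2L, 7))
  sizes <- vapply(preset$modules, function(m) m$size, 0L)
  expect_equal(sizes, c(230L, 225L, 135L, 123L, 72L))
  # exactly one module is down in every treatment condition
  all_down <- vapply(preset$modules,
                     function(m) all(m$directions == "down"), TRUE)
  expect_equal(sum(all_down), 1)
  expect_equal(preset$modules[[which(all_down)]]$size, 72L)
  # ground truth is consistent with the generated data
  expect_equal(length(sim$truth$module_genes$m5), 72)
  expect_true(all(unlist(sim$truth$module_genes) %in%
                  rownames(sim$experiment$matrix)))
})

test_that("planted effects are recovered at the stated size", {
  # mean(log2 treated) - mean(log2 control) ~ -effect_size for a down module
  diffs <- vapply(1:30, function(s) {
    des <- experiment_design(100, "A", replicates = 3, n_batches = 1,
                             batch_effect_sd = 0)
    mods <- list(module_spec("m", 20, c(A = "down")))
    sim <- generate_expression_experiment(des, mods, seed = 500 + s)
    lm <- log2(sim$experiment$matrix)
    sheet <- sim$experiment$sample_sheet
    genes <- sim$truth$module_genes$m
    mean(lm[genes, sheet$condition == "A"]) -
      mean(lm[genes, sheet$condition == "control"])
  }, 0)
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - (-1.5)), 3 * se + 1e-3)
})

test_that("gene-set generator plants true sets and unbiased decoys", {
  sim <- tiny_module_experiment(seed = 44, n_genes = 500, module_size = 60)
  # overlap_fraction 1 with set size = module size reproduces the module
  db1 <- generate_gene_set_db(sim$truth, n_decoy_sets = 0,
                              overlap_fraction = 1, seed = 45)
  expect_equal(length(db1$sets), 1)
  expect_setequal(db1$sets$true_sig, sim$truth$module_genes$sig)
  # decoy overlap with the module matches the hypergeometric mean
  db2 <- generate_gene_set_db(sim$truth, n_decoy_sets = 200,
                              set_size_range = c(50, 50), seed = 46)
  decoys <- db2$sets[grepl("^decoy", names(db2$sets))]
  ov <- vapply(decoys, function(s)
    length(intersect(s, sim$truth$module_genes$sig)), 0)
  expected <- 50 * 60 / 500
  expect_lt(abs(mean(ov) - expected), 4 * sd(ov) / sqrt(length(ov)))
  expect_error(generate_gene_set_db(sim$truth, set_size_range = c(10, 1e6)),
               "universe")
})

test_that("survival generator calibrates censoring and groups", {
  sig <- sprintf("s%02d", 1:10)
  no_cens <- generate_survival_cohort(100, sig, hazard_ratio = 2,
                                      censoring_rate = 0, seed = 47)
  expect_true(all(no_cens$clinical$event == 1))
  cens <- generate_survival_cohort(2000, sig, hazard_ratio = 1,
                                   censoring_rate = 0.4, seed = 48)
  frac <- mean(cens$clinical$event == 0)
  expect_lt(abs(frac - 0.4), 0.05)
  expect_error(generate_survival_cohort(10, sig, hazard_ratio = -1), "hazard")
  # bimodal metagene separates the latent groups
  coh <- generate_survival_cohort(200, sig, hazard_ratio = 3, seed = 49)
  mg <- compute_metagene(coh$matrix, sig)
  expect_gt(mean(mg[coh$truth$group == 0]), mean(mg[coh$truth$group == 1]))
})

test_that("expression TSV round trip preserves values and metadata", {
  sim <- tiny_module_experiment(seed = 50, n_genes = 80, module_size = 10)
  mf <- tempfile(fileext = ".tsv"); sf <- tempfile(fileext = ".tsv")
  write_expression(sim$experiment, mf, sf)
  back <- read_expression(mf, sf)
  expect_equal(back$matrix, sim$experiment$matrix, tolerance = 1e-12)
  expect_equal(back$sample_sheet$condition, sim$experiment$sample_sheet$condition)
  expect_equal(back$sample_sheet$batch, sim$experiment$sample_sheet$batch)
  # a second round trip is bit-identical (fixed printed precision)
  mf2 <- tempfile(fileext = ".tsv"); sf2 <- tempfile(fileext = ".tsv")
  write_expression(back, mf2, sf2)
  expect_identical(readLines(mf)[-1], readLines(mf2)[-1])
})

test_that("a full simulated study bundle is written and readable", {
  dir <- tempfile("study")
  paths <- write_simulated_study(dir, seed = 51)
  expect_true(all(file.exists(paths)))
  exp <- read_expression(paths["matrix"], paths["samples"])
  expect_equal(ncol(exp$matrix), 14)
  db <- read_gmt(paths["gmt"])
  expect_true(any(grepl("^true_", names(db$sets))))
  clin <- utils::read.delim(paths["clinical"])
  expect_true(all(c("sample_id", "time", "event") %in% names(clin)))
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(length(truth$module_genes$m5), 72)
})
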