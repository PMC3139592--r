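test_that("correlation distance follows the definition", {
  set.seed(4)
  x <- matrix(rnorm(5 * 10), 5, 10,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:10)))
  d <- correlation_distance_matrix(x)
  expect_equal(diag(d), rep(0, 5), ignore_attr = TRUE)
  expect_equal(d, t(d))
  # definitional oracle for one pair
  r12 <- sum((x[1, ] - mean(x[1, ])) * (x[2, ] - mean(x[2, ]))) /
    sqrt(sum((x[1, ] - mean(x[1, ]))^2) * sum((x[2, ] - mean(x[2, ]))^2))
  expect_equal(d[1, 2], 1 - r12, tolerance = 1e-12)
  # a row against its negation is at distance 2
  y <- rbind(a = x[1, ], b = -x[1, ])
  expect_equal(correlation_distance_matrix(y)["a", "b"], 2, tolerance = 1e-12)
  # constant rows are rejected
  xc <- rbind(x, const = rep(1, 10))
  expect_error(correlation_distance_matrix(xc), "const")
})

test_that("average linkage matches the naive re-averaging oracle (n <= 8)", {
  set.seed(5)
  for (n in c(4, 5, 6, 7, 8)) {
    x <- matrix(rnorm(n * 12), n, 12,
                dimnames = list(sprintf("g%d", 1:n), NULL))
    d <- correlation_distance_matrix(x)
    hc <- average_linkage_cluster(d)
    expect_equal(sort(hc$height), oracle_upgma_heights(d), tolerance = 1e-12)
    # no inversions along any root path
    expect_true(all(diff(hc$height) >= -1e-12))
  }
  # two points merge at their distance
  d2 <- matrix(c(0, .3, .3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(average_linkage_cluster(d2)$height, 0.3)
  # two tight pairs far apart merge pairwise first
  x <- rbind(p1 = c(0, 0.01), p2 = c(0.011, 0), q1 = c(5, 5.01), q2 = c(5.011, 5))
  hc <- stats::hclust(stats::dist(x), method = "average")
  expect_true(all(hc$merge[1, ] < 0) && all(hc$merge[2, ] < 0))
})

test_that("direction labelling recovers planted patterns", {
  # a single up-module in one of three conditions -> unique-up tag
  sim <- tiny_module_experiment(seed = 6, direction = "up", target = "B")
  pm <- preprocess_pipeline(sim$experiment, k = 300)
  hc <- average_linkage_cluster(correlation_distance_matrix(pm))
  res <- cut_and_label(hc, pm)
  up <- res$labels[res$labels$tag == "unique-up:B", ]
  expect_equal(nrow(up), 1)
  expect_gte(jaccard(cluster_genes(res, "unique-up:B"),
                     sim$truth$module_genes$sig), 0.75)

  # tau larger than any effect -> every labelled cluster is "none"
  res_hi <- cut_and_label(hc, pm, tau = 50)
  lab <- res_hi$labels[res_hi$labels$tag != "small", ]
  expect_true(all(lab$tag == "none"))

  # missing control errors
  expect_error(cut_and_label(hc, pm, control = "nope"), "control")
})

test_that("resistance-screen preset yields one common-down cluster at fixed seed", {
  preset <- resistance_screen_preset()
  sim <- generate_expression_experiment(preset$design, preset$modules, seed = 11)
  pm <- preprocess_pipeline(sim$experiment, k = 2500)
  hc <- average_linkage_cluster(correlation_distance_matrix(pm))
  res <- cut_and_label(hc, pm)
  expect_equal(sum(res$labels$tag == "common-down"), 1)
  cd <- cluster_genes(res, "common-down")
  expect_gte(jaccard(cd, sim$truth$module_genes$m5), 0.9)
  # up-modules are recovered with their planted conditions among the calls
  expect_true(any(grepl("^(unique|shared)-up.*ZF64", res$labels$tag) |
                  res$labels$call_ZF64 == "up"))
})

test_that("labelling is invariant to row and column permutation", {
  sim <- tiny_module_experiment(seed = 8)
  pm <- preprocess_pipeline(sim$experiment, k = 250)
  hc <- average_linkage_cluster(correlation_distance_matrix(pm))
  res <- cut_and_label(hc, pm)

  set.seed(9)
  pm2 <- pm
  rp <- sample(nrow(pm2$matrix)); cp <- sample(ncol(pm2$matrix))
  pm2$matrix <- pm2$matrix[rp, cp]
  pm2$sample_sheet <- pm2$sample_sheet[cp, ]
  hc2 <- average_linkage_cluster(correlation_distance_matrix(pm2))
  res2 <- cut_and_label(hc2, pm2)

  # same partition up to relabelling: compare membership co-assignment
  part_key <- function(r) {
    sets <- split(names(r$memberships), r$memberships)
    sort(vapply(sets, function(g) paste(sort(g), collapse = ","), ""))
  }
  expect_equal(part_key(res), part_key(res2), ignore_attr = TRUE)
  expect_setequal(cluster_genes(res, "unique-up:A"),
                  cluster_genes(res2, "unique-up:A"))
})

test_that("newick export is a valid tree with the right leaves", {
  set.seed(10)
  x <- matrix(rnorm(6 * 8), 6, 8, dimnames = list(letters[1:6], NULL))
  hc <- average_linkage_cluster(correlation_distance_matrix(x))
  f <- tempfile(fileext = ".nwk")
  write_newick(hc, f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, letters[1:6])
  # root-to-leaf path length equals the root merge height for every leaf
  depths <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
  expect_equal(unname(depths), rep(max(hc$height), 6), tolerance = 1e-8)
})

test_that("projection onto the reference itself agrees perfectly", {
  sim <- tiny_module_experiment(seed = 12)
  pm <- preprocess_pipeline(sim$experiment, k = 250)
  hc <- average_linkage_cluster(correlation_distance_matrix(pm))
  res <- cut_and_label(hc, pm)
  proj <- project_external(res, sim$experiment)
  ag <- proj$agreement$agreement[proj$agreement$tag == "unique-up:A"]
  expect_equal(ag, 1)
  expect_equal(rownames(proj$matrix), res$leaf_order)
})

test_that("projection finds shared regulation and is null on noise", {
  preset <- resistance_screen_preset()
  sim <- generate_expression_experiment(preset$design, preset$modules, seed = 13)
  pm <- preprocess_pipeline(sim$experiment, k = 2500)
  hc <- average_linkage_cluster(correlation_distance_matrix(pm))
  res <- cut_and_label(hc, pm)

  ext_preset <- external_mimic_preset()
  ext <- generate_expression_experiment(ext_preset$design, ext_preset$modules,
                                        seed = 14)
  proj <- project_external(res, ext$experiment)
  cd_ag <- proj$agreement$agreement[proj$agreement$tag == "common-down"]
  expect_gt(cd_ag, 0.9)

  # pure-noise external data: agreement hovers around 0.5
  noise_preset <- external_mimic_preset()
  ags <- vapply(1:15, function(s) {
    noise <- generate_expression_experiment(
      experiment_design(2500L, noise_preset$design$conditions,
                        n_batches = 1, batch_effect_sd = 0),
      list(module_spec("m1", 230,
                       c(cloneA = "up", cloneB = "none", cloneC = "none",
                         cloneD = "none"), effect_size = 0)),
      seed = 100 + s)
    p <- project_external(res, noise$experiment)
    mean(p$agreement$agreement, na.rm = TRUE)
  }, 0)
  expect_gt(mean(ags), 0.35)
  expect_lt(mean(ags), 0.65)

  # refusing projection when too few genes overlap
  small <- ext$experiment
  keep <- rownames(small$matrix)[1:500]
  small <- expression_experiment(small$matrix[keep, ], small$sample_sheet)
  expect_error(project_external(res, small), "present")
})
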