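test_that("metagene is the unweighted mean over available signature genes", {
  m <- rbind(g1 = c(1, 3), g2 = c(3, 1), g3 = c(10, 10))
  colnames(m) <- c("s1", "s2")
  expect_equal(unname(compute_metagene(m, "g1")), c(1, 3), ignore_attr = TRUE)
  expect_equal(unname(compute_metagene(m, c("g1", "g2"))), c(2, 2), ignore_attr = TRUE)
  set.seed(30)
  big <- matrix(rnorm(40 * 6), 40, 6,
                dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:6)))
  sig <- sample(rownames(big), 20)
  expect_equal(unname(compute_metagene(big, sig)),
               unname(colMeans(big[sig, ])), ignore_attr = TRUE)
  # missing genes are tolerated with a message; none present errors
  expect_message(mg <- compute_metagene(m, c("g1", "gX")), "missing")
  expect_equal(attr(mg, "genes_used"), 1)
  expect_error(compute_metagene(m, c("gX", "gY")), "none")
})

test_that("median split sends strictly-below-median samples to resistant", {
  v <- c(a = 1, b = 2, c = 3, d = 4)
  s <- stratify_by_median(v)
  expect_equal(unname(s[c("a", "b")]), rep("fulvestrant-resistant", 2))
  expect_equal(unname(s[c("c", "d")]), rep("fulvestrant-sensitive", 2))
  # odd n: the median sample itself is "sensitive" (not below the median)
  s3 <- stratify_by_median(c(a = 1, b = 2, c = 3))
  expect_equal(unname(s3), c("fulvestrant-resistant", "fulvestrant-sensitive",
                             "fulvestrant-sensitive"))
  expect_error(stratify_by_median(c(1, 1, 1)), "identical")
  # group sizes differ by at most the number of ties at the median
  set.seed(31)
  v286 <- round(rnorm(286), 1)
  st <- stratify_by_median(v286)
  ties <- sum(v286 == median(v286))
  expect_lte(abs(sum(st == "fulvestrant-resistant") -
                 sum(st == "fulvestrant-sensitive")), max(ties, 1))
  expect_equal(sum(st == "fulvestrant-resistant"), sum(v286 < median(v286)))
})

test_that("KM estimator matches the hand product-limit oracle", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km_surv_at(km, 2), 1 / 3)       # (2/3) * (1/2)
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # all censored: flat at 1
  kmc <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(kmc$surv == 1))
  # single patient with an event
  km1 <- km_estimate(5, 1)
  expect_equal(km_surv_at(km1, c(4.9, 5)), c(1, 0))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")

  # random small cohorts against the oracle
  set.seed(32)
  for (rep in 1:100) {
    n <- sample(2:10, 1)
    time <- sample(1:8, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    km <- km_estimate(time, event)
    orc <- oracle_km(time, event)
    expect_equal(km_surv_at(km, orc$time), orc$surv, tolerance = 1e-12)
  }
})

test_that("one-sided log-rank follows the signed normal construction", {
  # identical groups: z = 0, one-sided p = 1/2
  t0 <- c(1, 2, 3, 4); e0 <- c(1, 1, 0, 1)
  lr0 <- logrank_one_sided(rep(t0, 2), rep(e0, 2),
                           rep(c("A", "B"), each = 4), worse = "A")
  expect_equal(lr0$z, 0, tolerance = 1e-12)
  expect_equal(lr0$p_one_sided, 0.5, tolerance = 1e-12)

  # worked cohort: A events early, B late
  time <- c(1, 2, 3, 4); event <- c(1, 1, 1, 1)
  group <- c("A", "A", "B", "B")
  lr <- logrank_one_sided(time, event, group, worse = "A")
  z_oracle <- oracle_logrank_z(time, event, group, "A")
  expect_equal(lr$z, z_oracle, tolerance = 1e-12)
  expect_gt(lr$z, 0)                           # A did fare worse
  expect_lt(lr$p_one_sided, 0.5)
  expect_equal(lr$p_two_sided, pchisq(lr$z^2, 1, lower.tail = FALSE),
               tolerance = 1e-15)
  # opposite hypothesis is the complementary tail
  lrB <- logrank_one_sided(time, event, group, worse = "B")
  expect_equal(lr$p_one_sided + lrB$p_one_sided, 1, tolerance = 1e-12)

  # randomised small cohorts against the hand O/E/V table (with ties)
  set.seed(33)
  for (rep in 1:50) {
    n <- sample(6:10, 1)
    time <- sample(1:6, n, replace = TRUE)
    event <- rbinom(n, 1, 0.8)
    group <- sample(c("A", "B"), n, replace = TRUE)
    if (sum(event) == 0 || length(unique(group)) < 2) next
    lr <- logrank_one_sided(time, event, group, worse = "A")
    expect_equal(lr$z, oracle_logrank_z(time, event, group, "A"),
                 tolerance = 1e-10)
  }
  expect_error(logrank_one_sided(c(1, 2), c(0, 0), c("A", "B"), "A"), "events")
})

test_that("end-to-end prognosis stratifies and tests the planted hazard", {
  cohort <- generate_survival_cohort(300, sprintf("sig%02d", 1:20),
                                     hazard_ratio = 3, seed = 34)
  pr <- run_prognosis(cohort$matrix, cohort$clinical,
                      sprintf("sig%02d", 1:20))
  expect_s3_class(pr, "prognosis_result")
  expect_equal(pr$logrank$worse, "fulvestrant-resistant")
  expect_lt(pr$logrank$p_one_sided, 0.05)
  # the resistant stratum's KM curve sits below the sensitive one
  tq <- median(cohort$clinical$time)
  expect_lt(km_surv_at(pr$km[["fulvestrant-resistant"]], tq),
            km_surv_at(pr$km[["fulvestrant-sensitive"]], tq))
  # the median split recovers the planted latent groups almost perfectly
  agree <- mean(pr$strata$stratum ==
                cohort$truth$true_stratum[pr$strata$sample_id])
  expect_gt(agree, 0.9)
})

test_that("endpoint preference picks distant-metastasis-free survival", {
  cohort <- generate_survival_cohort(60, sprintf("s%d", 1:5),
                                     hazard_ratio = 2, seed = 35)
  clin <- cohort$clinical
  clin$dmfs_time <- clin$time; clin$dmfs_event <- clin$event
  clin$drfs_time <- clin$time * 2; clin$drfs_event <- clin$event
  clin$time <- NULL; clin$event <- NULL
  pr <- run_prognosis(cohort$matrix, clin, sprintf("s%d", 1:5))
  expect_equal(pr$endpoint, "dmfs")
  pr2 <- run_prognosis(cohort$matrix, clin, sprintf("s%d", 1:5),
                       endpoint = "drfs")
  expect_equal(pr2$endpoint, "drfs")
  # unmatched samples are dropped with a message
  clin_cut <- clin[1:50, ]
  expect_message(pr3 <- run_prognosis(cohort$matrix, clin_cut,
                                      sprintf("s%d", 1:5)), "dropped")
  expect_equal(nrow(pr3$strata), 50)
})
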