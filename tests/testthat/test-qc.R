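test_that("background threshold is the mean of the sample's negative probes", {
  e <- tiny_experiment()
  e$counts["NEG_A", "s1"] <- 10
  e$counts["NEG_B", "s1"] <- 14
  e$counts["NEG_C", "s1"] <- 6
  expect_equal(unname(background_threshold(e, "s1")), 10)

  # all-zero negatives: threshold 0 and no nonzero probe counts as below
  e$counts[c("NEG_A", "NEG_B", "NEG_C"), "s2"] <- 0
  expect_equal(unname(background_threshold(e, "s2")), 0)
  expect_equal(bio_missingness(e, "s2")$count_below, 0L)

  pr <- e$probes[e$probes$class != "NEGATIVE_SPIKE", ]
  e2 <- experiment(e$counts[pr$probe, ], pr, e$samples)
  expect_error(background_threshold(e2), "NEGATIVE_SPIKE")
})

test_that("technical flags trip at the configured lane thresholds", {
  e <- tiny_experiment()
  cfg <- qc_config()
  e$samples$fov_counted[1] <- 0.70 * 555
  expect_true("IMAGING" %in% technical_flags(e, "s1", cfg))
  expect_false("IMAGING" %in% technical_flags(e, "s2", cfg))

  e$samples$binding_density[2] <- 0.05
  expect_true("BINDING" %in% technical_flags(e, "s2", cfg))
  e$samples$binding_density[3] <- 2.5
  expect_true("BINDING" %in% technical_flags(e, "s3", cfg))

  # POS 0.5 fM at 120 counts vs negatives around 10: detectable, no LOD flag
  expect_false("LOD" %in% technical_flags(e, "s4", cfg))
  e$counts["POS_E(0.5)", "s4"] <- 5
  expect_true("LOD" %in% technical_flags(e, "s4", cfg))

  e$samples$fov_count[1] <- 0
  expect_error(technical_flags(e, "s1", cfg), "fov_count")
})

test_that("pca_outliers finds a planted global-shift sample and nothing else", {
  set.seed(21)
  sim <- simulate_experiment(sim_config(
    n_endogenous = 30L, group_sizes = c(A = 21L), n_latent = 0L, seed = 21))
  e <- sim$experiment
  bio <- probes_of_class(e, c("ENDOGENOUS", "BIO_POSITIVE", "HOUSEKEEPING"))
  e$counts[bio, "S021"] <- e$counts[bio, "S021"] * 50
  res <- pca_outliers(e)
  expect_equal(res$outliers, "S021")

  # invariant to sample ordering
  perm <- sample(ncol(e$counts))
  e2 <- experiment(e$counts[, perm], e$probes, e$samples[perm, ])
  expect_setequal(pca_outliers(e2)$outliers, res$outliers)
})

test_that("pca_outliers agrees with an explicit eigendecomposition oracle", {
  oracle <- function(e, m = 1.5) {
    x <- t(log2(e$counts[probes_of_class(
      e, c("ENDOGENOUS", "BIO_POSITIVE", "HOUSEKEEPING")), ] + 1))
    x <- sweep(x, 2, colMeans(x))
    ev <- eigen(cov(x), symmetric = TRUE)
    out <- rep(FALSE, nrow(x))
    for (j in 1:2) {
      s <- drop(x %*% ev$vectors[, j])
      q <- quantile(s, c(0.25, 0.75), type = 7, names = FALSE)
      f <- m * (q[2] - q[1])
      out <- out | s < q[1] - f | s > q[2] + f
    }
    rownames(x)[out]
  }
  for (seed in 1:5) {
    sim <- simulate_experiment(sim_config(
      n_endogenous = 8L, n_housekeeping = 3L, n_bio_positive = 2L,
      group_sizes = c(A = 5L, B = 5L), n_outliers = 1L, outlier_shift = 6,
      seed = seed))
    e <- sim$experiment
    expect_setequal(pca_outliers(e)$outliers, oracle(e))
  }
})

test_that("pca_outliers handles degenerate and undersized inputs", {
  e <- tiny_experiment()
  e$counts[, ] <- rep(e$counts[, 1], 4)   # identical samples
  expect_length(pca_outliers(e)$outliers, 0)
  expect_error(pca_outliers(e, samples = c("s1", "s2")), "3 samples")
})

test_that("bio missingness counts strictly-below genes and flips at the threshold", {
  sim <- simulate_experiment(sim_config(group_sizes = c(A = 4L), seed = 2))
  e <- sim$experiment
  bio <- probes_of_class(e, "BIO_POSITIVE")
  expect_length(bio, 11)
  thr <- unname(background_threshold(e, "S001"))

  suppress <- function(e, n) {
    e$counts[bio[seq_len(n)], "S001"] <- 0
    e
  }
  r3 <- bio_missingness(suppress(e, 3), "S001")
  expect_equal(r3$count_below, 3L)
  expect_false(r3$flag)
  r4 <- bio_missingness(suppress(e, 4), "S001")
  expect_equal(r4$count_below, 4L)
  expect_true(r4$flag)

  # a probe exactly at the background threshold is counted as detected
  e2 <- suppress(e, 3)
  e2$counts[bio[4], "S001"] <- ceiling(thr)
  stopifnot(e2$counts[bio[4], "S001"] >= thr)  # guard on fixture
  if (e2$counts[bio[4], "S001"] == thr) {
    expect_equal(bio_missingness(e2, "S001")$count_below, 3L)
  }
  e3 <- suppress(e, 3)
  e3$counts[bio[4], "S001"] <- thr   # exact tie
  expect_equal(bio_missingness(e3, "S001")$count_below, 3L)
})

test_that("count rule and fraction rule coincide for all 12 possible counts", {
  cfg <- qc_config()
  for (k in 0:11) {
    expect_equal(k >= cfg$bio_missing_min_genes,
                 k / 11 > cfg$bio_missing_fraction,
                 info = paste("count =", k))
  }
})

test_that("standard missingness is a conjunction of the two clauses", {
  sim <- simulate_experiment(sim_config(group_sizes = c(A = 4L), seed = 3))
  e <- sim$experiment
  endo <- probes_of_class(e, c("ENDOGENOUS", "BIO_POSITIVE"))
  hk <- probes_of_class(e, "HOUSEKEEPING")

  expect_false(std_missingness(e, "S001"))  # clean sample

  e2 <- e
  e2$counts[endo[seq_len(ceiling(0.4 * length(endo)))], "S001"] <- 0
  expect_false(std_missingness(e2, "S001"))       # endogenous only
  e3 <- e2
  e3$counts[hk[1:4], "S001"] <- 0                 # 4/15 >= 20% of HK too
  expect_true(std_missingness(e3, "S001"))
  expect_true(std_missingness(e2, "S001",
                              qc_config(std_rule = "or")))
})

test_that("suppressing additional bio-positive genes never un-flags a sample", {
  sim <- simulate_experiment(sim_config(group_sizes = c(A = 4L), seed = 4))
  e <- sim$experiment
  bio <- probes_of_class(e, "BIO_POSITIVE")
  prev <- 0L
  for (n in 1:11) {
    e$counts[bio[n], "S002"] <- 0
    cur <- bio_missingness(e, "S002")$count_below
    expect_gte(cur, prev)
    prev <- cur
  }
  expect_true(bio_missingness(e, "S002")$flag)
})

test_that("run_qc partitions samples, in stage order, with recorded reasons", {
  sim <- paper_like_cohort(seed = 3)
  qc <- run_qc(sim$experiment)
  expect_setequal(c(qc$retained, qc$excluded), sim$experiment$samples$sample_id)
  expect_length(intersect(qc$retained, qc$excluded), 0)
  expect_equal(qc$samples$status == "FLAG", !is.na(qc$samples$reason))

  # planted anomalies are found for the planted reason
  tr <- sim$truth$samples
  expect_setequal(qc$samples$sample_id[qc$samples$reason %in% "pca_outlier"],
                  tr$sample_id[tr$outlier])
  expect_setequal(
    qc$samples$sample_id[qc$samples$reason %in% "bio_missingness"],
    tr$sample_id[tr$degraded])

  # a clean cohort is fully retained
  clean <- null_experiment(sim_config(group_sizes = c(SSL = 10L, TA = 14L),
                                      seed = 8))$experiment
  qc2 <- run_qc(clean)
  expect_length(qc2$excluded, 0)

  # deterministic
  qc3 <- run_qc(sim$experiment)
  expect_identical(qc$samples, qc3$samples)
})

test_that("qc tidiers and plot methods return the expected shapes", {
  sim <- simulate_experiment(sim_config(group_sizes = c(A = 6L, B = 6L),
                                        seed = 12))
  qc <- run_qc(sim$experiment)
  expect_s3_class(tidy(qc), "tbl_df")
  expect_equal(nrow(tidy(qc)), 12)
  g <- glance(qc)
  expect_equal(g$n_samples, 12)
  expect_equal(g$n_retained + g$n_excluded, 12)
  expect_s3_class(autoplot(qc), "ggplot")
})
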