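test_that("build_design encodes groups against the referent", {
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     group = c("TA", "TA", "SSL", "TV"))
  X <- build_design(meta, referent = "TA")
  expect_equal(dim(X), c(4L, 3L))
  expect_equal(colnames(X), c("intercept", "SSL", "TV"))
  expect_equal(unname(X[, "SSL"]), c(0, 0, 1, 0))
  expect_equal(attr(X, "group_cols"), c("SSL", "TV"))

  meta$const <- 1
  expect_error(build_design(meta, "TA", covariates = "const"), "const")

  W <- matrix(rnorm(4), 4, 1)
  X2 <- build_design(meta, "TA", W = W)
  expect_equal(colnames(X2), c("intercept", "SSL", "TV", "W1"))

  expect_error(build_design(meta, "XX"), "not present")
})

test_that("fit_linear reproduces exact fits and matches a normal-equations oracle", {
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     group = rep(c("TA", "SSL"), each = 3))
  X <- build_design(meta, "TA")
  y <- 5 + 1.0 * X[, "SSL"]
  expr <- rbind(g1 = y, g2 = y + c(-1, 1, 0, -1, 1, 0) * 0.5)
  fit <- fit_linear(expr, X)
  expect_equal(unname(fit$coefficients["g1", "SSL"]), 1.0)
  expect_equal(unname(fit$sigma2["g1"]), 0)

  set.seed(41)
  for (i in 1:10) {
    Xr <- cbind(1, matrix(rnorm(16), 8, 2))
    colnames(Xr) <- c("intercept", "a", "b")
    Yr <- matrix(rnorm(8 * 5), 5, 8)        # 5 genes x 8 samples
    rownames(Yr) <- paste0("g", 1:5)
    f <- fit_linear(Yr, Xr)
    beta_or <- t(solve(crossprod(Xr), crossprod(Xr, t(Yr))))
    expect_equal(unname(f$coefficients), unname(beta_or), tolerance = 1e-10)
    rss <- rowSums((Yr - f$coefficients %*% t(Xr))^2)
    expect_equal(unname(f$sigma2), unname(rss / (8 - 3)), tolerance = 1e-10)
  }

  # consistent permutation of samples leaves the fit unchanged
  perm <- c(3, 1, 2, 6, 4, 5)
  f1 <- fit_linear(expr, X)
  f2 <- fit_linear(expr[, perm], X[perm, ])
  expect_equal(f1$coefficients, f2$coefficients)

  expect_error(fit_linear(expr[, 1:2, drop = FALSE], X[1:2, ]), "more samples")
})

test_that("ebayes limit cases behave as the hierarchy predicts", {
  meta <- data.frame(sample_id = paste0("s", 1:8),
                     group = rep(c("TA", "SSL"), each = 4))
  X <- build_design(meta, "TA")
  set.seed(42)
  expr <- matrix(rnorm(20 * 8), 20, 8,
                 dimnames = list(paste0("g", 1:20), meta$sample_id))
  fit <- fit_linear(expr, X)

  # d0 = 0: moderated t equals the ordinary t
  eb0 <- ebayes(fit, d0 = 0, s02 = 1)
  t_ord <- fit$coefficients[, "SSL"] /
    sqrt(fit$sigma2 * fit$unscaled["SSL"])
  expect_equal(unname(eb0$t[, "SSL"]), unname(t_ord))

  # d0 = Inf: all moderated variances collapse to s0^2
  ebI <- ebayes(fit, d0 = Inf, s02 = 0.7)
  expect_equal(unname(ebI$s2_post), rep(0.7, 20))
  expect_true(all(is.finite(ebI$p)))

  # identical residual variances drive the estimated d0 to infinity
  fit3 <- fit
  fit3$sigma2[] <- 0.5
  eb3 <- ebayes(fit3)
  expect_true(is.infinite(eb3$d0))
  expect_equal(length(unique(eb3$s2_post)), 1L)

  # moderated variance lies between s2 and s0^2
  eb <- ebayes(fit)
  lo <- pmin(fit$sigma2, eb$s02)
  hi <- pmax(fit$sigma2, eb$s02)
  expect_true(all(eb$s2_post >= lo - 1e-12 & eb$s2_post <= hi + 1e-12))
})

test_that("ebayes recovers the variance prior from simulated gene variances", {
  set.seed(7)
  d0 <- 4; s02 <- 0.25; dg <- 10; n_genes <- 500
  s2 <- s02 * d0 / rchisq(n_genes, d0) * rchisq(n_genes, dg) / dg
  fit <- structure(list(
    coefficients = matrix(0, n_genes, 2,
                          dimnames = list(paste0("g", seq_len(n_genes)),
                                          c("intercept", "SSL"))),
    sigma2 = setNames(s2, paste0("g", seq_len(n_genes))),
    df_residual = dg,
    unscaled = c(intercept = 0.1, SSL = 0.2),
    design = NULL), class = "ncx_lmfit")
  eb <- ebayes(fit)
  expect_gte(eb$d0, 2)
  expect_lte(eb$d0, 8)
  expect_equal(eb$s02, s02, tolerance = 0.30)
})

test_that("ebayes agrees with an independent moderated-statistics implementation", {
  skip_if_not_installed("limma")
  sim <- simulate_experiment(small_cfg(seed = 44))
  e <- sim$experiment
  X <- build_design(e$samples, "A")
  genes <- probes_of_class(e, c("ENDOGENOUS", "BIO_POSITIVE"))
  expr <- log2(e$counts[genes, ] + 1)
  eb <- ebayes(fit_linear(expr, X))

  lf <- limma::eBayes(limma::lmFit(expr, X))
  expect_equal(unname(eb$d0), unname(lf$df.prior), tolerance = 1e-6)
  expect_equal(unname(eb$s02), unname(lf$s2.prior), tolerance = 1e-6)
  expect_equal(unname(eb$t[, "B"]), unname(lf$t[, "B"]), tolerance = 1e-8)
  expect_equal(unname(eb$p[, "B"]), unname(lf$p.value[, "B"]),
               tolerance = 1e-8)
})

test_that("nb engine shrinks dispersions to near zero on Poisson data", {
  sim <- simulate_experiment(sim_config(
    n_endogenous = 40L, group_sizes = c(A = 20L, B = 20L),
    phi_range = c(0, 0), n_latent = 0L, seed = 45))
  e <- sim$experiment
  nb <- nb_glm_de(e, build_design(e$samples, "A"), nb_size_factors(e))
  phi <- nb$dispersion$phi_shrunk
  expect_gte(mean(phi <= 0.05, na.rm = TRUE), 0.95)
})

test_that("nb engine matches a Poisson GLM oracle in the small-dispersion limit", {
  sim <- simulate_experiment(sim_config(
    n_endogenous = 12L, group_sizes = c(A = 15L, B = 15L),
    phi_range = c(0, 0), n_latent = 0L, seed = 46))
  e <- sim$experiment
  X <- build_design(e$samples, "A")
  sf <- nb_size_factors(e)
  nb <- nb_glm_de(e, X, sf, dispersion = 1e-8)
  lam <- sf$lambda[match(rownames(X), sf$sample_id)]
  off <- log(sf$c * sf$d)[match(rownames(X), sf$sample_id)]
  for (g in c("IMM001", "IMM005", "IMM012")) {
    y <- round(pmax(e$counts[g, rownames(X)] - lam, 0))
    po <- glm(y ~ 0 + X + offset(off), family = poisson())
    est <- nb$tests$log2FC[nb$tests$gene == g] * log(2)  # natural-log scale
    expect_lt(abs(est - unname(coef(po)["XB"])), 1e-3)
  }
})

test_that("a gene with identical counts in both groups shows no effect", {
  e <- tiny_experiment()
  e$counts["GENE1", ] <- c(150, 150, 150, 150)
  sf <- nb_size_factors(e)
  sf$c[] <- 1; sf$d[] <- 1; sf$lambda[] <- 10
  nb <- nb_glm_de(e, build_design(e$samples, "TA"), sf, genes = "GENE1")
  expect_equal(nb$tests$log2FC, 0, tolerance = 1e-6)
  expect_equal(nb$tests$lrt, 0, tolerance = 1e-6)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  brute <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- rep(NA_real_, m)
    for (i in seq_len(m)) {
      js <- seq(i, m)
      q[o[i]] <- min(1, min(m * p[o[js]] / js))
    }
    q
  }
  set.seed(47)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, brute(p))
    expect_true(all(q >= p))
    # q is a monotone transform of the p-rank
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("de_table sorts, thresholds and respects referent symmetry", {
  sim <- simulate_experiment(small_cfg(
    de = data.frame(gene = "IMM001", group = "B", log2FC = 2), seed = 48))
  e <- sim$experiment
  resB <- run_de(e, "ruvg", referent = "A")$B
  resA <- run_de(e, "ruvg", referent = "B")$A
  m <- match(resA$gene, resB$gene)
  expect_equal(resA$log2FC, -resB$log2FC[m], tolerance = 1e-10)
  expect_equal(resA$p, resB$p[m], tolerance = 1e-10)
  expect_true(resB$significant[resB$gene == "IMM001"])
  expect_equal(resB$direction[resB$gene == "IMM001"], "over")
  expect_false(is.unsorted(resB$q, na.rm = TRUE))
  expect_equal(resB$significant, !is.na(resB$q) & resB$q < 0.05)

  X <- build_design(e$samples, "A")
  eb <- ebayes(fit_linear(log2(e$counts[probes_of_class(
    e, c("ENDOGENOUS", "BIO_POSITIVE")), ] + 1), X))
  expect_error(de_table(eb, "NOPE"), "Unknown contrast")

  # all p = 1 yields zero significant genes
  eb$p[] <- 1
  expect_equal(sum(de_table(eb, "B")$significant), 0)
})
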