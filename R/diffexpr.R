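#' Build a design matrix
#'
#' Intercept + one indicator per non-referent group + optional covariate
#' columns + optional unwanted-variation factor columns `W`. Character or
#' factor covariates are treatment-coded. Full column rank is verified.
#'
#' @param samples sample metadata (tibble with `group`, covariate columns)
#' @param referent reference group; group indicators are contrasts against it
#' @param covariates character vector of covariate column names (optional)
#' @param W optional samples x k matrix of unwanted-variation factors
#' @return design matrix (samples x p) with attributes `group_cols` (names of
#'   the group indicator columns) and `referent`
#' @export
build_design <- function(samples, referent, covariates = NULL, W = NULL) {
  samples <- tibble::as_tibble(samples)
  groups <- unique(samples$group)
  if (!referent %in% groups) {
    abort(paste0("Referent group '", referent, "' not present."))
  }
  if (length(groups) < 2) abort("Need at least two groups.")
  others <- setdiff(sort(groups), referent)
  X <- matrix(1, nrow(samples), 1, dimnames = list(samples$sample_id,
                                                   "intercept"))
  for (g in others) {
    X <- cbind(X, as.numeric(samples$group == g))
    colnames(X)[ncol(X)] <- g
  }
  for (cv in covariates) {
    v <- samples[[cv]]
    if (is.null(v)) abort(paste0("Covariate '", cv, "' not found."))
    if (is.numeric(v)) {
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- cv
    } else {
      f <- factor(v)
      mm <- model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cv, levels(f)[-1])
      X <- cbind(X, mm)
    }
  }
  if (!is.null(W)) {
    W <- as.matrix(W)
    if (is.null(colnames(W))) colnames(W) <- paste0("W", seq_len(ncol(W)))
    X <- cbind(X, W)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[-seq_len(qx$rank)]]
    abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  attr(X, "group_cols") <- others
  attr(X, "referent") <- referent
  X
}

#' Gene-wise ordinary least squares
#'
#' Fits the same linear model to every gene's log2 expression by QR
#' decomposition of the shared design: coefficients `(X'X)^-1 X'y_g` and
#' residual variance `s2_g = RSS_g / (n - p)`.
#'
#' @param log2_expr probes x samples matrix on the log2 scale
#' @param design design matrix from [build_design()]
#' @return an object of class `ncx_lmfit`: `coefficients` (genes x p),
#'   `sigma2`, `df_residual`, `unscaled` (diagonal of `(X'X)^-1`), `design`
#' @export
fit_linear <- function(log2_expr, design) {
  X <- as.matrix(design)
  Y <- t(as.matrix(log2_expr))    # samples x genes
  if (nrow(Y) != nrow(X)) abort("Samples in `log2_expr` must match design rows.")
  n <- nrow(X); p <- ncol(X)
  if (n <= p) abort("Need more samples than design columns.")
  qx <- qr(X)
  beta <- qr.coef(qx, Y)
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / (n - p)
  unscaled <- diag(chol2inv(qr.R(qx)))
  # chol2inv of R from an unpivoted QR; guard against pivoting
  if (!identical(qx$pivot, seq_len(p))) {
    unscaled <- diag(solve(crossprod(X)))
  }
  names(unscaled) <- colnames(X)
  structure(list(coefficients = t(beta), sigma2 = sigma2,
                 df_residual = n - p, unscaled = unscaled, design = X),
            class = "ncx_lmfit")
}

#' @export
tidy.ncx_lmfit <- function(x, ...) {
  tibble::as_tibble(x$coefficients, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "term", values_to = "estimate") |>
    dplyr::left_join(
      tibble::tibble(gene = rownames(x$coefficients),
                     sigma2 = unname(x$sigma2)), by = "gene")
}

# Newton inversion of the trigamma function, used by the moment-matching
# estimate of the variance prior degrees of freedom.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes variance moderation
#'
#' Fits the hierarchical model `s2_g ~ s0^2 chi^2_d0 / d0` to the gene-wise
#' residual variances by moment matching on `log s2_g` (digamma/trigamma
#' inversion), then forms moderated variances
#' `s~2_g = (d0 s0^2 + d_g s2_g) / (d0 + d_g)` and moderated t statistics for
#' every non-intercept coefficient, with `d0 + d_g` degrees of freedom.
#' `d0 = Inf` (all variances equal) is handled as the normal limit, and
#' `d0 = 0` reduces to the ordinary t-test. Genes with `s2 = 0` are allowed;
#' their moderated variance is pulled to the prior.
#'
#' @param fit an `ncx_lmfit` from [fit_linear()]
#' @param d0,s02 optional prior overrides (both must be given together);
#'   mainly for diagnostics and limit-case checks
#' @return an object of class `ncx_ebayes`: `d0`, `s02`, `s2_post`,
#'   `t` and `p` (genes x coefficients, intercept excluded), `df_total`,
#'   plus the fit
#' @export
ebayes <- function(fit, d0 = NULL, s02 = NULL) {
  stopifnot(inherits(fit, "ncx_lmfit"))
  s2 <- fit$sigma2
  dg <- fit$df_residual
  if (is.null(d0) != is.null(s02)) {
    abort("Provide both `d0` and `s02`, or neither.")
  }
  if (is.null(d0)) {
    ok <- s2 > 0
    if (sum(ok) < 2) abort("Need at least 2 genes with positive variance.")
    z <- log(s2[ok])
    e <- z - digamma(dg / 2) + log(dg / 2)
    n <- length(e)
    evar <- var(e) - trigamma(dg / 2)
    if (is.na(evar) || evar <= 0) {
      d0 <- Inf
      s02 <- exp(mean(e))
    } else {
      d0 <- 2 * trigamma_inverse(evar)
      s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + dg * s2) / (d0 + dg)
  names(s2_post) <- names(s2)
  df_total <- d0 + dg

  cols <- setdiff(colnames(fit$coefficients), "intercept")
  tmat <- sapply(cols, function(j) {
    fit$coefficients[, j] / sqrt(s2_post * fit$unscaled[j])
  })
  tmat <- matrix(tmat, ncol = length(cols),
                 dimnames = list(rownames(fit$coefficients), cols))
  pmat <- 2 * pt(-abs(tmat), df = df_total)
  structure(list(d0 = d0, s02 = s02, s2_post = s2_post, t = tmat, p = pmat,
                 df_total = df_total, fit = fit),
            class = "ncx_ebayes")
}

#' @export
glance.ncx_ebayes <- function(x, ...) {
  tibble::tibble(d0 = x$d0, s02 = x$s02, df_residual = x$fit$df_residual,
                 n_genes = nrow(x$t))
}

#' @export
tidy.ncx_ebayes <- function(x, ...) {
  purrr::map_dfr(colnames(x$t), function(j) {
    tibble::tibble(gene = rownames(x$t), term = j,
                   estimate = x$fit$coefficients[, j],
                   statistic = x$t[, j], p.value = x$p[, j])
  })
}

#' Negative-binomial GLM differential expression
#'
#' The joint count-model engine: for each tested gene the observed counts are
#' background-corrected (`Y - lambda`, floored at 0 and rounded) and modelled
#' as negative binomial with mean `c_i d_i mu_i`, `log mu_i = x_i' beta`,
#' i.e. a log-link NB GLM with offset `log(c_i d_i)`. The per-gene dispersion
#' is estimated by maximum likelihood, then shrunk toward the across-gene
#' mean of log dispersions with prior weight `n0`:
#' `log phi~ = w log phi-bar + (1 - w) log phi`, `w = n0 / (n0 + n)`.
#' Each group coefficient is tested by a likelihood-ratio test (full vs. the
#' model without that column) at the shrunk dispersion, with a chi-square
#' reference on 1 degree of freedom. Background correction by subtraction is
#' a deliberate simplification of a full background-convolution likelihood;
#' it preserves the three-factor normalization and the NB/empirical-Bayes
#' structure.
#'
#' Genes whose dispersion fit fails to converge are reported with `NA`
#' statistics and excluded from the multiple-testing denominator; the count
#' is carried in the result.
#'
#' @param exp an [experiment()]
#' @param design design matrix from [build_design()]
#' @param sf size factors from [nb_size_factors()]
#' @param genes genes to test (default endogenous + biological positive
#'   controls)
#' @param n0 prior weight for dispersion shrinkage (default 10)
#' @param dispersion optional fixed dispersion; skips estimation and
#'   shrinkage (diagnostics and limit-case checks, e.g. `1e-8` for the
#'   Poisson limit)
#' @return an object of class `ncx_nbfit`: `tests` tibble (gene, contrast,
#'   log2FC, lrt, p), `dispersion` tibble (gene, phi_raw, phi_shrunk),
#'   `n_failed`, `design`, `sf`
#' @export
nb_glm_de <- function(exp, design, sf,
                      genes = probes_of_class(exp, c("ENDOGENOUS",
                                                     "BIO_POSITIVE")),
                      n0 = 10, dispersion = NULL) {
  stopifnot(inherits(exp, "ncx_experiment"))
  X <- as.matrix(design)
  sf <- sf[match(rownames(X), sf$sample_id), ]
  if (any(is.na(sf$sample_id))) abort("Size factors must cover all design rows.")
  off <- log(sf$c * sf$d)
  lam <- sf$lambda
  group_cols <- attr(design, "group_cols")
  if (is.null(group_cols)) group_cols <- setdiff(colnames(X), "intercept")
  n <- nrow(X)

  cm <- exp$counts[genes, rownames(X), drop = FALSE]
  ydat <- lapply(genes, function(g) round(pmax(cm[g, ] - lam, 0)))
  names(ydat) <- genes

  phi_raw <- if (!is.null(dispersion)) {
    setNames(rep(max(dispersion, 1e-8), length(genes)), genes)
  } else vapply(genes, function(g) {
    y <- ydat[[g]]
    if (all(y == 0)) return(NA_real_)
    if (var(y) == 0) return(1e-8)  # no variation: no evidence of dispersion
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(y ~ 0 + X + offset(off),
                                    control = stats::glm.control(maxit = 50))),
      error = function(e) NULL)
    if (is.null(fit)) {
      # glm.nb diverges when the ML dispersion sits at the Poisson boundary;
      # accept the boundary when a Poisson fit shows no overdispersion
      po <- tryCatch(
        suppressWarnings(glm(y ~ 0 + X + offset(off), family = poisson())),
        error = function(e) NULL)
      if (is.null(po) || !po$converged) return(NA_real_)
      overdisp <- sum(stats::residuals(po, "pearson")^2) / po$df.residual
      return(if (overdisp <= 1.5) 1e-8 else NA_real_)
    }
    max(1 / fit$theta, 1e-8)
  }, 1.0)

  conv <- is.finite(phi_raw)
  if (!any(conv)) abort("No gene's dispersion fit converged.")
  phi_shrunk <- if (!is.null(dispersion)) phi_raw else {
    lbar <- mean(log(phi_raw[conv]))
    w <- n0 / (n0 + n)
    exp(w * lbar + (1 - w) * log(phi_raw))
  }

  fit_theta <- function(y, theta, Xm) {
    tryCatch(
      suppressWarnings(glm(y ~ 0 + Xm + offset(off),
                           family = MASS::negative.binomial(theta = theta),
                           control = stats::glm.control(maxit = 100))),
      error = function(e) NULL)
  }
  tests <- purrr::map_dfr(genes, function(g) {
    empty <- tibble::tibble(gene = g, contrast = group_cols,
                            log2FC = NA_real_, lrt = NA_real_, p = NA_real_)
    if (!conv[[g]]) return(empty)
    theta <- min(1 / phi_shrunk[[g]], 1e8)
    y <- ydat[[g]]
    full <- fit_theta(y, theta, X)
    if (is.null(full) || !full$converged) return(empty)
    b <- coef(full)
    names(b) <- colnames(X)
    ll_full <- as.numeric(logLik(full))
    purrr::map_dfr(group_cols, function(gc) {
      red <- fit_theta(y, theta, X[, setdiff(colnames(X), gc), drop = FALSE])
      if (is.null(red) || !red$converged) {
        return(tibble::tibble(gene = g, contrast = gc, log2FC = NA_real_,
                              lrt = NA_real_, p = NA_real_))
      }
      lrt <- max(2 * (ll_full - as.numeric(logLik(red))), 0)
      tibble::tibble(gene = g, contrast = gc, log2FC = b[[gc]] / log(2),
                     lrt = lrt, p = pchisq(lrt, df = 1, lower.tail = FALSE))
    })
  })
  structure(list(
    tests = tests,
    dispersion = tibble::tibble(gene = genes, phi_raw = unname(phi_raw),
                                phi_shrunk = unname(phi_shrunk)),
    n_failed = length(unique(tests$gene[is.na(tests$p)])),
    design = X, sf = sf),
    class = "ncx_nbfit")
}

#' @export
tidy.ncx_nbfit <- function(x, ...) x$tests

#' @export
glance.ncx_nbfit <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$dispersion), n_failed = x$n_failed,
                 mean_phi_shrunk = mean(x$dispersion$phi_shrunk, na.rm = TRUE))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: `q_(i) = min_{j >= i} m p_(j) / j`,
#' mapped back to the original order (computed via [stats::p.adjust()]).
#'
#' @param p vector of p-values in `[0, 1]` (`NA` allowed; passed through)
#' @return vector of q-values
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Differential expression results table
#'
#' Uniform per-gene results for one contrast from either engine: log2 fold
#' change vs. the referent, test statistic, p-value, BH q-value, significance
#' call at `q < threshold` and expression direction. Genes with failed fits
#' carry `NA` and are excluded from the multiple-testing denominator. Sorted
#' by q, then |log2FC| descending.
#'
#' @param stats an `ncx_ebayes` or `ncx_nbfit`
#' @param contrast name of the group coefficient to report
#' @param threshold significance threshold on q (default 0.05)
#' @return a tibble of class `ncx_de`: gene, log2FC, stat, p, q, significant,
#'   direction; attributes `method`, `contrast`, `threshold`, `n_failed`
#' @export
de_table <- function(stats, contrast, threshold = 0.05) {
  if (inherits(stats, "ncx_ebayes")) {
    if (!contrast %in% colnames(stats$t)) {
      abort(paste0("Unknown contrast '", contrast, "'."))
    }
    tab <- tibble::tibble(
      gene = rownames(stats$t),
      log2FC = stats$fit$coefficients[, contrast],
      stat = stats$t[, contrast],
      p = stats$p[, contrast])
    method <- "moderated"
  } else if (inherits(stats, "ncx_nbfit")) {
    sub <- stats$tests[stats$tests$contrast == contrast, ]
    if (!nrow(sub)) abort(paste0("Unknown contrast '", contrast, "'."))
    tab <- tibble::tibble(gene = sub$gene, log2FC = sub$log2FC,
                          stat = sub$lrt, p = sub$p)
    method <- "nbglm"
  } else {
    abort("`stats` must be an ncx_ebayes or ncx_nbfit object.")
  }
  tab$q <- bh_adjust(tab$p)
  tab$significant <- !is.na(tab$q) & tab$q < threshold
  tab$direction <- dplyr::case_when(
    is.na(tab$log2FC) ~ NA_character_,
    tab$log2FC >= 0 ~ "over",
    TRUE ~ "under")
  tab <- dplyr::arrange(tab, .data$q, dplyr::desc(abs(.data$log2FC)))
  structure(tab, class = c("ncx_de", class(tab)),
            method = method, contrast = contrast, threshold = threshold,
            n_failed = sum(is.na(tab$p)))
}

#' Volcano plot of a differential expression table
#'
#' @param object an `ncx_de` tibble from [de_table()]
#' @param ... unused
#' @return a ggplot of log2FC vs. -log10 q with significant genes highlighted
#' @export
autoplot.ncx_de <- function(object, ...) {
  dat <- volcano_table(object)
  ggplot2::ggplot(dat, ggplot2::aes(.data$log2FC, .data$neg_log10_q,
                                    colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10(q)",
                  title = paste0("Volcano: ", attr(object, "contrast"),
                                 " (", attr(object, "method"), ")")) +
    ggplot2::theme_minimal()
}
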