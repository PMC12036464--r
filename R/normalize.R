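#' Geometric mean
#'
#' `exp(mean(log(x)))` with a floor of 0.5 applied to zeros first, the
#' conventional count floor that keeps logs finite.
#'
#' @param x numeric vector of non-negative values
#' @param floor value substituted for entries below it (default 0.5)
#' @return positive scalar
#' @export
geometric_mean <- function(x, floor = 0.5) {
  if (!length(x)) abort("geometric_mean() of an empty vector.")
  x <- pmax(x, floor)
  exp(mean(log(x)))
}

new_norm <- function(log2_expr, method, scaling = NULL, W = NULL,
                     alpha = NULL) {
  structure(list(log2_expr = log2_expr, method = method, scaling = scaling,
                 W = W, alpha = alpha),
            class = "ncx_norm")
}

#' @export
print.ncx_norm <- function(x, ...) {
  cat("<ncx_norm> method=", x$method, ": ", nrow(x$log2_expr), " probes x ",
      ncol(x$log2_expr), " samples (log2 scale)\n", sep = "")
  invisible(x)
}

#' @export
tidy.ncx_norm <- function(x, ...) {
  tibble::as_tibble(x$log2_expr, rownames = "probe") |>
    tidyr::pivot_longer(-"probe", names_to = "sample_id",
                        values_to = "log2_expr")
}

#' @export
glance.ncx_norm <- function(x, ...) {
  tibble::tibble(method = x$method,
                 n_probes = nrow(x$log2_expr),
                 n_samples = ncol(x$log2_expr),
                 k = if (is.null(x$W)) 0L else ncol(x$W))
}

#' nSolver-style scaling normalization
#'
#' The platform's guideline normalization: per sample, a positive-control
#' scaling factor (mean of per-sample geometric means of the spike-in
#' positives divided by the sample's own), background subtraction (the plain
#' mean of the sample's scaled negative controls, result floored at 0.5), and
#' a housekeeping scaling factor computed on the scaled,
#' background-subtracted housekeeping geometric means. The returned matrix is
#' `log2` of the fully scaled, background-subtracted counts over biological
#' probes (endogenous, biological positive controls, housekeeping); spike-in
#' probes are controls, not biology, and are excluded from the output.
#'
#' @param exp an [experiment()]
#' @return an `ncx_norm` with `method = "NSOLVER"` and a `scaling` tibble
#'   (sample_id, pos_factor, background, hk_factor)
#' @export
nsolver_normalize <- function(exp) {
  pos <- probes_of_class(exp, "POSITIVE_SPIKE")
  neg <- probes_of_class(exp, "NEGATIVE_SPIKE")
  hk <- probes_of_class(exp, "HOUSEKEEPING")
  if (!length(pos) || !length(neg) || !length(hk)) {
    abort("nSolver normalization needs positive, negative and housekeeping probes.")
  }
  cm <- exp$counts
  dead <- apply(cm[pos, , drop = FALSE], 2, max) == 0
  if (any(dead)) {
    abort(paste0("Sample(s) with all-zero positive spikes cannot be ",
                 "normalized: ",
                 paste(colnames(cm)[dead], collapse = ", ")))
  }
  p <- apply(cm[pos, , drop = FALSE], 2, geometric_mean)
  f <- mean(p) / p
  scaled <- sweep(cm, 2, f, `*`)
  b <- colMeans(scaled[neg, , drop = FALSE])
  bio <- probes_of_class(exp, bio_probe_classes)
  adj <- pmax(sweep(scaled[bio, , drop = FALSE], 2, b, `-`), 0.5)
  hvals <- apply(pmax(sweep(scaled[hk, , drop = FALSE], 2, b, `-`), 0.5),
                 2, geometric_mean)
  if (any(apply(sweep(scaled[hk, , drop = FALSE], 2, b, `-`), 2, max)
          <= 0.5)) {
    abort("Sample(s) with all housekeeping counts at the background floor cannot be normalized.")
  }
  g <- mean(hvals) / hvals
  log2_expr <- log2(sweep(adj, 2, g, `*`))
  new_norm(log2_expr, "NSOLVER",
           scaling = tibble::tibble(sample_id = colnames(cm),
                                    pos_factor = unname(f),
                                    background = unname(b),
                                    hk_factor = unname(g)))
}

#' Estimate unwanted-variation factors from control genes
#'
#' Factor analysis of the control-gene block in the style of RUVg: on
#' `Y = log2(count + 1)` (samples x probes), the control-gene columns are
#' centered across samples and decomposed by SVD. `W` is the first `k` left
#' singular vectors scaled by their singular values (samples x k); `alpha`
#' (k x probes) is the least-squares regression of all biological probes on
#' `W`. Each `W` column's largest-magnitude entry is made positive, a
#' deterministic sign convention.
#'
#' @param exp an [experiment()] (biological probes are used)
#' @param control_probes character vector of control gene names (default: the
#'   experiment's housekeeping probes)
#' @param k number of unwanted-variation factors (default 1)
#' @return list with `W` (samples x k), `alpha` (k x probes), `Y`
#'   (samples x probes log2 matrix)
#' @export
ruvg_fit <- function(exp, control_probes = probes_of_class(exp, "HOUSEKEEPING"),
                     k = 1) {
  stopifnot(k >= 1)
  if (length(control_probes) < k) {
    abort("Need at least k control probes.")
  }
  bio <- probes_of_class(exp, bio_probe_classes)
  missing <- setdiff(control_probes, bio)
  if (length(missing)) {
    abort(paste0("Control probe(s) not among biological probes: ",
                 paste(missing, collapse = ", ")))
  }
  Y <- t(log2(exp$counts[bio, , drop = FALSE] + 1))
  if (nrow(Y) < k + 1) abort("Need at least k + 1 samples.")
  ctl <- scale(Y[, control_probes, drop = FALSE], center = TRUE,
               scale = FALSE)
  sv <- svd(ctl)
  tol <- max(dim(ctl)) * max(sv$d, 0) * .Machine$double.eps
  attainable <- sum(sv$d > max(tol, 1e-10))
  if (attainable < k) {
    abort(paste0("Control block has rank ", attainable,
                 "; cannot extract k = ", k, " factors."))
  }
  W <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], nrow = k)
  for (j in seq_len(k)) {
    if (W[which.max(abs(W[, j])), j] < 0) W[, j] <- -W[, j]
  }
  rownames(W) <- rownames(Y)
  colnames(W) <- paste0("W", seq_len(k))
  alpha <- solve(crossprod(W), crossprod(W, Y))
  rownames(alpha) <- colnames(W)
  list(W = W, alpha = alpha, Y = Y)
}

#' RUVg-style normalization
#'
#' Removes the estimated unwanted-variation component: the returned matrix is
#' `Y - W alpha` (log2 scale, probes x samples over biological probes).
#' `W` and `alpha` are retained in the result so the differential-expression
#' design can alternatively include `W` as covariates — the mode the DE
#' engines use, following standard practice in the RUV literature; the
#' subtracted matrix serves visualization and correlation outputs.
#'
#' @inheritParams ruvg_fit
#' @return an `ncx_norm` with `method = "RUVG"`, plus `W` and `alpha`
#' @export
ruvg_normalize <- function(exp,
                           control_probes =
                             probes_of_class(exp, "HOUSEKEEPING"),
                           k = 1) {
  if (k == 0) {
    bio <- probes_of_class(exp, bio_probe_classes)
    Y <- t(log2(exp$counts[bio, , drop = FALSE] + 1))
    return(new_norm(t(Y), "RUVG",
                    W = matrix(0, nrow(Y), 0), alpha = NULL))
  }
  fit <- ruvg_fit(exp, control_probes, k)
  new_norm(t(fit$Y - fit$W %*% fit$alpha), "RUVG",
           W = fit$W, alpha = fit$alpha)
}

#' Negative-binomial size factors
#'
#' The three-factor normalization feeding the joint count model: per sample, a
#' positive size factor `c` (geometric mean of the spike-in positives,
#' rescaled so the geometric mean of `c` across samples is exactly 1), a
#' background mean `lambda` (plain mean of the negative controls, the same
#' definition as [background_threshold()]), and a housekeeping size factor
#' `d` (geometric mean of background-subtracted housekeeping counts divided
#' by `c`, floored at 0.5 before the log, rescaled to geometric mean 1).
#' Dividing by `c` makes the pair consistent with the count model
#' `E[Y] = lambda + c d mu`: scaling a sample's every count by `t` scales
#' `c d` by `t` (up to the global rescaling).
#'
#' @param exp an [experiment()]
#' @return a tibble of class `ncx_sizefactors`: sample_id, c, d, lambda
#' @export
nb_size_factors <- function(exp) {
  pos <- probes_of_class(exp, "POSITIVE_SPIKE")
  neg <- probes_of_class(exp, "NEGATIVE_SPIKE")
  hk <- probes_of_class(exp, "HOUSEKEEPING")
  if (!length(pos) || !length(neg) || !length(hk)) {
    abort("Size factors need positive, negative and housekeeping probes.")
  }
  cm <- exp$counts
  craw <- apply(cm[pos, , drop = FALSE], 2, geometric_mean)
  cc <- craw / geometric_mean(craw, floor = 0)
  lambda <- colMeans(cm[neg, , drop = FALSE])
  hk_adj <- sweep(cm[hk, , drop = FALSE], 2, lambda, `-`)
  if (any(apply(hk_adj, 2, max) <= 0.5)) {
    abort("Sample(s) with all housekeeping counts at the background floor cannot be normalized.")
  }
  hk_adj <- pmax(hk_adj, 0.5)
  draw <- apply(sweep(hk_adj, 2, cc, `/`), 2, geometric_mean)
  dd <- draw / geometric_mean(draw, floor = 0)
  structure(tibble::tibble(sample_id = colnames(cm), c = unname(cc),
                           d = unname(dd), lambda = unname(lambda)),
            class = c("ncx_sizefactors", class(tibble::tibble())))
}
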