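#' Correlation of log fold changes between two DE results
#'
#' Pearson correlation over the intersection of tested genes; genes with a
#' failed fit in either result are excluded pairwise.
#'
#' @param a,b `ncx_de` tibbles from [de_table()]
#' @return Pearson r
#' @export
logfc_correlation <- function(a, b) {
  m <- dplyr::inner_join(a[, c("gene", "log2FC")], b[, c("gene", "log2FC")],
                         by = "gene", suffix = c("_a", "_b"))
  m <- m[complete.cases(m), ]
  if (nrow(m) < 3) abort("Need at least 3 shared genes with estimates.")
  cor(m$log2FC_a, m$log2FC_b)
}

#' Overlap of significant gene sets across methods
#'
#' Exact membership counts for every non-empty subset of methods (the numbers
#' behind a Venn diagram), computed on the common gene universe.
#'
#' @param results named list of `ncx_de` tibbles
#' @param threshold significance threshold on q (default 0.05)
#' @return a list of class `ncx_comparison`: `membership` tibble (one row per
#'   non-empty method subset: `methods`, `n_exclusive`, `n_intersection`),
#'   `deg_counts` (per-method significant counts), `correlations` (pairwise
#'   log2FC Pearson r), `universe_size`
#' @export
deg_overlap <- function(results, threshold = 0.05) {
  stopifnot(length(results) >= 1)
  if (is.null(names(results))) {
    names(results) <- paste0("method", seq_along(results))
  }
  universe <- Reduce(intersect, lapply(results, function(r) r$gene))
  sig <- lapply(results, function(r) {
    intersect(r$gene[!is.na(r$q) & r$q < threshold], universe)
  })
  m <- length(results)
  subsets <- utils::combn
  membership <- purrr::map_dfr(seq_len(2^m - 1), function(code) {
    inset <- as.logical(bitwAnd(code, 2^(seq_len(m) - 1)))
    inn <- Reduce(intersect, sig[inset])
    outt <- unique(unlist(sig[!inset]))
    tibble::tibble(
      methods = paste(names(results)[inset], collapse = "&"),
      n_exclusive = length(setdiff(inn, outt)),
      n_intersection = length(inn))
  })
  corrs <- NULL
  if (m >= 2) {
    pairs <- utils::combn(names(results), 2)
    corrs <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      tibble::tibble(
        method_a = pairs[1, i], method_b = pairs[2, i],
        r = tryCatch(logfc_correlation(results[[pairs[1, i]]],
                                       results[[pairs[2, i]]]),
                     error = function(e) NA_real_))
    })
  }
  structure(list(
    membership = membership,
    deg_counts = tibble::tibble(method = names(results),
                                n_significant = unname(lengths(sig))),
    correlations = corrs,
    universe_size = length(universe),
    threshold = threshold),
    class = "ncx_comparison")
}

#' @export
print.ncx_comparison <- function(x, ...) {
  cat("<ncx_comparison> ", nrow(x$deg_counts), " methods, universe ",
      x$universe_size, " genes, q < ", x$threshold, "\n", sep = "")
  print(x$deg_counts)
  invisible(x)
}

#' @export
tidy.ncx_comparison <- function(x, ...) x$membership

#' Permutation-based empirical Type I error
#'
#' For each replicate: permute the group labels uniformly at random, re-run
#' normalization and differential expression from scratch on the permuted
#' labels, and record the fraction of tested genes (both non-referent
#' contrasts pooled) with unadjusted p below `alpha`. Label permutation makes
#' every gene null, so a calibrated pipeline yields a mean fraction near
#' `alpha`. One master seed spawns per-replicate child seeds, recorded in the
#' result for auditability; labels do not enter the scaling normalizations,
#' but recomputation keeps the protocol uniform across engines.
#'
#' @param exp an [experiment()] with group labels
#' @param method pipeline id: `"ruvg"`, `"nsolver"` (each followed by the
#'   moderated linear model) or `"nbjoint"`
#' @param B number of permutation replicates
#' @param alpha per-test significance level (default 0.05)
#' @param seed master RNG seed
#' @param referent referent group (default the largest group)
#' @param k number of unwanted-variation factors for the RUVg path
#' @param stratify optional sample column name (e.g. `"cartridge"`); labels
#'   are then permuted within strata
#' @return an object of class `ncx_type1`: `method`, `B`, `alpha`,
#'   `fractions` (per-replicate), `mean`, `mc_se`, `seed`, `child_seeds`,
#'   `n_failed`
#' @export
type_i_simulation <- function(exp, method = c("ruvg", "nsolver", "nbjoint"),
                              B = 200, alpha = 0.05, seed = 1,
                              referent = NULL, k = 1, stratify = NULL) {
  method <- match.arg(method)
  if (B < 1) abort("B must be at least 1.")
  if (alpha < 0 || alpha > 1) abort("alpha must lie in [0, 1].")
  if (is.null(referent)) {
    tabg <- table(exp$samples$group)
    referent <- names(tabg)[which.max(tabg)]
  }
  set.seed(seed)
  child_seeds <- sample.int(.Machine$integer.max - 1, B)
  strata <- if (is.null(stratify)) rep(1L, nrow(exp$samples)) else
    exp$samples[[stratify]]

  fractions <- vapply(seq_len(B), function(r) {
    set.seed(child_seeds[r])
    perm <- exp
    idx <- seq_len(nrow(perm$samples))
    for (s in unique(strata)) {
      i <- idx[strata == s]
      perm$samples$group[i] <- sample(perm$samples$group[i])
    }
    res <- tryCatch(
      run_de(perm, method = method, referent = referent, k = k),
      error = function(e) NULL)
    if (is.null(res)) return(NA_real_)
    p <- unlist(lapply(res, function(tab) tab$p), use.names = FALSE)
    mean(p < alpha, na.rm = TRUE)
  }, 1.0)

  ok <- !is.na(fractions)
  structure(list(
    method = method, B = B, alpha = alpha,
    fractions = fractions[ok],
    mean = mean(fractions[ok]),
    mc_se = sd(fractions[ok]) / sqrt(sum(ok)),
    seed = seed, child_seeds = child_seeds,
    n_failed = sum(!ok)),
    class = "ncx_type1")
}

#' @export
print.ncx_type1 <- function(x, ...) {
  cat("<ncx_type1> ", x$method, ": mean Type I error ",
      signif(x$mean, 4), " (MC SE ", signif(x$mc_se, 3), ", B = ",
      length(x$fractions), ", alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.ncx_type1 <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$fractions),
                 child_seed = x$child_seeds[seq_along(x$fractions)],
                 fraction = x$fractions)
}

#' @export
glance.ncx_type1 <- function(x, ...) {
  tibble::tibble(method = x$method, B = x$B, alpha = x$alpha,
                 mean = x$mean, mc_se = x$mc_se, n_failed = x$n_failed,
                 seed = x$seed)
}

#' Plotting-ready volcano table
#'
#' @param res an `ncx_de` tibble from [de_table()]
#' @return a tibble with `gene`, `log2FC`, `neg_log10_q` (q floored at the
#'   smallest positive double before the log) and `significant`
#' @export
volcano_table <- function(res) {
  tibble::tibble(
    gene = res$gene,
    log2FC = res$log2FC,
    neg_log10_q = -log10(pmax(res$q, .Machine$double.xmin)),
    significant = res$significant)
}
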