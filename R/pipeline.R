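#' Run one normalization + differential expression pipeline
#'
#' Convenience wrapper chaining a normalization strategy into the matching DE
#' engine on the genes of interest (endogenous plus biological positive
#' controls; housekeeping genes are anchors and are not tested):
#' \describe{
#'   \item{ruvg}{unwanted-variation factors estimated from housekeeping
#'     genes, then the moderated linear model on raw `log2(count + 1)` with
#'     `W` included as design covariates}
#'   \item{nsolver}{scaling normalization, then the moderated linear model on
#'     the normalized log2 matrix}
#'   \item{nbjoint}{three-factor size factors, then the negative-binomial GLM
#'     on background-corrected counts}
#' }
#'
#' @param exp an [experiment()]
#' @param method `"ruvg"`, `"nsolver"` or `"nbjoint"`
#' @param referent referent group for contrasts
#' @param k number of unwanted-variation factors (RUVg path)
#' @param covariates optional covariate column names for the design
#' @param contrasts group coefficients to report (default: all non-referent
#'   groups)
#' @param threshold q-value significance threshold
#' @return named list of `ncx_de` tibbles, one per contrast, with attribute
#'   `engine`
#' @export
run_de <- function(exp, method = c("ruvg", "nsolver", "nbjoint"),
                   referent, k = 1, covariates = NULL, contrasts = NULL,
                   threshold = 0.05) {
  method <- match.arg(method)
  genes <- probes_of_class(exp, c("ENDOGENOUS", "BIO_POSITIVE"))
  if (method == "ruvg") {
    fit <- ruvg_fit(exp, k = k)
    design <- build_design(exp$samples, referent, covariates, W = fit$W)
    expr <- t(fit$Y)[genes, , drop = FALSE]
    stats <- ebayes(fit_linear(expr, design))
  } else if (method == "nsolver") {
    norm <- nsolver_normalize(exp)
    design <- build_design(exp$samples, referent, covariates)
    stats <- ebayes(fit_linear(norm$log2_expr[genes, , drop = FALSE],
                               design))
  } else {
    sf <- nb_size_factors(exp)
    design <- build_design(exp$samples, referent, covariates)
    stats <- nb_glm_de(exp, design, sf, genes = genes)
  }
  if (is.null(contrasts)) contrasts <- attr(design, "group_cols")
  out <- lapply(contrasts, de_table, stats = stats, threshold = threshold)
  names(out) <- contrasts
  attr(out, "engine") <- method
  out
}

#' Run the full workflow end to end
#'
#' Chains QC, sample exclusion, every requested normalization/DE method and
#' contrast, cross-method comparison, and (optionally) the permutation Type I
#' error simulation; writes all tables plus a reproducibility manifest into
#' `out_dir`. Rerunning with the same inputs and seed reproduces every output
#' byte for byte (the manifest records an md5 hash per file).
#'
#' @param exp an [experiment()]
#' @param out_dir output directory (created if needed)
#' @param methods pipelines to run (subset of `"ruvg"`, `"nsolver"`,
#'   `"nbjoint"`)
#' @param referent referent group (default the largest group)
#' @param contrasts contrasts to report (default all non-referent groups)
#' @param qc a [qc_config()]
#' @param k unwanted-variation factors for the RUVg path
#' @param covariates optional covariate names
#' @param threshold q-value threshold
#' @param type1 optional list with elements `B`, `alpha` and optionally
#'   `methods` to also run [type_i_simulation()]
#' @param seed seed for the Type I simulation
#' @return the manifest, invisibly (also written as `manifest.json`)
#' @export
run_pipeline <- function(exp, out_dir, methods = c("ruvg", "nsolver"),
                         referent = NULL, contrasts = NULL,
                         qc = qc_config(), k = 1, covariates = NULL,
                         threshold = 0.05, type1 = NULL, seed = 1) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("run_pipeline() needs the jsonlite package for its manifest.")
  }
  if (!length(methods)) abort("At least one method is required.")
  methods <- match.arg(methods, c("ruvg", "nsolver", "nbjoint"),
                       several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- Sys.time()
  if (is.null(referent)) {
    tabg <- table(exp$samples$group)
    referent <- names(tabg)[which.max(tabg)]
  }
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      abort(paste0("Pipeline failed at stage '", name, "': ",
                   conditionMessage(e)))
    })
  }
  outputs <- character()
  emit <- function(tab, file) {
    path <- file.path(out_dir, file)
    readr::write_tsv(tibble::as_tibble(tab), path)
    outputs <<- c(outputs, path)
  }

  qc_res <- stage("qc", function() run_qc(exp, qc))
  emit(qc_res$samples, "qc_report.tsv")
  kept <- stage("apply_qc", function() apply_qc(exp, qc_res))
  if (length(unique(kept$samples$group)) < 2) {
    abort("Fewer than two groups remain after QC.")
  }
  if (is.null(contrasts)) {
    contrasts <- setdiff(sort(unique(kept$samples$group)), referent)
  }
  if (!length(contrasts)) abort("At least one contrast is required.")

  de_res <- list()
  for (m in methods) {
    res <- stage(paste0("de_", m), function()
      run_de(kept, method = m, referent = referent, k = k,
             covariates = covariates, contrasts = contrasts,
             threshold = threshold))
    de_res[[m]] <- res
    for (ct in names(res)) {
      emit(res[[ct]], paste0("de_", m, "_", ct, "_vs_", referent, ".tsv"))
    }
  }

  comparison <- lapply(contrasts, function(ct) {
    cmp <- deg_overlap(lapply(de_res, `[[`, ct), threshold = threshold)
    list(contrast = ct, deg_counts = cmp$deg_counts,
         membership = cmp$membership, correlations = cmp$correlations,
         universe_size = cmp$universe_size)
  })
  names(comparison) <- contrasts
  cmp_path <- file.path(out_dir, "comparison.json")
  jsonlite::write_json(comparison, cmp_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  outputs <- c(outputs, cmp_path)

  t1_res <- NULL
  if (!is.null(type1)) {
    t1_methods <- type1$methods %||% methods
    t1_res <- lapply(t1_methods, function(m) {
      r <- stage(paste0("type1_", m), function()
        type_i_simulation(kept, method = m, B = type1$B,
                          alpha = type1$alpha %||% 0.05, seed = seed,
                          referent = referent, k = k))
      glance(r)
    })
    t1_path <- file.path(out_dir, "type1.json")
    jsonlite::write_json(dplyr::bind_rows(t1_res), t1_path,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    outputs <- c(outputs, t1_path)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ncountr")),
    r_version = R.version.string,
    seed = seed,
    referent = referent,
    contrasts = contrasts,
    methods = methods,
    threshold = threshold,
    qc_config = unclass(qc),
    counts = list(
      samples_in = ncol(exp$counts),
      samples_into_de = length(qc_res$retained),
      genes_tested = length(probes_of_class(kept, c("ENDOGENOUS",
                                                    "BIO_POSITIVE")))),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = lapply(outputs, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
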