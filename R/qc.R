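#' Quality-control configuration
#'
#' Tunable thresholds for pre-normalization QC. Defaults follow the package's
#' workflow for heterogeneous FFPE cohorts: the biological missingness flag
#' trips when 4 or more of the 11 tissue-specific positive-control genes fall
#' below the sample's background threshold (equivalently, more than 30% of an
#' 11-gene panel); the standard missingness rule flags samples with more than
#' 30% of endogenous and at least 20% of housekeeping genes below background;
#' lane-level technical cutoffs (FOV ratio 0.75, binding density 0.1-2.25
#' spots/um^2, limit of detection at mean + 2 SD of negatives) follow the
#' platform's published guidelines.
#'
#' @param bio_missing_min_genes minimum number of biological positive-control
#'   genes below background to flag a sample (default 4)
#' @param bio_missing_fraction equivalent fraction rule (default 0.30; with an
#'   11-gene panel `count/11 > 0.30` and `count >= 4` coincide)
#' @param std_endog_fraction endogenous fraction for the standard rule (> 0.30)
#' @param std_hk_fraction housekeeping fraction for the standard rule (>= 0.20)
#' @param std_rule character; combine the two standard-rule clauses with
#'   `"and"` (default) or `"or"` (sensitivity analysis)
#' @param iqr_multiplier fence multiplier for PCA outliers (default 1.5)
#' @param fov_ratio_min minimum counted/attempted fields-of-view ratio
#' @param binding_density_range acceptable binding density interval, spots/um^2
#' @param pc_axes number of principal components screened (default 2)
#' @param log_pseudocount pseudocount added before log2 for the PCA (default 1)
#' @param pca_after_technical logical; compute PCA outliers on technically
#'   passing samples only (default TRUE, the workflow's stage order)
#' @return a list of class `ncx_qc_config`
#' @export
qc_config <- function(bio_missing_min_genes = 4L,
                      bio_missing_fraction = 0.30,
                      std_endog_fraction = 0.30,
                      std_hk_fraction = 0.20,
                      std_rule = c("and", "or"),
                      iqr_multiplier = 1.5,
                      fov_ratio_min = 0.75,
                      binding_density_range = c(0.1, 2.25),
                      pc_axes = 2L,
                      log_pseudocount = 1,
                      pca_after_technical = TRUE) {
  std_rule <- match.arg(std_rule)
  stopifnot(bio_missing_min_genes >= 1, iqr_multiplier > 0,
            bio_missing_fraction > 0, bio_missing_fraction < 1,
            std_endog_fraction > 0, std_endog_fraction < 1,
            std_hk_fraction > 0, std_hk_fraction < 1,
            fov_ratio_min > 0, fov_ratio_min < 1,
            length(binding_density_range) == 2,
            binding_density_range[1] >= 0,
            diff(binding_density_range) > 0,
            pc_axes >= 1, log_pseudocount > 0)
  structure(list(
    bio_missing_min_genes = as.integer(bio_missing_min_genes),
    bio_missing_fraction = bio_missing_fraction,
    std_endog_fraction = std_endog_fraction,
    std_hk_fraction = std_hk_fraction,
    std_rule = std_rule,
    iqr_multiplier = iqr_multiplier,
    fov_ratio_min = fov_ratio_min,
    binding_density_range = binding_density_range,
    pc_axes = as.integer(pc_axes),
    log_pseudocount = log_pseudocount,
    pca_after_technical = pca_after_technical
  ), class = "ncx_qc_config")
}

#' Per-sample background threshold
#'
#' The arithmetic mean of a sample's negative-control counts. Probes counting
#' strictly below this threshold are treated as undetected.
#'
#' @param exp an [experiment()]
#' @param sample sample id (or vector of ids; default all samples)
#' @return named numeric vector of thresholds (counts)
#' @export
background_threshold <- function(exp, sample = exp$samples$sample_id) {
  neg <- probes_of_class(exp, "NEGATIVE_SPIKE")
  if (!length(neg)) {
    abort("No NEGATIVE_SPIKE probes: background threshold is undefined.")
  }
  colMeans(exp$counts[neg, sample, drop = FALSE])
}

#' Lane-level technical flags
#'
#' Flags a sample for imaging quality (counted/attempted FOV ratio below the
#' cutoff), binding density outside the acceptable range, and limit of
#' detection (the 0.5 fM positive spike not exceeding mean + 2 SD of the
#' sample's negative controls). Missing lane attributes leave the
#' corresponding flag unset.
#'
#' @param exp an [experiment()]
#' @param sample a single sample id
#' @param cfg a [qc_config()]
#' @return character vector, a subset of `c("IMAGING", "BINDING", "LOD")`
#' @export
technical_flags <- function(exp, sample, cfg = qc_config()) {
  sm <- exp$samples[match(sample, exp$samples$sample_id), ]
  flags <- character()
  fov_count <- sm$fov_count %||% NA_real_
  fov_counted <- sm$fov_counted %||% NA_real_
  if (!is.na(fov_count) && fov_count == 0) {
    abort(paste0("fov_count is 0 for sample ", sample))
  }
  if (!is.na(fov_count) && !is.na(fov_counted) &&
      fov_counted / fov_count < cfg$fov_ratio_min) {
    flags <- c(flags, "IMAGING")
  }
  bd <- sm$binding_density %||% NA_real_
  if (!is.na(bd) && (bd < cfg$binding_density_range[1] ||
                     bd > cfg$binding_density_range[2])) {
    flags <- c(flags, "BINDING")
  }
  pos <- exp$probes[exp$probes$class == "POSITIVE_SPIKE", ]
  pos <- pos[!is.na(pos$spike_fM) & pos$spike_fM > 0, ]
  if (nrow(pos)) {
    lod_probe <- pos$probe[which.min(abs(pos$spike_fM - 0.5))]
    neg <- probes_of_class(exp, "NEGATIVE_SPIKE")
    negs <- exp$counts[neg, sample]
    lod_cut <- mean(negs) + 2 * sd(negs)
    if (!is.na(lod_cut) &&
        exp$counts[lod_probe, sample] <= lod_cut) {
      flags <- c(flags, "LOD")
    }
  }
  flags
}

# log2(count + pseudocount) on biological probes, probes x samples
qc_log_matrix <- function(exp, cfg) {
  bio <- probes_of_class(exp, bio_probe_classes)
  log2(exp$counts[bio, , drop = FALSE] + cfg$log_pseudocount)
}

#' PCA outlier detection with IQR fences
#'
#' Computes a principal components analysis of samples on
#' `log2(count + pseudocount)` over all biological probes (endogenous,
#' biological positive controls and housekeeping; no prior normalization,
#' since QC precedes normalization). Each probe is centered across samples.
#' A sample is an outlier if its score on any of the first `pc_axes`
#' components lies outside `[Q1 - m*IQR, Q3 + m*IQR]` of that component's
#' scores, with quartiles by linear interpolation (type 7).
#'
#' @param exp an [experiment()]; `samples` optionally restricts the analysis
#' @param cfg a [qc_config()]
#' @param samples sample ids to include (default all)
#' @return list with `outliers` (character vector of sample ids) and `scores`
#'   (tibble: sample_id, PC1, PC2, ...)
#' @export
pca_outliers <- function(exp, cfg = qc_config(),
                         samples = exp$samples$sample_id) {
  if (length(samples) < 3) abort("PCA outlier detection needs >= 3 samples.")
  if (length(samples) < cfg$pc_axes) {
    abort("Fewer samples than requested principal components.")
  }
  x <- t(qc_log_matrix(exp, cfg)[, samples, drop = FALSE])
  x <- scale(x, center = TRUE, scale = FALSE)
  k <- min(cfg$pc_axes, nrow(x) - 1, ncol(x))
  pc <- prcomp(x, center = FALSE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  out <- rep(FALSE, nrow(scores))
  for (j in seq_len(ncol(scores))) {
    s <- scores[, j]
    q <- quantile(s, c(0.25, 0.75), type = 7, names = FALSE)
    fence <- cfg$iqr_multiplier * (q[2] - q[1])
    out <- out | s < q[1] - fence | s > q[2] + fence
  }
  sc <- tibble::as_tibble(scores)
  names(sc) <- paste0("PC", seq_len(ncol(scores)))
  list(outliers = samples[out],
       scores = dplyr::bind_cols(tibble::tibble(sample_id = samples), sc))
}

#' Biological positive-control missingness
#'
#' Counts how many biological positive-control genes (the tissue-specific
#' panel) fall strictly below the sample's background threshold, and flags the
#' sample when the count reaches `bio_missing_min_genes`. With the default
#' 11-gene panel the count rule (>= 4 genes) and the fraction rule
#' (> 30% of the panel) coincide for every possible count. Ties with the
#' background are counted as detected, conservatively favouring retention.
#'
#' @param exp an [experiment()]
#' @param sample a single sample id
#' @param cfg a [qc_config()]
#' @return list with `count_below` (integer) and `flag` (logical)
#' @export
bio_missingness <- function(exp, sample, cfg = qc_config()) {
  bio <- probes_of_class(exp, "BIO_POSITIVE")
  if (!length(bio)) {
    abort("No BIO_POSITIVE probes: the missingness flag is undefined.")
  }
  thr <- background_threshold(exp, sample)
  count_below <- sum(exp$counts[bio, sample] < thr)
  list(count_below = as.integer(count_below),
       flag = count_below >= cfg$bio_missing_min_genes)
}

#' Standard missingness rule
#'
#' The conventional codeset-wide rule: a sample is flagged when more than
#' `std_endog_fraction` of endogenous genes (including the biological
#' positive controls, which are endogenous biology) AND at least
#' `std_hk_fraction` of housekeeping genes fall below background. The
#' conjunction can be switched to a disjunction via `qc_config(std_rule=)`.
#'
#' @inheritParams bio_missingness
#' @return logical flag
#' @export
std_missingness <- function(exp, sample, cfg = qc_config()) {
  endo <- probes_of_class(exp, c("ENDOGENOUS", "BIO_POSITIVE"))
  hk <- probes_of_class(exp, "HOUSEKEEPING")
  if (!length(endo) || !length(hk)) {
    abort("Standard missingness needs endogenous and housekeeping probes.")
  }
  thr <- background_threshold(exp, sample)
  f_endo <- mean(exp$counts[endo, sample] < thr)
  f_hk <- mean(exp$counts[hk, sample] < thr)
  a <- f_endo > cfg$std_endog_fraction
  b <- f_hk >= cfg$std_hk_fraction
  if (cfg$std_rule == "and") a && b else a || b
}

#' Run the full pre-normalization QC
#'
#' Applies, in order: lane-level technical flags; PCA outlier detection
#' (computed on technically passing samples); and the biological
#' positive-control missingness flag on the remainder. Any flagged sample is
#' excluded; each sample's first triggering stage is recorded as its reason,
#' along with all flags. The standard codeset-wide missingness flag is
#' reported for comparison but does not drive exclusion.
#'
#' @param exp an [experiment()]
#' @param cfg a [qc_config()]
#' @return an object of class `ncx_qc`: list with `samples` (tibble, one row
#'   per sample: sample_id, background, fov_flag, binding_flag, lod_flag,
#'   pc1, pc2, pca_outlier, bio_below_n, bio_flag, std_flag, status, reason),
#'   `retained` and `excluded` (character vectors), `config`.
#' @export
run_qc <- function(exp, cfg = qc_config()) {
  ids <- exp$samples$sample_id
  thr <- background_threshold(exp)

  tech <- lapply(ids, function(s) technical_flags(exp, s, cfg))
  names(tech) <- ids
  tech_fail <- vapply(tech, function(f) length(f) > 0, TRUE)

  pca_ids <- if (cfg$pca_after_technical) ids[!tech_fail] else ids
  pca <- pca_outliers(exp, cfg, samples = pca_ids)
  is_pca_out <- ids %in% pca$outliers

  bio <- lapply(ids, function(s) bio_missingness(exp, s, cfg))
  std <- vapply(ids, function(s) std_missingness(exp, s, cfg), TRUE)

  bio_flag <- vapply(bio, `[[`, TRUE, "flag")
  reason <- dplyr::case_when(
    tech_fail ~ "technical",
    is_pca_out ~ "pca_outlier",
    bio_flag ~ "bio_missingness",
    TRUE ~ NA_character_
  )
  flagged <- !is.na(reason)

  sc <- pca$scores[match(ids, pca$scores$sample_id), ]
  tab <- tibble::tibble(
    sample_id = ids,
    background = unname(thr),
    fov_flag = vapply(tech, function(f) "IMAGING" %in% f, TRUE),
    binding_flag = vapply(tech, function(f) "BINDING" %in% f, TRUE),
    lod_flag = vapply(tech, function(f) "LOD" %in% f, TRUE),
    pc1 = if ("PC1" %in% names(sc)) sc$PC1 else NA_real_,
    pc2 = if ("PC2" %in% names(sc)) sc$PC2 else NA_real_,
    pca_outlier = is_pca_out,
    bio_below_n = vapply(bio, `[[`, 1L, "count_below"),
    bio_flag = bio_flag,
    std_flag = unname(std),
    status = ifelse(flagged, "FLAG", "PASS"),
    reason = reason
  )
  structure(list(samples = tab,
                 retained = ids[!flagged],
                 excluded = ids[flagged],
                 config = cfg),
            class = "ncx_qc")
}

#' @export
print.ncx_qc <- function(x, ...) {
  cat("<ncx_qc> ", length(x$retained), " retained / ",
      length(x$excluded), " excluded of ",
      nrow(x$samples), " samples\n", sep = "")
  if (length(x$excluded)) {
    rs <- table(x$samples$reason[x$samples$status == "FLAG"])
    cat("  reasons: ", paste0(names(rs), "=", as.integer(rs),
                              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.ncx_qc <- function(x, ...) x$samples

#' @export
glance.ncx_qc <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$samples),
    n_retained = length(x$retained),
    n_excluded = length(x$excluded),
    n_technical = sum(x$samples$reason == "technical", na.rm = TRUE),
    n_pca = sum(x$samples$reason == "pca_outlier", na.rm = TRUE),
    n_bio_missing = sum(x$samples$reason == "bio_missingness", na.rm = TRUE)
  )
}

#' PCA plot of QC results
#'
#' @param object an `ncx_qc` object from [run_qc()]
#' @param ... unused
#' @return a ggplot: samples on PC1/PC2, coloured by pass/flag status
#' @export
autoplot.ncx_qc <- function(object, ...) {
  dat <- object$samples[!is.na(object$samples$pc1), ]
  ggplot2::ggplot(dat, ggplot2::aes(.data$pc1, .data$pc2,
                                    colour = .data$status)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "PC1", y = "PC2", colour = NULL,
                  title = "Sample QC: principal component scores") +
    ggplot2::theme_minimal()
}

#' Drop QC-excluded samples from an experiment
#'
#' @param exp an [experiment()]
#' @param qc an `ncx_qc` from [run_qc()]
#' @return the experiment restricted to retained samples
#' @export
apply_qc <- function(exp, qc) {
  keep <- exp$samples$sample_id %in% qc$retained
  experiment(exp$counts[, keep, drop = FALSE], exp$probes,
             exp$samples[keep, ])
}
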