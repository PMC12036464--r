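#' Probe classes used throughout the package
#'
#' Every probe in an nCounter codeset carries exactly one class:
#' \describe{
#'   \item{ENDOGENOUS}{biological probes of interest}
#'   \item{HOUSEKEEPING}{stably expressed genes used as normalization anchors}
#'   \item{POSITIVE_SPIKE}{synthetic spike-in probes at known concentration (fM)}
#'   \item{NEGATIVE_SPIKE}{probes against sequence absent from biology; estimate
#'     nonspecific background}
#'   \item{BIO_POSITIVE}{tissue-specific positive-control genes: endogenous
#'     biology tracked separately because their drop-out flags degraded samples}
#' }
#' @export
probe_classes <- c(
  "ENDOGENOUS", "HOUSEKEEPING", "POSITIVE_SPIKE", "NEGATIVE_SPIKE",
  "BIO_POSITIVE"
)

# Printed symbol variants occasionally seen in panel documentation, mapped to
# the standard HGNC symbols the packaged lists use.
symbol_aliases <- c(ALASI = "ALAS1", LRG5 = "LGR5", OLMF4 = "OLFM4")

standardize_symbol <- function(x) {
  hit <- match(x, names(symbol_aliases))
  x[!is.na(hit)] <- symbol_aliases[hit[!is.na(hit)]]
  x
}

#' Construct an nCounter experiment
#'
#' The universal input object: a non-negative integer count matrix
#' (probes x samples) plus a probe annotation table and sample metadata.
#' Probe rows are canonicalized alphabetically (C-locale radix order) so that
#' downstream linear algebra is deterministic regardless of input order.
#'
#' @param counts numeric matrix, probes x samples, non-negative counts. Row
#'   names must be probe names, column names sample ids.
#' @param probes data frame with columns `probe`, `class` (one of
#'   [probe_classes]) and optionally `accession`, `spike_fM` (positive spike
#'   concentration, fM, `NA` for other classes).
#' @param samples data frame with columns `sample_id`, `group` and optionally
#'   covariates (`cartridge`, `size_mm`, `age`, `sex`) and lane attributes
#'   (`fov_count`, `fov_counted`, `binding_density`).
#' @return An object of class `ncx_experiment`: a list with elements `counts`
#'   (matrix), `probes` (tibble) and `samples` (tibble).
#' @examples
#' cm <- matrix(rpois(12, 50), 4, 3,
#'   dimnames = list(c("A", "B", "NEG_1", "POS_A"), paste0("s", 1:3)))
#' pr <- data.frame(probe = rownames(cm),
#'   class = c("ENDOGENOUS", "HOUSEKEEPING", "NEGATIVE_SPIKE", "POSITIVE_SPIKE"),
#'   spike_fM = c(NA, NA, NA, 128))
#' sm <- data.frame(sample_id = colnames(cm), group = c("TA", "SSL", "TV"))
#' experiment(cm, pr, sm)
#' @export
experiment <- function(counts, probes, samples) {
  counts <- as.matrix(counts)
  probes <- tibble::as_tibble(probes)
  samples <- tibble::as_tibble(samples)
  if (!all(c("probe", "class") %in% names(probes))) {
    abort("`probes` must have columns `probe` and `class`.")
  }
  if (!"spike_fM" %in% names(probes)) probes$spike_fM <- NA_real_
  if (!"accession" %in% names(probes)) probes$accession <- NA_character_
  if (!all(c("sample_id", "group") %in% names(samples))) {
    abort("`samples` must have columns `sample_id` and `group`.")
  }
  if (is.null(rownames(counts))) rownames(counts) <- probes$probe
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id

  if (nrow(counts) != nrow(probes)) {
    abort("Row count of `counts` must equal the number of probes.")
  }
  if (ncol(counts) != nrow(samples)) {
    abort("Column count of `counts` must equal the number of samples.")
  }
  if (anyDuplicated(probes$probe)) {
    abort("Probe names must be unique within a codeset.")
  }
  if (anyDuplicated(samples$sample_id)) abort("Sample ids must be unique.")
  if (!setequal(rownames(counts), probes$probe)) {
    abort("Row names of `counts` must match `probes$probe`.")
  }
  if (!setequal(colnames(counts), samples$sample_id)) {
    abort("Column names of `counts` must match `samples$sample_id`.")
  }
  bad <- setdiff(unique(probes$class), probe_classes)
  if (length(bad)) {
    abort(paste0("Unknown probe class: ", paste(bad, collapse = ", ")))
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    abort("Counts must be non-negative and non-missing.")
  }
  sp <- probes$spike_fM[probes$class == "POSITIVE_SPIKE"]
  if (any(is.na(sp)) || any(sp <= 0)) {
    abort("POSITIVE_SPIKE probes must carry a positive `spike_fM`.")
  }

  ord <- order(probes$probe, method = "radix")
  probes <- probes[ord, ]
  counts <- counts[probes$probe, samples$sample_id, drop = FALSE]
  structure(list(counts = counts, probes = probes, samples = samples),
            class = "ncx_experiment")
}

#' @export
print.ncx_experiment <- function(x, ...) {
  tab <- table(factor(x$probes$class, levels = probe_classes))
  cat("<ncx_experiment> ", nrow(x$counts), " probes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  probes: ", paste0(names(tab), "=", as.integer(tab), collapse = ", "),
      "\n", sep = "")
  cat("  groups: ", paste0(names(table(x$samples$group)), "=",
                           as.integer(table(x$samples$group)),
                           collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Probe names belonging to given classes
#' @param exp an [experiment()]
#' @param classes character vector of classes (see [probe_classes])
#' @return character vector of probe names (in canonical row order)
#' @export
probes_of_class <- function(exp, classes) {
  stopifnot(inherits(exp, "ncx_experiment"))
  exp$probes$probe[exp$probes$class %in% classes]
}

# Biological probes: everything that is actual biology (not spike-ins).
bio_probe_classes <- c("ENDOGENOUS", "BIO_POSITIVE", "HOUSEKEEPING")

#' @describeIn tidy.ncx_experiment long tibble of counts with annotation
#' @export
tidy.ncx_experiment <- function(x, ...) {
  tibble::as_tibble(x$counts, rownames = "probe") |>
    tidyr::pivot_longer(-"probe", names_to = "sample_id",
                        values_to = "count") |>
    dplyr::left_join(x$probes[, c("probe", "class")], by = "probe") |>
    dplyr::left_join(x$samples[, c("sample_id", "group")], by = "sample_id")
}

#' Tidy an nCounter experiment into a long tibble
#'
#' @param x an `ncx_experiment`
#' @param ... unused
#' @return a tibble with columns `probe`, `sample_id`, `count`, `class`,
#'   `group`, one row per probe/sample pair.
#' @name tidy.ncx_experiment
NULL

#' Packaged codeset gene lists
#'
#' Returns the colon-specific biological positive-control panel (11 genes)
#' used for the degradation missingness flag, and the 15 housekeeping genes
#' used as normalization anchors. These are the panels shipped with the
#' package's reference immune codeset.
#'
#' @return a list with character vectors `bio_positive` (11 symbols) and
#'   `housekeeping` (15 symbols).
#' @examples
#' load_packaged_codeset()$bio_positive
#' @export
load_packaged_codeset <- function() {
  list(
    bio_positive = c("MUC5AC", "TFF1", "CDH1", "CDX2", "CTNNB1", "ITLN1",
                     "B2M", "MUC2", "OLFM4", "PIGR", "SELENBP1"),
    housekeeping = c("ABCF1", "ALAS1", "EEF1G", "G6PD", "GAPDH", "GUSB",
                     "HPRT1", "OAZ1", "POLR1B", "POLR2A", "PPIA", "RPL19",
                     "SDHA", "TBP", "TUBB")
  )
}

#' Assemble parsed lanes into an experiment
#'
#' Combines per-lane probe/count records (from [read_rcc()]) with a sample
#' metadata table. Probes whose symbol is in `bio_positive_genes` are
#' reclassified from `ENDOGENOUS` to `BIO_POSITIVE`; this is an annotation
#' overlay — those genes remain part of the endogenous biology for analysis,
#' but additionally drive the missingness QC flag.
#'
#' @param lanes named list of lanes as returned by [read_rcc()]; names (or the
#'   lane's `sample_id` attribute) must match `meta$sample_id`.
#' @param meta sample metadata data frame with a `sample_id` column; the
#'   experiment's columns are ordered by `meta`.
#' @param bio_positive_genes character vector of gene symbols to overlay as
#'   `BIO_POSITIVE` (printed variants such as "ALASI" are standardized first).
#' @return an [experiment()]
#' @export
assemble_experiment <- function(lanes, meta,
                                bio_positive_genes =
                                  load_packaged_codeset()$bio_positive) {
  meta <- tibble::as_tibble(meta)
  stopifnot(length(lanes) >= 1)
  ids <- names(lanes)
  if (is.null(ids)) ids <- vapply(lanes, function(l) l$sample_id, "")
  if (!setequal(ids, meta$sample_id)) {
    abort(paste0("Lane sample ids and metadata disagree: ",
                 paste(c(setdiff(ids, meta$sample_id),
                         setdiff(meta$sample_id, ids)), collapse = ", ")))
  }
  ref <- sort(lanes[[1]]$codes$probe, method = "radix")
  for (l in lanes) {
    cur <- sort(l$codes$probe, method = "radix")
    if (!identical(ref, cur)) {
      diff <- c(setdiff(ref, cur), setdiff(cur, ref))
      abort(paste0("Probe sets differ between lanes: ",
                   paste(diff, collapse = ", ")))
    }
  }
  bio_positive_genes <- standardize_symbol(bio_positive_genes)
  missing_bio <- setdiff(bio_positive_genes, ref)
  if (length(missing_bio)) {
    abort(paste0("Biological positive-control gene(s) absent from codeset: ",
                 paste(missing_bio, collapse = ", ")))
  }

  codes1 <- lanes[[match(ids[1], ids)]]$codes
  codes1 <- codes1[order(codes1$probe, method = "radix"), ]
  counts <- vapply(meta$sample_id, function(s) {
    cd <- lanes[[match(s, ids)]]$codes
    cd$count[order(cd$probe, method = "radix")]
  }, numeric(nrow(codes1)))
  rownames(counts) <- codes1$probe

  cls <- codes1$class
  cls[codes1$probe %in% bio_positive_genes & cls == "ENDOGENOUS"] <-
    "BIO_POSITIVE"
  not_endo <- bio_positive_genes[
    !bio_positive_genes %in% codes1$probe[cls == "BIO_POSITIVE"]]
  if (length(not_endo)) {
    abort(paste0("Gene(s) listed as biological positive controls are not ",
                 "Endogenous in the codeset: ",
                 paste(not_endo, collapse = ", ")))
  }
  probes <- tibble::tibble(
    probe = codes1$probe, accession = codes1$accession,
    class = cls, spike_fM = codes1$spike_fM)

  lane_tab <- purrr::map_dfr(meta$sample_id, function(s) {
    la <- lanes[[match(s, ids)]]$lane
    tibble::tibble(sample_id = s,
                   lane_id = la$lane_id %||% NA_character_,
                   fov_count = la$fov_count %||% NA_real_,
                   fov_counted = la$fov_counted %||% NA_real_,
                   binding_density = la$binding_density %||% NA_real_)
  })
  keep <- setdiff(names(lane_tab), names(meta))
  samples <- dplyr::bind_cols(meta, lane_tab[, keep, drop = FALSE])
  experiment(counts, probes, samples)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
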