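#' Read and write experiment bundles
#'
#' An experiment bundle is a directory of three plain-text TSV files:
#' `counts.tsv` (column `probe` plus one column per sample), `probes.tsv`
#' (`probe`, `class`, `accession`, `spike_fM`) and `samples.tsv`
#' (`sample_id`, `group`, covariates and lane attributes). `write_counts()`
#' followed by `read_counts()` is the identity on the experiment.
#'
#' @param exp an [experiment()]
#' @param dir directory to write to / read from (created if needed)
#' @return `read_counts()` returns an [experiment()]; `write_counts()` returns
#'   `dir` invisibly.
#' @export
write_counts <- function(exp, dir) {
  stopifnot(inherits(exp, "ncx_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cm <- tibble::as_tibble(exp$counts, rownames = "probe")
  readr::write_tsv(cm, file.path(dir, "counts.tsv"))
  readr::write_tsv(exp$probes[, c("probe", "class", "accession", "spike_fM")],
                   file.path(dir, "probes.tsv"))
  readr::write_tsv(exp$samples, file.path(dir, "samples.tsv"))
  invisible(dir)
}

#' @rdname write_counts
#' @export
read_counts <- function(dir) {
  paths <- file.path(dir, c("counts.tsv", "probes.tsv", "samples.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("Experiment bundle is missing: ",
                 paste(basename(missing), collapse = ", ")))
  }
  cm <- readr::read_tsv(paths[1], show_col_types = FALSE)
  probes <- readr::read_tsv(paths[2], show_col_types = FALSE,
                            col_types = readr::cols(
                              probe = "c", class = "c", accession = "c",
                              spike_fM = "d"))
  samples <- readr::read_tsv(paths[3], show_col_types = FALSE)
  samples$sample_id <- as.character(samples$sample_id)

  counts <- as.matrix(cm[, -1, drop = FALSE])
  rownames(counts) <- cm$probe
  unannotated <- setdiff(rownames(counts), probes$probe)
  if (length(unannotated)) {
    abort(paste0("Probe(s) in counts lack annotation: ",
                 paste(unannotated, collapse = ", ")))
  }
  unmet <- setdiff(colnames(counts), samples$sample_id)
  if (length(unmet)) {
    abort(paste0("Sample column(s) absent from metadata: ",
                 paste(unmet, collapse = ", ")))
  }
  probes <- probes[match(rownames(counts), probes$probe), ]
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  experiment(counts, probes, samples)
}
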