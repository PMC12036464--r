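# Small hand-built experiment: 4 endogenous, 2 bio-positive, 2 housekeeping,
# 2 positive spikes, 3 negative probes, 4 samples in 2 groups. Counts chosen
# by hand so QC arithmetic is easy to verify.
tiny_experiment <- function(counts = NULL) {
  probes <- data.frame(
    probe = c("GENE1", "GENE2", "GENE3", "GENE4", "TFF1", "MUC2",
              "HKA", "HKB", "POS_A(128)", "POS_E(0.5)",
              "NEG_A", "NEG_B", "NEG_C"),
    class = c(rep("ENDOGENOUS", 4), rep("BIO_POSITIVE", 2),
              rep("HOUSEKEEPING", 2), rep("POSITIVE_SPIKE", 2),
              rep("NEGATIVE_SPIKE", 3)),
    spike_fM = c(rep(NA, 8), 128, 0.5, rep(NA, 3)))
  if (is.null(counts)) {
    set.seed(99)
    counts <- matrix(rpois(13 * 4, 120), 13, 4)
    counts[9, ] <- 20000          # POS_A
    counts[10, ] <- 120           # POS_E (0.5 fM), well above background
    counts[11:13, ] <- rpois(12, 10)
  }
  dimnames(counts) <- list(probes$probe, paste0("s", 1:4))
  samples <- data.frame(
    sample_id = paste0("s", 1:4), group = c("TA", "TA", "SSL", "SSL"),
    cartridge = "C01", fov_count = 555, fov_counted = 550,
    binding_density = 1.1)
  experiment(counts, probes, samples)
}

# A fast small simulation config for property tests.
small_cfg <- function(..., seed = 1) {
  sim_config(n_endogenous = 40L, group_sizes = c(A = 12L, B = 12L),
             samples_per_cartridge = 8L, seed = seed, ...)
}

# Write a minimal RCC file; `rows` is a character vector of Code_Summary
# lines "CodeClass,Name,Accession,Count".
write_min_rcc <- function(rows, path = tempfile(fileext = ".rcc"),
                          lane = c("ID,1", "FovCount,555", "FovCounted,550",
                                   "BindingDensity,1.05", "CartridgeID,C1"),
                          sample_id = "SAMP1", eol = "\n") {
  lines <- c("<Header>", "FileVersion,1.7", "</Header>", "",
             "<Sample_Attributes>", paste0("ID,", sample_id),
             "</Sample_Attributes>", "",
             "<Lane_Attributes>", lane, "</Lane_Attributes>", "",
             "<Code_Summary>", "CodeClass,Name,Accession,Count", rows,
             "</Code_Summary>")
  con <- file(path, "wb")
  writeLines(lines, con, sep = eol)
  close(con)
  path
}
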