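test_that("read_rcc maps CodeClass values and parses spike concentrations", {
  p <- write_min_rcc(c("Endogenous,GENE1,NM_001,55",
                       "Housekeeping,HKA,NM_002,200",
                       "Negative,NEG_A,,7"))
  lane <- read_rcc(p)
  expect_equal(nrow(lane$codes), 3)
  expect_equal(lane$codes$class,
               c("ENDOGENOUS", "HOUSEKEEPING", "NEGATIVE_SPIKE"))
  expect_equal(lane$codes$count, c(55, 200, 7))
  expect_equal(lane$sample_id, "SAMP1")
  expect_equal(lane$lane$binding_density, 1.05)

  p2 <- write_min_rcc("Positive,POS_A(128),,20000")
  expect_equal(read_rcc(p2)$codes$spike_fM, 128)
  p3 <- write_min_rcc("Positive,POS_E(0.5),,150")
  expect_equal(read_rcc(p3)$codes$spike_fM, 0.5)
})

test_that("read_rcc tolerates CRLF endings, mixed case and unknown sections", {
  p <- write_min_rcc(c("endogenous,GENE1,NM_001,55",
                       "NEGATIVE,NEG_A,,7"), eol = "\r\n")
  lane <- read_rcc(p)
  expect_equal(lane$codes$class, c("ENDOGENOUS", "NEGATIVE_SPIKE"))

  lines <- c("<Messages>", "some,vendor,noise", "</Messages>",
             readLines(p))
  p2 <- tempfile(fileext = ".rcc")
  writeLines(lines, p2)
  expect_equal(read_rcc(p2)$codes$count, c(55, 7))
})

test_that("read_rcc rejects malformed files with informative errors", {
  p <- tempfile(fileext = ".rcc")
  writeLines(c("<Header>", "FileVersion,1.7", "</Header>"), p)
  expect_error(read_rcc(p), "Code_Summary")

  p2 <- write_min_rcc("Endogenous,GENE1,NM_001,-5")
  expect_error(read_rcc(p2), "GENE1")
  p3 <- write_min_rcc("Endogenous,GENE1,NM_001,5.5")
  expect_error(read_rcc(p3), "GENE1")
})

test_that("assemble_experiment overlays bio-positive class and orders by metadata", {
  rows <- function(tff1, g1) {
    c(sprintf("Endogenous,TFF1,NM_003225,%d", tff1),
      sprintf("Endogenous,GENE1,NM_001,%d", g1),
      "Housekeeping,HKA,NM_002,200",
      "Positive,POS_A(128),,20000",
      "Negative,NEG_A,,7")
  }
  l1 <- read_rcc(write_min_rcc(rows(90, 10), sample_id = "a"))
  l2 <- read_rcc(write_min_rcc(rows(50, 20), sample_id = "b"))
  meta <- data.frame(sample_id = c("a", "b"), group = c("TA", "SSL"))
  e <- assemble_experiment(list(a = l1, b = l2), meta,
                           bio_positive_genes = "TFF1")
  expect_s3_class(e, "ncx_experiment")
  expect_equal(e$probes$class[e$probes$probe == "TFF1"], "BIO_POSITIVE")
  expect_equal(e$probes$class[e$probes$probe == "GENE1"], "ENDOGENOUS")
  expect_equal(unname(e$counts["TFF1", ]), c(90, 50))

  # permuting lane input order only permutes columns, matched to metadata
  e2 <- assemble_experiment(list(b = l2, a = l1), meta,
                            bio_positive_genes = "TFF1")
  expect_identical(e$counts, e2$counts)

  expect_error(assemble_experiment(list(a = l1, b = l2), meta,
                                   bio_positive_genes = "NOTAGENE"),
               "NOTAGENE")
})

test_that("assemble_experiment detects probe-set mismatch between lanes", {
  l1 <- read_rcc(write_min_rcc(c("Endogenous,GENE1,,5", "Negative,NEG_A,,7"),
                               sample_id = "a"))
  l2 <- read_rcc(write_min_rcc(c("Endogenous,GENE2,,5", "Negative,NEG_A,,7"),
                               sample_id = "b"))
  meta <- data.frame(sample_id = c("a", "b"), group = c("TA", "SSL"))
  expect_error(
    assemble_experiment(list(a = l1, b = l2), meta, bio_positive_genes = character()),
    "GENE1.*GENE2|GENE2.*GENE1")
})

test_that("packaged codeset lists match the reference panels", {
  cs <- load_packaged_codeset()
  expect_length(cs$bio_positive, 11)
  expect_length(cs$housekeeping, 15)
  expect_true("TFF1" %in% cs$bio_positive)
  expect_false("TFF1" %in% cs$housekeeping)
  expect_true("ALAS1" %in% cs$housekeeping)  # standardized symbol
  expect_false(anyDuplicated(c(cs$bio_positive, cs$housekeeping)) > 0)
})

test_that("RCC round trip through assemble_experiment reproduces the codeset", {
  sim <- simulate_experiment(sim_config(group_sizes = c(SSL = 2L, TA = 2L),
                                        seed = 5))
  e <- sim$experiment
  dir <- withr::local_tempdir()
  lanes <- lapply(e$samples$sample_id, function(s) {
    read_rcc(ncountr:::write_rcc(e, s, file.path(dir, paste0(s, ".rcc"))))
  })
  names(lanes) <- e$samples$sample_id
  e2 <- assemble_experiment(lanes, e$samples[, c("sample_id", "group")])
  expect_equal(unname(e2$counts), unname(e$counts))
  tab <- table(e2$probes$class)
  expect_equal(as.integer(tab[c("ENDOGENOUS", "HOUSEKEEPING", "BIO_POSITIVE",
                                "POSITIVE_SPIKE", "NEGATIVE_SPIKE")]),
               c(277L, 15L, 11L, 6L, 8L))
  # class partition: BIO_POSITIVE + ENDOGENOUS equals the RCC Endogenous rows
  n_rcc_endo <- sum(lanes[[1]]$codes$class == "ENDOGENOUS")
  expect_equal(sum(tab[c("ENDOGENOUS", "BIO_POSITIVE")]), n_rcc_endo)
})

test_that("experiment bundles round-trip exactly", {
  e <- tiny_experiment()
  dir <- withr::local_tempdir()
  write_counts(e, dir)
  e2 <- read_counts(dir)
  expect_equal(e2$counts, e$counts)
  expect_equal(e2$probes$class, e$probes$class)
  expect_equal(e2$samples$group, e$samples$group)

  # annotation missing a probe is named in the error
  probes <- readr::read_tsv(file.path(dir, "probes.tsv"),
                            show_col_types = FALSE)
  readr::write_tsv(probes[probes$probe != "GENE3", ],
                   file.path(dir, "probes.tsv"))
  expect_error(read_counts(dir), "GENE3")
})

test_that("counts columns without metadata rows are rejected", {
  e <- tiny_experiment()
  dir <- withr::local_tempdir()
  write_counts(e, dir)
  meta <- readr::read_tsv(file.path(dir, "samples.tsv"),
                          show_col_types = FALSE)
  readr::write_tsv(meta[meta$sample_id != "s2", ],
                   file.path(dir, "samples.tsv"))
  expect_error(read_counts(dir), "s2")
})

test_that("experiment constructor enforces its invariants", {
  e <- tiny_experiment()
  expect_error(experiment(e$counts[-1, ], e$probes, e$samples), "probes")
  cm <- e$counts; cm[1, 1] <- -1
  expect_error(experiment(cm, e$probes, e$samples), "non-negative")
  pr <- e$probes; pr$spike_fM[pr$probe == "POS_A(128)"] <- NA
  expect_error(experiment(e$counts, pr, e$samples), "spike_fM")
  # probes are canonicalized alphabetically
  expect_equal(e$probes$probe, sort(e$probes$probe, method = "radix"))
})
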