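#' Read an nCounter RCC lane file
#'
#' Parses the platform's per-lane sectioned-CSV output. Sections are delimited
#' by `<Name>` / `</Name>` lines; the parser uses `Sample_Attributes` (sample
#' id), `Lane_Attributes` (lane id, cartridge, FOV counts, binding density)
#' and `Code_Summary` (CodeClass,Name,Accession,Count rows). Unknown sections
#' are ignored and both LF and CRLF line endings are accepted, since vendor
#' files vary. CodeClass values are mapped case-insensitively:
#' Endogenous -> ENDOGENOUS, Housekeeping -> HOUSEKEEPING,
#' Positive -> POSITIVE_SPIKE, Negative -> NEGATIVE_SPIKE. Spike-in
#' concentrations are parsed from positive probe names of the form
#' `POS_X(conc)` (fM).
#'
#' @param path path to an RCC file
#' @return a list with elements `sample_id`, `lane` (list: `lane_id`,
#'   `cartridge_id`, `fov_count`, `fov_counted`, `binding_density`) and
#'   `codes`, a tibble with columns `probe`, `class`, `accession`, `count`,
#'   `spike_fM`.
#' @export
read_rcc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- gsub("\r$", "", lines)
  sec_open <- grep("^<[^/][^>]*>\\s*$", lines)
  sections <- list()
  for (i in sec_open) {
    nm <- sub("^<([^>]*)>\\s*$", "\\1", lines[i])
    close <- grep(paste0("^</", nm, ">\\s*$"), lines)
    close <- close[close > i]
    if (!length(close)) next
    sections[[nm]] <- lines[seq(i + 1, close[1] - 1)]
  }
  if (is.null(sections[["Code_Summary"]])) {
    abort(paste0("RCC file ", path,
                 " is missing the required Code_Summary section."))
  }

  kv <- function(sec) {
    if (is.null(sec)) return(character())
    parts <- strsplit(sec, ",", fixed = TRUE)
    setNames(vapply(parts, function(p) paste(p[-1], collapse = ","), ""),
             vapply(parts, `[`, "", 1))
  }
  samp <- kv(sections[["Sample_Attributes"]])
  lane <- kv(sections[["Lane_Attributes"]])
  num <- function(x) if (is.na(x) || !nzchar(x)) NA_real_ else as.numeric(x)

  body <- sections[["Code_Summary"]]
  body <- body[nzchar(trimws(body))]
  hdr <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  need <- c("CodeClass", "Name", "Accession", "Count")
  if (!all(need %in% hdr)) {
    abort("Code_Summary header must contain CodeClass,Name,Accession,Count.")
  }
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  get <- function(col) vapply(rows, function(r) r[match(col, hdr)], "")
  name <- get("Name")
  count_chr <- get("Count")
  count <- suppressWarnings(as.numeric(count_chr))
  bad <- which(is.na(count) | count < 0 | count != floor(count))
  if (length(bad)) {
    abort(paste0("Invalid Count '", count_chr[bad[1]], "' for probe '",
                 name[bad[1]], "' in ", path,
                 ": counts must be non-negative integers."))
  }
  class_map <- c(endogenous = "ENDOGENOUS", housekeeping = "HOUSEKEEPING",
                 positive = "POSITIVE_SPIKE", negative = "NEGATIVE_SPIKE")
  cls_raw <- tolower(get("CodeClass"))
  cls <- unname(class_map[cls_raw])
  if (any(is.na(cls))) {
    abort(paste0("Unknown CodeClass '", get("CodeClass")[is.na(cls)][1],
                 "' in ", path))
  }
  spike <- rep(NA_real_, length(name))
  is_pos <- cls == "POSITIVE_SPIKE"
  conc <- sub("^.*\\(([0-9.]+)\\)\\s*$", "\\1", name[is_pos])
  spike[is_pos] <- suppressWarnings(as.numeric(conc))

  list(
    sample_id = unname(samp["ID"]) %||% NA_character_,
    lane = list(
      lane_id = unname(lane["ID"]) %||% NA_character_,
      cartridge_id = unname(lane["CartridgeID"]) %||% NA_character_,
      fov_count = num(lane["FovCount"]),
      fov_counted = num(lane["FovCounted"]),
      binding_density = num(lane["BindingDensity"])
    ),
    codes = tibble::tibble(probe = name, class = cls,
                           accession = get("Accession"),
                           count = count, spike_fM = spike)
  )
}

# Write one lane of an experiment back out as an RCC file. Used to build
# plain-text fixtures and by the CLI round-trip; the inverse of read_rcc()
# up to probe ordering.
write_rcc <- function(exp, sample_id, path) {
  stopifnot(inherits(exp, "ncx_experiment"))
  i <- match(sample_id, exp$samples$sample_id)
  if (is.na(i)) abort(paste0("Unknown sample ", sample_id))
  sm <- exp$samples[i, ]
  rev_map <- c(ENDOGENOUS = "Endogenous", BIO_POSITIVE = "Endogenous",
               HOUSEKEEPING = "Housekeeping", POSITIVE_SPIKE = "Positive",
               NEGATIVE_SPIKE = "Negative")
  codes <- exp$probes
  lines <- c(
    "<Header>", "FileVersion,1.7", "SoftwareVersion,ncountr", "</Header>", "",
    "<Sample_Attributes>", paste0("ID,", sample_id), "</Sample_Attributes>",
    "",
    "<Lane_Attributes>",
    paste0("ID,", sm$lane_id %||% i),
    paste0("FovCount,", sm$fov_count %||% ""),
    paste0("FovCounted,", sm$fov_counted %||% ""),
    paste0("BindingDensity,", sm$binding_density %||% ""),
    paste0("CartridgeID,", sm$cartridge %||% ""),
    "</Lane_Attributes>", "",
    "<Code_Summary>",
    "CodeClass,Name,Accession,Count",
    paste(rev_map[codes$class], codes$probe,
          ifelse(is.na(codes$accession), "", codes$accession),
          exp$counts[codes$probe, sample_id], sep = ","),
    "</Code_Summary>"
  )
  writeLines(lines, path)
  invisible(path)
}
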