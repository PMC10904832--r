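#' Read a protein FASTA file
#'
#' Plain headers of the form `>protein_id description` are supported; the
#' id is the first whitespace-delimited token.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names = protein ids).
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(
    strsplit(names(aa), "\\s+"), `[`, character(1), 1L
  )
  seqs
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector (names become headers).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Read an MGF peak-list file
#'
#' Parses BEGIN IONS / END IONS blocks with TITLE, PEPMASS, CHARGE headers
#' and `m/z intensity` peak lines. Peaks are returned sorted by m/z.
#'
#' @param path Path to an MGF file.
#' @return List of spectrum records; each has `spectrum_id`,
#'   `precursor_mz`, `precursor_charge`, and `peaks` (two-column matrix
#'   `mz`, `intensity`).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) stop("malformed MGF: unbalanced blocks")
  lapply(seq_along(begins), function(i) {
    blk <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    hdr <- grepl("=", blk, fixed = TRUE)
    keyval <- strsplit(blk[hdr], "=", fixed = TRUE)
    keys <- vapply(keyval, `[`, character(1), 1L)
    vals <- vapply(keyval, function(kv) paste(kv[-1], collapse = "="), "")
    peak_lines <- blk[!hdr & nzchar(blk)]
    peaks <- if (length(peak_lines)) {
      m <- do.call(rbind, lapply(strsplit(peak_lines, "[ \t]+"), function(p) {
        as.numeric(p[1:2])
      }))
      colnames(m) <- c("mz", "intensity")
      m[order(m[, "mz"]), , drop = FALSE]
    } else {
      matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("mz", "intensity")))
    }
    pepmass <- as.numeric(strsplit(vals[keys == "PEPMASS"], "[ \t]+")[[1]][1])
    charge <- vals[keys == "CHARGE"]
    charge <- if (length(charge)) {
      as.integer(sub("\\+$", "", charge))
    } else {
      NA_integer_
    }
    list(
      spectrum_id = if (any(keys == "TITLE")) vals[keys == "TITLE"][1] else
        sprintf("spectrum_%d", i),
      precursor_mz = pepmass,
      precursor_charge = charge,
      peaks = peaks
    )
  })
}

#' Write spectra to an MGF file
#'
#' @param spectra List of spectrum records as produced by [read_mgf()] or
#'   [synthesize_spectra()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", sp$spectrum_id),
      sprintf("PEPMASS=%.6f", sp$precursor_mz),
      sprintf("CHARGE=%d+", sp$precursor_charge),
      sprintf("%.6f %.4f", sp$peaks[, "mz"], sp$peaks[, "intensity"]),
      "END IONS"
    ), con)
  }
  invisible(path)
}

#' Read / write tab-separated tables with a fixed schema
#'
#' Thin wrappers standardising TSV I/O across the pipeline.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `read_tsv_table` returns a data frame; `write_tsv_table` returns
#'   `path` invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path,
    sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
  )
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path,
    sep = "\t", header = TRUE,
    stringsAsFactors = FALSE, check.names = FALSE
  )
}
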