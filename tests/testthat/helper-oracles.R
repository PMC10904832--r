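# Independent brute-force oracles used to freeze expected values.

# Tryptic digestion by exhaustive substring enumeration: a substring is a
# valid peptide iff its boundaries are cleavage sites (or sequence ends)
# and it contains at most max_missed internal cleavage sites.
oracle_digest <- function(sequence, max_missed, restrict_proline = TRUE) {
  n <- nchar(sequence)
  if (n == 0L) {
    return(data.frame(
      sequence = character(0), start = integer(0), end = integer(0),
      missed_cleavages = integer(0), stringsAsFactors = FALSE
    ))
  }
  aa <- strsplit(sequence, "")[[1]]
  is_site <- vapply(seq_len(n), function(p) {
    p < n && aa[p] %in% c("K", "R") &&
      (!restrict_proline || aa[p + 1] != "P")
  }, logical(1))
  out <- list()
  for (s in seq_len(n)) {
    if (s > 1L && !is_site[s - 1L]) next
    for (e in s:n) {
      if (e < n && !is_site[e]) next
      internal <- if (e > s) sum(is_site[s:(e - 1L)]) else 0L
      if (internal > max_missed) next
      out[[length(out) + 1L]] <- data.frame(
        sequence = substring(sequence, s, e), start = s, end = e,
        missed_cleavages = internal, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

random_protein <- function(len,
                           alphabet = c(
                             "A", "G", "L", "S", "V", "T", "E", "D",
                             "K", "R", "P", "Y", "M", "C", "F", "H"
                           )) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

canon_peptides <- function(d) {
  d <- d[order(d$start, d$end), c("sequence", "start", "end",
    "missed_cleavages"
  )]
  rownames(d) <- NULL
  d
}

# spectra of pure noise: no true peptide behind any peak
null_spectra <- function(n, n_peaks = 80, seed = 1L,
                         scan_range = c(350, 1800)) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    mz <- sort(stats::runif(n_peaks, 150, 2000))
    list(
      spectrum_id = sprintf("null_%d_%d", seed, i),
      precursor_mz = stats::runif(1, scan_range[1], scan_range[2]),
      precursor_charge = sample(2:3, 1),
      peaks = cbind(mz = mz, intensity = stats::runif(n_peaks, 1, 100))
    )
  })
}
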