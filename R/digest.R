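#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K and R; with `restrict_proline = TRUE` (the
#' default, matching common search-engine trypsin rules) a K/R followed by
#' proline is not cleaved. Every contiguous run of at most `max_missed + 1`
#' fully-cleaved fragments is emitted, so the 0-missed set tiles the
#' sequence and higher missed-cleavage counts add the concatenations.
#'
#' @param sequence Protein sequence (one-letter codes).
#' @param max_missed Maximum number of missed cleavages (>= 0), default 2.
#' @param restrict_proline If `TRUE`, do not cleave K/R-P bonds.
#' @param min_length,max_length Optional peptide-length bounds applied to
#'   the returned table (`NULL` = no bound).
#' @return `data.frame` with columns `sequence`, `start`, `end` (1-based
#'   inclusive protein coordinates) and `missed_cleavages`. Empty input
#'   gives a zero-row table.
#' @examples
#' digest("MKRTYK", max_missed = 2)
#' @export
digest <- function(sequence, max_missed = 2L, restrict_proline = TRUE,
                   min_length = NULL, max_length = NULL) {
  stopifnot(max_missed >= 0L)
  n <- nchar(sequence)
  empty <- data.frame(
    sequence = character(0), start = integer(0), end = integer(0),
    missed_cleavages = integer(0), stringsAsFactors = FALSE
  )
  if (n == 0L) {
    return(empty)
  }
  aa <- strsplit(sequence, "")[[1]]
  cut <- which(aa %in% c("K", "R"))
  if (restrict_proline && length(cut)) {
    cut <- cut[cut == n | aa[pmin(cut + 1L, n)] != "P"]
  }
  bounds <- unique(c(0L, cut[cut < n], n)) # fragment boundaries
  k <- length(bounds) - 1L # number of fully-cleaved fragments
  starts <- integer(0)
  ends <- integer(0)
  missed <- integer(0)
  for (i in seq_len(k)) {
    jmax <- min(k, i + max_missed)
    js <- i:jmax
    starts <- c(starts, rep.int(bounds[i] + 1L, length(js)))
    ends <- c(ends, bounds[js + 1L])
    missed <- c(missed, js - i)
  }
  out <- data.frame(
    sequence = substring(sequence, starts, ends),
    start = starts, end = ends, missed_cleavages = missed,
    stringsAsFactors = FALSE
  )
  len <- out$end - out$start + 1L
  keep <- rep(TRUE, nrow(out))
  if (!is.null(min_length)) keep <- keep & len >= min_length
  if (!is.null(max_length)) keep <- keep & len <= max_length
  out[keep, , drop = FALSE]
}

# residue-mass vector of a peptide with modification deltas applied;
# errors on non-standard residues
.residue_mass_vector <- function(sequence, mod_pos = integer(0),
                                 mod_deltas = numeric(0)) {
  rm <- residue_masses()
  aa <- strsplit(sequence, "")[[1]]
  res <- rm[aa]
  if (anyNA(res)) {
    stop(
      "non-standard residue(s): ",
      paste(unique(aa[is.na(res)]), collapse = ", ")
    )
  }
  if (length(mod_pos)) {
    if (any(mod_pos < 1L | mod_pos > length(res))) {
      stop("mod position out of range")
    }
    res[mod_pos] <- res[mod_pos] + mod_deltas
  }
  res
}

# fast path: b/y fragment m/z values as plain vectors (no data.frame)
.fragment_arrays <- function(res, max_charge) {
  n <- length(res)
  cum <- cumsum(res)
  idx <- seq_len(n - 1L)
  b_neutral <- cum[idx]
  y_neutral <- (cum[n] - cum[n - idx]) + water_mass()
  mz <- numeric(0)
  type <- character(0)
  index <- integer(0)
  charge <- integer(0)
  for (z in seq_len(max_charge)) {
    mz <- c(mz, mass_to_mz(b_neutral, z), mass_to_mz(y_neutral, z))
    type <- c(type, rep("b", n - 1L), rep("y", n - 1L))
    index <- c(index, idx, idx)
    charge <- c(charge, rep.int(z, 2L * (n - 1L)))
  }
  list(mz = mz, type = type, index = index, charge = charge)
}

#' Theoretical b/y fragment ions of a peptide
#'
#' Generates all b1..b(n-1) and y1..y(n-1) ions at charges
#' `1..max_charge`. Modification deltas are carried by every fragment that
#' contains the modified residue. Only b/y series are produced (HCD-typical).
#'
#' @param sequence Peptide sequence (length >= 2).
#' @param mod_pos Integer vector of modified positions (1-based within the
#'   peptide).
#' @param mod_deltas Numeric vector of mass shifts, parallel to `mod_pos`.
#' @param max_charge Highest fragment charge generated (default 2).
#' @return `data.frame` with columns `type` ("b"/"y"), `index`, `charge`,
#'   `mz`.
#' @examples
#' fragment_ions("PEPTIDE")
#' @export
fragment_ions <- function(sequence, mod_pos = integer(0),
                          mod_deltas = numeric(0), max_charge = 2L) {
  n <- nchar(sequence)
  if (n < 2L) stop("peptide must have length >= 2")
  stopifnot(length(mod_pos) == length(mod_deltas))
  res <- .residue_mass_vector(sequence, mod_pos, mod_deltas)
  fr <- .fragment_arrays(res, max_charge)
  data.frame(
    type = fr$type, index = fr$index, charge = fr$charge, mz = fr$mz,
    stringsAsFactors = FALSE
  )
}
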