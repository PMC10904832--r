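#' Search engine configuration
#'
#' Collects the tolerances, digestion rules and modification sets of the
#' modification-aware spectrum search. Defaults mirror the study's
#' database-search settings: 10 ppm precursor and 0.02 Da fragment
#' tolerance, trypsin with up to two missed cleavages, static
#' carbamidomethyl-C and dynamic Met-oxidation, Ad-Y and Bt-K, reverse
#' decoys and a 1% FDR threshold at PSM and protein level.
#'
#' @param precursor_tol_ppm Precursor tolerance in ppm.
#' @param fragment_tol Fragment tolerance in Da.
#' @param max_missed Maximum missed cleavages.
#' @param min_length,max_length Peptide length bounds for the search space.
#' @param modifications Named list of [mod_spec()] objects (static mods are
#'   always applied; dynamic mods enumerated combinatorially).
#' @param max_dynamic_per_peptide Cap on simultaneous dynamic mods.
#' @param max_variants_per_peptide Hard cap on enumerated forms per peptide
#'   (guards combinatorial explosion; truncations are counted).
#' @param fdr_threshold q-value threshold for reporting.
#' @param charges Precursor charge states considered.
#' @param fragment_max_charge Highest fragment charge generated.
#' @param restrict_proline Trypsin proline rule (no cleavage before P).
#' @return A `search_config` list.
#' @export
search_config <- function(precursor_tol_ppm = 10,
                          fragment_tol = 0.02,
                          max_missed = 2L,
                          min_length = 6L,
                          max_length = 45L,
                          modifications = default_modifications(),
                          max_dynamic_per_peptide = 3L,
                          max_variants_per_peptide = 256L,
                          fdr_threshold = 0.01,
                          charges = c(2L, 3L),
                          fragment_max_charge = 2L,
                          restrict_proline = TRUE) {
  stopifnot(
    precursor_tol_ppm > 0, fragment_tol > 0,
    fdr_threshold > 0, fdr_threshold <= 1
  )
  structure(
    list(
      precursor_tol_ppm = precursor_tol_ppm,
      fragment_tol = fragment_tol,
      max_missed = as.integer(max_missed),
      min_length = as.integer(min_length),
      max_length = as.integer(max_length),
      modifications = modifications,
      max_dynamic_per_peptide = as.integer(max_dynamic_per_peptide),
      max_variants_per_peptide = as.integer(max_variants_per_peptide),
      fdr_threshold = fdr_threshold,
      charges = as.integer(charges),
      fragment_max_charge = as.integer(fragment_max_charge),
      restrict_proline = restrict_proline
    ),
    class = "search_config"
  )
}

.static_mods <- function(config) {
  Filter(function(m) m$mode == "static", config$modifications)
}
.dynamic_mods <- function(config) {
  Filter(function(m) m$mode == "dynamic", config$modifications)
}

# all mod placements on one peptide: static at every target residue,
# dynamic subsets up to the configured cap. Operates on a pre-split
# residue vector and returns plain vectors (hot path of the index build).
.enumerate_variants <- function(aa, static, dynamic, max_dynamic,
                                max_variants) {
  st_pos <- integer(0)
  st_delta <- numeric(0)
  st_name <- character(0)
  for (m in static) {
    p <- if (m$target_residue == "any") seq_along(aa) else
      which(aa == m$target_residue)
    if (length(p)) {
      st_pos <- c(st_pos, p)
      st_delta <- c(st_delta, rep.int(m$delta_mass, length(p)))
      st_name <- c(st_name, rep.int(m$name, length(p)))
    }
  }
  dy_pos <- integer(0)
  dy_delta <- numeric(0)
  dy_name <- character(0)
  for (m in dynamic) {
    p <- if (m$target_residue == "any") seq_along(aa) else
      which(aa == m$target_residue)
    if (length(p)) {
      dy_pos <- c(dy_pos, p)
      dy_delta <- c(dy_delta, rep.int(m$delta_mass, length(p)))
      dy_name <- c(dy_name, rep.int(m$name, length(p)))
    }
  }
  t <- length(dy_pos)
  kmax <- min(max_dynamic, t)
  subsets <- list(integer(0))
  for (k in seq_len(kmax)) {
    subsets <- c(subsets, utils::combn(t, k, simplify = FALSE))
    if (length(subsets) > max_variants) break
  }
  truncated <- length(subsets) > max_variants
  if (truncated) subsets <- subsets[seq_len(max_variants)]
  nv <- length(subsets)
  mod_pos <- character(nv)
  mod_deltas <- character(nv)
  mod_names <- character(nv)
  n_dynamic <- integer(nv)
  delta_total <- numeric(nv)
  st_sum <- sum(st_delta)
  for (j in seq_len(nv)) {
    s <- subsets[[j]]
    pos <- c(st_pos, dy_pos[s])
    ord <- order(pos)
    mod_pos[j] <- paste(pos[ord], collapse = ";")
    mod_deltas[j] <- paste(signif(c(st_delta, dy_delta[s])[ord], 10),
      collapse = ";"
    )
    mod_names[j] <- paste(c(st_name, dy_name[s])[ord], collapse = ";")
    n_dynamic[j] <- length(s)
    delta_total[j] <- st_sum + sum(dy_delta[s])
  }
  list(
    mod_pos = mod_pos, mod_deltas = mod_deltas, mod_names = mod_names,
    n_dynamic = n_dynamic, delta_total = delta_total, truncated = truncated
  )
}

.decode_mods <- function(mod_pos, mod_deltas) {
  if (!nzchar(mod_pos)) {
    return(list(pos = integer(0), deltas = numeric(0)))
  }
  list(
    pos = as.integer(strsplit(mod_pos, ";", fixed = TRUE)[[1]]),
    deltas = as.numeric(strsplit(mod_deltas, ";", fixed = TRUE)[[1]])
  )
}

#' Build the target + decoy search space
#'
#' Digests every target protein and its full-sequence reversal (reverse
#' decoy, id prefix `DECOY_`), applies static modifications everywhere and
#' enumerates dynamic-modification placements, and indexes all candidate
#' peptidoforms by neutral monoisotopic mass for tolerance lookup. A
#' peptide sequence occurring in both a target and a decoy protein is
#' counted as target.
#'
#' @param fasta Either a path to a FASTA file or a named character vector
#'   of protein sequences.
#' @param config A [search_config()].
#' @return A `search_index` object (list with `candidates` sorted by mass,
#'   `occurrences` mapping peptide sequences to proteins, and `config`).
#' @export
build_search_space <- function(fasta, config = search_config()) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    read_fasta(fasta)
  } else {
    fasta
  }
  if (length(seqs) == 0L) stop("empty protein database")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("protein sequences must be named")
  }
  rev_seq <- vapply(
    strsplit(seqs, ""), function(a) paste(rev(a), collapse = ""), ""
  )
  all_seqs <- c(seqs, stats::setNames(rev_seq, paste0("DECOY_", names(seqs))))
  occ <- do.call(rbind, lapply(names(all_seqs), function(id) {
    d <- digest(all_seqs[[id]],
      max_missed = config$max_missed,
      restrict_proline = config$restrict_proline,
      min_length = config$min_length, max_length = config$max_length
    )
    if (nrow(d) == 0L) {
      return(NULL)
    }
    d$protein_id <- id
    d
  }))
  if (is.null(occ) || nrow(occ) == 0L) {
    stop("digestion produced no peptides in the configured length range")
  }
  occ$is_decoy <- startsWith(occ$protein_id, "DECOY_")
  # representative protein per unique sequence: targets win; lexicographic
  occ_ord <- occ[order(occ$sequence, occ$is_decoy, occ$protein_id), ]
  first <- !duplicated(occ_ord$sequence)
  seq_tab <- occ_ord[first, c("sequence", "protein_id", "start", "is_decoy")]
  decoy_status <- tapply(occ$is_decoy, occ$sequence, all)
  seq_tab$is_decoy <- as.logical(decoy_status[seq_tab$sequence])
  aa_split <- strsplit(seq_tab$sequence, "")
  rm <- residue_masses()
  base_mass <- vapply(aa_split, function(a) sum(rm[a]), numeric(1)) +
    water_mass()
  static <- .static_mods(config)
  dynamic <- .dynamic_mods(config)
  n_trunc <- 0L
  var_list <- vector("list", nrow(seq_tab))
  for (i in seq_len(nrow(seq_tab))) {
    v <- .enumerate_variants(
      aa_split[[i]], static, dynamic,
      config$max_dynamic_per_peptide, config$max_variants_per_peptide
    )
    if (v$truncated) n_trunc <- n_trunc + 1L
    var_list[[i]] <- v
  }
  nvar <- vapply(var_list, function(v) length(v$n_dynamic), 0L)
  seq_idx <- rep.int(seq_len(nrow(seq_tab)), nvar)
  cand <- data.frame(
    mod_pos = unlist(lapply(var_list, `[[`, "mod_pos")),
    mod_deltas = unlist(lapply(var_list, `[[`, "mod_deltas")),
    mod_names = unlist(lapply(var_list, `[[`, "mod_names")),
    n_dynamic = unlist(lapply(var_list, `[[`, "n_dynamic")),
    delta_total = unlist(lapply(var_list, `[[`, "delta_total")),
    sequence = seq_tab$sequence[seq_idx],
    protein_id = seq_tab$protein_id[seq_idx],
    start = seq_tab$start[seq_idx],
    is_decoy = seq_tab$is_decoy[seq_idx],
    stringsAsFactors = FALSE
  )
  cand$mass <- base_mass[seq_idx] + cand$delta_total
  cand <- cand[order(cand$mass), ]
  rownames(cand) <- NULL
  structure(
    list(
      candidates = cand,
      occurrences = occ[, c("sequence", "protein_id", "start", "is_decoy")],
      n_truncated_peptides = n_trunc,
      config = config
    ),
    class = "search_index"
  )
}

#' @export
print.search_index <- function(x, ...) {
  cat(sprintf(
    "<search_index> %d candidate peptidoforms (%d decoy) from %d peptide occurrences\n",
    nrow(x$candidates), sum(x$candidates$is_decoy), nrow(x$occurrences)
  ))
  invisible(x)
}

# match theoretical fragments against a sorted peak list; returns matched
# fragment flags and the unique matched peak indices
.match_peaks <- function(frag_mz, peak_mz, tol) {
  if (length(peak_mz) == 0L) {
    return(list(hit = logical(length(frag_mz)), peaks = integer(0)))
  }
  idx <- findInterval(frag_mz, peak_mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, length(peak_mz))
  d_lo <- abs(frag_mz - peak_mz[lo])
  d_hi <- abs(frag_mz - peak_mz[hi])
  best <- ifelse(d_hi < d_lo, hi, lo)
  d <- pmin(d_lo, d_hi)
  hit <- d <= tol
  list(hit = hit, peaks = unique(best[hit]))
}

#' Score one peptide-spectrum match
#'
#' Hyperscore-style score: the log-factorials of the number of matched b-
#' and y-fragments plus the log of (1 + summed matched peak intensity).
#' Deterministic, increasing in matched fragment count and matched
#' intensity, and exactly 0 when no fragment matches a peak.
#'
#' @param spectrum A spectrum record (list with `peaks` matrix).
#' @param sequence Candidate peptide sequence.
#' @param mod_pos,mod_deltas Modification positions (1-based in peptide)
#'   and mass shifts.
#' @param config A [search_config()].
#' @return List with `score`, `n_b`, `n_y`, `matched_peak_count`,
#'   `matched_intensity`.
#' @export
score_psm <- function(spectrum, sequence, mod_pos = integer(0),
                      mod_deltas = numeric(0), config = search_config()) {
  res <- .residue_mass_vector(sequence, mod_pos, mod_deltas)
  frags <- .fragment_arrays(res, config$fragment_max_charge)
  peaks <- spectrum$peaks
  m <- .match_peaks(frags$mz, peaks[, "mz"], config$fragment_tol)
  # a fragment (type, index) counts once even if seen at both charges
  hit_key <- unique(paste0(frags$type, frags$index)[m$hit])
  n_b <- sum(startsWith(hit_key, "b"))
  n_y <- sum(startsWith(hit_key, "y"))
  intensity <- sum(peaks[m$peaks, "intensity"])
  list(
    score = lfactorial(n_b) + lfactorial(n_y) + log1p(intensity),
    n_b = n_b, n_y = n_y,
    matched_peak_count = length(m$peaks),
    matched_intensity = intensity
  )
}

# target-decoy q-values: FDR(s) = #decoy / #target at score >= s,
# monotonized from the bottom of the ranked list
.compute_qvalues <- function(score, is_decoy) {
  ord <- order(-score, !is_decoy) # decoys first at ties (conservative)
  d <- cumsum(is_decoy[ord])
  t <- cumsum(!is_decoy[ord])
  r <- d / pmax(t, 1L)
  q <- rev(cummin(rev(pmin(r, 1))))
  out <- numeric(length(score))
  out[ord] <- q
  out
}

#' Search spectra against an indexed candidate database
#'
#' For each spectrum, candidates within the precursor tolerance of the
#' observed neutral mass are scored with [score_psm()]; the best-scoring
#' candidate is retained (ties broken by fewer dynamic modifications, then
#' smaller absolute precursor error, then lexicographic sequence).
#' q-values are estimated by target-decoy competition over the best PSMs.
#' Spectra whose precursor charge is outside `config$charges` are skipped
#' and counted in the `n_skipped` attribute.
#'
#' @param spectra List of spectrum records ([read_mgf()] output).
#' @param index A `search_index` from [build_search_space()].
#' @param config A [search_config()]; defaults to the index's config.
#' @return A `psm_table` data frame (one row per matched spectrum) with
#'   q-values; attribute `n_skipped` counts skipped spectra.
#' @export
search_spectra <- function(spectra, index, config = index$config) {
  cand <- index$candidates
  masses <- cand$mass
  tol_f <- config$fragment_tol
  n_skipped <- 0L
  rows <- vector("list", length(spectra))
  for (si in seq_along(spectra)) {
    sp <- spectra[[si]]
    z <- sp$precursor_charge
    if (is.na(z) || !(z %in% config$charges)) {
      n_skipped <- n_skipped + 1L
      next
    }
    neutral <- mz_to_mass(sp$precursor_mz, z)
    tol <- neutral * config$precursor_tol_ppm * 1e-6
    lo <- findInterval(neutral - tol, masses) + 1L
    hi <- findInterval(neutral + tol, masses)
    if (hi < lo) next
    ids <- lo:hi
    best <- NULL
    for (ci in ids) {
      mods <- .decode_mods(cand$mod_pos[ci], cand$mod_deltas[ci])
      sc <- score_psm(sp, cand$sequence[ci], mods$pos, mods$deltas, config)
      err <- abs(neutral - cand$mass[ci]) / neutral * 1e6
      rec <- list(
        ci = ci, score = sc$score, n_dynamic = cand$n_dynamic[ci],
        err = err, sequence = cand$sequence[ci],
        matched_peak_count = sc$matched_peak_count,
        matched_intensity = sc$matched_intensity
      )
      if (is.null(best) ||
        rec$score > best$score ||
        (rec$score == best$score && (
          rec$n_dynamic < best$n_dynamic ||
            (rec$n_dynamic == best$n_dynamic && (
              rec$err < best$err ||
                (rec$err == best$err && rec$sequence < best$sequence)
            ))
        ))) {
        best <- rec
      }
    }
    ci <- best$ci
    rows[[si]] <- data.frame(
      spectrum_id = sp$spectrum_id,
      sequence = cand$sequence[ci],
      protein_id = cand$protein_id[ci],
      start = cand$start[ci],
      is_decoy = cand$is_decoy[ci],
      precursor_charge = z,
      precursor_error_ppm = best$err,
      score = best$score,
      n_dynamic = cand$n_dynamic[ci],
      mod_pos = cand$mod_pos[ci],
      mod_names = cand$mod_names[ci],
      mod_deltas = cand$mod_deltas[ci],
      matched_peak_count = best$matched_peak_count,
      peptide_intensity = best$matched_intensity,
      stringsAsFactors = FALSE
    )
  }
  psms <- do.call(rbind, rows)
  if (is.null(psms)) {
    psms <- data.frame(
      spectrum_id = character(0), sequence = character(0),
      protein_id = character(0), start = integer(0),
      is_decoy = logical(0), precursor_charge = integer(0),
      precursor_error_ppm = numeric(0), score = numeric(0),
      n_dynamic = integer(0), mod_pos = character(0),
      mod_names = character(0), mod_deltas = character(0),
      matched_peak_count = integer(0), peptide_intensity = numeric(0),
      stringsAsFactors = FALSE
    )
  }
  psms$q_value <- if (nrow(psms)) {
    .compute_qvalues(psms$score, psms$is_decoy)
  } else {
    numeric(0)
  }
  attr(psms, "n_skipped") <- n_skipped
  class(psms) <- c("psm_table", "data.frame")
  psms
}

#' Accepted identifications from a PSM table
#'
#' Target PSMs at `q <= fdr_threshold`.
#'
#' @param psms A `psm_table`.
#' @param fdr_threshold q-value cutoff (default 0.01).
#' @return Subset of `psms`.
#' @export
accepted_psms <- function(psms, fdr_threshold = 0.01) {
  psms[!psms$is_decoy & psms$q_value <= fdr_threshold, , drop = FALSE]
}

#' Parsimonious protein inference
#'
#' Greedy set-cover over confidently identified peptides: the protein
#' explaining the most remaining peptides is picked as a Master (ties
#' broken by lexicographic protein id) and its peptides are assigned to it
#' (razor rule). Group members are proteins whose identified peptide set is
#' a subset of the master's. Protein-level q-values are estimated by picked
#' target-decoy pairing (each target protein competes with its reversed
#' decoy; the higher-scoring of the pair is kept) on max-PSM-score protein
#' scores.
#'
#' @param psms A `psm_table`.
#' @param index The `search_index` used for the search (supplies the
#'   peptide-to-protein map).
#' @param fdr_threshold PSM-level q-value cutoff for peptides entering
#'   inference.
#' @return A `protein_groups` data frame with one row per master protein:
#'   `master_protein_id`, `member_ids`, `peptides`, `n_peptides`, `score`,
#'   `is_decoy`, `q_value`.
#' @export
infer_proteins <- function(psms, index, fdr_threshold = 0.01) {
  conf <- psms[psms$q_value <= fdr_threshold, , drop = FALSE]
  empty <- data.frame(
    master_protein_id = character(0), member_ids = character(0),
    peptides = character(0), n_peptides = integer(0), score = numeric(0),
    is_decoy = logical(0), q_value = numeric(0), stringsAsFactors = FALSE
  )
  if (nrow(conf) == 0L) {
    class(empty) <- c("protein_groups", "data.frame")
    return(empty)
  }
  pep_score <- tapply(conf$score, conf$sequence, max)
  peptides <- names(pep_score)
  occ <- index$occurrences
  occ <- occ[occ$sequence %in% peptides, , drop = FALSE]
  prot_peps <- split(occ$sequence, occ$protein_id)
  prot_peps <- lapply(prot_peps, unique)
  remaining <- peptides
  groups <- list()
  while (length(remaining)) {
    cover <- vapply(prot_peps, function(p) sum(p %in% remaining), 0L)
    cover <- cover[cover > 0L]
    if (!length(cover)) break
    best <- sort(names(cover)[cover == max(cover)])[1]
    razor <- intersect(prot_peps[[best]], remaining)
    members <- names(prot_peps)[vapply(
      prot_peps,
      function(p) length(p) > 0L && all(p %in% prot_peps[[best]]) &&
        length(intersect(p, razor)) > 0L,
      logical(1)
    )]
    groups[[best]] <- list(peptides = razor, members = sort(members))
    remaining <- setdiff(remaining, razor)
  }
  out <- data.frame(
    master_protein_id = names(groups),
    member_ids = vapply(groups, function(g) {
      paste(g$members, collapse = ";")
    }, ""),
    peptides = vapply(groups, function(g) {
      paste(sort(g$peptides), collapse = ";")
    }, ""),
    n_peptides = vapply(groups, function(g) length(g$peptides), 0L),
    score = vapply(groups, function(g) max(pep_score[g$peptides]), 0),
    stringsAsFactors = FALSE
  )
  out$is_decoy <- startsWith(out$master_protein_id, "DECOY_")
  # picked pairing: target vs its own reversed decoy, better score survives
  base_id <- sub("^DECOY_", "", out$master_protein_id)
  keep <- rep(TRUE, nrow(out))
  for (b in unique(base_id[duplicated(base_id)])) {
    ix <- which(base_id == b)
    keep[ix] <- seq_along(ix) == which.max(out$score[ix])
  }
  picked <- out[keep, , drop = FALSE]
  picked$q_value <- .compute_qvalues(picked$score, picked$is_decoy)
  picked <- picked[order(-picked$score), ]
  rownames(picked) <- NULL
  class(picked) <- c("protein_groups", "data.frame")
  picked
}

#' Label-free quantification by peptide-intensity averaging
#'
#' Protein intensity is the arithmetic mean of its razor peptides'
#' intensities; a peptide's intensity is the summed matched peak intensity
#' of its PSMs. Groups without quantifiable peptides get `NA`, never zero.
#'
#' @param psms A `psm_table`.
#' @param groups A `protein_groups` table from [infer_proteins()].
#' @param fdr_threshold PSM q-value cutoff.
#' @return Data frame `protein_id`, `n_peptides`, `intensity`.
#' @export
lfq <- function(psms, groups, fdr_threshold = 0.01) {
  conf <- accepted_psms(psms, fdr_threshold)
  pep_int <- tapply(conf$peptide_intensity, conf$sequence, sum)
  tgt <- groups[!groups$is_decoy, , drop = FALSE]
  ints <- vapply(seq_len(nrow(tgt)), function(i) {
    peps <- strsplit(tgt$peptides[i], ";", fixed = TRUE)[[1]]
    v <- pep_int[peps]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  data.frame(
    protein_id = tgt$master_protein_id,
    n_peptides = tgt$n_peptides,
    intensity = ints,
    stringsAsFactors = FALSE
  )
}
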