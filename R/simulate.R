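#' Default compartment mixture for simulated proteomes
#'
#' Proportions of the topology compartments emulating a cell-wide proteome
#' view of the ER-mitochondria interface: ER lumen, ER membrane (ERM),
#' outer/inner mitochondrial membrane (OMM/IMM), cytosol, mitochondrial
#' matrix, and everything else.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_compartment_mix <- function() {
  c(
    ER_lumen = 0.10, ERM = 0.12, OMM = 0.08, IMM = 0.08,
    cytosol = 0.40, matrix = 0.12, other = 0.10
  )
}

# human-like amino-acid background frequencies (normalised in use)
.aa_frequencies <- c(
  A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023,
  E = 0.071, Q = 0.048, G = 0.066, H = 0.026, I = 0.043,
  L = 0.100, K = 0.057, M = 0.021, F = 0.037, P = 0.063,
  S = 0.083, T = 0.054, W = 0.012, Y = 0.027, V = 0.060
)

# membrane sidedness faces by compartment, in alternation order
.membrane_faces <- list(
  ERM = c("cytosol", "lumen"),
  OMM = c("cytosol", "IMS"),
  IMM = c("matrix", "IMS")
)

.soluble_side <- c(
  ER_lumen = "lumen", cytosol = "cytosol", matrix = "matrix", other = "na"
)

# random transmembrane topology: alternating loops and 21-residue
# membrane-buried helices
.make_sidedness <- function(n, compartment) {
  if (!compartment %in% names(.membrane_faces)) {
    return(rep(.soluble_side[[compartment]], n))
  }
  faces <- .membrane_faces[[compartment]]
  tmd_len <- 21L
  min_loop <- 5L
  n_tmd <- sample(1:3, 1L)
  while (n_tmd > 1L && n < n_tmd * tmd_len + (n_tmd + 1L) * min_loop) {
    n_tmd <- n_tmd - 1L
  }
  if (n < tmd_len + 2L * min_loop) {
    # too short for a helix plus loops: single face
    return(rep(faces[sample(1:2, 1L)], n))
  }
  extra <- n - n_tmd * tmd_len - (n_tmd + 1L) * min_loop
  loops <- min_loop +
    as.integer(stats::rmultinom(1L, extra, rep(1, n_tmd + 1L)))
  side0 <- sample(0:1, 1L)
  side <- character(0)
  for (i in seq_len(n_tmd)) {
    side <- c(
      side,
      rep(faces[1L + (side0 + i) %% 2L], loops[i]),
      rep("membrane", tmd_len)
    )
  }
  c(side, rep(faces[1L + (side0 + n_tmd + 1L) %% 2L], loops[n_tmd + 1L]))
}

#' Generate a topology-annotated synthetic proteome
#'
#' Each protein receives a random sequence (human-like residue
#' frequencies), a compartment, per-residue membrane sidedness (membrane
#' proteins get 1-3 random 21-residue transmembrane helices with
#' alternating faces), a log-normal abundance, a distance to the
#' ER-mitochondria junction (arbitrary units; exponentially distributed,
#' closer for ERM/OMM proteins), and - with small probability, emulating
#' endogenously biotinylated carboxylases - endogenous biotin lysines.
#' The annotation table maps each protein to the GOCC-style class
#' \{ER, mitochondria, both, other\}.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param compartment_mix Named proportions over compartments (must sum
#'   to 1).
#' @param seed Integer seed; output is fully reproducible.
#' @param length_meanlog,length_sdlog Log-normal sequence-length
#'   parameters.
#' @param endogenous_biotin_frac Fraction of matrix/cytosol proteins with
#'   endogenous biotin sites.
#' @param both_annotation_frac Fraction of ER/mito proteins annotated
#'   "both".
#' @return An `annotated_proteome` data frame with list-columns
#'   `sidedness` and `endogenous_biotin`; the annotation table is in the
#'   `annotation` column.
#' @export
generate_proteome <- function(n_proteins,
                              compartment_mix = default_compartment_mix(),
                              seed = 1L,
                              length_meanlog = log(110),
                              length_sdlog = 0.35,
                              endogenous_biotin_frac = 0.01,
                              both_annotation_frac = 0.05) {
  stopifnot(n_proteins >= 1L)
  if (any(compartment_mix < 0) || abs(sum(compartment_mix) - 1) > 1e-8) {
    stop("compartment_mix must be non-negative proportions summing to 1")
  }
  known <- c("ER_lumen", "ERM", "OMM", "IMM", "cytosol", "matrix", "other")
  if (!all(names(compartment_mix) %in% known)) {
    stop("unknown compartment in compartment_mix")
  }
  set.seed(seed)
  compartment <- sample(names(compartment_mix), n_proteins,
    replace = TRUE, prob = compartment_mix
  )
  len <- pmin(pmax(round(stats::rlnorm(
    n_proteins, length_meanlog, length_sdlog
  )), 40L), 400L)
  aa <- names(.aa_frequencies)
  p_aa <- .aa_frequencies / sum(.aa_frequencies)
  sequences <- vapply(len, function(n) {
    paste(sample(aa, n, replace = TRUE, prob = p_aa), collapse = "")
  }, "")
  sidedness <- lapply(seq_len(n_proteins), function(i) {
    .make_sidedness(len[i], compartment[i])
  })
  abundance <- stats::rlnorm(n_proteins, meanlog = 0, sdlog = 1)
  near <- compartment %in% c("ERM", "OMM")
  distance <- ifelse(near, stats::rexp(n_proteins, 1),
    stats::rexp(n_proteins, 0.25)
  )
  endo <- vector("list", n_proteins)
  carrier <- compartment %in% c("matrix", "cytosol") &
    stats::runif(n_proteins) < endogenous_biotin_frac
  for (i in which(carrier)) {
    kpos <- which(strsplit(sequences[i], "")[[1]] == "K")
    if (length(kpos)) {
      endo[[i]] <- sort(sample(kpos, min(length(kpos), sample(1:3, 1L))))
    }
  }
  endo[!vapply(endo, is.integer, TRUE)] <- list(integer(0))
  annotation <- ifelse(
    compartment %in% c("ER_lumen", "ERM"), "ER",
    ifelse(compartment %in% c("OMM", "IMM", "matrix"), "mitochondria",
      "other"
    )
  )
  dual_ann <- annotation != "other" &
    stats::runif(n_proteins) < both_annotation_frac
  annotation[dual_ann] <- "both"
  out <- data.frame(
    protein_id = sprintf("P%04d", seq_len(n_proteins)),
    compartment = compartment,
    length = len,
    abundance = abundance,
    distance_to_junction = distance,
    annotation = annotation,
    stringsAsFactors = FALSE
  )
  out$sequence <- sequences
  out$sidedness <- sidedness
  out$endogenous_biotin <- endo
  class(out) <- c("annotated_proteome", "data.frame")
  out
}

#' @export
print.annotated_proteome <- function(x, ...) {
  cat(sprintf(
    "<annotated_proteome> %d proteins (%s)\n",
    nrow(x),
    paste(names(table(x$compartment)), table(x$compartment),
      sep = ":", collapse = " "
    )
  ))
  invisible(x)
}

#' Long-format topology table of a simulated proteome
#'
#' One row per residue with its sidedness and endogenous-biotin flag;
#' this is the table the topology validator consumes.
#'
#' @param proteome An `annotated_proteome`.
#' @return Data frame `protein_id`, `position`, `residue`, `sidedness`,
#'   `endogenous_biotin`.
#' @export
topology_table <- function(proteome) {
  do.call(rbind, lapply(seq_len(nrow(proteome)), function(i) {
    aa <- strsplit(proteome$sequence[i], "")[[1]]
    data.frame(
      protein_id = proteome$protein_id[i],
      position = seq_along(aa),
      residue = aa,
      sidedness = proteome$sidedness[[i]],
      endogenous_biotin = seq_along(aa) %in% proteome$endogenous_biotin[[i]],
      stringsAsFactors = FALSE
    )
  }))
}

#' Labeling model parameters
#'
#' Per-replicate Bernoulli labeling probabilities for each exposed
#' residue, the junction distance-decay weight, and per-protein replicate
#' dropout. All probabilities are per exposed residue per replicate.
#'
#' @param p_bt Biotinylation probability of a cytosol-facing lysine (before
#'   distance weighting).
#' @param p_ad Ad-labeling probability of a lumen-facing tyrosine.
#' @param leakage_p Ad leakage probability on junction-proximal
#'   cytosol-facing tyrosines of OMM/ERM proteins (before distance
#'   weighting).
#' @param cccp_ims_p Ad probability on IMS-facing tyrosines under CCCP.
#' @param distance_decay Monotone non-increasing weight function of
#'   junction distance with `distance_decay(0) == 1`.
#' @param junction_cutoff Maximum junction distance at which Ad leakage can
#'   occur (the declared leakage exception class).
#' @param replicate_dropout Per-protein per-replicate probability that all
#'   of a protein's enzymatic labeling is missing.
#' @return A `labeling_model` list.
#' @export
labeling_model <- function(p_bt = 0.6, p_ad = 0.6, leakage_p = 0.5,
                           cccp_ims_p = 0.5,
                           distance_decay = function(d) exp(-d),
                           junction_cutoff = 2,
                           replicate_dropout = 0.1) {
  probs <- c(p_bt, p_ad, leakage_p, cccp_ims_p, replicate_dropout)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(distance_decay(0) - 1) > 1e-9) {
    stop("distance_decay(0) must be 1")
  }
  structure(
    list(
      p_bt = p_bt, p_ad = p_ad, leakage_p = leakage_p,
      cccp_ims_p = cccp_ims_p, distance_decay = distance_decay,
      junction_cutoff = junction_cutoff,
      replicate_dropout = replicate_dropout
    ),
    class = "labeling_model"
  )
}

# map each labeled residue to the tryptic peptide used downstream: the
# containing peptide with the fewest missed cleavages (then smallest
# start) inside the length window; detectability additionally requires a
# 2+ or 3+ precursor inside the scan range
.event_peptide_map <- function(proteome, min_length, max_length,
                               max_missed, restrict_proline, scan_range,
                               mods) {
  cam <- mods$Carbamidomethyl$delta_mass
  deltas <- c(Bt = mods$Bt$delta_mass, Ad = mods$Ad$delta_mass)
  maps <- list()
  for (i in seq_len(nrow(proteome))) {
    d <- digest(proteome$sequence[i],
      max_missed = max_missed,
      restrict_proline = restrict_proline,
      min_length = min_length, max_length = max_length
    )
    maps[[proteome$protein_id[i]]] <- d
  }
  function(protein_id, position, label) {
    d <- maps[[protein_id]]
    hit <- d[d$start <= position & d$end >= position, , drop = FALSE]
    if (nrow(hit) == 0L) {
      return(NULL)
    }
    hit <- hit[order(hit$missed_cleavages, hit$start), , drop = FALSE]
    pep <- hit[1L, ]
    n_c <- lengths(regmatches(pep$sequence, gregexpr("C", pep$sequence)))
    mass <- peptide_neutral_mass(pep$sequence) + n_c * cam +
      deltas[[label]]
    mzs <- mass_to_mz(mass, 2:3)
    pep$detectable <- any(mzs >= scan_range[1] & mzs <= scan_range[2])
    pep
  }
}

#' Simulate enzyme labeling events
#'
#' Draws per-replicate labeling events under the topology rules of the
#' dual-enzyme system: Bt only on cytosol-facing lysines (weighted by the
#' distance decay to the OMM-anchored ligase), Ad on lumen-facing
#' tyrosines, Ad leakage on junction-proximal cytosol-facing tyrosines of
#' OMM/ERM proteins, and - under CCCP only - Ad on IMS-facing tyrosines.
#' Endogenous biotin lysines appear as Bt background in every replicate.
#' Each event is mapped to its tryptic peptide and flagged detectable if
#' that peptide lies in the 6-45 residue window with a 2+/3+ precursor
#' inside the scan range. A protein's ground-truth status for an arm is
#' "reliable" when it has detectable events in at least `min_reps`
#' replicates; dual status requires both arms.
#'
#' @param proteome An `annotated_proteome`.
#' @param condition `"NT"` or `"CCCP"`.
#' @param model A [labeling_model()].
#' @param n_replicates Number of biological replicates (default 3).
#' @param seed Integer seed.
#' @param min_reps Replicates required for ground-truth reliability.
#' @param min_length,max_length,max_missed,restrict_proline,scan_range
#'   Digestion/acquisition settings used for detectability (keep equal to
#'   the search configuration).
#' @param modifications Modification set supplying the label masses.
#' @return A `labeling_truth` list with `events` (one row per label event,
#'   with peptide coordinates and `detectable` flag) and `truth` (one row
#'   per protein: detectable-replicate counts per arm and the dual flag).
#' @export
simulate_labeling <- function(proteome, condition = c("NT", "CCCP"),
                              model = labeling_model(),
                              n_replicates = 3L, seed = 1L,
                              min_reps = 2L,
                              min_length = 6L, max_length = 45L,
                              max_missed = 2L, restrict_proline = TRUE,
                              scan_range = c(350, 1800),
                              modifications = default_modifications()) {
  condition <- match.arg(condition)
  stopifnot(n_replicates >= 1L)
  set.seed(seed)
  pepmap <- .event_peptide_map(
    proteome, min_length, max_length, max_missed, restrict_proline,
    scan_range, modifications
  )
  rows <- list()
  for (i in seq_len(nrow(proteome))) {
    aa <- strsplit(proteome$sequence[i], "")[[1]]
    side <- proteome$sidedness[[i]]
    comp <- proteome$compartment[i]
    dist <- proteome$distance_to_junction[i]
    w <- model$distance_decay(dist)
    bt_pos <- which(aa == "K" & side == "cytosol")
    ad_lumen <- which(aa == "Y" & side == "lumen")
    ad_leak <- if (comp %in% c("OMM", "ERM") &&
      dist <= model$junction_cutoff) {
      which(aa == "Y" & side == "cytosol")
    } else {
      integer(0)
    }
    ad_ims <- if (condition == "CCCP") {
      which(aa == "Y" & side == "IMS")
    } else {
      integer(0)
    }
    endo <- proteome$endogenous_biotin[[i]]
    for (r in seq_len(n_replicates)) {
      dropped <- stats::runif(1) < model$replicate_dropout
      draw <- function(pos, p, class, label) {
        if (dropped || !length(pos) || p <= 0) {
          return(NULL)
        }
        hit <- pos[stats::runif(length(pos)) < p]
        if (!length(hit)) {
          return(NULL)
        }
        data.frame(
          protein_id = proteome$protein_id[i], replicate = r,
          position = hit, residue = aa[hit], label = label,
          class = class, stringsAsFactors = FALSE
        )
      }
      rows <- c(rows, list(
        draw(bt_pos, model$p_bt * w, "topology", "Bt"),
        draw(ad_lumen, model$p_ad, "topology", "Ad"),
        draw(ad_leak, model$leakage_p * w, "leakage", "Ad"),
        draw(ad_ims, model$cccp_ims_p, "cccp_ims", "Ad")
      ))
      if (length(endo)) {
        rows <- c(rows, list(data.frame(
          protein_id = proteome$protein_id[i], replicate = r,
          position = endo, residue = aa[endo], label = "Bt",
          class = "endogenous", stringsAsFactors = FALSE
        )))
      }
    }
  }
  events <- do.call(rbind, rows)
  if (is.null(events)) {
    events <- data.frame(
      protein_id = character(0), replicate = integer(0),
      position = integer(0), residue = character(0),
      label = character(0), class = character(0), stringsAsFactors = FALSE
    )
  }
  if (nrow(events)) {
    peps <- lapply(seq_len(nrow(events)), function(k) {
      pepmap(events$protein_id[k], events$position[k], events$label[k])
    })
    has_pep <- !vapply(peps, is.null, TRUE)
    events$pep_start <- NA_integer_
    events$pep_end <- NA_integer_
    events$pep_sequence <- NA_character_
    events$detectable <- FALSE
    if (any(has_pep)) {
      pd <- do.call(rbind, peps[has_pep])
      events$pep_start[has_pep] <- pd$start
      events$pep_end[has_pep] <- pd$end
      events$pep_sequence[has_pep] <- pd$sequence
      events$detectable[has_pep] <- pd$detectable
    }
  } else {
    events$pep_start <- integer(0)
    events$pep_end <- integer(0)
    events$pep_sequence <- character(0)
    events$detectable <- logical(0)
  }
  det <- events[events$detectable, , drop = FALSE]
  count_reps <- function(label) {
    sub <- det[det$label == label, c("protein_id", "replicate")]
    if (!nrow(sub)) {
      return(stats::setNames(integer(0), character(0)))
    }
    tapply(sub$replicate, sub$protein_id, function(r) length(unique(r)))
  }
  bt_reps <- count_reps("Bt")
  ad_reps <- count_reps("Ad")
  truth <- data.frame(
    protein_id = proteome$protein_id,
    condition = condition,
    bt_reps = as.integer(bt_reps[proteome$protein_id]),
    ad_reps = as.integer(ad_reps[proteome$protein_id]),
    stringsAsFactors = FALSE
  )
  truth$bt_reps[is.na(truth$bt_reps)] <- 0L
  truth$ad_reps[is.na(truth$ad_reps)] <- 0L
  truth$bt_reliable <- truth$bt_reps >= min_reps
  truth$ad_reliable <- truth$ad_reps >= min_reps
  truth$dual <- truth$bt_reliable & truth$ad_reliable
  structure(
    list(
      events = events, truth = truth, condition = condition,
      n_replicates = n_replicates, min_reps = min_reps, model = model
    ),
    class = "labeling_truth"
  )
}

#' @export
print.labeling_truth <- function(x, ...) {
  cat(sprintf(
    "<labeling_truth> %s: %d events on %d proteins; %d ground-truth dual\n",
    x$condition, nrow(x$events), length(unique(x$events$protein_id)),
    sum(x$truth$dual)
  ))
  invisible(x)
}

#' Simulate affinity-bead enrichment
#'
#' Builds the per-replicate peptide pools of one enrichment arm.
#' The SA (streptavidin) arm retains Bt-carrying peptides - including
#' endogenous-biotin background - with probability `capture_eff`; the
#' CB7 (cucurbit[7]uril) arm symmetrically retains Ad-carrying peptides.
#' Unlabeled tryptic peptides of every protein wash into the pool at
#' `background_rate`.
#'
#' @param proteome An `annotated_proteome`.
#' @param labeling A `labeling_truth` from [simulate_labeling()].
#' @param arm `"SA"` or `"CB7"`.
#' @param capture_eff Capture efficiency in `[0, 1]`.
#' @param background_rate Per-peptide nonspecific binding rate in `[0, 1]`.
#' @param seed Integer seed.
#' @param min_length,max_length,restrict_proline Digestion window for the
#'   background peptides.
#' @return Data frame, one row per pooled peptide instance: `protein_id`,
#'   `replicate`, `pep_sequence`, `pep_start`, `pep_end`, `label`
#'   (`NA` for background), `label_pos` (protein coordinate), `origin`
#'   (`labeled`/`endogenous`/`background`), `abundance`, `arm`.
#' @export
simulate_enrichment <- function(proteome, labeling,
                                arm = c("SA", "CB7"),
                                capture_eff = 0.9,
                                background_rate = 0.01,
                                seed = 1L,
                                min_length = 6L, max_length = 45L,
                                restrict_proline = TRUE) {
  arm <- match.arg(arm)
  stopifnot(
    capture_eff >= 0, capture_eff <= 1,
    background_rate >= 0, background_rate <= 1
  )
  set.seed(seed)
  want_label <- if (arm == "SA") "Bt" else "Ad"
  ev <- labeling$events
  ev <- ev[ev$label == want_label & !is.na(ev$pep_start), , drop = FALSE]
  keep <- stats::runif(nrow(ev)) < capture_eff
  ev <- ev[keep, , drop = FALSE]
  abun <- stats::setNames(proteome$abundance, proteome$protein_id)
  labeled <- if (nrow(ev)) {
    data.frame(
      protein_id = ev$protein_id, replicate = ev$replicate,
      pep_sequence = ev$pep_sequence, pep_start = ev$pep_start,
      pep_end = ev$pep_end, label = ev$label, label_pos = ev$position,
      origin = ifelse(ev$class == "endogenous", "endogenous", "labeled"),
      abundance = abun[ev$protein_id],
      stringsAsFactors = FALSE
    )
  } else {
    NULL
  }
  bg <- NULL
  if (background_rate > 0) {
    bg_list <- list()
    for (i in seq_len(nrow(proteome))) {
      d <- digest(proteome$sequence[i],
        max_missed = 0L,
        restrict_proline = restrict_proline,
        min_length = min_length, max_length = max_length
      )
      if (!nrow(d)) next
      for (r in seq_len(labeling$n_replicates)) {
        pick <- stats::runif(nrow(d)) < background_rate
        if (!any(pick)) next
        dd <- d[pick, , drop = FALSE]
        bg_list[[length(bg_list) + 1L]] <- data.frame(
          protein_id = proteome$protein_id[i], replicate = r,
          pep_sequence = dd$sequence, pep_start = dd$start,
          pep_end = dd$end, label = NA_character_,
          label_pos = NA_integer_, origin = "background",
          abundance = proteome$abundance[i],
          stringsAsFactors = FALSE
        )
      }
    }
    bg <- if (length(bg_list)) do.call(rbind, bg_list) else NULL
  }
  pool <- rbind(labeled, bg)
  if (is.null(pool)) {
    pool <- data.frame(
      protein_id = character(0), replicate = integer(0),
      pep_sequence = character(0), pep_start = integer(0),
      pep_end = integer(0), label = character(0),
      label_pos = integer(0), origin = character(0),
      abundance = numeric(0), stringsAsFactors = FALSE
    )
  }
  pool$arm <- arm
  rownames(pool) <- NULL
  pool
}

#' Spectrum noise model
#'
#' @param mass_jitter_ppm Uniform m/z perturbation half-width in ppm
#'   (applied to precursor and fragments; keep below the fragment
#'   tolerance).
#' @param peak_dropout Probability that a theoretical fragment peak is
#'   missing.
#' @param n_noise_peaks Poisson mean of uniform-random noise peaks per
#'   spectrum.
#' @param met_ox_p Per-methionine oxidation probability (sample-handling
#'   artifact).
#' @return A `noise_model` list.
#' @export
noise_model <- function(mass_jitter_ppm = 5, peak_dropout = 0.1,
                        n_noise_peaks = 10, met_ox_p = 0.05) {
  stopifnot(
    mass_jitter_ppm >= 0, peak_dropout >= 0, peak_dropout < 1,
    n_noise_peaks >= 0, met_ox_p >= 0, met_ox_p <= 1
  )
  structure(
    list(
      mass_jitter_ppm = mass_jitter_ppm, peak_dropout = peak_dropout,
      n_noise_peaks = n_noise_peaks, met_ox_p = met_ox_p
    ),
    class = "noise_model"
  )
}

#' Synthesize MS/MS spectra from a peptide pool
#'
#' Each pooled peptide yields one centroided spectrum at charge 2+ or 3+
#' (precursors outside the scan range at both charges are discarded,
#' emulating the instrument's m/z window). Peaks are the theoretical b/y
#' fragments of the modified peptide - static carbamidomethyl-C plus the
#' carried label plus random Met oxidation - with exponential-decay
#' intensities scaled by protein abundance, perturbed by uniform ppm
#' jitter, thinned by peak dropout, and topped with uniform noise peaks.
#' Spectrum titles encode the ground-truth link.
#'
#' @param pool Peptide pool from [simulate_enrichment()] (one replicate or
#'   several; the replicate column is carried through).
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param scan_range Precursor m/z window (default 350-1800).
#' @param modifications Modification set supplying masses.
#' @param mgf_path Optional path: when given the spectra are also written
#'   as MGF.
#' @return List with `spectra` (spectrum records) and `links` (data frame
#'   mapping spectrum ids to ground truth).
#' @export
synthesize_spectra <- function(pool, noise = noise_model(), seed = 1L,
                               scan_range = c(350, 1800),
                               modifications = default_modifications(),
                               mgf_path = NULL) {
  set.seed(seed)
  cam <- modifications$Carbamidomethyl$delta_mass
  ox <- modifications$Oxidation$delta_mass
  deltas <- c(
    Bt = modifications$Bt$delta_mass,
    Ad = modifications$Ad$delta_mass
  )
  spectra <- list()
  links <- list()
  jit <- function(mz) {
    mz * (1 + stats::runif(length(mz), -noise$mass_jitter_ppm,
      noise$mass_jitter_ppm
    ) * 1e-6)
  }
  for (k in seq_len(nrow(pool))) {
    seq_k <- pool$pep_sequence[k]
    aa <- strsplit(seq_k, "")[[1]]
    mod_pos <- which(aa == "C")
    mod_deltas <- rep(cam, length(mod_pos))
    mod_names <- rep("Carbamidomethyl", length(mod_pos))
    if (!is.na(pool$label[k])) {
      rel <- pool$label_pos[k] - pool$pep_start[k] + 1L
      mod_pos <- c(mod_pos, rel)
      mod_deltas <- c(mod_deltas, deltas[[pool$label[k]]])
      mod_names <- c(mod_names, pool$label[k])
    }
    m_pos <- which(aa == "M")
    if (length(m_pos) && noise$met_ox_p > 0) {
      oxed <- m_pos[stats::runif(length(m_pos)) < noise$met_ox_p]
      if (length(oxed)) {
        mod_pos <- c(mod_pos, oxed)
        mod_deltas <- c(mod_deltas, rep(ox, length(oxed)))
        mod_names <- c(mod_names, rep("Oxidation", length(oxed)))
      }
    }
    mass <- peptide_neutral_mass(seq_k) + sum(mod_deltas)
    mz2 <- mass_to_mz(mass, 2L)
    mz3 <- mass_to_mz(mass, 3L)
    ok2 <- mz2 >= scan_range[1] && mz2 <= scan_range[2]
    ok3 <- mz3 >= scan_range[1] && mz3 <= scan_range[2]
    z <- if (ok2 && ok3) {
      if (stats::runif(1) < 0.7) 2L else 3L
    } else if (ok2) {
      2L
    } else if (ok3) {
      3L
    } else {
      next
    }
    res <- .residue_mass_vector(seq_k, mod_pos, mod_deltas)
    frags <- .fragment_arrays(res, max_charge = max(1L, z - 1L))
    base <- pool$abundance[k] * 100
    inten <- base * exp(-0.05 * frags$index) *
      ifelse(frags$type == "y", 1.5, 1) / frags$charge
    keep <- stats::runif(length(frags$mz)) >= noise$peak_dropout
    mzs <- jit(frags$mz[keep])
    ints <- inten[keep]
    n_noise <- if (noise$n_noise_peaks > 0) {
      stats::rpois(1, noise$n_noise_peaks)
    } else {
      0L
    }
    if (n_noise > 0L) {
      mzs <- c(mzs, stats::runif(n_noise, 150, min(
        scan_range[2],
        max(frags$mz) * 1.05
      )))
      ints <- c(ints, stats::runif(n_noise, 0, 0.05 * base))
    }
    ord <- order(mzs)
    peaks <- cbind(mz = mzs[ord], intensity = ints[ord])
    sid <- sprintf(
      "gt|%d|%s|%d|%s|%s|%s|r%d",
      k, pool$protein_id[k], pool$pep_start[k],
      ifelse(is.na(pool$label[k]), "none", pool$label[k]),
      ifelse(is.na(pool$label_pos[k]), "0", pool$label_pos[k]),
      pool$origin[k], pool$replicate[k]
    )
    spectra[[length(spectra) + 1L]] <- list(
      spectrum_id = sid,
      precursor_mz = jit(mass_to_mz(mass, z)),
      precursor_charge = z,
      peaks = peaks
    )
    links[[length(links) + 1L]] <- data.frame(
      spectrum_id = sid, protein_id = pool$protein_id[k],
      replicate = pool$replicate[k], pep_sequence = seq_k,
      pep_start = pool$pep_start[k], label = pool$label[k],
      label_pos = pool$label_pos[k], origin = pool$origin[k],
      arm = pool$arm[k], stringsAsFactors = FALSE
    )
  }
  links <- if (length(links)) {
    do.call(rbind, links)
  } else {
    data.frame(
      spectrum_id = character(0), protein_id = character(0),
      replicate = integer(0), pep_sequence = character(0),
      pep_start = integer(0), label = character(0),
      label_pos = integer(0), origin = character(0),
      arm = character(0), stringsAsFactors = FALSE
    )
  }
  if (!is.null(mgf_path)) write_mgf(spectra, mgf_path)
  list(spectra = spectra, links = links)
}
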