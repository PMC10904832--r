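# modification each enrichment arm reports on
.arm_mods <- c(SA = "Bt", CB7 = "Ad")

# peptide sequence -> master protein map from a protein_groups table
.peptide_master_map <- function(groups) {
  tgt <- groups[!groups$is_decoy, , drop = FALSE]
  if (!nrow(tgt)) {
    return(stats::setNames(character(0), character(0)))
  }
  peps <- strsplit(tgt$peptides, ";", fixed = TRUE)
  stats::setNames(
    rep(tgt$master_protein_id, lengths(peps)),
    unlist(peps)
  )
}

# protein-coordinate label sites carried by accepted PSMs, mapped to
# master proteins via the razor assignment
.psm_label_sites <- function(psms, index, master_map,
                             labels = c("Ad", "Bt")) {
  if (!nrow(psms)) {
    return(data.frame(
      spectrum_id = character(0), protein_id = character(0),
      position = integer(0), label = character(0),
      stringsAsFactors = FALSE
    ))
  }
  occ <- index$occurrences
  rows <- lapply(seq_len(nrow(psms)), function(i) {
    if (!nzchar(psms$mod_pos[i])) {
      return(NULL)
    }
    pos <- as.integer(strsplit(psms$mod_pos[i], ";")[[1]])
    nm <- strsplit(psms$mod_names[i], ";")[[1]]
    keep <- nm %in% labels
    if (!any(keep)) {
      return(NULL)
    }
    master <- master_map[psms$sequence[i]]
    if (is.na(master)) master <- psms$protein_id[i]
    st <- occ$start[occ$sequence == psms$sequence[i] &
      occ$protein_id == master]
    st <- if (length(st)) st[1] else psms$start[i]
    data.frame(
      spectrum_id = psms$spectrum_id[i],
      protein_id = unname(master),
      position = st + pos[keep] - 1L,
      label = nm[keep],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      spectrum_id = character(0), protein_id = character(0),
      position = integer(0), label = character(0), stringsAsFactors = FALSE
    )
  }
  out
}

#' Per-run protein detections from PSMs
#'
#' Applies the arm's identification rule to one search run: a protein is
#' detected in a run when it is a Master protein (parsimony inference at
#' the protein FDR threshold) with at least one accepted PSM carrying the
#' arm's modification (Bt for the SA arm, Ad for the CB7 arm). LFQ
#' intensities and the labeled protein-coordinate sites are attached.
#'
#' @param psms A `psm_table` for one (arm, replicate, condition) run.
#' @param index The `search_index` used.
#' @param arm `"SA"` or `"CB7"`.
#' @param fdr_threshold PSM- and protein-level q-value threshold.
#' @return Data frame with one row per detected protein: `protein_id`,
#'   `n_labeled_psms`, `sites` (semicolon-separated protein positions),
#'   `intensity`.
#' @export
run_detections <- function(psms, index, arm = c("SA", "CB7"),
                           fdr_threshold = 0.01) {
  arm <- match.arg(arm)
  want <- .arm_mods[[arm]]
  acc <- accepted_psms(psms, fdr_threshold)
  groups <- infer_proteins(psms, index, fdr_threshold)
  masters <- groups$master_protein_id[!groups$is_decoy &
    groups$q_value <= fdr_threshold]
  mm <- .peptide_master_map(groups)
  sites <- .psm_label_sites(acc, index, mm, labels = want)
  sites <- sites[sites$protein_id %in% masters, , drop = FALSE]
  if (!nrow(sites)) {
    return(data.frame(
      protein_id = character(0), n_labeled_psms = integer(0),
      sites = character(0), intensity = numeric(0),
      stringsAsFactors = FALSE
    ))
  }
  quant <- lfq(psms, groups, fdr_threshold)
  qmap <- stats::setNames(quant$intensity, quant$protein_id)
  agg <- split(sites, sites$protein_id)
  data.frame(
    protein_id = names(agg),
    n_labeled_psms = vapply(
      agg, function(s) length(unique(s$spectrum_id)), 0L
    ),
    sites = vapply(
      agg, function(s) paste(sort(unique(s$position)), collapse = ";"), ""
    ),
    intensity = unname(qmap[names(agg)]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Replicate-consensus reliable proteins
#'
#' A protein is reliable for an arm and condition when it was detected in
#' at least `min_reps` of the replicates (the study's >= 2-of-3 rule).
#'
#' @param detections Data frame of per-run detections with columns
#'   `protein_id`, `arm`, `replicate`, `condition`.
#' @param arm,condition Which slice to evaluate.
#' @param min_reps Replicates required (default 2).
#' @return Character vector of reliable protein ids (sorted).
#' @export
replicate_consensus <- function(detections, arm, condition, min_reps = 2L) {
  d <- detections[detections$arm == arm &
    detections$condition == condition, , drop = FALSE]
  if (!nrow(d)) {
    return(character(0))
  }
  reps <- tapply(d$replicate, d$protein_id, function(r) length(unique(r)))
  sort(names(reps)[reps >= min_reps])
}

#' Partition proteins by organelle annotation
#'
#' Assigns each protein its GOCC-style class (`ER`, `mitochondria`,
#' `both`, `other`); proteins absent from the annotation table fall into
#' `other` (and are counted). Only the ER, mitochondria and both classes
#' propagate into the arm intersection; `other` is kept in a side table
#' for audit.
#'
#' @param proteins Character vector of protein ids.
#' @param annotation Data frame with columns `protein_id`, `annotation`.
#' @return List with one character vector per class, `retained`
#'   (ER + mitochondria + both), and `n_unannotated`.
#' @export
annotation_filter <- function(proteins, annotation) {
  cls <- stats::setNames(annotation$annotation, annotation$protein_id)
  got <- cls[proteins]
  n_missing <- sum(is.na(got))
  got[is.na(got)] <- "other"
  out <- list(
    ER = sort(proteins[got == "ER"]),
    mitochondria = sort(proteins[got == "mitochondria"]),
    both = sort(proteins[got == "both"]),
    other = sort(proteins[got == "other"]),
    n_unannotated = n_missing
  )
  out$retained <- sort(c(out$ER, out$mitochondria, out$both))
  out
}

#' Intersect the two enrichment arms
#'
#' The dual-labeled candidate set: proteins reliable in both the CB7 (Ad)
#' and SA (Bt) arms of the same condition.
#'
#' @param reliable_cb7,reliable_sa Character vectors of reliable proteins.
#' @return Sorted character vector (the OrthoID candidate set).
#' @export
intersect_arms <- function(reliable_cb7, reliable_sa) {
  sort(intersect(reliable_cb7, reliable_sa))
}

#' Validate labeled sites against protein topology
#'
#' A protein is topology-consistent when every Bt site is a cytosol-facing
#' lysine (or a known endogenous biotin site) and every Ad site is a
#' lumen-facing tyrosine or belongs to a declared exception class:
#' radical leakage (cytosol-facing Y on an OMM/ERM protein within
#' `junction_cutoff` of the junction) or, under CCCP, an IMS-facing Y.
#' Proteins missing from the topology table are flagged `"unknown"`,
#' never silently consistent.
#'
#' @param sites Data frame of labeled sites (`protein_id`, `position`,
#'   `label`).
#' @param topology Long-format topology table ([topology_table()]).
#' @param protein_meta Data frame with `protein_id`, `compartment`,
#'   `distance_to_junction`.
#' @param condition `"NT"` or `"CCCP"`.
#' @param junction_cutoff Maximum junction distance of the leakage class.
#' @return List with `flags` (per protein: `topology_consistent` one of
#'   `"yes"`, `"no"`, `"unknown"`) and `violations` (per offending site,
#'   with a reason), plus `exceptions` (sites passing via an exception
#'   class).
#' @export
topology_check <- function(sites, topology, protein_meta,
                           condition = "NT", junction_cutoff = 2) {
  if (!nrow(sites)) {
    return(list(
      flags = data.frame(
        protein_id = character(0), topology_consistent = character(0),
        stringsAsFactors = FALSE
      ),
      violations = data.frame(
        protein_id = character(0), position = integer(0),
        label = character(0), reason = character(0),
        stringsAsFactors = FALSE
      ),
      exceptions = data.frame(
        protein_id = character(0), position = integer(0),
        label = character(0), class = character(0), stringsAsFactors = FALSE
      )
    ))
  }
  key <- paste(topology$protein_id, topology$position)
  side <- stats::setNames(topology$sidedness, key)
  resid <- stats::setNames(topology$residue, key)
  endo <- stats::setNames(topology$endogenous_biotin, key)
  comp <- stats::setNames(protein_meta$compartment, protein_meta$protein_id)
  dist <- stats::setNames(
    protein_meta$distance_to_junction, protein_meta$protein_id
  )
  skey <- paste(sites$protein_id, sites$position)
  known <- skey %in% key & sites$protein_id %in% names(comp)
  verdict <- character(nrow(sites)) # "ok", "exception:<class>", "violation"
  reason <- character(nrow(sites))
  excl <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    if (!known[i]) {
      verdict[i] <- "unknown"
      next
    }
    s <- side[[skey[i]]]
    r <- resid[[skey[i]]]
    p <- sites$protein_id[i]
    if (sites$label[i] == "Bt") {
      if (r == "K" && s == "cytosol") {
        verdict[i] <- "ok"
      } else if (r == "K" && isTRUE(endo[[skey[i]]])) {
        verdict[i] <- "exception"
        excl[i] <- "endogenous"
      } else {
        verdict[i] <- "violation"
        reason[i] <- sprintf("Bt on %s-facing %s", s, r)
      }
    } else if (sites$label[i] == "Ad") {
      if (r == "Y" && s == "lumen") {
        verdict[i] <- "ok"
      } else if (r == "Y" && s == "cytosol" &&
        comp[[p]] %in% c("OMM", "ERM") &&
        dist[[p]] <= junction_cutoff) {
        verdict[i] <- "exception"
        excl[i] <- "leakage"
      } else if (r == "Y" && s == "IMS" && condition == "CCCP") {
        verdict[i] <- "exception"
        excl[i] <- "cccp_ims"
      } else {
        verdict[i] <- "violation"
        reason[i] <- sprintf("Ad on %s-facing %s", s, r)
      }
    } else {
      verdict[i] <- "violation"
      reason[i] <- paste("unknown label", sites$label[i])
    }
  }
  per_prot <- tapply(verdict, sites$protein_id, function(v) {
    if (any(v == "unknown")) "unknown" else
      if (any(v == "violation")) "no" else "yes"
  })
  list(
    flags = data.frame(
      protein_id = names(per_prot),
      topology_consistent = as.character(per_prot),
      stringsAsFactors = FALSE
    ),
    violations = data.frame(
      protein_id = sites$protein_id, position = sites$position,
      label = sites$label, reason = reason,
      stringsAsFactors = FALSE
    )[verdict == "violation", , drop = FALSE],
    exceptions = data.frame(
      protein_id = sites$protein_id, position = sites$position,
      label = sites$label, class = excl,
      stringsAsFactors = FALSE
    )[verdict == "exception", , drop = FALSE]
  )
}

#' Condition-contrast of labeled sites by PSM counts
#'
#' Per (protein, residue, modification), counts accepted PSMs in each
#' condition. A site is `CCCP-gained` when it has at least `min_psm` PSMs
#' under CCCP and none under NT, and symmetrically `NT-only`; all other
#' sites are `stable`.
#'
#' @param sites_nt,sites_cccp Site tables (one row per accepted PSM-site,
#'   columns `spectrum_id`, `protein_id`, `position`, `label`) from the
#'   two conditions.
#' @param min_psm PSM count required in the gaining condition (default 2).
#' @return Data frame `protein_id`, `position`, `label`, `n_NT`, `n_CCCP`,
#'   `flag`.
#' @export
differential_sites <- function(sites_nt, sites_cccp, min_psm = 2L) {
  count <- function(s) {
    if (is.null(s) || !nrow(s)) {
      return(stats::setNames(integer(0), character(0)))
    }
    k <- paste(s$protein_id, s$position, s$label, sep = "\r")
    tapply(s$spectrum_id, k, function(x) length(unique(x)))
  }
  n_nt <- count(sites_nt)
  n_cc <- count(sites_cccp)
  keys <- union(names(n_nt), names(n_cc))
  if (!length(keys)) {
    return(data.frame(
      protein_id = character(0), position = integer(0),
      label = character(0), n_NT = integer(0), n_CCCP = integer(0),
      flag = character(0), stringsAsFactors = FALSE
    ))
  }
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  nt <- unname(ifelse(is.na(n_nt[keys]), 0L, n_nt[keys]))
  cc <- unname(ifelse(is.na(n_cc[keys]), 0L, n_cc[keys]))
  flag <- ifelse(cc >= min_psm & nt == 0L, "CCCP-gained",
    ifelse(nt >= min_psm & cc == 0L, "NT-only", "stable")
  )
  out <- data.frame(
    protein_id = parts[, 1], position = as.integer(parts[, 2]),
    label = parts[, 3], n_NT = as.integer(nt), n_CCCP = as.integer(cc),
    flag = flag, stringsAsFactors = FALSE
  )
  out <- out[order(out$protein_id, out$position), ]
  rownames(out) <- NULL
  out
}

#' Assemble per-protein OrthoID calls for one condition
#'
#' Combines replicate consensus per arm, the annotation partition, the
#' arm intersection and the topology validation into the per-protein
#' verdict table.
#'
#' @param detections Per-run detection table (columns `protein_id`, `arm`,
#'   `replicate`, `condition`, `sites`).
#' @param annotation Annotation table (`protein_id`, `annotation`).
#' @param topology Long-format topology table.
#' @param protein_meta `protein_id`, `compartment`, `distance_to_junction`.
#' @param condition Condition to evaluate.
#' @param min_reps Replicate-consensus threshold.
#' @param junction_cutoff Leakage distance cutoff.
#' @return An `orthoid_calls` data frame, one row per protein appearing in
#'   either arm's reliable set, with columns `protein_id`,
#'   `annotation_class`, `reliable_SA`, `reliable_CB7`, `dual`,
#'   `topology_consistent`; the dual (candidate) set is restricted to
#'   ER/mitochondria/both annotations. Attributes carry the side sets.
#' @export
orthoid_calls <- function(detections, annotation, topology, protein_meta,
                          condition = "NT", min_reps = 2L,
                          junction_cutoff = 2) {
  rel_sa <- replicate_consensus(detections, "SA", condition, min_reps)
  rel_cb7 <- replicate_consensus(detections, "CB7", condition, min_reps)
  ann_sa <- annotation_filter(rel_sa, annotation)
  ann_cb7 <- annotation_filter(rel_cb7, annotation)
  dual <- intersect_arms(ann_cb7$retained, ann_sa$retained)
  prots <- sort(union(rel_sa, rel_cb7))
  cls <- stats::setNames(annotation$annotation, annotation$protein_id)
  got <- cls[prots]
  got[is.na(got)] <- "other"
  d <- detections[detections$condition == condition, , drop = FALSE]
  sites <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    if (!nzchar(d$sites[i])) {
      return(NULL)
    }
    pos <- as.integer(strsplit(d$sites[i], ";")[[1]])
    data.frame(
      protein_id = d$protein_id[i], position = pos,
      label = .arm_mods[[d$arm[i]]], stringsAsFactors = FALSE
    )
  }))
  if (is.null(sites)) {
    sites <- data.frame(
      protein_id = character(0), position = integer(0),
      label = character(0), stringsAsFactors = FALSE
    )
  }
  sites <- unique(sites)
  topo <- topology_check(
    sites[sites$protein_id %in% prots, , drop = FALSE],
    topology, protein_meta, condition, junction_cutoff
  )
  tmap <- stats::setNames(
    topo$flags$topology_consistent, topo$flags$protein_id
  )
  calls <- data.frame(
    protein_id = prots,
    annotation_class = unname(got),
    reliable_SA = prots %in% rel_sa,
    reliable_CB7 = prots %in% rel_cb7,
    dual = prots %in% dual,
    topology_consistent = ifelse(is.na(tmap[prots]), "unknown",
      tmap[prots]
    ),
    condition = condition,
    stringsAsFactors = FALSE
  )
  stopifnot(all(dual %in% rel_sa), all(dual %in% rel_cb7))
  attr(calls, "dual_set") <- dual
  attr(calls, "reliable_SA") <- rel_sa
  attr(calls, "reliable_CB7") <- rel_cb7
  attr(calls, "annotation_SA") <- ann_sa
  attr(calls, "annotation_CB7") <- ann_cb7
  attr(calls, "topology") <- topo
  class(calls) <- c("orthoid_calls", "data.frame")
  calls
}

#' @export
print.orthoid_calls <- function(x, ...) {
  cat(sprintf(
    "<orthoid_calls> %s: %d SA-reliable, %d CB7-reliable, %d dual\n",
    x$condition[1] %||% "?", sum(x$reliable_SA), sum(x$reliable_CB7),
    sum(x$dual)
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
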