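#' Pipeline configuration
#'
#' Builds the single configuration object controlling every stage of the
#' simulate -> search -> classify pipeline. All thresholds live here and
#' only here. The configuration round-trips through YAML; unknown keys are
#' rejected.
#'
#' @param ... Named overrides of the defaults; nested sections
#'   (`proteome`, `labeling`, `enrichment`, `noise`, `search`, `orthoid`)
#'   are given as named lists and merged key-wise.
#' @param file Optional YAML file of overrides (applied before `...`).
#' @return A `pipeline_config` list.
#' @examples
#' cfg <- pipeline_config(n_proteins = 50, labeling = list(p_bt = 1))
#' @export
pipeline_config <- function(..., file = NULL) {
  defaults <- list(
    seed = 1L,
    n_proteins = 500L,
    n_replicates = 3L,
    conditions = c("NT", "CCCP"),
    arms = c("SA", "CB7"),
    scan_range = c(350, 1800),
    proteome = list(
      compartment_mix = as.list(default_compartment_mix()),
      length_meanlog = log(110),
      length_sdlog = 0.35,
      endogenous_biotin_frac = 0.01,
      both_annotation_frac = 0.05
    ),
    labeling = list(
      p_bt = 0.6, p_ad = 0.6, leakage_p = 0.5, cccp_ims_p = 0.5,
      decay_rate = 1, junction_cutoff = 2, replicate_dropout = 0.1
    ),
    enrichment = list(capture_eff = 0.9, background_rate = 0.01),
    noise = list(
      mass_jitter_ppm = 5, peak_dropout = 0.1, n_noise_peaks = 10,
      met_ox_p = 0.05
    ),
    search = list(
      precursor_tol_ppm = 10, fragment_tol = 0.02, max_missed = 2L,
      min_length = 6L, max_length = 45L, max_dynamic_per_peptide = 3L,
      fdr_threshold = 0.01
    ),
    orthoid = list(min_reps = 2L, min_psm = 2L)
  )
  cfg <- defaults
  if (!is.null(file)) {
    cfg <- .merge_config(cfg, yaml::yaml.load_file(file), "config")
  }
  overrides <- list(...)
  if (length(overrides)) {
    cfg <- .merge_config(cfg, overrides, "config")
  }
  .validate_config(cfg)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

.merge_config <- function(base, override, path) {
  if (is.null(names(override)) && length(override)) {
    stop("configuration entries under '", path, "' must be named")
  }
  for (nm in names(override)) {
    if (!nm %in% names(base)) {
      stop("unknown configuration key: ", path, "$", nm)
    }
    bv <- base[[nm]]
    ov <- override[[nm]]
    if (is.list(bv) && !is.null(names(bv))) {
      if (!is.list(ov)) stop(path, "$", nm, " must be a named list")
      base[[nm]] <- .merge_config(bv, ov, paste0(path, "$", nm))
    } else if (is.numeric(bv)) {
      base[[nm]] <- as.numeric(unlist(ov))
    } else if (is.character(bv)) {
      base[[nm]] <- as.character(unlist(ov))
    } else {
      base[[nm]] <- ov
    }
  }
  base
}

.validate_config <- function(cfg) {
  stopifnot(
    cfg$n_proteins >= 1, cfg$n_replicates >= 1,
    all(cfg$conditions %in% c("NT", "CCCP")),
    all(cfg$arms %in% c("SA", "CB7")),
    length(cfg$scan_range) == 2, cfg$scan_range[1] < cfg$scan_range[2]
  )
  mix <- unlist(cfg$proteome$compartment_mix)
  if (abs(sum(mix) - 1) > 1e-8) {
    stop("proteome$compartment_mix must sum to 1")
  }
  probs <- unlist(cfg$labeling[c(
    "p_bt", "p_ad", "leakage_p", "cccp_ims_p", "replicate_dropout"
  )])
  if (any(probs < 0 | probs > 1)) {
    stop("labeling probabilities must lie in [0, 1]")
  }
  with(cfg$enrichment, stopifnot(
    capture_eff >= 0, capture_eff <= 1,
    background_rate >= 0, background_rate <= 1
  ))
  stopifnot(
    cfg$search$fdr_threshold > 0, cfg$search$fdr_threshold <= 1,
    cfg$orthoid$min_reps >= 1, cfg$orthoid$min_psm >= 1
  )
  invisible(cfg)
}

# derived sub-seed: one master seed drives every stochastic stage
.sub_seed <- function(seed, k) {
  (as.integer(seed) %% 100000L) * 1000L + k
}

.cfg_search_config <- function(cfg) {
  search_config(
    precursor_tol_ppm = cfg$search$precursor_tol_ppm,
    fragment_tol = cfg$search$fragment_tol,
    max_missed = cfg$search$max_missed,
    min_length = cfg$search$min_length,
    max_length = cfg$search$max_length,
    max_dynamic_per_peptide = cfg$search$max_dynamic_per_peptide,
    fdr_threshold = cfg$search$fdr_threshold
  )
}

.cfg_labeling_model <- function(cfg) {
  rate <- cfg$labeling$decay_rate
  labeling_model(
    p_bt = cfg$labeling$p_bt, p_ad = cfg$labeling$p_ad,
    leakage_p = cfg$labeling$leakage_p,
    cccp_ims_p = cfg$labeling$cccp_ims_p,
    distance_decay = function(d) exp(-rate * d),
    junction_cutoff = cfg$labeling$junction_cutoff,
    replicate_dropout = cfg$labeling$replicate_dropout
  )
}

#' Spectrum-level label sites of accepted PSMs
#'
#' Maps every accepted PSM's Ad/Bt modification to protein coordinates
#' (via the razor master of its peptide). One row per (PSM, site).
#'
#' @param psms A `psm_table` for one run.
#' @param index The `search_index` used.
#' @param fdr_threshold q-value cutoff.
#' @return Data frame `spectrum_id`, `protein_id`, `position`, `label`.
#' @export
psm_label_sites <- function(psms, index, fdr_threshold = 0.01) {
  acc <- accepted_psms(psms, fdr_threshold)
  groups <- infer_proteins(psms, index, fdr_threshold)
  .psm_label_sites(acc, index, .peptide_master_map(groups))
}

#' Run the full OrthoID pipeline
#'
#' Executes simulate -> digest/spectra -> search (per arm x replicate x
#' condition) -> classify, persisting every intermediate as FASTA, MGF or
#' TSV in `outdir`, echoing the effective configuration, and finishing
#' with [write_report()]. Fully deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @param quiet Suppress per-stage log lines.
#' @return An `orthoid_run` list: `outdir`, `config`, `proteome`,
#'   `detections`, `calls` (per condition), `differential`, `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         quiet = FALSE) {
  .validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_line <- function(fmt, ...) {
    if (!quiet) {
      message(sprintf(
        "[orthoid +%5.1fs] %s",
        as.numeric(difftime(Sys.time(), t0, units = "secs")),
        sprintf(fmt, ...)
      ))
    }
  }
  yaml::write_yaml(unclass(config), file.path(outdir, "config.yaml"),
    precision = 15L
  )
  scfg <- .cfg_search_config(config)
  model <- .cfg_labeling_model(config)

  proteome <- generate_proteome(
    n_proteins = config$n_proteins,
    compartment_mix = unlist(config$proteome$compartment_mix),
    seed = .sub_seed(config$seed, 1L),
    length_meanlog = config$proteome$length_meanlog,
    length_sdlog = config$proteome$length_sdlog,
    endogenous_biotin_frac = config$proteome$endogenous_biotin_frac,
    both_annotation_frac = config$proteome$both_annotation_frac
  )
  log_line("proteome: %d proteins", nrow(proteome))
  seqs <- stats::setNames(proteome$sequence, proteome$protein_id)
  write_fasta(seqs, file.path(outdir, "proteome.fasta"))
  write_tsv_table(
    proteome[, c("protein_id", "annotation")],
    file.path(outdir, "annotation.tsv")
  )
  write_tsv_table(
    proteome[, c(
      "protein_id", "compartment", "length", "abundance",
      "distance_to_junction"
    )],
    file.path(outdir, "protein_meta.tsv")
  )
  topo <- topology_table(proteome)
  write_tsv_table(topo, file.path(outdir, "topology.tsv"))

  index <- build_search_space(seqs, scfg)
  log_line(
    "search space: %d candidates (%d decoy)",
    nrow(index$candidates), sum(index$candidates$is_decoy)
  )

  all_psms <- list()
  all_detect <- list()
  sites_by_cond <- list()
  truths <- list()
  run_id <- 0L
  for (cond in config$conditions) {
    labeling <- simulate_labeling(
      proteome,
      condition = cond, model = model,
      n_replicates = config$n_replicates,
      seed = .sub_seed(config$seed, if (cond == "NT") 2L else 3L),
      min_reps = config$orthoid$min_reps,
      min_length = config$search$min_length,
      max_length = config$search$max_length,
      max_missed = config$search$max_missed,
      scan_range = config$scan_range
    )
    truths[[cond]] <- labeling
    write_tsv_table(
      labeling$events,
      file.path(outdir, sprintf("events_%s.tsv", cond))
    )
    write_tsv_table(
      labeling$truth,
      file.path(outdir, sprintf("truth_%s.tsv", cond))
    )
    log_line(
      "%s labeling: %d events, %d ground-truth dual", cond,
      nrow(labeling$events), sum(labeling$truth$dual)
    )
    cond_sites <- list()
    for (arm in config$arms) {
      run_id <- run_id + 1L
      pool <- simulate_enrichment(
        proteome, labeling,
        arm = arm,
        capture_eff = config$enrichment$capture_eff,
        background_rate = config$enrichment$background_rate,
        seed = .sub_seed(config$seed, 10L + run_id),
        min_length = config$search$min_length,
        max_length = config$search$max_length
      )
      for (r in seq_len(config$n_replicates)) {
        pool_r <- pool[pool$replicate == r, , drop = FALSE]
        syn <- synthesize_spectra(
          pool_r,
          noise = noise_model(
            mass_jitter_ppm = config$noise$mass_jitter_ppm,
            peak_dropout = config$noise$peak_dropout,
            n_noise_peaks = config$noise$n_noise_peaks,
            met_ox_p = config$noise$met_ox_p
          ),
          seed = .sub_seed(config$seed, 100L + 10L * run_id + r),
          scan_range = config$scan_range,
          mgf_path = file.path(
            outdir, sprintf("spectra_%s_%s_r%d.mgf", cond, arm, r)
          )
        )
        psms <- search_spectra(syn$spectra, index, scfg)
        det <- run_detections(psms, index, arm, scfg$fdr_threshold)
        sites <- psm_label_sites(psms, index, scfg$fdr_threshold)
        psms$arm <- arm
        psms$replicate <- r
        psms$condition <- cond
        all_psms[[length(all_psms) + 1L]] <- psms
        if (nrow(det)) {
          det$arm <- arm
          det$replicate <- r
          det$condition <- cond
          all_detect[[length(all_detect) + 1L]] <- det
        }
        if (nrow(sites)) {
          sites$arm <- arm
          sites$replicate <- r
          sites$condition <- cond
          cond_sites[[length(cond_sites) + 1L]] <- sites
        }
        log_line(
          "%s/%s r%d: %d spectra, %d PSMs, %d proteins detected",
          cond, arm, r, length(syn$spectra), nrow(psms), nrow(det)
        )
      }
    }
    sites_by_cond[[cond]] <- if (length(cond_sites)) {
      do.call(rbind, cond_sites)
    } else {
      data.frame(
        spectrum_id = character(0), protein_id = character(0),
        position = integer(0), label = character(0),
        arm = character(0), replicate = integer(0),
        condition = character(0), stringsAsFactors = FALSE
      )
    }
  }
  psms_all <- do.call(rbind, all_psms)
  write_tsv_table(psms_all, file.path(outdir, "psms.tsv"))
  detections <- if (length(all_detect)) {
    do.call(rbind, all_detect)
  } else {
    data.frame(
      protein_id = character(0), n_labeled_psms = integer(0),
      sites = character(0), intensity = numeric(0), arm = character(0),
      replicate = integer(0), condition = character(0),
      stringsAsFactors = FALSE
    )
  }
  write_tsv_table(detections, file.path(outdir, "detections.tsv"))
  write_tsv_table(
    do.call(rbind, sites_by_cond),
    file.path(outdir, "sites.tsv")
  )

  annotation <- proteome[, c("protein_id", "annotation")]
  meta <- proteome[, c("protein_id", "compartment", "distance_to_junction")]
  calls <- list()
  violations <- list()
  for (cond in config$conditions) {
    cl <- orthoid_calls(
      detections, annotation, topo, meta,
      condition = cond,
      min_reps = config$orthoid$min_reps,
      junction_cutoff = config$labeling$junction_cutoff
    )
    calls[[cond]] <- cl
    write_tsv_table(
      as.data.frame(cl),
      file.path(outdir, sprintf("calls_%s.tsv", cond))
    )
    v <- attr(cl, "topology")$violations
    if (nrow(v)) {
      v$condition <- cond
      violations[[cond]] <- v
    }
    log_line(
      "%s calls: %d dual of %d reliable", cond, sum(cl$dual), nrow(cl)
    )
  }
  viol <- if (length(violations)) {
    do.call(rbind, violations)
  } else {
    data.frame(
      protein_id = character(0), position = integer(0),
      label = character(0), reason = character(0),
      condition = character(0), stringsAsFactors = FALSE
    )
  }
  write_tsv_table(viol, file.path(outdir, "violations.tsv"))

  differential <- NULL
  if (all(c("NT", "CCCP") %in% config$conditions)) {
    differential <- differential_sites(
      sites_by_cond[["NT"]], sites_by_cond[["CCCP"]],
      min_psm = config$orthoid$min_psm
    )
    write_tsv_table(
      differential, file.path(outdir, "differential_sites.tsv")
    )
    log_line(
      "differential sites: %d CCCP-gained / %d total",
      sum(differential$flag == "CCCP-gained"), nrow(differential)
    )
  }

  report <- write_report(outdir)
  log_line("report written")
  structure(
    list(
      outdir = outdir, config = config, proteome = proteome,
      index = index, truths = truths, detections = detections,
      calls = calls, differential = differential, report = report
    ),
    class = "orthoid_run"
  )
}

#' @export
print.orthoid_run <- function(x, ...) {
  cat(sprintf("<orthoid_run> %s\n", x$outdir))
  for (cond in names(x$calls)) {
    cl <- x$calls[[cond]]
    cat(sprintf(
      "  %s: SA %d, CB7 %d, dual %d\n", cond,
      sum(cl$reliable_SA), sum(cl$reliable_CB7), sum(cl$dual)
    ))
  }
  invisible(x)
}

#' Recompute the run report from persisted tables
#'
#' Reads only the TSV/YAML artifacts in `outdir` and recomputes every
#' reported number from them: per-arm reliable-protein counts by
#' annotation class, intersection and condition-exclusive counts, FDR
#' diagnostics, topology-violation counts, and - when ground truth is
#' present - dual-call precision and recall. Writes `report.json` and a
#' human-readable `report.txt`.
#'
#' @param outdir A directory produced by [run_pipeline()].
#' @return The report, an `orthoid_report` list, invisibly written to
#'   disk.
#' @export
write_report <- function(outdir) {
  need <- function(f) {
    p <- file.path(outdir, f)
    if (!file.exists(p)) stop("missing pipeline artifact: ", f)
    p
  }
  cfg <- yaml::yaml.load_file(need("config.yaml"))
  detections <- read_tsv_table(need("detections.tsv"))
  annotation <- read_tsv_table(need("annotation.tsv"))
  psms <- read_tsv_table(need("psms.tsv"))
  viol <- read_tsv_table(need("violations.tsv"))
  fdr <- cfg$search$fdr_threshold
  min_reps <- cfg$orthoid$min_reps
  conditions <- unlist(cfg$conditions)
  report <- list(conditions = list())
  dual_sets <- list()
  for (cond in conditions) {
    rel <- list(
      SA = replicate_consensus(detections, "SA", cond, min_reps),
      CB7 = replicate_consensus(detections, "CB7", cond, min_reps)
    )
    ann <- lapply(rel, annotation_filter, annotation = annotation)
    dual <- intersect_arms(ann$CB7$retained, ann$SA$retained)
    dual_sets[[cond]] <- dual
    calls_file <- file.path(outdir, sprintf("calls_%s.tsv", cond))
    n_calls_dual <- if (file.exists(calls_file)) {
      sum(read_tsv_table(calls_file)$dual)
    } else {
      NA_integer_
    }
    if (!is.na(n_calls_dual) && n_calls_dual != length(dual)) {
      stop("report/calls mismatch for condition ", cond)
    }
    truth_file <- file.path(outdir, sprintf("truth_%s.tsv", cond))
    pr <- list(precision = NA_real_, recall = NA_real_)
    if (file.exists(truth_file)) {
      truth <- read_tsv_table(truth_file)
      true_dual <- truth$protein_id[truth$dual]
      tp <- length(intersect(dual, true_dual))
      pr$precision <- if (length(dual)) tp / length(dual) else NA_real_
      pr$recall <- if (length(true_dual)) {
        tp / length(true_dual)
      } else {
        NA_real_
      }
    }
    class_counts <- function(a) {
      list(
        ER = length(a$ER), mitochondria = length(a$mitochondria),
        both = length(a$both), other = length(a$other),
        retained = length(a$retained)
      )
    }
    report$conditions[[cond]] <- list(
      reliable_SA = class_counts(ann$SA),
      reliable_CB7 = class_counts(ann$CB7),
      venn = list(
        SA_only = length(setdiff(ann$SA$retained, dual)),
        CB7_only = length(setdiff(ann$CB7$retained, dual)),
        intersection = length(dual)
      ),
      dual_proteins = dual,
      precision_recall = pr,
      n_topology_violations = sum(viol$condition == cond)
    )
  }
  if (all(c("NT", "CCCP") %in% conditions)) {
    report$condition_contrast <- list(
      dual_NT_only = length(setdiff(dual_sets$NT, dual_sets$CCCP)),
      dual_CCCP_only = length(setdiff(dual_sets$CCCP, dual_sets$NT)),
      dual_shared = length(intersect(dual_sets$NT, dual_sets$CCCP))
    )
    diff_file <- file.path(outdir, "differential_sites.tsv")
    if (file.exists(diff_file)) {
      ds <- read_tsv_table(diff_file)
      report$differential <- list(
        n_sites = nrow(ds),
        n_cccp_gained = sum(ds$flag == "CCCP-gained"),
        n_nt_only = sum(ds$flag == "NT-only")
      )
    }
  }
  report$fdr_diagnostics <- list(
    n_psms = nrow(psms),
    n_accepted = sum(!psms$is_decoy & psms$q_value <= fdr),
    n_decoy_at_threshold = sum(psms$is_decoy & psms$q_value <= fdr),
    decoy_fraction_accepted = if (any(psms$q_value <= fdr)) {
      sum(psms$is_decoy & psms$q_value <= fdr) /
        sum(psms$q_value <= fdr)
    } else {
      NA_real_
    }
  )
  class(report) <- c("orthoid_report", "list")
  jsonlite::write_json(
    unclass(report), file.path(outdir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(outdir, "report.txt"))
  report
}

#' @export
print.orthoid_report <- function(x, ...) {
  cat("OrthoID run report\n==================\n")
  for (cond in names(x$conditions)) {
    c_ <- x$conditions[[cond]]
    cat(sprintf(
      paste0(
        "%s: SA reliable %d (ER %d / mito %d / both %d), ",
        "CB7 reliable %d (ER %d / mito %d / both %d)\n",
        "    intersection (dual) %d; precision %.3f recall %.3f; ",
        "topology violations %d\n"
      ),
      cond,
      c_$reliable_SA$retained, c_$reliable_SA$ER,
      c_$reliable_SA$mitochondria, c_$reliable_SA$both,
      c_$reliable_CB7$retained, c_$reliable_CB7$ER,
      c_$reliable_CB7$mitochondria, c_$reliable_CB7$both,
      c_$venn$intersection,
      c_$precision_recall$precision, c_$precision_recall$recall,
      c_$n_topology_violations
    ))
  }
  if (!is.null(x$condition_contrast)) {
    cat(sprintf(
      "dual sets: %d NT-only, %d CCCP-only, %d shared\n",
      x$condition_contrast$dual_NT_only,
      x$condition_contrast$dual_CCCP_only,
      x$condition_contrast$dual_shared
    ))
  }
  if (!is.null(x$differential)) {
    cat(sprintf(
      "differential sites: %d total, %d CCCP-gained, %d NT-only\n",
      x$differential$n_sites, x$differential$n_cccp_gained,
      x$differential$n_nt_only
    ))
  }
  cat(sprintf(
    "PSMs: %d total, %d accepted at FDR, decoy fraction %.4f\n",
    x$fdr_diagnostics$n_psms, x$fdr_diagnostics$n_accepted,
    x$fdr_diagnostics$decoy_fraction_accepted
  ))
  invisible(x)
}
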