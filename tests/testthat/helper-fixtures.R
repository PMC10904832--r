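# Shared fixtures built once per test session.

.fixture_env <- new.env(parent = emptyenv())

# a small default-noise pipeline run reused by the decision-layer and
# pipeline tests
shared_run <- function() {
  if (is.null(.fixture_env$run)) {
    cfg <- pipeline_config(seed = 101L, n_proteins = 60L)
    .fixture_env$run <- suppressMessages(
      run_pipeline(cfg, outdir = file.path(tempdir(), "orthoid-shared"),
        quiet = TRUE
      )
    )
  }
  .fixture_env$run
}

# a noiseless / perfect-capture run of both conditions with saturated
# CCCP IMS labeling; shared by the soundness, site-recovery and
# topology-soundness checks
noiseless_run <- function() {
  if (is.null(.fixture_env$noiseless)) {
    cfg <- pipeline_config(
      seed = 404L, n_proteins = 80L,
      labeling = list(replicate_dropout = 0, cccp_ims_p = 1),
      enrichment = list(capture_eff = 1, background_rate = 0),
      noise = list(
        mass_jitter_ppm = 0, peak_dropout = 0, n_noise_peaks = 0,
        met_ox_p = 0
      )
    )
    .fixture_env$noiseless <- suppressMessages(
      run_pipeline(cfg,
        outdir = file.path(tempdir(), "orthoid-noiseless"),
        quiet = TRUE
      )
    )
  }
  .fixture_env$noiseless
}

# pipeline configuration of the noiseless / perfect-capture limit
noiseless_config <- function(n_proteins, seed, ...) {
  pipeline_config(
    seed = seed, n_proteins = n_proteins,
    labeling = list(replicate_dropout = 0),
    enrichment = list(capture_eff = 1, background_rate = 0),
    noise = list(
      mass_jitter_ppm = 0, peak_dropout = 0, n_noise_peaks = 0,
      met_ox_p = 0
    ),
    ...
  )
}

# the three-model-protein mixture: a Bt-only protein (myoglobin analog),
# an Ad-only protein (ovalbumin analog) and a dual-labeled protein (BSA
# analog), as labeled peptide pools for both enrichment arms
model_protein_pools <- function(n_replicates = 3L) {
  seqs <- c(
    MYB = "GLSDGEWQLVLNVWGKVEADIPGHGQEVLIRLFTGHPETLEK",
    OVA = "GSIGAASMEFCFDVFKELKVHHANENIFYCPIAIMSALAMVYLGAK",
    BSA = "DLGEEHFKGLVLIAFSQYLQQCPFDEHVKLVNELTEFAKTCVADESHAGCEK"
  )
  label_site <- function(id, residue) {
    aa <- strsplit(seqs[[id]], "")[[1]]
    which(aa == residue)[1]
  }
  plan <- rbind(
    data.frame(protein_id = "MYB", label = "Bt", residue = "K"),
    data.frame(protein_id = "OVA", label = "Ad", residue = "Y"),
    data.frame(protein_id = "BSA", label = "Bt", residue = "K"),
    data.frame(protein_id = "BSA", label = "Ad", residue = "Y")
  )
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    id <- plan$protein_id[i]
    pos <- label_site(id, plan$residue[i])
    d <- digest(seqs[[id]], max_missed = 2, min_length = 6,
      max_length = 45
    )
    pep <- d[d$start <= pos & d$end >= pos, ]
    pep <- pep[order(pep$missed_cleavages, pep$start), ][1, ]
    for (r in seq_len(n_replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, replicate = r, pep_sequence = pep$sequence,
        pep_start = pep$start, pep_end = pep$end,
        label = plan$label[i], label_pos = pos, origin = "labeled",
        abundance = 1, stringsAsFactors = FALSE
      )
    }
  }
  pool <- do.call(rbind, rows)
  list(
    sequences = seqs,
    pools = list(
      SA = transform(pool[pool$label == "Bt", ], arm = "SA"),
      CB7 = transform(pool[pool$label == "Ad", ], arm = "CB7")
    )
  )
}

# run the model-protein mixture through spectra -> search -> detection ->
# consensus -> intersection; returns the dual-labeled candidate set
run_model_protein_experiment <- function(seed = 1L) {
  mp <- model_protein_pools()
  cfg <- search_config()
  index <- build_search_space(mp$sequences, cfg)
  quiet <- noise_model(
    mass_jitter_ppm = 0, peak_dropout = 0, n_noise_peaks = 0, met_ox_p = 0
  )
  # detections per (arm, replicate), then the consensus rule
  det_rows <- list()
  for (arm in c("SA", "CB7")) {
    for (r in 1:3) {
      pool_r <- mp$pools[[arm]]
      pool_r <- pool_r[pool_r$replicate == r, , drop = FALSE]
      syn <- synthesize_spectra(pool_r, quiet, seed = seed + r)
      psms <- search_spectra(syn$spectra, index, cfg)
      det <- run_detections(psms, index, arm, cfg$fdr_threshold)
      if (nrow(det)) {
        det$arm <- arm
        det$replicate <- r
        det$condition <- "NT"
        det_rows[[length(det_rows) + 1L]] <- det
      }
    }
  }
  detections <- do.call(rbind, det_rows)
  rel_sa <- replicate_consensus(detections, "SA", "NT", 2L)
  rel_cb7 <- replicate_consensus(detections, "CB7", "NT", 2L)
  list(
    detections = detections,
    reliable_SA = rel_sa, reliable_CB7 = rel_cb7,
    dual = intersect_arms(rel_cb7, rel_sa)
  )
}
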