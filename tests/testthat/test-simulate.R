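test_that("proteome generation is deterministic and respects the mixture", {
  a <- generate_proteome(50, seed = 3)
  b <- generate_proteome(50, seed = 3)
  expect_identical(a, b)
  onlycyt <- generate_proteome(30,
    compartment_mix = c(cytosol = 1), seed = 4
  )
  expect_true(all(onlycyt$compartment == "cytosol"))
  expect_true(all(onlycyt$annotation == "other"))
  expect_error(
    generate_proteome(10, compartment_mix = c(cytosol = 0.5)),
    "summing to 1"
  )
})

test_that("compartment counts fall within binomial 99% intervals", {
  n <- 500
  pro <- generate_proteome(n, seed = 9)
  mix <- default_compartment_mix()
  counts <- table(factor(pro$compartment, levels = names(mix)))
  for (cm in names(mix)) {
    lo <- qbinom(0.005, n, mix[[cm]])
    hi <- qbinom(0.995, n, mix[[cm]])
    expect_gte(counts[[cm]], lo)
    expect_lte(counts[[cm]], hi)
  }
})

test_that("topology annotations are structurally sound", {
  pro <- generate_proteome(120, seed = 5)
  for (i in seq_len(nrow(pro))) {
    side <- pro$sidedness[[i]]
    expect_length(side, nchar(pro$sequence[i]))
    comp <- pro$compartment[i]
    if (comp %in% c("ERM", "OMM", "IMM")) {
      expect_true(any(side == "membrane"), info = pro$protein_id[i])
      allowed <- switch(comp,
        ERM = c("cytosol", "lumen"),
        OMM = c("cytosol", "IMS"),
        IMM = c("matrix", "IMS")
      )
      expect_true(all(side %in% c(allowed, "membrane")))
    } else {
      expect_length(unique(side), 1L)
    }
  }
  expect_true(all(pro$distance_to_junction >= 0))
  expect_true(all(pro$abundance > 0))
})

test_that("labeling follows topology: Bt on cytosolic K, Ad on luminal Y only", {
  pro <- generate_proteome(150, seed = 21)
  lab <- simulate_labeling(pro, "NT", labeling_model(), seed = 22)
  ev <- lab$events
  topo <- topology_table(pro)
  key <- paste(topo$protein_id, topo$position)
  side <- setNames(topo$sidedness, key)
  endo <- setNames(topo$endogenous_biotin, key)
  ek <- paste(ev$protein_id, ev$position)
  bt <- ev$label == "Bt"
  expect_true(all(ev$residue[bt] == "K"))
  expect_true(all(side[ek[bt]] == "cytosol" | endo[ek[bt]]))
  ad <- ev$label == "Ad"
  expect_true(all(ev$residue[ad] == "Y"))
  expect_true(all(side[ek[ad]] %in% c("lumen", "cytosol")))
  expect_true(all(ev$class[ad & side[ek] == "cytosol"] == "leakage"))
})

test_that("degenerate labeling models behave as contracted", {
  pro <- generate_proteome(40, seed = 31, endogenous_biotin_frac = 0)
  zero <- labeling_model(
    p_bt = 0, p_ad = 0, leakage_p = 0, cccp_ims_p = 0,
    replicate_dropout = 0
  )
  expect_equal(nrow(simulate_labeling(pro, "NT", zero, seed = 1)$events), 0L)
  sat <- labeling_model(p_ad = 1, replicate_dropout = 0)
  lab <- simulate_labeling(pro, "NT", sat, n_replicates = 3, seed = 2)
  ev <- lab$events[lab$events$label == "Ad" & lab$events$class == "topology", ]
  topo <- topology_table(pro)
  lumY <- topo[topo$sidedness == "lumen" & topo$residue == "Y", ]
  expect_equal(nrow(ev), 3L * nrow(lumY))
})

test_that("IMS tyrosine labeling occurs under CCCP and never under NT", {
  pro <- generate_proteome(150, seed = 41)
  model <- labeling_model(cccp_ims_p = 0.8)
  for (s in 1:3) {
    nt <- simulate_labeling(pro, "NT", model, seed = 50 + s)
    expect_equal(sum(nt$events$class == "cccp_ims"), 0L)
  }
  cc <- simulate_labeling(pro, "CCCP", model, seed = 54)
  expect_gt(sum(cc$events$class == "cccp_ims"), 0L)
})

test_that("enrichment arms separate the two labels and keep endogenous biotin in SA", {
  pro <- generate_proteome(100, seed = 61, endogenous_biotin_frac = 0.2)
  lab <- simulate_labeling(pro, "NT", labeling_model(), seed = 62)
  sa <- simulate_enrichment(pro, lab, "SA",
    capture_eff = 1, background_rate = 0, seed = 63
  )
  cb <- simulate_enrichment(pro, lab, "CB7",
    capture_eff = 1, background_rate = 0, seed = 64
  )
  expect_true(all(sa$label == "Bt"))
  expect_true(all(cb$label == "Ad"))
  # at full capture, the SA pool is exactly the detectable Bt peptides
  ev <- lab$events
  bt <- ev[ev$label == "Bt" & !is.na(ev$pep_start), ]
  expect_equal(nrow(sa), nrow(bt))
  expect_true(any(sa$origin == "endogenous"))
  expect_false(any(cb$origin == "endogenous"))
})

test_that("pool size matches the capture/background binomial expectation", {
  pro <- generate_proteome(80, seed = 71)
  lab <- simulate_labeling(pro, "NT", labeling_model(), seed = 72)
  ce <- 0.5
  br <- 0.05
  sa <- simulate_enrichment(pro, lab, "SA",
    capture_eff = ce, background_rate = br, seed = 73
  )
  ev <- lab$events
  n_lab <- sum(ev$label == "Bt" & !is.na(ev$pep_start))
  got_lab <- sum(sa$origin != "background")
  expect_gte(got_lab, qbinom(0.005, n_lab, ce))
  expect_lte(got_lab, qbinom(0.995, n_lab, ce))
  # background: 0-missed in-window peptides per protein per replicate
  n_bg_pool <- sum(vapply(pro$sequence, function(s) {
    nrow(digest(s, 0, min_length = 6, max_length = 45))
  }, 0)) * lab$n_replicates
  got_bg <- sum(sa$origin == "background")
  expect_gte(got_bg, qbinom(0.005, n_bg_pool, br))
  expect_lte(got_bg, qbinom(0.995, n_bg_pool, br))
})

test_that("noiseless spectra are exactly the theoretical fragments", {
  pro <- generate_proteome(30, seed = 81)
  lab <- simulate_labeling(pro, "NT",
    labeling_model(replicate_dropout = 0),
    seed = 82
  )
  pool <- simulate_enrichment(pro, lab, "SA",
    capture_eff = 1, background_rate = 0, seed = 83
  )
  pool <- pool[pool$replicate == 1, ][1:5, ]
  quiet <- noise_model(
    mass_jitter_ppm = 0, peak_dropout = 0, n_noise_peaks = 0, met_ox_p = 0
  )
  syn <- synthesize_spectra(pool, quiet, seed = 84)
  bt <- default_modifications()$Bt$delta_mass
  cam <- default_modifications()$Carbamidomethyl$delta_mass
  for (k in seq_along(syn$spectra)) {
    sp <- syn$spectra[[k]]
    link <- syn$links[k, ]
    aa <- strsplit(link$pep_sequence, "")[[1]]
    mp <- c(which(aa == "C"), link$label_pos - link$pep_start + 1L)
    md <- c(rep(cam, sum(aa == "C")), bt)
    th <- fragment_ions(link$pep_sequence, mp, md,
      max_charge = sp$precursor_charge - 1L
    )
    expect_equal(sp$peaks[, "mz"], sort(th$mz),
      tolerance = 1e-9, ignore_attr = TRUE
    )
  }
})

test_that("precursors outside the scan range are discarded", {
  pool <- data.frame(
    protein_id = "P1", replicate = 1L, pep_sequence = "GAGAGA",
    pep_start = 1L, pep_end = 6L, label = NA_character_,
    label_pos = NA_integer_, origin = "background", abundance = 1,
    arm = "SA", stringsAsFactors = FALSE
  )
  quiet <- noise_model(0, 0, 0, 0)
  # neutral mass ~ 402 Da: 2+ at 202 and 3+ at 135, both below 350
  syn <- synthesize_spectra(pool, quiet, seed = 1)
  expect_length(syn$spectra, 0L)
  syn2 <- synthesize_spectra(pool, quiet, seed = 1, scan_range = c(100, 1800))
  expect_length(syn2$spectra, 1L)
})

test_that("peak dropout retains the configured fraction", {
  pro <- generate_proteome(40, seed = 91)
  lab <- simulate_labeling(pro, "NT",
    labeling_model(replicate_dropout = 0),
    seed = 92
  )
  pool <- simulate_enrichment(pro, lab, "SA",
    capture_eff = 1, background_rate = 0, seed = 93
  )
  n_theory <- 0L
  for (k in seq_len(nrow(pool))) {
    z <- NULL
    aa <- strsplit(pool$pep_sequence[k], "")[[1]]
    n_theory <- n_theory + 2L * (length(aa) - 1L)
  }
  syn <- synthesize_spectra(
    pool, noise_model(0, peak_dropout = 0.3, 0, 0),
    seed = 94
  )
  # only spectra at 3+ carry two fragment charges; count retained peaks
  n_all <- sum(vapply(syn$spectra, function(s) nrow(s$peaks), 0L))
  n_possible <- sum(vapply(seq_along(syn$spectra), function(k) {
    n <- nchar(syn$links$pep_sequence[k])
    zc <- syn$spectra[[k]]$precursor_charge - 1L
    2L * (n - 1L) * zc
  }, 0L))
  expect_gte(n_all, qbinom(0.005, n_possible, 0.7))
  expect_lte(n_all, qbinom(0.995, n_possible, 0.7))
})

test_that("spectrum synthesis is deterministic under a fixed seed", {
  pro <- generate_proteome(25, seed = 95)
  lab <- simulate_labeling(pro, "NT", labeling_model(), seed = 96)
  pool <- simulate_enrichment(pro, lab, "SA", seed = 97)
  a <- synthesize_spectra(pool, noise_model(), seed = 98)
  b <- synthesize_spectra(pool, noise_model(), seed = 98)
  expect_identical(a, b)
})

test_that("every ground-truth spectrum link resolves to a digestible peptide", {
  pro <- generate_proteome(40, seed = 99)
  lab <- simulate_labeling(pro, "NT", labeling_model(), seed = 100)
  pool <- simulate_enrichment(pro, lab, "SA", seed = 101)
  syn <- synthesize_spectra(pool, noise_model(), seed = 102)
  seqs <- setNames(pro$sequence, pro$protein_id)
  for (k in seq_len(nrow(syn$links))) {
    lk <- syn$links[k, ]
    d <- digest(seqs[[lk$protein_id]], 2)
    expect_true(lk$pep_sequence %in% d$sequence)
  }
})
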