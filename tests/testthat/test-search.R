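test_that("search space enumerates targets, decoys and modification forms", {
  # no K/R/C/M/Y anywhere: one unmodified form each for target and decoy
  idx <- build_search_space(c(P1 = "GAVLITGAVLDE"))
  expect_equal(nrow(idx$candidates), 2L)
  expect_setequal(idx$candidates$is_decoy, c(TRUE, FALSE))
  expect_true(all(idx$candidates$mod_pos == ""))
  expect_error(build_search_space(character(0)), "empty")
})

test_that("a two-tyrosine peptide yields the 2^2 Ad ladder separated by 414.252", {
  idx <- build_search_space(c(P1 = "AAYAAYAAGGGK"))
  cand <- idx$candidates
  pep <- cand[cand$sequence == "AAYAAYAAGGGK" & !cand$is_decoy, ]
  # restrict to Ad-only forms (the K also admits Bt variants)
  ad_only <- pep[!grepl("Oxidation|Bt", pep$mod_names), ]
  n_ad <- vapply(strsplit(ad_only$mod_names, ";"), function(x) {
    sum(x == "Ad")
  }, 0L)
  expect_equal(unname(table(n_ad)), c(1L, 2L, 1L), ignore_attr = TRUE)
  m0 <- ad_only$mass[n_ad == 0]
  m2 <- ad_only$mass[n_ad == 2]
  expect_equal(m2 - m0, 2 * 414.252, tolerance = 2e-6)
})

test_that("reversed decoys preserve the peptide mass multiset on symmetric cleavage structures", {
  # K positions symmetric under reversal: same fragment masses re-ordered
  s <- "KAGLDESVK"
  idx <- build_search_space(setNames(s, "P1"))
  cand <- idx$candidates[idx$candidates$mod_pos == "", ]
  t_mass <- sort(cand$mass[!cand$is_decoy])
  d_mass <- sort(cand$mass[cand$is_decoy])
  expect_equal(length(t_mass), length(d_mass))
  expect_equal(t_mass, d_mass, tolerance = 1e-6)
})

test_that("self-match is optimal on noiseless spectra and absent overlap scores zero", {
  pro <- generate_proteome(30, seed = 7)
  idx <- build_search_space(setNames(pro$sequence, pro$protein_id))
  cfg <- idx$config
  cand <- idx$candidates
  pick <- which(!cand$is_decoy & cand$n_dynamic == 1 &
    nchar(cand$sequence) >= 8)[1]
  mods <- orthoid:::.decode_mods(cand$mod_pos[pick], cand$mod_deltas[pick])
  th <- fragment_ions(cand$sequence[pick], mods$pos, mods$deltas, 1)
  sp <- list(
    spectrum_id = "t", precursor_mz = mass_to_mz(cand$mass[pick], 2L),
    precursor_charge = 2L,
    peaks = cbind(mz = sort(th$mz), intensity = 100)
  )
  neutral <- cand$mass[pick]
  tol <- neutral * cfg$precursor_tol_ppm * 1e-6
  within <- which(abs(cand$mass - neutral) <= tol)
  scores <- vapply(within, function(ci) {
    m <- orthoid:::.decode_mods(cand$mod_pos[ci], cand$mod_deltas[ci])
    score_psm(sp, cand$sequence[ci], m$pos, m$deltas, cfg)$score
  }, numeric(1))
  expect_equal(within[which.max(scores)], pick)
  # disjoint peaks: score exactly zero
  far <- list(
    spectrum_id = "z", precursor_mz = sp$precursor_mz,
    precursor_charge = 2L,
    peaks = cbind(mz = c(10000, 10001), intensity = c(1, 1))
  )
  expect_equal(score_psm(far, cand$sequence[pick], mods$pos, mods$deltas,
    cfg
  )$score, 0)
})

test_that("planted noiseless peptides are recovered with 100% top-rank identity", {
  pro <- generate_proteome(60, seed = 17)
  idx <- build_search_space(setNames(pro$sequence, pro$protein_id))
  lab <- simulate_labeling(pro, "NT",
    labeling_model(replicate_dropout = 0),
    seed = 18
  )
  pool <- simulate_enrichment(pro, lab, "SA",
    capture_eff = 1, background_rate = 0, seed = 19
  )
  pool <- pool[!duplicated(paste(pool$pep_sequence, pool$label_pos)), ]
  pool <- pool[seq_len(min(30L, nrow(pool))), ]
  quiet <- noise_model(0, 0, 0, 0)
  syn <- synthesize_spectra(pool, quiet, seed = 20)
  psms <- search_spectra(syn$spectra, idx)
  acc <- accepted_psms(psms, 0.01)
  expect_equal(nrow(acc), length(syn$spectra))
  hit <- merge(acc, syn$links, by = "spectrum_id")
  expect_true(all(hit$sequence == hit$pep_sequence))
  expect_true(all(hit$protein_id.x == hit$protein_id.y))
})

test_that("q-values are monotone in score and respect decoy competition", {
  pro <- generate_proteome(40, seed = 27)
  idx <- build_search_space(setNames(pro$sequence, pro$protein_id))
  lab <- simulate_labeling(pro, "NT", labeling_model(), seed = 28)
  pool <- simulate_enrichment(pro, lab, "SA", seed = 29)
  syn <- synthesize_spectra(pool, noise_model(), seed = 30)
  psms <- search_spectra(syn$spectra, idx)
  ord <- order(-psms$score)
  expect_true(all(diff(psms$q_value[ord]) >= -1e-12))
  expect_true(all(psms$q_value >= 0 & psms$q_value <= 1))
})

test_that("reported label localizations land on chemically valid residues", {
  run <- shared_run()
  psms <- run$detections # detections already restricted to labeled PSMs
  all_psms <- read_tsv_table(file.path(run$outdir, "psms.tsv"))
  acc <- all_psms[!all_psms$is_decoy & all_psms$q_value <= 0.01 &
    nzchar(all_psms$mod_pos), ]
  for (i in seq_len(nrow(acc))) {
    pos <- as.integer(strsplit(acc$mod_pos[i], ";")[[1]])
    nm <- strsplit(acc$mod_names[i], ";")[[1]]
    aa <- strsplit(acc$sequence[i], "")[[1]]
    expect_true(all(aa[pos[nm == "Ad"]] == "Y"))
    expect_true(all(aa[pos[nm == "Bt"]] == "K"))
    expect_true(all(aa[pos[nm == "Carbamidomethyl"]] == "C"))
    expect_true(all(aa[pos[nm == "Oxidation"]] == "M"))
  }
})

test_that("protein inference applies parsimony with documented tie-breaks", {
  # identical peptide sets: single group, lexicographically smaller master
  psms <- data.frame(
    spectrum_id = c("s1", "s2"), sequence = c("GAVLITK", "GAVLITK"),
    protein_id = c("B_prot", "B_prot"), start = 1L, is_decoy = FALSE,
    precursor_charge = 2L, precursor_error_ppm = 0, score = c(10, 9),
    n_dynamic = 0L, mod_pos = "", mod_names = "", mod_deltas = "",
    matched_peak_count = 10L, peptide_intensity = c(100, 90),
    q_value = 0, stringsAsFactors = FALSE
  )
  index <- list(occurrences = data.frame(
    sequence = c("GAVLITK", "GAVLITK"),
    protein_id = c("B_prot", "A_prot"), start = c(1L, 5L),
    is_decoy = FALSE, stringsAsFactors = FALSE
  ))
  g <- infer_proteins(psms, index)
  expect_equal(nrow(g), 1L)
  expect_identical(g$master_protein_id, "A_prot")
  expect_true(grepl("B_prot", g$member_ids))

  # a protein subsumed by another with an extra unique peptide never masters
  psms2 <- rbind(psms, transform(psms[1, ],
    spectrum_id = "s3",
    sequence = "LLDDFEK"
  ))
  index2 <- list(occurrences = data.frame(
    sequence = c("GAVLITK", "GAVLITK", "LLDDFEK"),
    protein_id = c("big", "small", "big"), start = c(1L, 5L, 20L),
    is_decoy = FALSE, stringsAsFactors = FALSE
  ))
  g2 <- infer_proteins(psms2, index2)
  expect_identical(g2$master_protein_id, "big")
  expect_equal(g2$n_peptides, 2L)
})

test_that("LFQ averages peptide intensities and scales linearly", {
  run <- shared_run()
  psms <- read_tsv_table(file.path(run$outdir, "psms.tsv"))
  one <- psms[psms$arm == "SA" & psms$replicate == 1 &
    psms$condition == "NT", ]
  class(one) <- c("psm_table", "data.frame")
  groups <- infer_proteins(one, run$index)
  q1 <- lfq(one, groups)
  two <- one
  two$peptide_intensity <- two$peptide_intensity * 2
  q2 <- lfq(two, groups)
  expect_equal(q2$intensity, q1$intensity * 2, tolerance = 1e-12)
  singles <- groups$master_protein_id[groups$n_peptides == 1 &
    !groups$is_decoy]
  for (p in singles) {
    pep <- groups$peptides[groups$master_protein_id == p]
    expect_equal(
      q1$intensity[q1$protein_id == p],
      sum(one$peptide_intensity[one$sequence == pep &
        one$q_value <= 0.01 & !one$is_decoy])
    )
  }
})

test_that("spectra with unconfigured charge are skipped and counted", {
  idx <- build_search_space(c(P1 = "GAVLITGAVLDEK"))
  sp <- list(list(
    spectrum_id = "z5", precursor_mz = 400, precursor_charge = 5L,
    peaks = cbind(mz = 200, intensity = 1)
  ))
  psms <- search_spectra(sp, idx)
  expect_equal(nrow(psms), 0L)
  expect_equal(attr(psms, "n_skipped"), 1L)
})
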