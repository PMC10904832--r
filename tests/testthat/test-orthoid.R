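make_detections <- function(reps, arm = "SA", cond = "NT",
                            protein = "P1") {
  if (!length(reps)) {
    return(data.frame(
      protein_id = character(0), arm = character(0),
      replicate = integer(0), condition = character(0),
      stringsAsFactors = FALSE
    ))
  }
  data.frame(
    protein_id = protein, arm = arm, replicate = reps, condition = cond,
    stringsAsFactors = FALSE
  )
}

test_that("replicate consensus implements the at-least-2-of-3 rule", {
  expect_identical(
    replicate_consensus(make_detections(c(1, 3)), "SA", "NT"), "P1"
  )
  expect_identical(
    replicate_consensus(make_detections(2), "SA", "NT"), character(0)
  )
  expect_identical(
    replicate_consensus(make_detections(1:3), "SA", "NT"), "P1"
  )
  # duplicated detections within one replicate do not count twice
  expect_identical(
    replicate_consensus(make_detections(c(2, 2)), "SA", "NT"),
    character(0)
  )
  # a 3-of-3 requirement never enlarges the reliable set
  det <- rbind(
    make_detections(c(1, 2), protein = "P1"),
    make_detections(1:3, protein = "P2")
  )
  r2 <- replicate_consensus(det, "SA", "NT", min_reps = 2)
  r3 <- replicate_consensus(det, "SA", "NT", min_reps = 3)
  expect_true(all(r3 %in% r2))
  expect_identical(r3, "P2")
})

test_that("annotation partitioning keeps only organelle-annotated proteins", {
  ann <- data.frame(
    protein_id = c("a", "b", "c", "d"),
    annotation = c("ER", "mitochondria", "both", "other"),
    stringsAsFactors = FALSE
  )
  f <- annotation_filter(c("a", "b", "c", "d", "zz"), ann)
  expect_identical(f$ER, "a")
  expect_identical(f$mitochondria, "b")
  expect_identical(f$both, "c")
  expect_setequal(f$other, c("d", "zz"))
  expect_equal(f$n_unannotated, 1L)
  expect_setequal(f$retained, c("a", "b", "c"))
  empty <- annotation_filter(character(0), ann)
  expect_length(empty$retained, 0L)
})

test_that("arm intersection is an exact set intersection", {
  expect_length(intersect_arms(c("a", "b"), c("c", "d")), 0L)
  expect_identical(intersect_arms(c("b", "a"), c("a", "c")), "a")
})

test_that("the model-protein mixture resolves BSA as the only dual-labeled protein", {
  res <- run_model_protein_experiment(seed = 5)
  expect_setequal(res$reliable_SA, c("MYB", "BSA"))
  expect_setequal(res$reliable_CB7, c("OVA", "BSA"))
  expect_identical(res$dual, "BSA")
})

test_that("topology validation separates rule, exception classes and violations", {
  topo <- data.frame(
    protein_id = rep(c("omm1", "er1", "mat1"), each = 3),
    position = rep(1:3, 3),
    residue = c("K", "Y", "Y", "K", "Y", "K", "K", "K", "Y"),
    sidedness = c(
      "cytosol", "cytosol", "IMS",
      "lumen", "lumen", "cytosol",
      "matrix", "matrix", "matrix"
    ),
    endogenous_biotin = c(rep(FALSE, 6), TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  meta <- data.frame(
    protein_id = c("omm1", "er1", "mat1"),
    compartment = c("OMM", "ER_lumen", "matrix"),
    distance_to_junction = c(0.5, 3, 9),
    stringsAsFactors = FALSE
  )
  sites <- data.frame(
    protein_id = c("omm1", "omm1", "omm1", "er1", "er1", "mat1", "mat1"),
    position = c(1, 2, 3, 2, 1, 1, 2),
    label = c("Bt", "Ad", "Ad", "Ad", "Bt", "Bt", "Bt"),
    stringsAsFactors = FALSE
  )
  nt <- topology_check(sites, topo, meta, condition = "NT")
  flags <- setNames(nt$flags$topology_consistent, nt$flags$protein_id)
  # omm1: cytosolic K ok; leakage Y ok; IMS Y under NT is a violation
  expect_identical(flags[["omm1"]], "no")
  expect_true(any(
    nt$violations$protein_id == "omm1" & nt$violations$position == 3
  ))
  expect_true(any(
    nt$exceptions$class == "leakage" & nt$exceptions$protein_id == "omm1"
  ))
  # er1: lumen Ad ok, but Bt on a lumen-side K is a violation
  expect_identical(flags[["er1"]], "no")
  # mat1: endogenous biotin K excepted; plain matrix K violates
  expect_true(any(
    nt$exceptions$class == "endogenous" & nt$exceptions$protein_id == "mat1"
  ))
  cc <- topology_check(sites[1:3, ], topo, meta, condition = "CCCP")
  ccflags <- setNames(cc$flags$topology_consistent, cc$flags$protein_id)
  expect_identical(ccflags[["omm1"]], "yes")
  # a protein absent from the topology table is never silently consistent
  unk <- topology_check(
    data.frame(
      protein_id = "ghost", position = 1, label = "Bt",
      stringsAsFactors = FALSE
    ),
    topo, meta
  )
  expect_identical(unk$flags$topology_consistent, "unknown")
})

test_that("differential site flags follow the PSM-count contrast rule", {
  site <- function(n, cond, pos = 10) {
    if (n == 0) {
      return(NULL)
    }
    data.frame(
      spectrum_id = sprintf("%s_%d_%d", cond, pos, seq_len(n)),
      protein_id = "P1", position = pos, label = "Ad",
      stringsAsFactors = FALSE
    )
  }
  empty <- site(0, "NT")
  ds <- differential_sites(
    rbind(site(0, "NT")),
    rbind(site(3, "CCCP"))
  )
  expect_identical(ds$flag, "CCCP-gained")
  ds2 <- differential_sites(site(2, "NT"), site(2, "CCCP"))
  expect_identical(ds2$flag, "stable")
  # one PSM in the gaining condition is below the default threshold
  ds3 <- differential_sites(site(0, "NT"), site(1, "CCCP"))
  expect_identical(ds3$flag, "stable")
  ds4 <- differential_sites(site(2, "NT"), site(0, "CCCP"))
  expect_identical(ds4$flag, "NT-only")
})

test_that("dual calls are always a subset of each arm's reliable set", {
  run <- shared_run()
  for (cond in names(run$calls)) {
    cl <- run$calls[[cond]]
    dual <- cl$protein_id[cl$dual]
    expect_true(all(dual %in% cl$protein_id[cl$reliable_SA]))
    expect_true(all(dual %in% cl$protein_id[cl$reliable_CB7]))
    expect_true(all(
      cl$annotation_class[cl$dual] %in% c("ER", "mitochondria", "both")
    ))
  }
})

test_that("endogenously biotinylated background never enters the dual set", {
  run <- shared_run()
  endo <- run$proteome$protein_id[
    lengths(run$proteome$endogenous_biotin) > 0
  ]
  for (cond in names(run$calls)) {
    cl <- run$calls[[cond]]
    # endogenous carriers are matrix/cytosol proteins with no Ad exposure
    expect_length(intersect(cl$protein_id[cl$dual], endo), 0L)
  }
})
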