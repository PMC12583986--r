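refs <- load_reference_proteins()
shc_ref <- protein_record("REF_SHC", as.character(refs[["REF_SHC"]]))

test_that("mutation is exact at 100, validated, and deterministic per seed", {
  same <- mutate_protein(shc_ref, 100, seed = 1)
  expect_equal(same$sequence, shc_ref$sequence)
  expect_error(mutate_protein(shc_ref, 0, seed = 1), "target_similarity")
  expect_error(mutate_protein(shc_ref, 101, seed = 1), "target_similarity")
  a <- mutate_protein(shc_ref, 60, seed = 4)
  b <- mutate_protein(shc_ref, 60, seed = 4)
  c <- mutate_protein(shc_ref, 60, seed = 5)
  expect_identical(a$sequence, b$sequence)
  expect_false(identical(a$sequence, c$sequence))
})

test_that("realized similarity lands within 5 points of target over 100 seeds", {
  # measured with the alignment oracle the mutants are built against
  for (target in c(55, 75)) {
    realized <- vapply(1:50, function(s) {
      m <- mutate_protein(shc_ref, target, seed = s)
      align_local(shc_ref, m)$percent_similarity
    }, numeric(1))
    expect_true(all(abs(realized - target) <= 5),
                label = sprintf("target %d: range %.1f-%.1f", target,
                                min(realized), max(realized)))
  }
})

test_that("a full canonical cluster scenario is recovered as one contiguous BGC", {
  fams <- c(mep_families, "hpnC", "hpnD", "hpnE", "shc", "hpnG", "hpnH",
            "hpnI", "hpnJ", "hpnK", "hpnN")
  sim <- simulate_genome(genotype_scenario(fams, n_background = 40,
                                           n_decoys = 1), seed = 2024)
  # locus tags step by 5 within each contig
  for (ctg in unique(sim$features$contig)) {
    nums <- as.integer(sub(".*_", "", sim$features$locus_tag[
      sim$features$contig == ctg]))
    expect_equal(unique(diff(sort(nums))), 5L)
  }
  hits <- scan_proteome(sim$proteome, genome_id = "sim")
  expect_setequal(accepted_hits(hits)$family_id, fams)
  # the planted decoy is recognized as the secondary shc clade
  decoy_calls <- hits$call[hits$protein_id %in% sim$truth$decoy_tags &
                             hits$family_id == "shc"]
  expect_true(all(decoy_calls == "rejected_decoy"))
  ar <- classify_architecture(cluster_hits(hits, sim$features))
  expect_equal(ar$class, "contiguous")
  expect_equal(ar$order_concordance, 1.0)
})

test_that("an Ensifer-like genome predicts C30 hopanoids but no BHPDs", {
  fams <- c(mep_families, "hpnC", "hpnD", "hpnE", "shc")
  sim <- simulate_genome(genotype_scenario(fams, n_background = 30), seed = 77)
  hits <- scan_proteome(sim$proteome, genome_id = "ens")
  pred <- predict_chemotype(assemble_genotype(hits))
  expect_true(pred$c30_hopanoids)
  expect_false(pred$bhpd_any)
})

test_that("genome simulation is reproducible under a fixed seed", {
  sc <- genotype_scenario(c(mep_families, "shc"), n_background = 15)
  a <- simulate_genome(sc, seed = 9)
  b <- simulate_genome(sc, seed = 9)
  c <- simulate_genome(sc, seed = 10)
  expect_identical(as.character(a$proteome), as.character(b$proteome))
  expect_identical(a$features, b$features)
  expect_false(identical(as.character(a$proteome), as.character(c$proteome)))
})

test_that("noiseless lipidomes reproduce every planted quantity exactly", {
  chem <- predict_chemotype(genotype("s", presence_from(
    c(mep_families, "hpnC", "hpnD", "hpnE", "shc", "hpnG", "hpnH",
      "hpnO", "hpnP", "hpnR"))))
  sim <- simulate_lipidome(chem, seed = 31, noise_cv = 0,
                           me2_degree_pct = 5.1, me3_degree_pct = 0.2,
                           s22_pct = 21)
  pk <- sim$gc_peaks
  u <- sum(pk$area[pk$analyte %in% c("c32_hopanol", "c32_hopanol_22S",
                                     "c32_hopanol_22R")])
  m2 <- pk$area[pk$analyte == "2me_c32_hopanol"]
  expect_equal(methylation_degree(m2, u), 5.1)
  m3 <- pk$area[pk$analyte == "3me_c32_hopanol"]
  expect_equal(methylation_degree(m3, u), 0.2)
  expect_equal(epimer_fraction(pk$area[pk$analyte == "c32_hopanol_22S"],
                               pk$area[pk$analyte == "c32_hopanol_22R"]), 21)
  # internal-standard quantification recovers the planted visible concentration
  vis <- 100 - attr(sim$truth$gc_profile, "invisible_fraction")
  conc <- quantify_by_internal_standard(
    sum(pk$area[pk$product_mz %in% 191]),
    pk$area[pk$analyte == "IS_n-tricosan-1-ol"],
    biomass_g = sim$truth$biomass_g)
  expect_equal(conc, sim$truth$total_conc_mg_g * vis / 100, tolerance = 1e-9)
})

test_that("noisy methylation recovery is unbiased at the planted degree", {
  chem <- predict_chemotype(genotype("s", presence_from(
    c(mep_families, "hpnC", "hpnD", "hpnE", "shc", "hpnG", "hpnH", "hpnP"))))
  recovered <- vapply(1:200, function(s) {
    sim <- simulate_lipidome(chem, seed = s, noise_cv = 0.05,
                             me2_degree_pct = 5.1)
    pk <- sim$gc_peaks
    methylation_degree(sum(pk$area[pk$analyte == "2me_c32_hopanol"]),
                       sum(pk$area[pk$analyte == "c32_hopanol"]))
  }, numeric(1))
  expect_lt(abs(mean(recovered) - 5.1), 0.5)
})

test_that("the generator never emits structures the chemotype forbids", {
  chem_no_me <- predict_chemotype(genotype("s", presence_from(
    c(mep_families, "hpnC", "hpnD", "hpnE", "shc", "hpnG", "hpnH"))))
  for (s in 1:20) {
    sim <- simulate_lipidome(chem_no_me, seed = s)
    expect_false(any(grepl("^2me_|^3me_", sim$gc_peaks$analyte)))
  }
  none <- predict_chemotype(genotype("n", presence_from(character(0))))
  expect_error(simulate_lipidome(none, seed = 1), "nothing to simulate")
})
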