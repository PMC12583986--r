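catalog <- load_gene_catalog()

test_that("MEP completeness handles the fused ispDF and the aceE bypass", {
  g1 <- genotype("a", presence_from(mep_families))
  expect_true(g1$mep_complete)
  expect_match(paste(g1$mep_notes, collapse = ";"), "fused")
  g2 <- genotype("b", presence_from(c(setdiff(mep_families, "dxs"), "aceE")))
  expect_true(g2$mep_complete)
  expect_match(paste(g2$mep_notes, collapse = ";"), "bypass")
  g3 <- genotype("c", presence_from(setdiff(mep_families, "dxs")))
  expect_false(g3$mep_complete)
  # split ispD + ispF is as good as the fusion
  g4 <- genotype("d", presence_from(c(setdiff(mep_families, "ispDF"),
                                      "ispD", "ispF")))
  expect_true(g4$mep_complete)
})

test_that("assemble_genotype covers the catalog and rejects mixed genomes", {
  hits <- fake_hits(c("shc", "hpnH"), c("x1", "x2"))
  g <- assemble_genotype(hits)
  expect_setequal(names(g$presence), catalog$family_id)
  expect_equal(unname(g$presence[c("shc", "hpnH")]), c("present", "present"))
  expect_true(all(g$presence[setdiff(catalog$family_id, c("shc", "hpnH"))]
                  == "absent"))
  mixed <- rbind(fake_hits("shc", "x1", genome_id = "g1"),
                 fake_hits("hpnH", "x2", genome_id = "g2"))
  expect_error(assemble_genotype(mixed), "mixed")
  empty <- assemble_genotype(fake_hits(character(0), character(0)))
  expect_true(all(empty$presence == "absent"))
  expect_false(empty$mep_complete)
})

test_that("biosynthesis rules reproduce the narrated genotype cases", {
  # shc without hpnH/hpnG: C30 hopanoids but no BHPDs (Ensifer-like)
  p1 <- predict_chemotype(genotype("e", presence_from(c(mep_families,
    "hpnC", "hpnD", "hpnE", "shc"))))
  expect_true(p1$c30_hopanoids)
  expect_false(p1$bhpd_any)
  # full core plus hpnI/hpnK but no hpnJ: glucosamine-terminal CE branch
  p2 <- predict_chemotype(genotype("r", presence_from(c(mep_families,
    "hpnC", "hpnD", "hpnE", "shc", "hpnG", "hpnH", "hpnI", "hpnK"))))
  expect_true(p2$bht)
  expect_true(p2$ce_glucosamine_terminal)
  expect_false(p2$ce_terminal)
  expect_false(p2$ce_acetylglucosamine_terminal)
  # tetrahymanol synthase alone suffices for tetrahymanol
  p3 <- predict_chemotype(genotype("t", presence_from("ths")))
  expect_true(p3$tetrahymanol)
  # nothing present: nothing predicted
  p4 <- predict_chemotype(genotype("z", presence_from(character(0))))
  expect_false(any(unlist(p4[vapply(p4, is.logical, logical(1))])))
})

test_that("unknown gene states never assert a flag and are surfaced as notes", {
  pres <- presence_from(c(mep_families, "hpnC", "hpnD", "hpnE", "shc"))
  pres["hpnH"] <- "unknown"
  p <- predict_chemotype(genotype("u", pres))
  expect_false(p$bhpd_any)
  expect_match(paste(p$confidence_notes, collapse = "; "), "hpnH")
})

test_that("implication chain and terminal exclusivity hold over random genotypes", {
  set.seed(77)
  fams <- catalog$family_id
  for (i in 1:1000) {
    pres <- stats::setNames(sample(c("present", "absent"), length(fams),
                                   replace = TRUE), fams)
    p <- predict_chemotype(genotype("x", pres))
    expect_true(!p$bhpd_any || p$c30_hopanoids)
    expect_true(!p$bht || p$bhpd_any)
    expect_true(!p$ce_terminal || p$bht)
    expect_lte(sum(p$ce_acetylglucosamine_terminal,
                   p$ce_glucosamine_terminal, p$ce_terminal), 1)
  }
})

test_that("adding a gene never retracts a cumulative capacity", {
  # the three ce_* flags describe the terminal branch stage, which by design
  # moves forward when hpnK/hpnJ arrive; monotonicity is asserted for the
  # cumulative capacities
  cumulative <- c("c30_hopanoids", "bhpd_any", "adenosylhopane", "bht",
                  "aminotriol", "methyl_2", "methyl_3",
                  "dimethyl_2_3_possible", "tetrahymanol",
                  "unsaturation_suggested")
  set.seed(123)
  fams <- catalog$family_id
  for (i in 1:300) {
    pres <- stats::setNames(sample(c("present", "absent"), length(fams),
                                   replace = TRUE, prob = c(0.4, 0.6)), fams)
    before <- predict_chemotype(genotype("m", pres))
    absent <- names(pres)[pres == "absent"]
    if (!length(absent)) next
    pres[sample(absent, 1)] <- "present"
    after <- predict_chemotype(genotype("m", pres))
    for (f in cumulative)
      expect_true(!isTRUE(before[[f]]) || isTRUE(after[[f]]), label = f)
  }
})
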