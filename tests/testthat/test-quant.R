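test_that("internal-standard quantification follows the protocol arithmetic", {
  # equal areas with the protocol's 0.03075 mg of standard over 30 mg cells
  expect_equal(quantify_by_internal_standard(1e5, 1e5, 0.03075, 0.030), 1.025)
  expect_equal(quantify_by_internal_standard(0, 1e5, 0.03075, 0.030), 0)
  one <- quantify_by_internal_standard(2e4, 1e5, biomass_g = 0.02)
  two <- quantify_by_internal_standard(4e4, 1e5, biomass_g = 0.02)
  expect_equal(two, 2 * one)
  expect_error(quantify_by_internal_standard(1, 0, biomass_g = 0.02), "> 0")
  expect_error(quantify_by_internal_standard(1, 1, biomass_g = 0), "> 0")
})

test_that("degree of methylation and epimer fraction are exact ratios", {
  expect_equal(methylation_degree(5.1, 94.9), 5.1)
  expect_equal(methylation_degree(0, 10), 0)
  expect_equal(methylation_degree(3, 3), 50)
  expect_error(methylation_degree(0, 0), "zero")
  expect_equal(epimer_fraction(79, 21), 79)
  expect_equal(epimer_fraction(0, 5), 0)
  expect_equal(epimer_fraction(2, 2), 50)
  expect_error(epimer_fraction(0, 0), "zero")
})

test_that("ratio statistics are invariant under area rescaling", {
  set.seed(5)
  for (i in 1:50) {
    a <- runif(1, 0, 100); b <- runif(1, 0.1, 100); c <- runif(1, 1e-6, 1e6)
    expect_equal(methylation_degree(a, b), methylation_degree(c * a, c * b))
    expect_equal(epimer_fraction(a, b), epimer_fraction(c * a, c * b))
  }
})

test_that("inventory normalization is proportional and drops zero responses", {
  bht <- bhpd_structure("tetrol", c22_config = "R", structure_id = "IIa")
  pent <- bhpd_structure("pentol", structure_id = "IIf")
  hex <- bhpd_structure("hexol", structure_id = "IIi")
  single <- normalize_inventory(list(bht), 7)
  expect_equal(single$rel_abundance, 100)
  inv <- normalize_inventory(list(bht, pent, hex), c(1, 1, 2))
  expect_equal(inv$rel_abundance, c(25, 25, 50))
  dropped <- normalize_inventory(list(bht, pent), c(3, 0))
  expect_equal(nrow(dropped), 1)
  expect_error(normalize_inventory(list(bht), 0), "positive")
  set.seed(8)
  for (i in 1:30) {
    n <- sample(1:10, 1)
    inv <- normalize_inventory(rep(list(bht), n), runif(n, 0.01, 5))
    expect_equal(sum(inv$rel_abundance), 100, tolerance = 1e-9)
  }
})

test_that("inventory summaries follow their definitions exactly", {
  s_empty <- summarize_inventory(NULL)
  expect_equal(s_empty$n_bhpds, 0)
  expect_equal(s_empty$pct_unsaturated, 0)

  d6bht <- bhpd_structure("tetrol", unsaturation = "d6", c22_config = "R")
  bht <- bhpd_structure("tetrol", c22_config = "R")
  s <- summarize_inventory(normalize_inventory(list(d6bht, bht), c(60, 40)))
  expect_equal(s$pct_unsaturated, 60)
  expect_equal(s$pct_pentol_plus_hexol, 0)

  # generator-style bookkeeping: a known class mixture summarizes exactly
  mix <- list(
    bhpd_structure("nucleoside", subtype = "adenosyl", c22_config = "R"),
    bhpd_structure("tetrol", c22_config = "R"),
    bhpd_structure("pentol", c22_config = "S"),
    bhpd_structure("ce_series", base = "hexol", stage = "cyclitol"),
    bhpd_structure("carbamoyl", base = "pentol"),
    bhpd_structure("amino", subtype = "aminotriol"))
  sm <- summarize_inventory(normalize_inventory(mix, c(10, 20, 30, 15, 5, 20)))
  expect_equal(sm$n_bhpds, 6)
  expect_equal(sm$pct_pentol_plus_hexol, 30 + 15 + 5)
  expect_equal(unname(sm$pct_by_group),
               c(10, 50, 15, 5, 20))  # nucleoside, polyol, ce, carbamoyl, amino
  expect_equal(sum(sm$pct_by_group), 100, tolerance = 0.1)
  expect_equal(sm$s22_fraction, 100 * 30 / (10 + 20 + 30))
})

test_that("structure validation rejects illegal field combinations", {
  expect_error(bhpd_structure("nucleoside"), "subtype")
  expect_error(bhpd_structure("tetrol", subtype = "Me-ether"), "not applicable")
  expect_error(bhpd_structure("ce_series", stage = "cyclitol"), "base")
  expect_error(bhpd_structure("ce_series", base = "tetrol"), "stage")
  expect_error(bhpd_structure("tetrol", ring_a_methyl = "4Me"), "ring_a_methyl")
  expect_error(bhpd_structure("tetrol", unsaturation = "d9"), "unsaturation")
  expect_error(bhpd_structure("tetrol", c22_config = "T"), "c22_config")
  expect_error(bhpd_structure("mystery"), "side_chain_class")
})

test_that("report rendering switches precision at 10 and flags trace values", {
  expect_equal(render_percent(c(49, 5.1, 0.005)), c("49%", "5.1%", "<d.l."))
})
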