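test_that("degradation products fingerprint the parent polyol class", {
  bht <- bhpd_structure("tetrol", c22_config = "R")
  p <- degradation_product(bht)
  expect_equal(p$carbon_number, 32)
  expect_equal(p$c22_config, "R")
  expect_null(degradation_product(
    bhpd_structure("nucleoside", subtype = "adenosyl")))
  expect_equal(degradation_product(bhpd_structure("hexol"))$carbon_number, 30)
  expect_equal(degradation_product(bhpd_structure("pentol"))$carbon_number, 31)
  # CE and carbamoyl derivatives cleave at the polyol diols of their base
  expect_equal(degradation_product(bhpd_structure("ce_series", base = "pentol",
    stage = "cyclitol"))$carbon_number, 31)
  expect_equal(degradation_product(bhpd_structure("carbamoyl",
    base = "hexol"))$carbon_number, 30)
  # the internal ether of anhydro pentols removes the free diol
  expect_null(degradation_product(bhpd_structure("anhydro_pentol")))
  # methylation, unsaturation and C-22 configuration pass through
  m <- degradation_product(bhpd_structure("tetrol", ring_a_methyl = "2Me",
    unsaturation = c("d6", "d11"), c22_config = "S"))
  expect_equal(m$ring_a_methyl, "2Me")
  expect_equal(m$n_double_bonds, 2)
  expect_equal(m$c22_config, "S")
})

test_that("every roster structure maps to a legal product or none", {
  for (s in load_structure_roster()) {
    p <- degradation_product(s)
    if (!is.null(p)) {
      expect_true(p$carbon_number %in% c(30L, 31L, 32L))
      expect_equal(p$ring_a_methyl, s$ring_a_methyl)
    }
  }
})

test_that("GC profiles weight, renormalize and track the invisible fraction", {
  adeno <- bhpd_structure("nucleoside", subtype = "adenosyl", c22_config = "R")
  bht <- bhpd_structure("tetrol", c22_config = "R")
  pent <- bhpd_structure("pentol", c22_config = "R")

  only_adeno <- predict_gc_profile(normalize_inventory(list(adeno), 1))
  expect_equal(nrow(only_adeno), 0)
  expect_equal(attr(only_adeno, "invisible_fraction"), 100)

  half <- predict_gc_profile(normalize_inventory(list(bht, pent), c(1, 1)))
  expect_equal(attr(half, "invisible_fraction"), 0)
  expect_equal(half$share[half$carbon_number == 32], 50)
  expect_equal(half$share[half$carbon_number == 31], 50)
})

test_that("random inventories match a per-structure enumeration oracle", {
  roster <- load_structure_roster()
  set.seed(91)
  for (rep in 1:25) {
    pick <- sample(roster, sample(3:12, 1))
    inv <- normalize_inventory(unname(pick), runif(length(pick), 0.1, 10))
    prof <- predict_gc_profile(inv)
    # oracle: accumulate shares structure by structure
    vis <- 0; by_cn <- c(`30` = 0, `31` = 0, `32` = 0)
    for (i in seq_len(nrow(inv))) {
      p <- degradation_product(inv$structure[[i]])
      if (!is.null(p)) {
        vis <- vis + inv$rel_abundance[i]
        by_cn[as.character(p$carbon_number)] <-
          by_cn[as.character(p$carbon_number)] + inv$rel_abundance[i]
      }
    }
    expect_equal(attr(prof, "invisible_fraction"), 100 - vis)
    for (cn in c(30, 31, 32)) {
      got <- sum(prof$share[prof$carbon_number == cn])
      want <- if (vis > 0) 100 * by_cn[as.character(cn)] / vis else 0
      expect_equal(got, unname(want), tolerance = 1e-9)
    }
    # with no nucleoside (or anhydro) share everything is visible
    if (!any(vapply(inv$structure, function(s)
      s$side_chain_class %in% c("nucleoside", "anhydro_pentol"), logical(1))))
      expect_equal(attr(prof, "invisible_fraction"), 0)
  }
})

test_that("cross-platform checks pass on consistent pairs and flag corruption", {
  bht <- bhpd_structure("tetrol", c22_config = "R")
  pent <- bhpd_structure("pentol", c22_config = "R")
  d6 <- bhpd_structure("tetrol", unsaturation = "d6", c22_config = "R")
  inv <- normalize_inventory(list(bht, pent, d6), c(50, 30, 20))
  lc <- summarize_inventory(inv)
  gc <- predict_gc_profile(inv)
  rep_ok <- cross_platform_check(lc, gc)
  expect_true(all(rep_ok$pass))
  expect_equal(rep_ok$delta, rep(0, 3))
  # corrupt the pentol share by +20 points
  bad <- normalize_inventory(list(bht, pent, d6), c(30, 50, 20))
  rep_bad <- cross_platform_check(summarize_inventory(bad), gc)
  expect_false(rep_bad$pass[rep_bad$quantity == "pct_pentol_plus_hexol"])
})
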