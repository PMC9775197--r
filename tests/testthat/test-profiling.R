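test_that("descriptor vector is complete and matches hand values", {
  d <- compute_descriptors(c("C", "CCO", "c1ccccc1"))
  expect_false(anyNA(d))
  expect_equal(d$mw[1], 16.04, tolerance = 1e-3)   # methane, atomic masses
  expect_equal(d$hbd[2], 1)                        # ethanol
  expect_equal(d$hba[2], 1)
  expect_equal(d$n_aromatic_rings[3], 1)           # benzene
  expect_equal(d$fr_Ar_OH[3], 0)
  # schema identical for all inputs
  expect_equal(names(compute_descriptors("CCN")), names(d))
})

test_that("functional-group counts hit the intended chemotypes", {
  d <- compute_descriptors(c("Oc1ccccc1", "OCC", "NNc1ccccc1",
                             "NS(=O)(=O)c1ccccc1", "Sc1ccccc1",
                             "Cc1ccccc1"))
  expect_equal(d$fr_Ar_OH, c(1, 0, 0, 0, 0, 0))
  expect_equal(d$fr_Al_OH, c(0, 1, 0, 0, 0, 0))
  expect_equal(d$fr_hdrzine, c(0, 0, 1, 0, 0, 0))
  expect_equal(d$fr_sulfonamd, c(0, 0, 0, 1, 0, 0))
  expect_equal(d$fr_SH, c(0, 0, 0, 0, 1, 0))
  expect_equal(d$fr_aryl_methyl, c(0, 0, 0, 0, 0, 1))
})

test_that("rule-of-5 filter applies limits with boundary compliance", {
  d <- data.frame(mw = c(46, 600, 500), logp = c(0, 2, 2),
                  hbd = c(1, 1, 1), hba = c(1, 2, 2))
  f <- lipinski_filter(d)
  expect_equal(f$pass, c(TRUE, FALSE, TRUE))     # exactly 500 is compliant
  expect_equal(f$violations[2], "MW>500")
  f1 <- lipinski_filter(data.frame(mw = 600, logp = 7, hbd = 1, hba = 2),
                        max_violations = 1)
  expect_false(f1$pass)                          # two violations
  expect_equal(f1$violations, "MW>500;logP>5")
})

test_that("structural alerts flag catechol and thiocarbonyl, not methane", {
  a <- structural_alerts(c("Oc1ccccc1O", "NC(=S)Nc1ccccc1", "C"), "brenk")
  expect_true("catechol" %in% a[[1]])
  expect_true("thiocarbonyl" %in% a[[2]])
  expect_equal(a[[3]], character(0))
  p <- structural_alerts("O=C1C=CC(=O)C=C1", "pains")
  expect_true("quinone_A" %in% p[[1]])
})

test_that("alerts under a superset catalog contain the subset's alerts", {
  full <- load_alert_catalog("brenk")
  small <- full[c("thiocarbonyl", "catechol", "nitro")]
  smi <- cached_curated()$compounds$canonical_smiles[1:30]
  a_small <- structural_alerts(smi, small)
  a_full <- structural_alerts(smi, full)
  for (i in seq_along(smi))
    expect_true(all(a_small[[i]] %in% a_full[[i]]))
})

test_that("group census counts compounds once and is monotone", {
  gl <- cached_library()
  cur <- cached_curated()
  census <- group_census(cur, default_group_map())
  # planted truth: hydrazine-bearing compounds are known exactly
  n_hdr <- sum(gl$truth$compounds$rule_bearing)
  expect_equal(census$n_compounds[census$group == "hydrazine"], n_hdr)
  expect_equal(census$pct_active[census$group == "hydrazine"], 100)
  # monotonicity: census over a subset never exceeds the full census
  sub_census <- group_census(head(cur$compounds, 150), default_group_map())
  expect_true(all(sub_census$n_compounds <= census$n_compounds))
  # degenerate cases
  one <- group_census(data.frame(canonical_smiles = "NNc1ccccc1",
                                 activity_class = "active",
                                 stringsAsFactors = FALSE),
                      c(hydrazine = "[NX3][NX3]"))
  expect_equal(one$n_compounds, 1)
  expect_equal(one$pct_active, 100)
  empty <- group_census(cur$compounds[0, ], default_group_map())
  expect_equal(nrow(empty), 0)
})

test_that("temporal trends aggregate by year with an unknown bucket", {
  comp <- data.frame(
    first_year = c(2013L, 2013L, 2013L, NA),
    activity_class = c("active", "inactive", "inactive", "active"),
    stringsAsFactors = FALSE)
  tr <- temporal_trends(comp)
  expect_equal(tr$n_compounds[tr$year == "2013"], 3)
  expect_equal(tr$pct_active[tr$year == "2013"], 33.3)
  expect_equal(tr$n_compounds[tr$year == "unknown"], 1)
  all_unknown <- temporal_trends(data.frame(first_year = c(NA, NA),
                                            activity_class = c("active",
                                                               "inactive")))
  expect_equal(all_unknown$year, "unknown")
})

test_that("species concordance flags cross-species class flips", {
  rec <- data.frame(
    inchikey = c("K1", "K1", "K2", "K2", "K3", "K3", "K4", "K5", "K5",
                 "K6", "K6", "K7", "K7"),
    species = c("a", "b", "a", "b", "a", "b", "a", "a", "b", "a", "b",
                "a", "b"),
    activity_class = c("active", "active",      # K1 concordant
                       "active", "inactive",    # K2 discordant
                       "inactive", "inactive",  # K3 concordant
                       "active",                # K4 single species
                       "active", "active",      # K5 concordant
                       "inactive", "inactive",  # K6 concordant
                       "active", "active"),     # K7 concordant
    stringsAsFactors = FALSE)
  conc <- species_concordance(rec)
  expect_equal(conc$n_multi_species, 6)
  expect_equal(conc$n_discordant, 1)
  # 5 multi-species compounds with 1 discordant: 20.0%
  rec5 <- rec[rec$inchikey %in% c("K1", "K2", "K3", "K5", "K6"), ]
  expect_equal(species_concordance(rec5)$pct_discordant, 20.0)
})

test_that("class-conditional descriptor histograms conserve mass", {
  cur <- cached_curated()
  d <- cached_descriptors()
  cls <- cur$compounds$activity_class
  breaks <- pretty(d$mw, 12)
  counts <- table(cls, cut(d$mw, breaks, include.lowest = TRUE))
  expect_equal(unname(rowSums(counts)), unname(as.vector(table(cls))))
})
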