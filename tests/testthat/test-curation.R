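test_that("standardization is deterministic and canonicalizes spellings", {
  a <- standardize_structure(c("c1ccccc1", "C1=CC=CC=C1", "c1ccccc1"))
  expect_false(any(a$parse_error))
  expect_equal(a$inchikey[1], a$inchikey[2])
  expect_equal(a$canonical_smiles[1], a$canonical_smiles[3])
  expect_equal(a$inchikey[1], a$inchikey[3])
})

test_that("salt stripping and neutralization map salt and parent together", {
  pair <- standardize_structure(c("OC(=O)c1ccccc1.[Na+]", "OC(=O)c1ccccc1",
                                  "[O-]C(=O)c1ccccc1"))
  expect_equal(pair$inchikey[1], pair$inchikey[2])
  expect_equal(pair$inchikey[2], pair$inchikey[3])
})

test_that("unparsable SMILES are reported, not dropped silently", {
  res <- standardize_structure(c("CCO", "C1CC", "not_a_smiles"))
  expect_equal(res$parse_error, c(FALSE, TRUE, TRUE))
})

test_that("structure exclusion separates keeps, metals, and mixtures", {
  fate <- exclude_structure(c("CCO",
                              "CC[Ni]CC",
                              "CCO.OCCC",
                              "OC(=O)c1ccccc1.[Na+]",
                              "C1CC"))
  expect_equal(fate, c("keep", "metal_complex", "mixture", "keep",
                       "parse_error"))
  # duplicated organic fragments collapse to the parent, not a mixture
  expect_equal(exclude_structure("CCO.CCO"), "keep")
})

test_that("qualitative inactives get the 1000 uM excess value", {
  rec <- data.frame(activity_value = c(NA, 5, NA),
                    activity_type = c("qualitative_inactive", "IC50",
                                      "qualitative_inactive"))
  out <- impute_qualitative_inactive(rec)
  expect_equal(out$activity_value, c(1000, 5, 1000))
  # downstream ratio with the default 20 uM control
  expect_equal(normalize_activity(out$activity_value[1], NA), 50)
})

test_that("normalization divides by the control with a 20 uM fallback", {
  expect_equal(normalize_activity(40, 20), 2)
  expect_equal(normalize_activity(10, NA), 0.5)
  expect_equal(normalize_activity(20, 20), 1)
  expect_error(normalize_activity(10, -5), "control")
  expect_error(normalize_activity(-1, 20), "positive")
})

test_that("normalization is scale-consistent", {
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 0.1, 1000); c0 <- runif(1, 1, 100); f <- runif(1, 0.01, 100)
    expect_equal(normalize_activity(a * f, c0 * f), normalize_activity(a, c0))
  }
})

test_that("classification is strict at ratio 1", {
  expect_equal(as.character(classify_activity(c(0.5, 1.0, 50))),
               c("active", "inactive", "inactive"))
})

test_that("unit conversion to uM is exact", {
  expect_equal(convert_to_um(c(1500, 2, 0.003, 1e-6),
                             c("nM", "uM", "mM", "M")),
               c(1.5, 2, 3, 1))
  expect_error(convert_to_um(1, "pM"), "unit")
})

test_that("deduplication keeps the most potent record and merges metadata", {
  rec <- data.frame(
    inchikey = c("K1", "K1", "K2"),
    canonical_smiles = c("CCO", "CCO", "CCC"),
    ratio = c(2.0, 0.3, 5),
    activity_value = c(40, 6, 100),
    species = c("sp_a", "sp_b", "sp_a"),
    year = c(2010L, 2005L, NA),
    reference_id = c("r2", "r1", "r3"),
    stringsAsFactors = FALSE)
  out <- deduplicate(rec)
  expect_equal(nrow(out), 2)
  k1 <- out[out$inchikey == "K1", ]
  expect_equal(k1$ratio, 0.3)
  expect_equal(k1$n_merged, 2)
  expect_equal(k1$species, "sp_a;sp_b")
  expect_equal(k1$first_year, 2005L)
  expect_equal(k1$activity_class, "active")
  expect_true(is.na(out$first_year[out$inchikey == "K2"]))
})

test_that("dedup ratio ties break on the lexically smallest reference", {
  rec <- data.frame(inchikey = "K1", canonical_smiles = "CCO",
                    ratio = c(1.5, 1.5), activity_value = c(30, 30),
                    species = "x", year = c(2001L, 1999L),
                    reference_id = c("rB", "rA"), stringsAsFactors = FALSE)
  out <- deduplicate(rec)
  # winner is rA's record; metadata still merged
  expect_equal(out$first_year, 1999L)
  expect_equal(out$n_merged, 2)
})

test_that("deduplication is idempotent", {
  cur <- cached_curated()
  again <- deduplicate(cur$compounds)
  expect_equal(again$inchikey, cur$compounds$inchikey)
  expect_equal(again$ratio, cur$compounds$ratio)
  expect_true(all(again$n_merged == 1))
})

test_that("curation accounts for every raw record", {
  gl <- cached_library()
  cur <- cached_curated()
  expect_equal(sum(cur$compounds$n_merged) + nrow(cur$rejects),
               nrow(gl$records))
  # stored class always matches the class recomputed from the ratio
  expect_equal(cur$compounds$activity_class,
               as.character(classify_activity(cur$compounds$ratio)))
  expect_equal(anyDuplicated(cur$compounds$inchikey), 0L)
})

test_that("invalid rows are rejected with reasons, valid rows survive", {
  gl <- cached_library()
  raw <- head(gl$records, 20)
  raw$record_id <- sprintf("X%03d", seq_len(nrow(raw)))
  bad <- raw[1:3, ]
  bad$record_id <- c("B1", "B2", "B3")
  bad$smiles <- c("C1CC", "CC[Fe]CC", "CCO.OCCC")
  cur <- curate_bioassay(rbind(raw, bad))
  expect_setequal(cur$rejects$record_id, c("B1", "B2", "B3"))
  expect_setequal(cur$rejects$reason,
                  c("parse_error", "metal_complex", "mixture"))
  expect_equal(sum(cur$compounds$n_merged), nrow(raw))
})
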