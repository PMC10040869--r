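test_that("unit normalization covers the concentration scale", {
  expect_equal(normalize_to_nm(1, "uM"), 1000)
  expect_equal(normalize_to_nm(500, "nM"), 500)
  expect_equal(normalize_to_nm(2, "pM"), 0.002)
  expect_equal(normalize_to_nm(1, "mM"), 1e6)
  expect_equal(normalize_to_nm(1e-9, "M"), 1)
  expect_true(is.na(normalize_to_nm(1, "parsecs")))
})

test_that("record retrieval standardizes structures and keeps unknown units", {
  rec <- tibble::tibble(
    smiles = c("OCC", "c1ccccc1", "brokensmiles("),
    target_uniprot = "P10001", value_type = "IC50",
    standard_value = c(1, 2, 3), standard_units = c("uM", "parsecs", "nM"))
  expect_warning(out <- read_activity_records(rec), "skipped")
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_skipped"), 1)
  # ethanol canonicalized; record with unknown units retained at this stage
  expect_true("parsecs" %in% out$standard_units)
  # and excluded only at labeling, with a warning
  expect_warning(lab <- label_compounds(out, value_type = "IC50"),
                 "non-normalizable")
  expect_equal(nrow(lab), 1)
})

test_that("the dominant value type wins; ties break by binding-first priority", {
  rec <- tibble::tibble(
    smiles = "CCO", target_uniprot = "P10001",
    value_type = c(rep("IC50", 3), rep("Ki", 2)),
    standard_value = 1, standard_units = "nM")
  vt <- select_primary_value_type(read_activity_records(rec))
  expect_equal(as.character(vt), "IC50")
  counts <- attr(vt, "counts")
  expect_equal(counts$n_records[counts$value_type == "IC50"], 3)

  tie <- tibble::tibble(
    smiles = "CCO", target_uniprot = "P10001",
    value_type = c(rep("IC50", 2), rep("Ki", 2)),
    standard_value = 1, standard_units = "nM")
  expect_equal(as.character(select_primary_value_type(read_activity_records(tie))),
               "Ki")

  single <- tibble::tibble(smiles = "CCO", target_uniprot = "P10001",
                           value_type = "EC50", standard_value = 1,
                           standard_units = "nM")
  expect_equal(as.character(select_primary_value_type(read_activity_records(single))),
               "EC50")
})

test_that("potency labeling uses an inclusive cutoff and median aggregation", {
  rec <- read_activity_records(toy_records())
  lab <- label_compounds(rec, value_type = "IC50")
  expect_s3_class(lab, "lvs_labeled")
  expect_setequal(lab$inchikey[lab$label == "active"], toy_active_keys())
  expect_setequal(lab$inchikey[lab$label == "inactive"], toy_inactive_keys())
  # boundary: benzene's median is exactly 1000 nM -> active
  benzene <- standardize_molecule("c1ccccc1")$inchikey
  expect_equal(lab$label[lab$inchikey == benzene], "active")
  # evidence counts reflect the number of measurements
  toluene <- standardize_molecule("Cc1ccccc1")$inchikey
  expect_equal(lab$evidence_count[lab$inchikey == toluene], 3L)
})

test_that("percent-inhibition labeling is inclusive at the cutoff", {
  rec <- tibble::tibble(
    smiles = c("CCO", "c1ccccc1", "CCN"),
    target_uniprot = "P10001", value_type = "INH",
    standard_value = c(50, 49.9, 80), standard_units = "%")
  lab <- label_compounds(read_activity_records(rec), value_type = "INH")
  eth <- standardize_molecule("CCO")$inchikey
  ben <- standardize_molecule("c1ccccc1")$inchikey
  expect_equal(lab$label[lab$inchikey == eth], "active")
  expect_equal(lab$label[lab$inchikey == ben], "inactive")
})

test_that("cross-target conflicts follow the configured policy", {
  rec <- tibble::tibble(
    smiles = "CCO",
    target_uniprot = c("P10001", "P10002"),
    value_type = "IC50",
    standard_value = c(100, 50000),
    standard_units = "nM")
  records <- read_activity_records(rec)
  pooled <- label_compounds(records, value_type = "IC50",
                            conflict_policy = "pooled-median")
  # pooled median of {100, 50000} = 25050 -> inactive
  expect_equal(pooled$label, "inactive")
  any_active <- label_compounds(records, value_type = "IC50",
                                conflict_policy = "any-active")
  expect_equal(any_active$label, "active")
  expect_equal(any_active$evidence_count, 2L)
})

test_that("labeling partitions compounds and is monotone in the cutoff", {
  rec <- read_activity_records(toy_records())
  lab <- label_compounds(rec, value_type = "IC50")
  expect_equal(sum(lab$label == "active") + sum(lab$label == "inactive"),
               length(unique(rec$inchikey)))
  expect_false(any(duplicated(lab$inchikey)))
  prev_active <- character(0)
  for (cut in c(50, 200, 1000, 2500, 1e5)) {
    l <- label_compounds(rec, value_type = "IC50", potency_cutoff_nm = cut)
    act <- l$inchikey[l$label == "active"]
    expect_true(all(prev_active %in% act)) # raising cutoff never flips to inactive
    prev_active <- act
  }
})
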