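test_that("fixture construction honours the spec counts and schemas", {
  fx <- mini_fixture()
  spec <- fx$spec
  # bioactivity: per target, actives + inactives as IC50 plus a few Ki rows
  ba <- fx$bioactivity_tbl
  n_ic50 <- spec$n_targets * (spec$n_actives_per_target + spec$n_inactives_per_target)
  expect_equal(sum(ba$value_type == "IC50"), n_ic50)
  expect_true(all(c("smiles", "inchikey", "target_uniprot", "value_type",
                    "standard_value", "standard_units") %in% names(ba)))
  expect_equal(nrow(fx$homology_tbl), spec$n_targets)
  expect_equal(fx$homology_tbl$percent_identity, spec$identities)
  lib <- readLines(fx$library)
  expect_equal(length(lib), spec$library_size)
  # all structures valid: standardization loses nothing
  std <- standardize_molecules(ba$smiles)
  expect_equal(nrow(std), nrow(ba))
})

test_that("every active carries the planted motif and no inactive does", {
  fx <- mini_fixture()
  ba <- fx$bioactivity_tbl[fx$bioactivity_tbl$value_type == "IC50", ]
  # actives drawn from the potent lognormal; identify by construction medians
  med <- ifelse(ba$standard_units == "uM", ba$standard_value * 1000, ba$standard_value)
  is_act_row <- med < 3000 # far between the two lognormal medians
  planted <- plant_check(ba$smiles, fx$spec$planted_smarts)
  expect_true(all(planted[is_act_row]))
  expect_false(any(planted[!is_act_row & med > 10000]))
})

test_that("the same seed reproduces the fixture byte for byte", {
  spec <- fixture_spec(n_targets = 2, identities = c(100, 60),
                       n_actives_per_target = 5, n_inactives_per_target = 8,
                       library_size = 40, seed = 99)
  d1 <- tempfile(); d2 <- tempfile()
  generate_fixture(spec, d1); generate_fixture(spec, d2)
  for (f in c("homology.csv", "bioactivity.csv", "library.smi")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed changes the compound draw
  generate_fixture(fixture_spec(n_targets = 2, identities = c(100, 60),
                                n_actives_per_target = 5,
                                n_inactives_per_target = 8,
                                library_size = 40, seed = 100), d2)
  expect_false(identical(readLines(file.path(d1, "library.smi")),
                         readLines(file.path(d2, "library.smi"))))
})

test_that("substructure checks are notation-invariant and validated", {
  expect_true(plant_check("O=S(=O)(N)c1ccc(F)cc1"))
  expect_true(plant_check("NS(=O)(=O)c1ccc(F)cc1")) # same molecule, other notation
  expect_false(plant_check("CC"))
  expect_error(plant_check("CC", smarts = "notasmarts("), "invalid SMARTS")
})

test_that("labeling recovers the planted actives at the closed-form rate", {
  fx <- mini_fixture()
  spec <- fx$spec
  rec <- read_activity_records(fx$bioactivity)
  lab <- label_compounds(rec, value_type = "IC50")
  planted <- plant_check(lab$smiles, spec$planted_smarts)
  recovered <- mean(lab$label[planted] == "active")
  # lognormal tail: P(value <= 1000 | median 100, sigma 1) from the closed form
  expected <- stats::pnorm(log(1000 / spec$active_potency[[1]]) / spec$active_potency[[2]])
  expect_gte(recovered, 0.95)
  expect_lt(abs(recovered - expected), 0.05)
})

test_that("an infeasible spec fails with the achieved count", {
  spec <- fixture_spec(n_targets = 5, identities = c(100, 80, 70, 60, 50),
                       n_actives_per_target = 5000,
                       n_inactives_per_target = 10, library_size = 10)
  expect_error(generate_fixture(spec, tempfile()), "could be enumerated")
})
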