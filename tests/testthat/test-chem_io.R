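test_that("standardization canonicalizes notation variants to one structure", {
  a <- standardize_molecule("OCC")
  b <- standardize_molecule("CCO")
  expect_identical(a$smiles, b$smiles)
  expect_identical(a$inchikey, b$inchikey)
  expect_match(a$inchikey, "^[A-Z]{14}-[A-Z]{10}-[A-Z]$")
})

test_that("salt stripping keeps the largest fragment", {
  salt <- standardize_molecule("CCO.Cl")
  plain <- standardize_molecule("CCO")
  expect_identical(salt$inchikey, plain$inchikey)
  # tie on heavy atoms broken by molecular weight
  tie <- standardize_molecule("CCO.CCS")
  expect_identical(tie$inchikey, standardize_molecule("CCS")$inchikey)
})

test_that("unparseable SMILES raise a structured parse error", {
  err <- tryCatch(standardize_molecule("C1CC"), error = identity)
  expect_s3_class(err, "lvs_parse_error")
  expect_identical(err$smiles, "C1CC")
  expect_match(conditionMessage(err), "C1CC", fixed = TRUE)
})

test_that("standardization is idempotent", {
  inputs <- c("OCC", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O", "C[C@H](N)C(=O)O",
              "O=S(=O)(N)c1ccc(F)cc1")
  first <- standardize_molecules(inputs)
  second <- standardize_molecules(first$smiles)
  expect_identical(first$smiles, second$smiles)
  expect_identical(first$inchikey, second$inchikey)
})

test_that("vectorized standardization skips invalid entries and records them", {
  expect_warning(
    out <- standardize_molecules(c("CCO", "notasmiles(", "c1ccccc1"),
                                 c("a", "b", "c")),
    "skipped")
  expect_equal(nrow(out), 2)
  expect_identical(attr(out, "skipped")$source_id, "b")
})

test_that("smi library reading skips invalid lines and dedupes by identity key", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("CCO id1", "c1ccccc1 id2", "C1CC broken", "OCC id4", "CCN id5"), f)
  lib <- suppressWarnings(suppressMessages(read_library(f)))
  # 5 lines: one invalid, one duplicate of ethanol under different notation
  expect_equal(nrow(lib), 3)
  expect_equal(attr(lib, "n_skipped"), 1)
  expect_equal(attr(lib, "n_duplicates"), 1)
  expect_false(any(duplicated(lib$inchikey)))
  # first occurrence kept
  expect_equal(lib$source_id[lib$inchikey == standardize_molecule("CCO")$inchikey],
               "id1")
})

test_that("sdf reading yields distinct identity keys per record", {
  # build a 3-record SDF from known structures via the conversion toolkit
  smi <- tempfile(fileext = ".smi"); sdf <- tempfile(fileext = ".sdf")
  writeLines(c("CCO ethanol", "c1ccccc1 benzene", "c1ccncc1 pyridine"), smi)
  system2(Sys.which("obabel"), c(shQuote(smi), "-osdf", "-O", shQuote(sdf), "--gen2d"),
          stdout = FALSE, stderr = FALSE)
  lib <- read_library(sdf)
  expect_equal(nrow(lib), 3)
  # frozen keys computed independently with a second chemistry toolkit
  expect_setequal(lib$inchikey,
                  c("LFQSCWFLJHTTHZ-UHFFFAOYSA-N",   # ethanol
                    "UHOVQNZJYSORNB-UHFFFAOYSA-N",   # benzene
                    "JUJWROOIHBZHMG-UHFFFAOYSA-N"))  # pyridine
})

test_that("library reading is deterministic", {
  f <- tempfile(fileext = ".smi")
  writeLines(c("CCO a", "c1ccccc1 b", "CCN c"), f)
  l1 <- read_library(f); l2 <- read_library(f)
  expect_identical(tibble::as_tibble(l1), tibble::as_tibble(l2))
})

test_that("write_table round-trips values", {
  df <- tibble::tibble(s = c("a", "b"), i = c(1L, 2L), x = c(1 / 3, 2e-9))
  f <- tempfile(fileext = ".csv")
  write_table(df, f)
  expect_equal(length(readLines(f)), 3) # header + 2 rows
  back <- readr::read_csv(f, show_col_types = FALSE)
  expect_identical(back$s, df$s)
  expect_equal(back$i, as.numeric(df$i))
  expect_equal(back$x, df$x, tolerance = 1e-9)
  expect_error(write_table(df[0, ], tempfile()), "non-empty")
})
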