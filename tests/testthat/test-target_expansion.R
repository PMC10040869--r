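fixture_table <- tibble::tibble(
  query_uniprot = "P10001",
  gene_name = c("G1", "G2", "G3", "G4", "G5"),
  subject_uniprot = c("P10001", "P10002", "P10003", "P10004", "P10005"),
  percent_identity = c(100, 62, 45, 40, 38)
)

test_that("fixture backend returns stored hits verbatim, max identity per subject", {
  b <- homology_backend_fixture(fixture_table)
  hits <- search_homologs(b, target_query("P10001"))
  expect_equal(nrow(hits), 5)
  expect_equal(hits$percent_identity[hits$uniprot_id == "P10001"], 100)
  # duplicate subject rows collapse to the maximum identity
  dup <- dplyr::bind_rows(fixture_table,
                          tibble::tibble(query_uniprot = "P10001", gene_name = "G2",
                                         subject_uniprot = "P10002",
                                         percent_identity = 70))
  hits2 <- search_homologs(homology_backend_fixture(dup), target_query("P10001"))
  expect_equal(nrow(hits2), 5)
  expect_equal(hits2$percent_identity[hits2$uniprot_id == "P10002"], 70)
})

test_that("unknown accession yields an empty list with a warning", {
  b <- homology_backend_fixture(fixture_table)
  expect_warning(hits <- search_homologs(b, target_query("Q99999")), "no homology hits")
  expect_equal(nrow(hits), 0)
})

test_that("identity filtering is inclusive at the cutoff and sorted", {
  b <- homology_backend_fixture(fixture_table)
  q <- target_query("P10001")
  hits <- search_homologs(b, q)
  kept <- filter_homologs(hits, 40, query = q)
  expect_equal(nrow(kept), 4) # 38 excluded, 40 retained
  expect_true(all(diff(kept$percent_identity) <= 0))
  only_self <- filter_homologs(hits, 100, query = q)
  expect_equal(only_self$uniprot_id, "P10001")
})

test_that("the query is always present when include_query is set", {
  hits <- tibble::tibble(gene_name = c("A", "B"), uniprot_id = c("P20001", "P20002"),
                         percent_identity = c(30, 20))
  q <- target_query("P10001")
  expect_warning(kept <- filter_homologs(hits, 40, query = q), "query-only")
  expect_equal(kept$uniprot_id, "P10001")
})

test_that("filtering is monotone in the cutoff and a subset of input plus query", {
  b <- homology_backend_fixture(fixture_table)
  q <- target_query("P10001")
  hits <- search_homologs(b, q)
  prev <- NULL
  for (cut in c(20, 40, 60, 80, 100)) {
    kept <- filter_homologs(hits, cut, query = q)
    expect_true(all(kept$uniprot_id %in% c(hits$uniprot_id, q$uniprot_id)))
    if (!is.null(prev)) expect_true(all(kept$uniprot_id %in% prev))
    prev <- kept$uniprot_id
  }
})

test_that("accession syntax is validated", {
  expect_error(target_query("not-an-accession"), "not a valid UniProt")
  expect_silent(target_query("P09238"))
  expect_silent(target_query("A0A0B4J2F0"))
})

test_that("local blastp backend reports identities with a 100 percent self-hit", {
  subj <- tempfile(fileext = ".fasta"); qf <- tempfile(fileext = ".fasta")
  seq1 <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQVKVKALPDAQ"
  seq2 <- "MKTGYIAKQRELSFVKSHFSRQLEDRLGLIEVQGPILSRVGDGTQDNLSGAEKGVQVKVKALPDAQ"
  writeLines(c(">P10001|GENE1", seq1, ">P10002|GENE2", seq2), subj)
  writeLines(c(">P10001|GENE1", seq1), qf)
  hits <- search_homologs(homology_backend_blastp(subj, qf), target_query("P10001"))
  expect_equal(hits$percent_identity[hits$uniprot_id == "P10001"], 100)
  expect_true(hits$percent_identity[hits$uniprot_id == "P10002"] < 100)
  expect_setequal(hits$gene_name, c("GENE1", "GENE2"))
})
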