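test_that("the ethanol profile matches independently computed descriptor values", {
  p <- profile_compound("CCO")
  # verified against a second chemistry toolkit: 1 donor, 1 acceptor, no
  # rotatable bonds, MW 46.07, TPSA 20.23
  expect_equal(p$hbd, 1L)
  expect_equal(p$hba, 1L)
  expect_equal(p$rotatable_bonds, 0L)
  expect_equal(p$mw, 46.07, tolerance = 1e-3)
  expect_equal(p$tpsa, 20.23, tolerance = 1e-3)
  expect_equal(p$aromatic_rings, 0L)
  expect_equal(p$alerts, 0L)
})

test_that("qed stays in [0,1] and is invariant to SMILES notation", {
  mols <- standardize_molecules(c("OCC", "CCO", "O=S(=O)(N)c1ccc(F)cc1",
                                  "CC(=O)Oc1ccccc1C(=O)O", "c1ccncc1"))
  p <- profile_compounds(mols)
  expect_true(all(p$qed >= 0 & p$qed <= 1))
  expect_equal(p$qed[1], p$qed[2])
  expect_equal(p[1, -which(names(p) == "inchikey")],
               p[2, -which(names(p) == "inchikey")], ignore_attr = TRUE)
  # a mid-sized drug-like molecule is more drug-like than ethanol
  expect_gt(p$qed[3], p$qed[1])
})

test_that("structural alerts are counted for flagged motifs", {
  p <- profile_compounds(standardize_molecules(c("CCO", "CC(=O)C(C)=O", "CC=O")))
  expect_equal(p$alerts[1], 0L)
  expect_gte(p$alerts[2], 1L) # 1,2-diketone
  expect_gte(p$alerts[3], 1L) # aldehyde
})

test_that("score histograms conserve counts on the fixed 50-bin grid", {
  set.seed(14)
  rep <- tibble::tibble(score_rf = stats::runif(500),
                        score_mlp = rep(0.5, 500))
  s <- summarize_scores(rep)
  counts <- tapply(s$histogram$count, s$histogram$model, sum)
  expect_equal(unname(counts["rf"]), 500)
  expect_equal(unname(counts["mlp"]), 500)
  # constant scores occupy a single bin
  mlp_bins <- s$histogram[s$histogram$model == "mlp", ]
  expect_equal(sum(mlp_bins$count > 0), 1)
  expect_equal(s$stats$mean[s$stats$model == "rf"], mean(rep$score_rf),
               tolerance = 1e-12)
})

test_that("k-means recovers well-separated blobs and handles degenerate k", {
  set.seed(15)
  x <- rbind(matrix(rbinom(30 * 64, 1, 0.9), 30, 64),
             matrix(rbinom(30 * 64, 1, 0.05), 30, 64))
  keys <- sprintf("K%02d", 1:60)
  fp <- ligandvs:::new_fpmat(x, keys, fingerprint_spec("morgan", n_bits = 64))
  sc <- stats::setNames(c(rep(0.9, 30), rep(0.1, 30)), keys)
  cl <- cluster_library(fp, sc, n_clusters = 2, seed = 16, n_restarts = 5)
  grp <- cl$assignments$cluster
  expect_equal(length(unique(grp[1:30])), 1)
  expect_equal(length(unique(grp[31:60])), 1)
  expect_false(grp[1] == grp[31])
  expect_equal(cl$top_cluster, grp[1])
  # k = N: every compound its own cluster, cluster means equal own scores
  cln <- cluster_library(fp, sc, n_clusters = 60, seed = 16, n_restarts = 1)
  expect_equal(sort(cln$summary$n), rep(1L, 60), ignore_attr = TRUE)
  expect_setequal(round(cln$summary$mean_score, 10), round(unname(sc), 10))
  # determinism
  cl2 <- cluster_library(fp, sc, n_clusters = 2, seed = 16, n_restarts = 5)
  expect_identical(cl$assignments, cl2$assignments)
  expect_error(cluster_library(fp, sc, n_clusters = 61), "exceeds")
})

test_that("the 2-d embedding is deterministic with coincident duplicates", {
  set.seed(17)
  x <- matrix(rbinom(20 * 32, 1, 0.3), 20, 32)
  x[20, ] <- x[1, ] # exact duplicate
  e1 <- embed_2d(x, seed = 18, perplexity = 5, max_iter = 100)
  e2 <- embed_2d(x, seed = 18, perplexity = 5, max_iter = 100)
  expect_equal(ncol(as.matrix(e1[, c("dim1", "dim2")])), 2)
  expect_identical(e1$dim1, e2$dim1)
  expect_lt(abs(e1$dim1[1] - e1$dim1[20]) + abs(e1$dim2[1] - e1$dim2[20]), 1e-8)
})

test_that("tanimoto search ranks the query itself first with Tc 1", {
  mols <- standardize_molecules(c("CCO", "c1ccccc1", "CCCC", "CCCO", "CCN"))
  fp <- compute_fingerprints(mols, fingerprint_spec("morgan"))
  res <- tanimoto_search("CCO", fp)
  expect_equal(res$inchikey[1], mols$inchikey[1])
  expect_equal(res$tc[1], 1)
  expect_true(all(res$tc >= 0 & res$tc <= 1))
  expect_true(all(diff(res$tc) <= 0))
})

test_that("tanimoto equals a set-based brute force on random vector pairs", {
  set.seed(19)
  for (i in 1:500) {
    a <- rbinom(64, 1, 0.3); b <- rbinom(64, 1, 0.3)
    sa <- which(a == 1); sb <- which(b == 1)
    expected <- if (length(union(sa, sb)) == 0) 0 else
      length(intersect(sa, sb)) / length(union(sa, sb))
    expect_identical(tanimoto(a, b), expected)
    expect_identical(tanimoto(a, b), tanimoto(b, a))
  }
  expect_equal(tanimoto(rep(1, 8), rep(1, 8)), 1)
})
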