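fake_scores <- function(keys, values) stats::setNames(values, keys)

test_that("ranks are a strict permutation with deterministic tie-breaking", {
  keys <- c("B", "A", "C", "D")
  s <- list(rf = fake_scores(keys, c(0.9, 0.9, 0.5, 0.1)))
  rep <- rank_and_merge(s, top_fraction = 0.5)
  expect_setequal(rep$rank_rf, 1:4)
  # tie between A and B resolved lexicographically: A gets the better rank
  expect_equal(rep$rank_rf[rep$inchikey == "A"], 1L)
  expect_equal(rep$rank_rf[rep$inchikey == "B"], 2L)
})

test_that("opposite rankings average to a flat ensemble", {
  keys <- c("A", "B", "C")
  s <- list(rf = fake_scores(keys, c(0.9, 0.5, 0.1)),
            mlp = fake_scores(keys, c(0.1, 0.5, 0.9)))
  rep <- rank_and_merge(s, top_fraction = 1)
  expect_equal(rep$ensemble_rank, rep(2, 3))
  # final ordering resolved by the documented tie policy (inchikey)
  expect_equal(rep$inchikey, c("A", "B", "C"))
})

test_that("the merged top list unions per-model and ensemble lists without duplicates", {
  set.seed(10)
  n <- 2000
  keys <- sprintf("K%04d", 1:n)
  s <- list(rf = fake_scores(keys, stats::runif(n)),
            mlp = fake_scores(keys, stats::runif(n)))
  rep <- rank_and_merge(s, top_fraction = 0.01)
  top <- attr(rep, "top_hits")
  k <- attr(rep, "top_k_per_list")
  expect_equal(k, 20)
  expect_gte(nrow(top), k)
  expect_lte(nrow(top), 3 * k)
  expect_false(any(duplicated(top$inchikey)))
  # the single best compound of every contributing ranking is always present
  best_rf <- rep$inchikey[rep$rank_rf == 1]
  best_mlp <- rep$inchikey[rep$rank_mlp == 1]
  best_ens <- rep$inchikey[which.min(rep$ensemble_rank)]
  expect_true(all(c(best_rf, best_mlp, best_ens) %in% top$inchikey))
  # a compound ranked first by both models appears exactly once
  s2 <- list(rf = fake_scores(keys, c(1, stats::runif(n - 1))),
             mlp = fake_scores(keys, c(1, stats::runif(n - 1))))
  top2 <- attr(rank_and_merge(s2, top_fraction = 0.01), "top_hits")
  expect_equal(sum(top2$inchikey == "K0001"), 1)
})

test_that("merging is invariant to input order and monotone in top_fraction", {
  set.seed(11)
  n <- 500
  keys <- sprintf("K%03d", 1:n)
  rf <- fake_scores(keys, stats::runif(n))
  mlp <- fake_scores(keys, stats::runif(n))
  r1 <- rank_and_merge(list(rf = rf, mlp = mlp), 0.02)
  perm <- sample(n)
  r2 <- rank_and_merge(list(rf = rf[perm], mlp = mlp[perm]), 0.02)
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))
  prev <- character(0)
  for (f in c(0.01, 0.05, 0.2, 1)) {
    top <- attr(rank_and_merge(list(rf = rf, mlp = mlp), f), "top_hits")$inchikey
    expect_true(all(prev %in% top))
    prev <- top
  }
})

test_that("score/spec contracts are enforced when scoring a library", {
  mols <- standardize_molecules(c("CCO", "c1ccccc1", "CCCC", "CCN",
                                  "CCCO", "c1ccncc1", "CCOC", "CCS"))
  fp1024 <- compute_fingerprints(mols, fingerprint_spec("morgan"))
  cfg <- training_config(n_folds = 2, seed = 12,
                         rf_grid = list(num_trees = 50, max_depth = 4),
                         mlp_grid = list(hidden = list(50), activation = "relu",
                                         alpha = 1e-4))
  m <- train_model(fp1024, c(1, 0, 1, 0, 1, 0, 1, 0), "rf", cfg)
  sc <- score_library(m, fp1024)
  expect_true(all(sc >= 0 & sc <= 1))
  fp_maccs <- compute_fingerprints(mols, fingerprint_spec("maccs"))
  expect_error(score_library(m, fp_maccs), "spec mismatch")
})

test_that("training actives score above training inactives on the fit data", {
  f <- make_planted_fp(n_per_class = 40, n_bits = 256, seed = 13)
  cfg <- mini_training_config(seed = 13)
  m <- train_model(f$x, f$y, "rf", cfg)
  sc <- ligandvs:::predict_engine(m$model, f$x)
  expect_gt(mean(sc[f$y == 1]), mean(sc[f$y == 0]))
})
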