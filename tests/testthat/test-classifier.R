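test_that("training follows the configured protocol and is seed-deterministic", {
  model <- demo_model()
  expect_s3_class(model, "mhc_model")
  expect_equal(model$ensemble$num.trees, 150)
  expect_identical(model$metadata$n_binders, model$metadata$n_decoys)  # 1:1 ratio
  probe <- c(demo_heldout_binders(10L), sample_decoys(demo_proteome(), 10L, seed = 1L))
  s1 <- score_peptides(model, probe)
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_identical(s1, score_peptides(model, probe))      # scoring deterministic
  # retraining with the same config reproduces scores exactly
  ds <- allele_dataset("A0101", sample_binders(demo_motif(), 120L, seed = 7003L),
                       min_peptides = 50L)
  model2 <- train_allele_model(ds, demo_proteome(), train_config(n_trees = 150L, seed = 7004L))
  expect_identical(unname(score_peptides(model2, probe)), unname(s1))
  # scores do not depend on batch composition or order
  s_solo <- score_peptides(model, probe[3])
  expect_equal(unname(s_solo), unname(s1[3]))
  s_rev <- score_peptides(model, rev(probe))
  expect_equal(unname(rev(s_rev)), unname(s1))
})

test_that("held-out binders score above decoys", {
  model <- demo_model()
  binders <- demo_heldout_binders(60L)
  decoys <- sample_decoys(demo_proteome(), 300L, exclude = binders, seed = 77L)
  expect_gt(mean(score_peptides(model, binders)), mean(score_peptides(model, decoys)))
})

test_that("untrainable datasets and empty configs are rejected", {
  small <- allele_dataset("A0101", demo_heldout_binders(20L), min_peptides = 50L)
  expect_error(train_allele_model(small, demo_proteome()),
               class = "mhcforest_training_error")
  expect_error(train_config(n_trees = 0), class = "mhcforest_config_error")
  expect_error(rank_multi_allele(list(), "SIINFEKLV"), class = "mhcforest_config_error")
})

test_that("multi-allele ranking is the per-peptide maximum over models", {
  model <- demo_model()
  peps <- c(demo_heldout_binders(15L), sample_decoys(demo_proteome(), 15L, seed = 4L))
  single <- rank_multi_allele(list(model), peps)
  s <- score_peptides(model, peps)
  expect_equal(single$best_score, unname(sort(s, decreasing = TRUE)))
  # second model with a different motif
  ds2 <- allele_dataset("B0702", sample_binders(make_motif(991L), 80L, seed = 88L),
                        min_peptides = 50L)
  model2 <- train_allele_model(ds2, demo_proteome(), train_config(n_trees = 80L, seed = 89L))
  both <- rank_multi_allele(list(model, model2), peps)
  expect_true(all(both$best_score >= both$score_A0101 - 1e-12))
  expect_true(all(both$best_score >= both$score_B0702 - 1e-12))
  expect_equal(both$best_score, pmax(both$score_A0101, both$score_B0702))
  # adding a model never decreases any peptide's combined score
  m_single <- single$best_score[match(peps, single$peptide)]
  m_both <- both$best_score[match(peps, both$peptide)]
  expect_true(all(m_both >= m_single - 1e-12))
})

test_that("model persistence round-trips scores and guards configuration", {
  model <- demo_model()
  probe <- c(demo_heldout_binders(8L), sample_decoys(demo_proteome(), 8L, seed = 21L))
  before <- score_peptides(model, probe)
  dir <- withr::local_tempdir()
  save_model(model, file.path(dir, "m"))
  loaded <- load_model(file.path(dir, "m"))
  expect_identical(score_peptides(loaded, probe), before)   # bit-for-bit
  expect_identical(loaded$allele, model$allele)
  # scoring or loading under a different property configuration is refused
  other <- residue_properties(aromatic_set = "FWY")
  expect_error(score_peptides(loaded, probe, properties = other),
               class = "mhcforest_integrity_error")
  expect_error(load_model(file.path(dir, "m"), properties = other),
               class = "mhcforest_integrity_error")
  # truncated ensemble file is an I/O error
  writeLines("not an rds", file.path(dir, "m", "ensemble.rds"))
  expect_error(load_model(file.path(dir, "m")), class = "mhcforest_io_error")
  expect_error(load_model(file.path(dir, "missing")), class = "mhcforest_io_error")
})
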