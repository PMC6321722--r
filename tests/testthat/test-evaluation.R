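test_that("top-fraction precision matches hand counts and edge conventions", {
  # perfect separation: 1 binder + 99 decoys, binder ranked first
  scores <- c(1, runif(99, 0, 0.5))
  labels <- c(1L, rep(0L, 99))
  expect_equal(prec_at_top_fraction(scores, labels), 1.0)
  # N = 200, positives at ranks 1 and 3, window k = 2 -> 0.5
  sc <- seq(200, 1)
  lb <- rep(0L, 200); lb[c(1, 3)] <- 1L
  expect_equal(prec_at_top_fraction(sc, lb), 0.5)
  # no positives is defined (0), empty input is an error
  expect_equal(prec_at_top_fraction(runif(100), rep(0L, 100)), 0)
  expect_error(prec_at_top_fraction(numeric(0), integer(0)),
               class = "mhcforest_input_error")
})

test_that("AUPRC is average precision with no interpolation", {
  expect_equal(auprc(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1.0)   # perfect separation
  # scores (.9,.8,.7,.6), labels (1,0,1,0): precision 1 at rank 1, 2/3 at rank 3
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), (1 + 2 / 3) / 2)
  expect_error(auprc(runif(5), rep(0L, 5)), class = "mhcforest_input_error")
})

test_that("AUROC follows the Mann-Whitney tie convention", {
  expect_equal(auroc(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.5, 10), rep(c(1L, 0L), 5)), 0.5)  # all tied
  expect_error(auroc(runif(5), rep(1L, 5)), class = "mhcforest_input_error")
})

test_that("metrics agree with brute-force oracles on small random instances", {
  set.seed(301)
  for (i in 1:400) {
    n <- sample(2:8, 1)
    labels <- integer(n)
    labels[sample(n, sample(n - 1, 1))] <- 1L
    scores <- runif(n)   # continuous: ties have probability zero
    frac <- runif(1, 0.05, 1)
    expect_equal(prec_at_top_fraction(scores, labels, fraction = frac),
                 oracle_prec_top(scores, labels, fraction = frac))
    if (sum(labels) > 0) {
      expect_equal(auprc(scores, labels), oracle_average_precision(scores, labels))
    }
    if (sum(labels) > 0 && sum(labels) < n) {
      expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
    }
  }
  # tied scores: AUROC oracle counts ties as half
  for (i in 1:100) {
    n <- sample(4:8, 1)
    labels <- rep_len(c(1L, 0L), n)
    scores <- sample(1:3, n, TRUE)
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
  }
})

test_that("metrics are rank-based: invariant to monotone score transforms", {
  set.seed(302)
  for (i in 1:20) {
    n <- 60
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) %in% c(0, n)) next
    scores <- runif(n)
    trans <- exp(3 * scores) - 2
    expect_equal(prec_at_top_fraction(scores, labels, fraction = 0.1),
                 prec_at_top_fraction(trans, labels, fraction = 0.1))
    expect_equal(auprc(scores, labels), auprc(trans, labels))
    expect_equal(auroc(scores, labels), auroc(trans, labels))
  }
  # appending a decoy scored below everything never decreases top-k precision
  scores <- runif(50); labels <- rbinom(50, 1, 0.2)
  p0 <- prec_at_top_fraction(scores, labels, fraction = 0.1)
  p1 <- prec_at_top_fraction(c(scores, min(scores) - 1), c(labels, 0L), fraction = 0.1)
  expect_gte(p1, p0 - 1e-12)
})

test_that("decoy-excess evaluation enforces the configured class ratio", {
  model <- demo_model()
  binders <- demo_heldout_binders(30L)
  res <- evaluate_with_decoys(model, binders, demo_proteome(),
                              excess = 19L, n_decoy_sets = 3L, seed = 5L)
  expect_identical(nrow(res), 3L)
  expect_true(all(res$n_neg == 19L * res$n_pos))
  expect_true(all(res$n_pos == 30L))
  expect_true(all(res$prec1 >= 0 & res$prec1 <= 1))
  expect_s3_class(attr(res, "summary"), "data.frame")
  # default replicate count is five
  expect_identical(eval(formals(evaluate_with_decoys)$n_decoy_sets), 5L)
  # reruns with the same seed reproduce the metrics exactly
  res2 <- evaluate_with_decoys(model, binders, demo_proteome(),
                               excess = 19L, n_decoy_sets = 3L, seed = 5L)
  expect_identical(res$prec1, res2$prec1)
  expect_identical(res$auprc, res2$auprc)
})

test_that("repeated random holdouts are reproducible and sized correctly", {
  ds <- allele_dataset("A0101", sample_binders(demo_motif(), 80L, seed = 411L),
                       min_peptides = 40L)
  cfg <- train_config(n_trees = 60L, seed = 412L)
  res <- repeated_split_validation(ds, demo_proteome(), cfg,
                                   n_iterations = 2L, excess = 19L)
  expect_identical(nrow(res), 2L)
  expect_identical(res$n_pos, rep(20L, 2))   # 25% of 80 withheld
  res2 <- repeated_split_validation(ds, demo_proteome(), cfg,
                                    n_iterations = 2L, excess = 19L)
  expect_identical(res$prec1, res2$prec1)    # fixed master seed reproduces splits
  # too small after the split
  tiny <- allele_dataset("A0101", sample_binders(demo_motif(), 45L, seed = 413L),
                         min_peptides = 40L)
  expect_error(repeated_split_validation(tiny, demo_proteome(), cfg),
               class = "mhcforest_training_error")
})
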