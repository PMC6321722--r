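# Shared fixtures, built in code and memoised so expensive objects (the
# background proteome, one small trained model) are constructed once per
# test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- build()
  fixture_env[[key]]
}

demo_proteome <- function() {
  memo("proteome", function() synth_proteome(60L, 300, seed = 7001L))
}

demo_motif <- function() memo("motif", function() make_motif(7002L))

# one small anchored model shared by classifier / importance / evaluation
# tests; 120 binders, 150 trees keeps training around a second
demo_model <- function() {
  memo("model", function() {
    ds <- allele_dataset("A0101", sample_binders(demo_motif(), 120L, seed = 7003L),
                         min_peptides = 50L)
    train_allele_model(ds, demo_proteome(),
                       train_config(n_trees = 150L, seed = 7004L))
  })
}

demo_heldout_binders <- function(n = 60L) {
  sample_binders(demo_motif(), n, seed = 7005L)
}

# brute-force metric oracles, kept deliberately independent of the package
# implementations (explicit threshold enumeration / pairwise counting)

oracle_prec_top <- function(scores, labels, fraction = 0.01) {
  k <- max(1L, round(fraction * length(scores)))
  ord <- order(scores, decreasing = TRUE)
  sum(labels[ord][seq_len(k)]) / k
}

oracle_average_precision <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  n_pos <- sum(lab)
  total <- 0
  prev_recall <- 0
  for (k in seq_along(lab)) {          # every cut-point is a threshold
    recall <- sum(lab[seq_len(k)]) / n_pos
    if (recall > prev_recall) {
      total <- total + (recall - prev_recall) * (sum(lab[seq_len(k)]) / k)
      prev_recall <- recall
    }
  }
  total
}

oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

oracle_cliffs_d <- function(x, y) {
  total <- 0
  for (a in x) for (b in y) total <- total + sign(a - b)
  total / (length(x) * length(y))
}

toy_path <- function(file) {
  system.file("extdata", "toy", file, package = "mhcforest")
}
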