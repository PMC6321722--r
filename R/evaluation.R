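# Ranking metrics and the decoy-excess evaluation protocol.
#
# Binders are evaluated mixed with a large excess of proteome decoys
# (default 99 decoys per binder), so the positive prevalence is 1% and a
# random scorer has expected Prec1% and AUPRC of 0.01 while AUROC stays at
# 0.5 regardless of the class ratio.

as_binary_labels <- function(labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (!all(labels %in% c(0L, 1L))) abort("labels must be binary 0/1", "mhcforest_input_error")
  as.integer(labels)
}

# Seeded random permutation used to break score ties without input-order
# bias: applied before the stable sort, so tied items appear in random
# order.
tie_broken_order <- function(scores, tie_seed) {
  perm <- with_seed(tie_seed, sample.int(length(scores)))
  ord <- order(-scores[perm])
  perm[ord]
}

#' Precision among the top fraction of ranked predictions
#'
#' Ranks items by descending score and reports the fraction of true
#' positives among the top `max(1, round(fraction * N))` items. With the
#' default 1% window and a 99:1 decoy excess this is the headline Prec1%
#' metric: 1.0 for a perfect scorer and 0.01 in expectation for a random
#' one. Ties are broken by a seeded random permutation applied before
#' sorting.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary labels (1 = positive/binder).
#' @param fraction Top fraction to label positive (default 0.01).
#' @param tie_seed Seed for the tie-breaking permutation.
#' @return Precision in `[0, 1]`.
#' @export
prec_at_top_fraction <- function(scores, labels, fraction = 0.01,
                                 tie_seed = 1L) {
  if (length(scores) == 0L || length(scores) != length(labels)) {
    abort("scores and labels must be non-empty and of equal length", "mhcforest_input_error")
  }
  labels <- as_binary_labels(labels)
  k <- max(1L, round(fraction * length(scores)))
  idx <- tie_broken_order(scores, tie_seed)[seq_len(k)]
  sum(labels[idx]) / k
}

#' Area under the precision-recall curve (average precision)
#'
#' Computed as average precision: the step-wise sum of precision at each
#' positive's rank weighted by the recall increment, with no linear
#' interpolation between operating points (trapezoidal PR areas are
#' optimistically biased). Ties are broken by a seeded permutation.
#'
#' @inheritParams prec_at_top_fraction
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels, tie_seed = 1L) {
  if (length(scores) == 0L || length(scores) != length(labels)) {
    abort("scores and labels must be non-empty and of equal length", "mhcforest_input_error")
  }
  labels <- as_binary_labels(labels)
  n_pos <- sum(labels)
  if (n_pos == 0L) abort("AUPRC undefined without positives", "mhcforest_input_error")
  ranked <- labels[tie_broken_order(scores, tie_seed)]
  hits <- cumsum(ranked)
  precision_at_hit <- hits[ranked == 1L] / which(ranked == 1L)
  sum(precision_at_hit) / n_pos
}

#' Area under the ROC curve
#'
#' Computed in its Mann-Whitney form, `P(score_pos > score_neg) + 0.5 *
#' P(tie)`, via midranks; 0.5 for a random scorer at any class ratio.
#'
#' @inheritParams prec_at_top_fraction
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  if (length(scores) == 0L || length(scores) != length(labels)) {
    abort("scores and labels must be non-empty and of equal length", "mhcforest_input_error")
  }
  labels <- as_binary_labels(labels)
  n_pos <- sum(labels)
  n_neg <- length(labels) - n_pos
  if (n_pos == 0L || n_neg == 0L) {
    abort("AUROC needs at least one positive and one negative", "mhcforest_input_error")
  }
  r <- rank(scores)  # midranks handle ties
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

metric_row <- function(scores, labels, replicate, allele, seed, tie_seed) {
  labels <- as_binary_labels(labels)
  data.frame(allele = allele, replicate = replicate,
             prec1 = prec_at_top_fraction(scores, labels, tie_seed = tie_seed),
             auprc = auprc(scores, labels, tie_seed = tie_seed),
             auroc = auroc(scores, labels),
             n_pos = sum(labels), n_neg = sum(labels == 0L),
             seed = if (is.null(seed)) NA_integer_ else seed,
             stringsAsFactors = FALSE)
}

summarize_results <- function(res) {
  data.frame(metric = c("prec1", "auprc", "auroc"),
             mean = vapply(res[c("prec1", "auprc", "auroc")], mean, numeric(1)),
             sd = vapply(res[c("prec1", "auprc", "auroc")], sd, numeric(1)),
             row.names = NULL)
}

#' Evaluate a model on binders mixed with excess decoys
#'
#' Implements the decoy-mixing protocol: each replicate mixes the binders
#' with `excess` times as many freshly sampled proteome decoys, scores the
#' mixture and computes Prec1%, AUPRC and AUROC; by default five
#' replicates with different decoy sets. Mean and SD across replicates are
#' attached as the `"summary"` attribute.
#'
#' @param model An `mhc_model`.
#' @param binders Character vector of true binder peptides (the test
#'   positives).
#' @param proteome An `mhc_proteome` for decoy sampling.
#' @param excess Decoys per binder (default 99).
#' @param n_decoy_sets Number of decoy replicates (default 5).
#' @param seed Master seed.
#' @param exclude Extra peptides to exclude from decoys (the binders are
#'   always excluded).
#' @param properties Property tables.
#' @return data.frame with one row per replicate (columns `allele`,
#'   `replicate`, `prec1`, `auprc`, `auroc`, `n_pos`, `n_neg`, `seed`).
#' @export
evaluate_with_decoys <- function(model, binders, proteome, excess = 99L,
                                 n_decoy_sets = 5L, seed = 1L,
                                 exclude = character(),
                                 properties = residue_properties()) {
  if (length(binders) == 0L) abort("no binders to evaluate", "mhcforest_input_error")
  rows <- lapply(seq_len(n_decoy_sets), function(r) {
    rep_seed <- derive_seed(seed, 100L + r)
    decoys <- sample_decoys(proteome, excess * length(binders),
                            exclude = c(binders, exclude), seed = rep_seed)
    scores <- score_peptides(model, c(binders, decoys), properties)
    labels <- rep(c(1L, 0L), c(length(binders), length(decoys)))
    metric_row(scores, labels, r, model$allele, rep_seed,
               tie_seed = derive_seed(seed, 200L + r))
  })
  res <- do.call(rbind, rows)
  attr(res, "summary") <- summarize_results(res)
  res
}

#' Repeated random-holdout validation of an allele dataset
#'
#' Over `n_iterations` iterations, a random `holdout_fraction` of the
#' binders is withheld, a model is trained on the remainder (with fresh
#' 1:1 decoys) and the withheld binders are evaluated mixed with an
#' `excess`-fold decoy load. Train and test binders are disjoint within
#' each iteration.
#'
#' @param dataset An [allele_dataset()]; must remain trainable after the
#'   split.
#' @param proteome An `mhc_proteome`.
#' @param config A [train_config()]; its seed drives splits, decoys and
#'   trees.
#' @param n_iterations Number of random holdouts (default 5).
#' @param holdout_fraction Fraction of binders withheld (default 0.25).
#' @param excess Test decoys per withheld binder (default 99).
#' @param properties Property tables.
#' @return data.frame with one row per iteration, plus a `"summary"`
#'   attribute.
#' @export
repeated_split_validation <- function(dataset, proteome,
                                      config = train_config(),
                                      n_iterations = 5L,
                                      holdout_fraction = 0.25,
                                      excess = 99L,
                                      properties = residue_properties()) {
  stopifnot(inherits(dataset, "mhc_allele_dataset"))
  n <- length(dataset$binders)
  n_test <- max(1L, round(holdout_fraction * n))
  if (n - n_test < dataset$min_peptides) {
    abort(sprintf("allele %s: %d binders leave only %d for training after a %.0f%% holdout",
                  dataset$allele, n, n - n_test, 100 * holdout_fraction),
          "mhcforest_training_error")
  }
  rows <- lapply(seq_len(n_iterations), function(it) {
    it_seed <- derive_seed(config$seed, 1000L + it)
    test_idx <- with_seed(it_seed, sample.int(n, n_test))
    train_set <- allele_dataset(dataset$allele, dataset$binders[-test_idx],
                                min_peptides = dataset$min_peptides)
    it_config <- config
    it_config$seed <- it_seed
    model <- train_allele_model(train_set, proteome, it_config, properties)
    res <- evaluate_with_decoys(model, dataset$binders[test_idx], proteome,
                                excess = excess, n_decoy_sets = 1L,
                                seed = derive_seed(it_seed, 7L),
                                exclude = dataset$binders,
                                properties = properties)
    res$replicate <- it
    res
  })
  res <- do.call(rbind, rows)
  attr(res, "summary") <- summarize_results(res)
  res
}
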