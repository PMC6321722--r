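# Exhaustive feature-subset search and the parsimony selection rule.

#' Evaluate every feature subset across alleles
#'
#' For each non-empty subset of the candidate features, trains a model per
#' allele on a random 75% of its binders (1:1 decoys) and evaluates on the
#' withheld 25% mixed with an `excess`-fold decoy load, then averages
#' Prec1% and AUPRC across alleles (unweighted).
#'
#' @param datasets List of trainable [allele_dataset()] objects.
#' @param proteome An `mhc_proteome`.
#' @param config A [train_config()]; its `feature_set` is ignored (each
#'   subset is swapped in).
#' @param features Candidate feature letters (default all six).
#' @param holdout_fraction Test fraction per allele (default 0.25).
#' @param excess Test decoy excess (default 99).
#' @param properties Property tables.
#' @return data.frame of class `mhc_subset_table`: one row per subset with
#'   columns `subset`, `size`, `mean_prec1`, `mean_auprc` and per-allele
#'   `prec1_<allele>` / `auprc_<allele>` columns.
#' @export
exhaustive_feature_search <- function(datasets, proteome,
                                      config = train_config(),
                                      features = FEATURE_ORDER,
                                      holdout_fraction = 0.25,
                                      excess = 99L,
                                      properties = residue_properties()) {
  datasets <- Filter(function(d) d$trainable, datasets)
  if (length(datasets) == 0L) abort("no trainable allele datasets", "mhcforest_training_error")
  subsets <- enumerate_feature_subsets(features)
  alleles <- vapply(datasets, function(d) d$allele, character(1))

  # fixed per-allele split so every subset sees the same train/test peptides
  splits <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    n <- length(d$binders)
    n_test <- max(1L, round(holdout_fraction * n))
    test_idx <- with_seed(derive_seed(config$seed, 5000L + i), sample.int(n, n_test))
    list(train = d$binders[-test_idx], test = d$binders[test_idx])
  })

  rows <- lapply(seq_along(subsets), function(s) {
    fs <- subsets[[s]]
    per_allele <- vapply(seq_along(datasets), function(i) {
      d <- datasets[[i]]
      cfg <- config
      cfg$feature_set <- fs
      cfg$seed <- derive_seed(config$seed, 10000L + 100L * s + i)
      model <- train_allele_model(
        allele_dataset(d$allele, splits[[i]]$train, min_peptides = d$min_peptides),
        proteome, cfg, properties)
      res <- evaluate_with_decoys(model, splits[[i]]$test, proteome,
                                  excess = excess, n_decoy_sets = 1L,
                                  seed = derive_seed(cfg$seed, 3L),
                                  exclude = d$binders, properties = properties)
      c(res$prec1[1L], res$auprc[1L])
    }, numeric(2))
    row <- data.frame(subset = format(fs), size = length(fs),
                      mean_prec1 = mean(per_allele[1L, ]),
                      mean_auprc = mean(per_allele[2L, ]),
                      stringsAsFactors = FALSE)
    for (i in seq_along(alleles)) {
      row[[paste0("prec1_", alleles[i])]] <- per_allele[1L, i]
      row[[paste0("auprc_", alleles[i])]] <- per_allele[2L, i]
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mhc_subset_table", class(out))
  out
}

#' Select a feature subset from a performance table
#'
#' Among subsets whose mean Prec1% AND mean AUPRC are both within
#' `tolerance_fraction` of the respective maxima (i.e. at least `(1 -
#' tolerance) * max`), returns the smallest subset; ties on size are
#' broken by higher mean Prec1%, then lexicographically. This is the
#' parsimony rule under which `HASM` is preferred to the slightly
#' better-scoring but larger `HCASM`.
#'
#' @param table A subset-performance table from
#'   [exhaustive_feature_search()] (or any data.frame with `subset`,
#'   `size`, `mean_prec1`, `mean_auprc`).
#' @param tolerance_fraction Allowed shortfall from each maximum
#'   (default 0.01).
#' @return The selected `mhc_feature_set`.
#' @export
select_feature_set <- function(table, tolerance_fraction = 0.01) {
  if (is.null(table) || nrow(table) == 0L) abort("empty subset table", "mhcforest_input_error")
  ok <- table$mean_prec1 >= (1 - tolerance_fraction) * max(table$mean_prec1) &
    table$mean_auprc >= (1 - tolerance_fraction) * max(table$mean_auprc)
  cand <- table[ok, , drop = FALSE]
  cand <- cand[order(cand$size, -cand$mean_prec1, cand$subset), , drop = FALSE]
  feature_set(cand$subset[1L])
}

#' Write a subset-performance table as TSV
#'
#' @param table Result of [exhaustive_feature_search()].
#' @param path Output TSV path.
#' @export
write_subset_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
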