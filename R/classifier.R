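# Per-allele random-forest classifiers: training, scoring, ranking,
# persistence.

#' Training configuration for a per-allele classifier
#'
#' Defaults follow the final published-style protocol: 1000 trees, Gini
#' impurity splits, square-root of the feature count tried at each node,
#' bootstrap resampling, and decoys mixed at a 1:1 ratio with binders.
#'
#' @param n_trees Number of trees (default 1000).
#' @param decoy_ratio_train Decoys per binder in the training sample
#'   (default 1).
#' @param feature_set Feature combination (default `HASM`).
#' @param min_node_size Minimum node size; `NULL` uses the ranger default.
#' @param seed Master seed for decoy sampling and tree growing.
#' @return An object of class `mhc_train_config`.
#' @export
train_config <- function(n_trees = 1000L, decoy_ratio_train = 1,
                         feature_set = default_feature_set(),
                         min_node_size = NULL, seed = 1L) {
  if (n_trees < 1) abort("n_trees must be >= 1", "mhcforest_config_error")
  if (decoy_ratio_train <= 0) abort("decoy_ratio_train must be > 0", "mhcforest_config_error")
  structure(list(n_trees = as.integer(n_trees),
                 decoy_ratio_train = decoy_ratio_train,
                 feature_set = feature_set(feature_set),
                 split_criterion = "gini",
                 max_features_rule = "sqrt",
                 bootstrap = TRUE,
                 min_node_size = min_node_size,
                 seed = as.integer(seed)),
            class = "mhc_train_config")
}

#' Train the random-forest classifier for one allele
#'
#' Binders are labelled positive; an equal-size (by default) sample of
#' proteome decoys, excluding the binders themselves, is labelled
#' negative. The ensemble is grown on the configured feature encoding
#' with Gini-impurity splits, sqrt(p) candidate features per node and
#' bootstrap resampling, and records impurity importances for
#' [model_importance()]. Deterministic for a fixed config seed.
#'
#' @param dataset An [allele_dataset()]; must be trainable.
#' @param proteome An `mhc_proteome` to draw decoys from.
#' @param config A [train_config()].
#' @param properties Property tables from [residue_properties()].
#' @return An object of class `mhc_model`.
#' @export
train_allele_model <- function(dataset, proteome, config = train_config(),
                               properties = residue_properties()) {
  stopifnot(inherits(dataset, "mhc_allele_dataset"),
            inherits(config, "mhc_train_config"))
  if (!dataset$trainable) {
    abort(sprintf("allele %s has %d binders, below the training minimum of %d",
                  dataset$allele, length(dataset$binders), dataset$min_peptides),
          "mhcforest_training_error")
  }
  binders <- dataset$binders
  n_decoys <- max(1L, round(config$decoy_ratio_train * length(binders)))
  decoys <- sample_decoys(proteome, n_decoys, exclude = binders,
                          seed = derive_seed(config$seed, 1L))
  x <- encode_peptides(c(binders, decoys), config$feature_set, properties)
  y <- factor(rep(c("binder", "decoy"), c(length(binders), length(decoys))),
              levels = c("decoy", "binder"))
  dat <- data.frame(x, check.names = FALSE)
  fit <- ranger::ranger(
    x = dat, y = y,
    num.trees = config$n_trees,
    mtry = floor(sqrt(ncol(dat))),
    splitrule = "gini",
    replace = config$bootstrap,
    probability = TRUE,
    importance = "impurity",
    min.node.size = if (is.null(config$min_node_size)) NULL else config$min_node_size,
    seed = derive_seed(config$seed, 2L),
    num.threads = 1L)
  structure(list(allele = dataset$allele,
                 feature_set = config$feature_set,
                 ensemble = fit,
                 layout = feature_layout(config$feature_set),
                 metadata = list(
                   allele = dataset$allele,
                   feature_set = format(config$feature_set),
                   n_binders = length(binders),
                   n_decoys = length(decoys),
                   n_trees = config$n_trees,
                   seed = config$seed,
                   properties = properties$meta,
                   package_version = as.character(utils::packageVersion("mhcforest")))),
            class = "mhc_model")
}

#' @export
print.mhc_model <- function(x, ...) {
  cat(sprintf("<model %s: %s features, %d trees, %d binders>\n",
              x$allele, format(x$feature_set), x$metadata$n_trees,
              x$metadata$n_binders))
  invisible(x)
}

#' Score peptides with a trained per-allele model
#'
#' The score is the ensemble's positive-class probability in `[0, 1]`
#' (averaged over trees); higher means more binder-like.
#'
#' @param model An `mhc_model`.
#' @param peptides Character vector of valid 9-mers.
#' @param properties Property tables; must match the tables the model was
#'   trained with.
#' @return Named numeric vector of scores in `[0, 1]`.
#' @export
score_peptides <- function(model, peptides,
                           properties = residue_properties()) {
  stopifnot(inherits(model, "mhc_model"))
  if (!identical(properties$meta, model$metadata$properties)) {
    abort("property-table configuration differs from the one the model was trained with",
          "mhcforest_integrity_error")
  }
  x <- encode_peptides(peptides, model$feature_set, properties)
  if (!identical(colnames(x), model$layout$name)) {
    abort("feature layout mismatch between model and encoder", "mhcforest_integrity_error")
  }
  pred <- predict(model$ensemble, data = data.frame(x, check.names = FALSE),
                  num.threads = 1L)
  scores <- pred$predictions[, "binder"]
  names(scores) <- toupper(peptides)
  scores
}

#' Rank peptides across several allele models
#'
#' Each peptide's combined score is the maximum of its per-allele scores
#' (a peptide is presentable if any of the sample's alleles presents it);
#' the output is sorted by descending combined score.
#'
#' @param models Non-empty list of `mhc_model` objects sharing a feature
#'   set.
#' @param peptides Character vector of valid 9-mers.
#' @param properties Property tables.
#' @return data.frame with columns `peptide`, `best_score`, `best_allele`
#'   and one `score_<allele>` column per model, sorted by `best_score`
#'   descending.
#' @export
rank_multi_allele <- function(models, peptides,
                              properties = residue_properties()) {
  if (length(models) == 0L) abort("need at least one model", "mhcforest_config_error")
  fsets <- vapply(models, function(m) format(m$feature_set), character(1))
  if (length(unique(fsets)) != 1L) {
    abort("all models must share one feature set", "mhcforest_config_error")
  }
  score_mat <- vapply(models, function(m) score_peptides(m, peptides, properties),
                      numeric(length(peptides)))
  if (is.null(dim(score_mat))) score_mat <- matrix(score_mat, nrow = length(peptides))
  alleles <- vapply(models, function(m) m$allele, character(1))
  colnames(score_mat) <- alleles
  best <- max.col(score_mat, ties.method = "first")
  out <- data.frame(peptide = toupper(peptides),
                    best_score = score_mat[cbind(seq_along(peptides), best)],
                    best_allele = alleles[best],
                    stringsAsFactors = FALSE)
  for (a in alleles) out[[paste0("score_", a)]] <- score_mat[, a]
  out[order(-out$best_score), , drop = FALSE]
}

#' Persist and restore a trained model
#'
#' A model is saved as a directory holding the serialised ensemble plus a
#' JSON metadata sidecar (allele, feature set, property-table
#' conventions, training counts, seed, package version). On load the
#' metadata is checked against the runtime property configuration so a
#' model can never silently be scored with different encodings than it
#' was trained on; a mismatch raises an integrity error.
#'
#' @param model An `mhc_model`.
#' @param path Directory to create/read.
#' @return `load_model()` returns the restored `mhc_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mhc_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$ensemble, file.path(path, "ensemble.rds"))
  jsonlite::write_json(model$metadata, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @param properties Runtime property tables to validate against.
#' @export
load_model <- function(path, properties = residue_properties()) {
  meta_path <- file.path(path, "metadata.json")
  ens_path <- file.path(path, "ensemble.rds")
  if (!file.exists(meta_path) || !file.exists(ens_path)) {
    abort(paste0("not a model directory: ", path), "mhcforest_io_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(unlist(meta$properties), unlist(properties$meta))) {
    abort(paste0("model '", meta$allele, "' was trained under a different ",
                 "property-table configuration (e.g. aromatic set or mass type); ",
                 "load it with matching residue_properties()"),
          "mhcforest_integrity_error")
  }
  ensemble <- tryCatch(readRDS(ens_path),
                       error = function(e) abort(paste0("corrupt model file: ",
                                                        conditionMessage(e)),
                                                 "mhcforest_io_error"))
  fs <- feature_set(meta$feature_set)
  structure(list(allele = meta$allele, feature_set = fs, ensemble = ensemble,
                 layout = feature_layout(fs), metadata = meta),
            class = "mhc_model")
}
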