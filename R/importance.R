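# Gini-impurity feature importances aggregated by peptide position.

#' Impurity-reduction importance profile of one model
#'
#' Extracts the ensemble's mean-decrease-in-impurity importance for every
#' feature-vector coordinate, normalised to sum to one (so models trained
#' on datasets of different sizes contribute equally when aggregated),
#' and aggregates it per (feature letter, peptide position): the 20
#' residue coordinates of an S/B block at one position are summed.
#'
#' @param model A fitted `mhc_model` (trained with impurity importance,
#'   the default).
#' @return Object of class `mhc_importance`: list with `per_coordinate`
#'   (named numeric, sums to 1), `per_position_feature` (data.frame
#'   `feature`, `position`, `importance`) and `layout`.
#' @export
model_importance <- function(model) {
  stopifnot(inherits(model, "mhc_model"))
  imp <- tryCatch(ranger::importance(model$ensemble),
                  error = function(e) abort("model has no importance values; train with the default settings",
                                            "mhcforest_state_error"))
  if (is.null(imp) || length(imp) == 0L) {
    abort("model has no importance values", "mhcforest_state_error")
  }
  imp <- pmax(imp, 0)
  total <- sum(imp)
  per_coordinate <- if (total > 0) imp / total else imp
  new_importance(per_coordinate, model$layout)
}

new_importance <- function(per_coordinate, layout) {
  stopifnot(length(per_coordinate) == nrow(layout))
  agg <- aggregate(per_coordinate,
                   by = list(feature = layout$feature, position = layout$position),
                   FUN = sum)
  names(agg)[3L] <- "importance"
  agg <- agg[order(match(agg$feature, FEATURE_ORDER), agg$position), ]
  rownames(agg) <- NULL
  structure(list(per_coordinate = setNames(as.numeric(per_coordinate), layout$name),
                 per_position_feature = agg,
                 layout = layout),
            class = "mhc_importance")
}

#' Average importance profiles across models
#'
#' Coordinate-wise arithmetic mean of per-model (already normalised)
#' profiles; the per-position aggregation is recomputed from the mean.
#' All profiles must share one feature layout.
#'
#' @param profiles Non-empty list of `mhc_importance` objects.
#' @return An aggregated `mhc_importance`.
#' @export
aggregate_importance <- function(profiles) {
  if (length(profiles) == 0L) abort("need at least one profile", "mhcforest_input_error")
  stopifnot(all(vapply(profiles, inherits, logical(1), "mhc_importance")))
  ref <- profiles[[1L]]$layout$name
  for (p in profiles) {
    if (!identical(p$layout$name, ref)) {
      abort("importance profiles have different feature layouts", "mhcforest_integrity_error")
    }
  }
  mat <- vapply(profiles, function(p) p$per_coordinate, numeric(length(ref)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(ref))
  new_importance(rowMeans(mat), profiles[[1L]]$layout)
}

#' Write an importance profile as TSV
#'
#' Two files are produced: `<stem>_coordinates.tsv` with one row per
#' feature-vector coordinate and `<stem>_positions.tsv` with the
#' per-(feature, position) aggregation.
#'
#' @param profile An `mhc_importance`.
#' @param stem Output path stem.
#' @export
write_importance <- function(profile, stem) {
  coord <- cbind(profile$layout[, c("feature", "position", "sub")],
                 importance = unname(profile$per_coordinate))
  write.table(coord, paste0(stem, "_coordinates.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(profile$per_position_feature, paste0(stem, "_positions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(stem)
}
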