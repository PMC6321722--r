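# Filtering and pooling of peptide records into per-allele training sets.

#' Construct a table of raw peptide records
#'
#' @param sequence Character vector of peptide sequences.
#' @param allele HLA allele names (or `NA` where unassigned).
#' @param confidence Assignment confidence in `[0,1]` from polyallelic
#'   deconvolution, `NA` for monoallelic records.
#' @param source Sample/dataset identifier.
#' @return A data.frame with one row per record.
#' @export
peptide_records <- function(sequence, allele = NA_character_,
                            confidence = NA_real_, source = NA_character_) {
  data.frame(sequence = toupper(sequence),
             allele = rep_len(as.character(allele), length(sequence)),
             confidence = rep_len(as.numeric(confidence), length(sequence)),
             source = rep_len(as.character(source), length(sequence)),
             stringsAsFactors = FALSE)
}

#' Filter peptide records to valid 9-mers over the standard alphabet
#'
#' Keeps exactly the records whose sequence is a length-9 peptide over the
#' 20 standard amino acids; the counts removed for each reason are
#' attached as the `"removed"` attribute.
#'
#' @param records A data.frame from [peptide_records()] (any extra columns
#'   are carried through).
#' @return The filtered data.frame, with `attr(, "removed")` a named
#'   integer vector `c(length = , alphabet = )`.
#' @export
filter_records <- function(records) {
  status <- peptide_status(records$sequence)
  out <- records[status == "ok", , drop = FALSE]
  out$sequence <- toupper(out$sequence)
  rownames(out) <- NULL
  attr(out, "removed") <- c(length = sum(status == "length"),
                            alphabet = sum(status == "alphabet"))
  out
}

#' Normalise an HLA allele name to a compact token
#'
#' `"HLA-A*02:01"`, `"A*02:01"` and `"A0201"` all normalise to `"A0201"`;
#' two-digit resolution (`"A02"`) is allowed.
#'
#' @param allele Character vector of HLA names.
#' @return Character vector of normalised tokens.
#' @export
normalize_allele <- function(allele) {
  x <- toupper(trimws(allele))
  x <- sub("^HLA-", "", x)
  x <- gsub("[*:]", "", x)
  bad <- !is.na(x) & !grepl("^[ABC][0-9]{2}([0-9]{2})?$", x)
  if (any(bad)) {
    abort(paste0("malformed HLA allele name(s): ",
                 paste(head(unique(allele[bad]), 3L), collapse = ", ")),
          "mhcforest_format_error")
  }
  x
}

#' Construct a per-allele binder dataset
#'
#' @param allele Normalised HLA allele token.
#' @param binders Character vector of unique binder peptides.
#' @param min_peptides Minimum unique binders for the allele to be
#'   trainable (default 50).
#' @return An object of class `mhc_allele_dataset`.
#' @export
allele_dataset <- function(allele, binders, min_peptides = 50L) {
  binders <- unique(toupper(binders))
  status <- peptide_status(binders)
  if (any(status != "ok")) abort("allele dataset contains invalid peptides", "mhcforest_format_error")
  structure(list(allele = normalize_allele(allele), binders = binders,
                 min_peptides = as.integer(min_peptides),
                 trainable = length(binders) >= min_peptides),
            class = "mhc_allele_dataset")
}

#' @export
print.mhc_allele_dataset <- function(x, ...) {
  cat(sprintf("<allele %s: %d unique binders, %strainable>\n",
              x$allele, length(x$binders), if (x$trainable) "" else "NOT "))
  invisible(x)
}

#' Pool filtered records into per-allele datasets
#'
#' Polyallelic records with missing allele assignment or confidence below
#' `conf_threshold` are discarded; mono- and polyallelic records are then
#' merged per allele with duplicates collapsed (a peptide may legitimately
#' appear under two different alleles; deduplication is within-allele
#' only). Alleles with fewer than `min_peptides` unique binders are
#' retained but flagged untrainable.
#'
#' @param mono Records from monoallelic samples (allele column set,
#'   confidence `NA`). May be `NULL`.
#' @param poly Records from polyallelic deconvolution (allele +
#'   confidence). May be `NULL`.
#' @param conf_threshold Minimum assignment confidence (default 0.95).
#' @param min_peptides Trainability threshold (default 50).
#' @return Named list of [allele_dataset()] objects, sorted by allele,
#'   with a `"summary"` attribute data.frame (allele, n_unique,
#'   trainable).
#' @export
pool_by_allele <- function(mono = NULL, poly = NULL, conf_threshold = 0.95,
                           min_peptides = 50L) {
  keep <- list()
  if (!is.null(mono) && nrow(mono)) {
    m <- mono[!is.na(mono$allele), , drop = FALSE]
    keep$mono <- m
  }
  if (!is.null(poly) && nrow(poly)) {
    p <- poly[!is.na(poly$allele) & !is.na(poly$confidence) &
                poly$confidence >= conf_threshold, , drop = FALSE]
    keep$poly <- p
  }
  if (length(keep) == 0L) return(structure(list(), summary = data.frame(
    allele = character(0), n_unique = integer(0), trainable = logical(0))))
  all <- do.call(rbind, lapply(keep, function(x) x[, c("sequence", "allele")]))
  all$allele <- normalize_allele(all$allele)
  split_seqs <- split(all$sequence, all$allele)
  split_seqs <- split_seqs[order(names(split_seqs))]
  datasets <- lapply(names(split_seqs), function(a) {
    allele_dataset(a, unique(split_seqs[[a]]), min_peptides = min_peptides)
  })
  names(datasets) <- names(split_seqs)
  summary <- data.frame(allele = names(datasets),
                        n_unique = vapply(datasets, function(d) length(d$binders), integer(1)),
                        trainable = vapply(datasets, function(d) d$trainable, logical(1)),
                        row.names = NULL)
  structure(datasets, summary = summary)
}

#' Read mono-/polyallelic assignment tables
#'
#' Mono TSV columns: `peptide`, `allele`, optional `source`. Poly TSV
#' columns: `peptide`, `allele`, `confidence`, optional `source`.
#'
#' @param path TSV file path.
#' @return A records data.frame as from [peptide_records()].
#' @export
read_assignments <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read assignments: ", path), "mhcforest_io_error")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("peptide", "allele") %in% names(tab))) {
    abort("assignment TSV needs columns: peptide, allele", "mhcforest_format_error")
  }
  peptide_records(tab$peptide, allele = tab$allele,
                  confidence = if ("confidence" %in% names(tab)) tab$confidence else NA_real_,
                  source = if ("source" %in% names(tab)) tab$source else NA_character_)
}

#' Write a pooling summary and per-allele peptide lists
#'
#' @param datasets Result of [pool_by_allele()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_allele_datasets <- function(datasets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in datasets) {
    write_peptides(d$binders, file.path(dir, paste0(d$allele, ".txt")))
  }
  write.table(attr(datasets, "summary"), file.path(dir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
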