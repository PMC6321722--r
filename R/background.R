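# Background proteome handling: FASTA ingestion and random decoy nonamers.

#' Read a proteome from a FASTA file
#'
#' Sequences are upper-cased. Records containing non-standard residues are
#' retained, but 9-mer windows overlapping those residues are never
#' sampled as decoys.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @return An object of class `mhc_proteome`: list with `ids` and
#'   `sequences` (character vectors of equal length).
#' @export
read_proteome <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read proteome: ", path), "mhcforest_io_error")
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) abort(paste0("FASTA parse failure: ", conditionMessage(e)),
                                            "mhcforest_io_error"))
  if (length(set) == 0L) abort("proteome FASTA contains no records", "mhcforest_format_error")
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) abort("duplicate FASTA identifiers", "mhcforest_format_error")
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) abort("empty sequence record in FASTA", "mhcforest_format_error")
  new_proteome(ids, seqs)
}

new_proteome <- function(ids, sequences) {
  structure(list(ids = unname(ids), sequences = unname(sequences)),
            class = "mhc_proteome")
}

#' @export
print.mhc_proteome <- function(x, ...) {
  cat(sprintf("<proteome: %d records, %d eligible 9-mer windows>\n",
              length(x$ids), sum(lengths(eligible_window_starts(x)))))
  invisible(x)
}

#' Eligible decoy windows of a proteome
#'
#' A window is eligible when all nine of its residues are standard amino
#' acids.
#'
#' @param proteome An `mhc_proteome`.
#' @return List (one element per record) of integer start positions.
#' @keywords internal
eligible_window_starts <- function(proteome) {
  lapply(proteome$sequences, function(s) {
    len <- nchar(s)
    if (len < PEPTIDE_LENGTH) return(integer(0))
    chars <- strsplit(s, "")[[1]]
    bad <- cumsum(!(chars %in% AA_ALPHABET))
    starts <- seq_len(len - PEPTIDE_LENGTH + 1L)
    # window [i, i+8] clean iff no invalid residue inside
    clean <- (bad[starts + PEPTIDE_LENGTH - 1L] -
                c(0L, bad)[starts]) == 0L
    starts[clean]
  })
}

#' Sample random decoy nonamers from a proteome
#'
#' Draws contiguous 9-mer substrings uniformly over all eligible windows
#' (length-weighted across proteins), emulating randomly generated
#' nonamers from a reference proteome used as presumed non-binders.
#' Sampling is with replacement unless `unique` is set; peptides listed in
#' `exclude` (e.g. known binders) are never returned.
#'
#' @param proteome An `mhc_proteome`.
#' @param n Number of decoys to draw.
#' @param exclude Character vector of peptides that must not appear.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param unique If `TRUE`, returned decoys are distinct.
#' @return Character vector of `n` valid 9-mer peptides.
#' @export
sample_decoys <- function(proteome, n, exclude = character(), seed = NULL,
                          unique = FALSE) {
  stopifnot(inherits(proteome, "mhc_proteome"))
  if (n < 0) abort("n must be non-negative", "mhcforest_config_error")
  if (n == 0) return(character(0))
  starts <- eligible_window_starts(proteome)
  counts <- lengths(starts)
  total <- sum(counts)
  if (total == 0L) abort("proteome has no eligible 9-mer windows", "mhcforest_sampling_error")
  exclude <- toupper(exclude)
  offset <- cumsum(c(0L, counts))

  draw <- function(k) {
    # flat window index -> (record, start)
    flat <- sample.int(total, k, replace = TRUE)
    rec <- findInterval(flat - 1L, offset, rightmost.closed = FALSE)
    pos <- vapply(seq_len(k), function(i) starts[[rec[i]]][flat[i] - offset[rec[i]]],
                  integer(1))
    substring(proteome$sequences[rec], pos, pos + PEPTIDE_LENGTH - 1L)
  }

  with_seed(seed, {
    out <- character(0)
    attempts <- 0L
    while (length(out) < n && attempts < 60L) {
      batch <- draw(max(n - length(out), 64L))
      batch <- batch[!batch %in% exclude]
      if (unique) {
        out <- base::unique(c(out, batch))
      } else {
        out <- c(out, batch)
      }
      attempts <- attempts + 1L
    }
    if (length(out) < n) {
      # rejection is starving: enumerate the distinct window peptides
      all_windows <- base::unique(unlist(lapply(seq_along(starts), function(i) {
        substring(proteome$sequences[i], starts[[i]], starts[[i]] + PEPTIDE_LENGTH - 1L)
      })))
      pool <- setdiff(all_windows, exclude)
      if (length(pool) == 0L || (unique && length(pool) < n - length(out))) {
        abort("no eligible decoy windows remain after exclusion", "mhcforest_sampling_error")
      }
      extra <- sample(pool, n - length(out), replace = !unique)
      out <- c(out, extra)
    }
    out[seq_len(n)]
  })
}

#' Read / write plain-text peptide lists (one peptide per line)
#'
#' @param path File path.
#' @return `read_peptides()` returns a character vector.
#' @export
read_peptides <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read peptide list: ", path), "mhcforest_io_error")
  x <- readLines(path)
  toupper(trimws(x[nzchar(trimws(x))]))
}

#' @rdname read_peptides
#' @param peptides Character vector of peptides.
#' @export
write_peptides <- function(peptides, path) {
  writeLines(peptides, path)
  invisible(path)
}
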