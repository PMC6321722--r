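# Residue alphabet, peptide validation, and per-residue property tables.
# All vector encodings use the canonical alphabetical residue order below.

#' The 20 standard amino acids, in canonical (alphabetical) order
#'
#' Every encoder lays out residue-indexed blocks in this order, so persisted
#' models remain portable across sessions.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

PEPTIDE_LENGTH <- 9L

prop_env <- new.env(parent = emptyenv())

read_property_tsv <- function(file) {
  path <- system.file("extdata", "properties", file, package = "mhcforest")
  if (!nzchar(path)) abort(paste0("property table not found: ", file), "mhcforest_io_error")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  version <- sub("^#\\s*", "", readLines(path, n = 1L))
  vals <- tab[[2]][match(AA_ALPHABET, tab[[1]])]
  if (anyNA(vals)) abort(paste0("incomplete property table: ", file), "mhcforest_format_error")
  names(vals) <- AA_ALPHABET
  attr(vals, "version") <- version
  vals
}

#' Per-residue biophysical property tables
#'
#' Returns the four property tables used by the scalar feature encoders:
#' hydropathy (Kyte-Doolittle), aromatic-ring indicator, formal side-chain
#' charge at physiological pH (pH 7.4), and residue mass. The tables ship
#' with the package as versioned TSV resources; the aromatic set, charge
#' convention and mass type are configurable here because the underlying
#' conventions are genuinely a matter of choice:
#'
#' * `aromatic_set = "FWYH"` counts every chemically aromatic side chain
#'   (phenylalanine, tryptophan, tyrosine, histidine); `"FWY"` restricts to
#'   the classic hydrophobic aromatics.
#' * Charge uses integer formal charges: D, E = -1; K, R = +1; histidine is
#'   treated as neutral at pH 7.4.
#' * `mass_type` selects monoisotopic (default) or average residue masses.
#'
#' @param aromatic_set Which residues count as aromatic, `"FWYH"` (default)
#'   or `"FWY"`.
#' @param mass_type `"monoisotopic"` (default) or `"average"` residue masses.
#' @return An object of class `mhc_properties`: a list with named numeric
#'   vectors `hydropathy`, `aromatic`, `charge`, `mass` (one value per
#'   residue in [AA_ALPHABET]) and a `meta` list recording the conventions,
#'   used to stamp trained models.
#' @examples
#' p <- residue_properties()
#' p$hydropathy[["I"]]  # 4.5
#' @export
residue_properties <- function(aromatic_set = c("FWYH", "FWY"),
                               mass_type = c("monoisotopic", "average")) {
  aromatic_set <- match.arg(aromatic_set)
  mass_type <- match.arg(mass_type)
  key <- paste(aromatic_set, mass_type, sep = "/")
  if (!is.null(prop_env[[key]])) return(prop_env[[key]])

  hydropathy <- read_property_tsv("hydropathy_kyte_doolittle.tsv")
  mass <- read_property_tsv(paste0("mass_", mass_type, ".tsv"))
  aromatic <- setNames(as.numeric(AA_ALPHABET %in% strsplit(aromatic_set, "")[[1]]),
                       AA_ALPHABET)
  charge <- setNames(rep(0, 20L), AA_ALPHABET)
  charge[c("D", "E")] <- -1
  charge[c("K", "R")] <- 1

  out <- structure(
    list(hydropathy = hydropathy, aromatic = aromatic, charge = charge,
         mass = mass,
         meta = list(hydropathy_scale = "kyte_doolittle",
                     hydropathy_version = attr(hydropathy, "version"),
                     aromatic_set = aromatic_set,
                     charge_convention = "formal_ph7.4",
                     mass_type = mass_type,
                     mass_version = attr(mass, "version"))),
    class = "mhc_properties")
  prop_env[[key]] <- out
  out
}

#' Look up a single residue property value
#'
#' @param aa One-letter code of a standard residue.
#' @param property_name One of `"hydropathy"`, `"aromatic"`, `"charge"`,
#'   `"mass"`.
#' @param properties A property-table set from [residue_properties()].
#' @return The tabulated numeric value.
#' @examples
#' residue_property("K", "charge")  # +1
#' @export
residue_property <- function(aa, property_name,
                             properties = residue_properties()) {
  if (!is.character(property_name) || length(property_name) != 1L ||
      !property_name %in% c("hydropathy", "aromatic", "charge", "mass")) {
    abort("unknown property name", "mhcforest_lookup_error")
  }
  if (!is.character(aa) || length(aa) != 1L || !aa %in% AA_ALPHABET) {
    abort(paste0("unknown residue: ", aa), "mhcforest_lookup_error")
  }
  unname(properties[[property_name]][[aa]])
}

#' The BLOSUM62 substitution matrix over the 20 standard residues
#'
#' Read from the package's versioned TSV resource; rows and columns follow
#' the canonical residue order.
#'
#' @return A symmetric 20 x 20 integer matrix with dimnames [AA_ALPHABET].
#' @export
blosum62_matrix <- function() {
  if (!is.null(prop_env$blosum62)) return(prop_env$blosum62)
  path <- system.file("extdata", "properties", "blosum62.tsv", package = "mhcforest")
  tab <- read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m <- m[AA_ALPHABET, AA_ALPHABET]
  storage.mode(m) <- "integer"
  if (!isSymmetric(unname(m))) abort("BLOSUM62 resource is not symmetric", "mhcforest_format_error")
  prop_env$blosum62 <- m
  m
}

#' Validate a candidate 9-mer peptide sequence
#'
#' Accepts exactly the peptides the classifiers are defined on: length-9
#' sequences over the 20 standard amino acids. Lowercase input is
#' upper-cased before checking.
#'
#' @param seq A single character string.
#' @return The validated, upper-cased peptide string.
#' @examples
#' validate_peptide("siinfeklv")
#' @export
validate_peptide <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    abort("peptide must be a non-empty string", "mhcforest_length_error")
  }
  seq <- toupper(seq)
  if (nchar(seq) != PEPTIDE_LENGTH) {
    abort(sprintf("peptide '%s' has length %d, expected 9", seq, nchar(seq)),
          "mhcforest_length_error")
  }
  if (!all(strsplit(seq, "")[[1]] %in% AA_ALPHABET)) {
    abort(sprintf("peptide '%s' contains non-standard residues", seq),
          "mhcforest_alphabet_error")
  }
  seq
}

#' Classify a vector of peptide sequences by validity
#'
#' Vectorised companion to [validate_peptide()] used by the filtering
#' pipeline: instead of raising, it reports why each sequence fails.
#'
#' @param seqs Character vector of candidate sequences.
#' @return Character vector with entries `"ok"`, `"length"` or `"alphabet"`.
#' @export
peptide_status <- function(seqs) {
  seqs <- toupper(seqs)
  status <- rep("ok", length(seqs))
  bad_len <- is.na(seqs) | nchar(seqs) != PEPTIDE_LENGTH
  status[bad_len] <- "length"
  check <- !bad_len
  if (any(check)) {
    ok_alpha <- grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), seqs[check])
    status[check][!ok_alpha] <- "alphabet"
  }
  status
}
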