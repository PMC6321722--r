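# Downstream analyses: score-affinity rank correlation and the gene
# expression effect on presentation.

#' Cliff's delta effect size
#'
#' `d = (#\{x_i > y_j\} - #\{x_i < y_j\}) / (mn)`: the probability that a
#' value from `x` exceeds one from `y`, minus the reverse. Computed via
#' midranks (equivalent to the O(mn) pairwise definition, ties counted
#' half), so it scales to large samples.
#'
#' @param x,y Non-empty numeric vectors.
#' @return d in `[-1, 1]`.
#' @examples
#' cliffs_d(c(1, 2, 3), c(2, 3, 4))  # -5/9
#' @export
cliffs_d <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    abort("both samples must be non-empty", "mhcforest_input_error")
  }
  if (anyNA(x) || anyNA(y)) abort("NA values not allowed", "mhcforest_input_error")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))  # midranks
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2  # = #{x>y} + 0.5 #{ties}
  2 * u / (m * n) - 1
}

#' Effect of gene expression on peptide presentation
#'
#' Per sample, compares the expression of genes whose products yielded
#' presented peptides against all other genes with Cliff's delta. Samples
#' with `min_genes` or fewer mapped presented genes are excluded
#' (threshold is strict: a sample needs *more than* `min_genes`). The
#' cross-sample mean is reported both unweighted and weighted by each
#' sample's mapped-gene count.
#'
#' @param samples List of expression samples: each a list with `name`,
#'   `expression` (named non-negative numeric vector over genes) and
#'   `presented_genes` (character subset of the expression names).
#' @param min_genes Exclusion threshold on mapped presented genes
#'   (default 50).
#' @return List with `per_sample` (data.frame `sample`, `d`, `n_presented`,
#'   `n_genes`), `weighted_mean` and `unweighted_mean`.
#' @export
expression_effect <- function(samples, min_genes = 50L) {
  if (length(samples) == 0L) abort("no samples", "mhcforest_input_error")
  rows <- lapply(samples, function(s) {
    genes <- names(s$expression)
    if (!all(s$presented_genes %in% genes)) {
      abort(paste0("sample '", s$name, "': presented genes missing from the expression table"),
            "mhcforest_format_error")
    }
    presented <- unique(s$presented_genes)
    if (length(presented) <= min_genes) return(NULL)
    rest <- setdiff(genes, presented)
    if (length(rest) == 0L) return(NULL)
    data.frame(sample = s$name,
               d = cliffs_d(unname(s$expression[presented]),
                            unname(s$expression[rest])),
               n_presented = length(presented),
               n_genes = length(genes),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    abort(sprintf("no sample has more than %d mapped presented genes", min_genes),
          "mhcforest_input_error")
  }
  per_sample <- do.call(rbind, rows)
  w <- per_sample$n_presented
  list(per_sample = per_sample,
       weighted_mean = sum(per_sample$d * w) / sum(w),
       unweighted_mean = mean(per_sample$d))
}

#' Correlation of classifier score with binding affinity
#'
#' Joins model scores to IC50 affinity measurements and reports per-allele
#' Spearman (midrank-tie-corrected) and Pearson correlations between
#' score and IC50, excluding alleles with fewer than `min_entries`
#' records. Since low IC50 means tight binding, a well-behaved classifier
#' shows strongly negative Spearman. Means across alleles are weighted by
#' entry count; unweighted means are also reported.
#'
#' @param scored data.frame with columns `allele`, `score`, `ic50`
#'   (nanomolar, positive).
#' @param min_entries Minimum records per allele (default 25).
#' @param log_ic50 Correlate against `log(ic50)` instead of raw IC50
#'   (affects Pearson only; Spearman is rank-invariant).
#' @return List with `per_allele` (data.frame `allele`, `n`, `spearman`,
#'   `pearson`), `weighted_spearman`, `weighted_pearson`,
#'   `unweighted_spearman`, `unweighted_pearson`.
#' @export
affinity_correlation <- function(scored, min_entries = 25L, log_ic50 = FALSE) {
  need <- c("allele", "score", "ic50")
  if (!all(need %in% names(scored))) {
    abort("scored table needs columns: allele, score, ic50", "mhcforest_format_error")
  }
  if (any(scored$ic50 <= 0)) abort("IC50 values must be positive", "mhcforest_input_error")
  groups <- split(scored, scored$allele)
  rows <- lapply(groups, function(g) {
    if (nrow(g) < min_entries) return(NULL)
    y <- if (log_ic50) log(g$ic50) else g$ic50
    data.frame(allele = g$allele[1L], n = nrow(g),
               spearman = cor(g$score, y, method = "spearman"),
               pearson = cor(g$score, y, method = "pearson"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    abort(sprintf("no allele has at least %d affinity entries", min_entries),
          "mhcforest_input_error")
  }
  per_allele <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  w <- per_allele$n
  list(per_allele = per_allele,
       weighted_spearman = sum(per_allele$spearman * w) / sum(w),
       weighted_pearson = sum(per_allele$pearson * w) / sum(w),
       unweighted_spearman = mean(per_allele$spearman),
       unweighted_pearson = mean(per_allele$pearson))
}

#' Read an affinity TSV (`allele`, `peptide`, `ic50_nM`)
#'
#' @param path TSV path.
#' @return data.frame with columns `allele`, `peptide`, `ic50`.
#' @export
read_affinity <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("allele", "peptide", "ic50_nM")
  if (!all(need %in% names(tab))) {
    abort("affinity TSV needs columns: allele, peptide, ic50_nM", "mhcforest_format_error")
  }
  data.frame(allele = normalize_allele(tab$allele),
             peptide = toupper(tab$peptide),
             ic50 = as.numeric(tab$ic50_nM), stringsAsFactors = FALSE)
}
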