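# internal helpers: classed conditions and local RNG scoping

abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "mhcforest_error", "error")))
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the R random seed for the duration of `code` and restores the
#' caller's RNG state afterwards, so seeded operations do not perturb the
#' surrounding random stream. A `NULL` seed leaves the RNG untouched.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a stream seed from a master seed; stays inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * as.double(offset)) %% 2147483647)
}
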