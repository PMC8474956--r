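#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so callers do not perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences over A/C/G/T (case preserved as
#'   upper case).
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Fractional G+C content of DNA strings
#'
#' @param x character vector of sequences.
#' @return numeric vector in \[0, 1\].
#' @export
gc_content <- function(x) {
  f <- Biostrings::letterFrequency(Biostrings::DNAStringSet(x), letters = "GC")
  as.numeric(f) / nchar(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic integer sub-seed derived from a master seed (kept < 2^31)
derive_seed <- function(seed, k) {
  (as.integer(seed) * 1009L + as.integer(k) * 9176L) %% 2147483629L
}
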