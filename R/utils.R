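#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable 31-bit string hash
#'
#' Polynomial rolling hash used to fan a global seed out to per-generator
#' subseeds and to assign cross-validation folds from sequence ids.  Stable
#' across sessions and platforms (pure integer arithmetic mod 2^31 - 1).
#'
#' @param x character vector
#' @return integer vector of hashes in `[0, 2^31 - 2]`
#' @export
stable_hash <- function(x) {
  mod <- 2147483647
  vapply(as.character(x), function(s) {
    h <- 0
    for (code in utf8ToInt(s)) h <- (h * 31 + code) %% mod
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

#' Derive a deterministic subseed for a named generator
#'
#' Adding a new generator name never perturbs the subseed of any other, so
#' synthetic studies stay reproducible as the generator set grows.
#'
#' @param seed global integer seed
#' @param name generator name
#' @return integer subseed below 2^31
#' @export
fan_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  as.integer((as.numeric(seed) * 10007 + stable_hash(name)) %% 2147483647)
}

#' Reverse complement of DNA strings
#' @param x character vector of A/C/G/T strings
#' @return character vector
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters (first offender: %s)",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}

#' @noRd
sample_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' @noRd
gc_fraction <- function(x) {
  nch <- nchar(x)
  gc <- vapply(x, function(s) {
    sum(strsplit(s, "")[[1]] %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
  gc / nch
}
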