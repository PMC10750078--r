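#' Explicit gapped k-mer feature map
#'
#' Enumerates, for every gap pattern (choice of `k` informative positions
#' out of `l`) and every l-window of the sequence, the length-k string read
#' at the informative positions, and counts occurrences keyed by
#' `"<pattern index>:<k-string>"`.  With `both_strands = TRUE` (the default,
#' and the convention used throughout the package) the reverse-complement
#' windows are counted too, which makes downstream kernels and decision
#' values strand-invariant.
#'
#' This is the direct, enumerative construction; the kernel itself is
#' computed in compiled code via the mismatch identity.  Their agreement is
#' asserted in the test suite.
#'
#' @param sequence a single A/C/G/T string
#' @param l word length
#' @param k informative positions (`k <= l`)
#' @param both_strands count reverse-complement windows as well
#' @return named integer vector of feature counts (empty when the sequence
#'   is shorter than `l`)
#' @export
gapped_kmer_feature_map <- function(sequence, l = 11, k = 7,
                                    both_strands = TRUE) {
  stopifnot(length(sequence) == 1, k >= 1, k <= l)
  n <- nchar(sequence)
  if (n < l) return(setNames(integer(0), character(0)))
  assert_dna(sequence)
  starts <- seq_len(n - l + 1)
  wins <- substring(sequence, starts, starts + l - 1)
  if (both_strands) wins <- c(wins, revcomp(wins))
  chars <- matrix(unlist(strsplit(wins, ""), use.names = FALSE),
                  nrow = length(wins), byrow = TRUE)
  pats <- combn(l, k)
  keys <- unlist(lapply(seq_len(ncol(pats)), function(j) {
    sub <- apply(chars[, pats[, j], drop = FALSE], 1, paste, collapse = "")
    paste0(j, ":", sub)
  }), use.names = FALSE)
  tab <- table(keys)
  setNames(as.integer(tab), names(tab))
}

#' Normalized gapped k-mer kernel between two sequences
#'
#' `K(a, b) = <phi(a), phi(b)> / sqrt(<phi(a), phi(a)> <phi(b), phi(b)>)`
#' where `phi` is the both-strand gapped k-mer count vector.  Computed in
#' compiled code through the identity that a pair of l-windows with `m`
#' mismatching positions shares exactly `choose(l - m, k)` gapped k-mer
#' features.  A sequence shorter than `l` has an empty feature vector; its
#' kernel against anything is defined as 0 and flagged with a warning.
#'
#' @param a,b A/C/G/T strings
#' @param l word length (default 11)
#' @param k informative positions (default 7)
#' @return similarity in `[0, 1]`
#' @export
gkm_kernel <- function(a, b, l = 11, k = 7) {
  gkm_kernel_matrix(c(a, b), l = l, k = k)[1, 2]
}

#' Normalized gapped k-mer kernel matrix
#'
#' @param seqs character vector of sequences (rows)
#' @param seqs2 optional second set (columns); when omitted the symmetric
#'   matrix over `seqs` is computed
#' @param l,k kernel orders, see [gkm_kernel()]
#' @return numeric matrix of similarities in `[0, 1]`
#' @export
gkm_kernel_matrix <- function(seqs, seqs2 = NULL, l = 11, k = 7) {
  selfA <- cpp_self_raw(seqs, l, k)
  if (is.null(seqs2)) {
    raw <- cpp_gkm_raw_sym(seqs, l, k)
    selfB <- selfA
  } else {
    raw <- cpp_gkm_raw_cross(seqs, seqs2, l, k)
    selfB <- cpp_self_raw(seqs2, l, k)
  }
  if (any(selfA == 0) || any(selfB == 0))
    warning("sequence(s) shorter than l have empty feature vectors; ",
            "their kernel rows/columns are 0")
  denom <- sqrt(outer(selfA, selfB))
  K <- ifelse(denom > 0, raw / denom, 0)
  dimnames(K) <- NULL
  K
}
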