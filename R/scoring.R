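#' Enumerate canonical k-mers
#'
#' Returns every l-mer whose 2-bit encoding is no greater than that of its
#' reverse complement, in lexicographic order.  For odd `l` no l-mer is its
#' own reverse complement, so the count is exactly `4^l / 2`; for even `l`
#' the `4^(l/2)` palindromes are each included once.
#'
#' @param l word length (1..13; the count grows as `4^l`)
#' @return character vector of canonical l-mers
#' @export
enumerate_canonical_kmers <- function(l) {
  if (l < 1) stop("l must be >= 1")
  cpp_enumerate_canonical(as.integer(l))
}

#' Score a sequence with a trained gkm SVM
#'
#' The SVM decision value; positive scores predict TF-DNA binding.  Values
#' are strand-invariant because the feature map counts both strands.
#'
#' @param model a `gkm_model`
#' @param sequence a single A/C/G/T string of length >= `l`
#' @return numeric decision value
#' @export
score_sequence <- function(model, sequence) {
  decision_values(model, sequence)
}

#' Build the exhaustive k-mer weight table of a model
#'
#' Scores every canonical l-mer with the model decision function.  The
#' computation runs in feature space: the support-sequence expansion
#' `w = sum_i a_i y_i phi(s_i) / |phi(s_i)|` is accumulated once over the
#' `choose(l, k) * 4^k` (gap-pattern, k-string) features, and each l-mer is
#' then scored as `<w, phi(x)> / |phi(x)| + b` — algebraically identical to
#' summing normalized kernels against every support sequence, but linear
#' rather than quadratic in the support set.
#'
#' @param model a `gkm_model`
#' @param l word length (defaults to the model's `l`; guarded at <= 13)
#' @return object of class `kmer_weight_table` with fields `l`, `weights`
#'   (full `4^l` lookup vector indexed by 2-bit encoding; identical values
#'   for a k-mer and its reverse complement), `bias`, `n_support`
#' @export
build_kmer_weight_table <- function(model, l = model$config$l) {
  if (l > 13) stop("4^l/2 exceeds the configured weight-table cap (l <= 13)")
  k <- model$config$k
  self_raw <- cpp_self_raw(model$support_sequences, l, k)
  coefs <- model$dual_coefficients / sqrt(self_raw)
  wv <- cpp_feature_weights(model$support_sequences, coefs, l, k)
  weights <- cpp_score_all_kmers(wv, l, k) + model$bias
  structure(list(l = as.integer(l), weights = weights, bias = model$bias,
                 n_support = length(model$support_sequences)),
            class = "kmer_weight_table")
}

#' @export
print.kmer_weight_table <- function(x, ...) {
  cat(sprintf("k-mer weight table: l=%d, %d canonical k-mers\n",
              x$l, length(x$weights) / 2))
  invisible(x)
}

#' Canonical view of a weight table
#'
#' @param table a `kmer_weight_table`
#' @param sorted sort descending by weight (ties broken lexicographically by
#'   k-mer, so any "top n" cut is deterministic)
#' @return data.table with columns `kmer` (canonical) and `weight`
#' @export
kmer_weight_view <- function(table, sorted = TRUE) {
  kmers <- enumerate_canonical_kmers(table$l)
  dt <- data.table(kmer = kmers,
                   weight = table$weights[cpp_encode_kmers(kmers, table$l) + 1])
  if (sorted) setorder(dt, -weight, kmer)
  dt
}

#' Look up weights for arbitrary l-mers
#' @param table a `kmer_weight_table`
#' @param kmers character vector of l-mers
#' @return numeric weights (strand-symmetric)
#' @export
kmer_weight_lookup <- function(table, kmers) {
  table$weights[cpp_encode_kmers(kmers, table$l) + 1]
}

#' Score genomic regions with a weight table
#'
#' `mode = "sliding_sum"` (default) sums the weights of every l-window in
#' the region — the deltaSVM-compatible aggregate.  `mode = "center_window"`
#' restricts scoring to the central `window` bp of each region before the
#' sliding sum, mirroring the fixed-width-probe reading of footprint
#' scoring.  Regions shorter than `l` (after centering) are reported and
#' skipped.
#'
#' @param table a `kmer_weight_table`
#' @param genome `synthetic_genome` or `DNAStringSet`
#' @param regions [GenomicRanges::GRanges]
#' @param mode `"sliding_sum"` or `"center_window"`
#' @param window center width for `center_window` mode (default 18 bp)
#' @return data.table with `id`, `chrom`, `start`, `end`, `score`,
#'   `best_window` (0-based offset of the max-weight l-window within the
#'   scored sequence), `n_windows`; attribute `skipped` lists unscorable
#'   regions with reasons
#' @export
score_regions <- function(table, genome, regions,
                          mode = c("sliding_sum", "center_window"),
                          window = 18) {
  mode <- match.arg(mode)
  seqs <- extract_sequences(genome, regions)
  skipped <- data.table(id = character(), reason = character())
  if (length(attr(seqs, "excluded")))
    skipped <- rbind(skipped, data.table(id = attr(seqs, "excluded"),
                                         reason = "non-ACGT sequence"))
  out <- vector("list", nrow(seqs))
  chr <- as.character(GenomicRanges::seqnames(regions))
  ids <- if (!is.null(regions$name)) as.character(regions$name) else
    sprintf("%s:%d-%d", chr, GenomicRanges::start(regions),
            GenomicRanges::end(regions))
  reg_dt <- data.table(id = ids, chrom = chr,
                       start = GenomicRanges::start(regions),
                       end = GenomicRanges::end(regions))
  for (i in seq_len(nrow(seqs))) {
    s <- seqs$sequence[i]
    if (mode == "center_window") {
      n <- nchar(s)
      if (n > window) {
        off <- (n - window) %/% 2
        s <- substr(s, off + 1, off + window)
      }
    }
    if (nchar(s) < table$l) {
      skipped <- rbind(skipped,
                       data.table(id = seqs$id[i],
                                  reason = sprintf("shorter than l = %d", table$l)))
      next
    }
    scan <- cpp_sliding_scan(s, table$weights, table$l)
    out[[i]] <- data.table(id = seqs$id[i], score = scan$sum,
                           best_window = scan$best_offset,
                           n_windows = scan$n_windows)
  }
  res <- rbindlist(out[!vapply(out, is.null, logical(1))])
  if (nrow(res) == 0) {
    res <- data.table(id = character(), score = numeric(),
                      best_window = integer(), n_windows = integer())
  }
  res <- merge(reg_dt, res, by = "id", sort = FALSE)
  attr(res, "skipped") <- skipped
  res
}

#' Reconstruct a PWM from the top-weighted k-mers
#'
#' Takes the `top_n` canonical k-mers by weight (ties broken
#' lexicographically), anchors on the top-1 k-mer as a seed, and aligns each
#' k-mer to the seed by choosing the orientation (forward or reverse
#' complement) and shift within `±max_shift` that maximizes positional
#' identity over the overlap (ties prefer forward orientation, then smaller
#' |shift|, then positive shift).  Aligned bases are accumulated into
#' position frequency counts with a pseudocount of `pseudocount` per base,
#' and rows are normalized to probabilities.  This seed-anchored ungapped
#' alignment replaces motif-discovery EM: the inputs are fixed-length
#' k-mers, so a full EM adds nothing at this scale.
#'
#' @param table a `kmer_weight_table`
#' @param top_n number of top k-mers (clamped to the table size with a
#'   warning)
#' @param max_shift maximum alignment shift in bp
#' @param pseudocount added to each base count per position
#' @return object of class `pwm`: list with `matrix` (L x 4 probabilities,
#'   columns A, C, G, T), `n_contributing_kmers`, `seed_kmer`
#' @export
build_pwm_from_top_kmers <- function(table, top_n = 1000, max_shift = 2,
                                     pseudocount = 0.25) {
  view <- kmer_weight_view(table, sorted = TRUE)
  if (top_n > nrow(view)) {
    warning("top_n exceeds table size; clamped to ", nrow(view))
    top_n <- nrow(view)
  }
  top <- view$kmer[seq_len(top_n)]
  seed <- top[1]
  l <- table$l
  bases <- c("A", "C", "G", "T")
  counts <- matrix(pseudocount, nrow = l, ncol = 4,
                   dimnames = list(NULL, bases))
  seed_chars <- strsplit(seed, "")[[1]]
  shifts <- seq(-max_shift, max_shift)
  ## candidate order encodes the tie-break: forward first, small |shift|
  cand <- expand.grid(shift = shifts, rc = c(FALSE, TRUE))
  cand <- cand[order(cand$rc, abs(cand$shift), -sign(cand$shift)), ]
  for (km in top) {
    variants <- c(km, revcomp(km))
    best <- NULL
    for (ci in seq_len(nrow(cand))) {
      s <- cand$shift[ci]
      chars <- strsplit(variants[1 + cand$rc[ci]], "")[[1]]
      ## k-mer position j aligns to seed position j + s
      pos_seed <- seq_len(l) + s
      ok <- pos_seed >= 1 & pos_seed <= l
      ident <- sum(chars[ok] == seed_chars[pos_seed[ok]])
      if (is.null(best) || ident > best$ident) {
        best <- list(ident = ident, chars = chars, pos = pos_seed, ok = ok)
      }
    }
    idx <- cbind(best$pos[best$ok], match(best$chars[best$ok], bases))
    for (r in seq_len(nrow(idx)))
      counts[idx[r, 1], idx[r, 2]] <- counts[idx[r, 1], idx[r, 2]] + 1
  }
  structure(list(matrix = counts / rowSums(counts),
                 n_contributing_kmers = top_n, seed_kmer = seed),
            class = "pwm")
}

#' Per-position information content of a PWM
#'
#' `2 + sum_b p_b log2 p_b` against a uniform background; 0 bits for a
#' uniform position, 2 bits for a point mass.
#'
#' @param pwm a `pwm` object or a plain L x 4 probability matrix
#' @return numeric vector of bits per position
#' @export
pwm_information_content <- function(pwm) {
  m <- if (inherits(pwm, "pwm")) pwm$matrix else as.matrix(pwm)
  apply(m, 1, function(p) {
    p <- p[p > 0]
    2 + sum(p * log2(p))
  })
}

#' Best-alignment per-position correlation between two PWMs
#'
#' Slides the query PWM (both orientations) along the reference and returns
#' the maximum mean per-position Pearson correlation between probability
#' columns over the overlap.  Used to quantify recovery of a planted motif.
#'
#' @param query,reference `pwm` objects or L x 4 probability matrices
#' @param min_overlap minimum overlapping positions considered
#' @return list with `correlation` (best mean per-position correlation),
#'   `shift`, `orientation`
#' @export
pwm_match_correlation <- function(query, reference, min_overlap = 5) {
  q <- if (inherits(query, "pwm")) query$matrix else as.matrix(query)
  r <- if (inherits(reference, "pwm")) reference$matrix else as.matrix(reference)
  rc_pwm <- function(m) m[rev(seq_len(nrow(m))), c(4, 3, 2, 1), drop = FALSE]
  best <- list(correlation = -Inf, shift = NA_integer_, orientation = NA)
  for (orient in c("forward", "revcomp")) {
    qq <- if (orient == "forward") q else rc_pwm(q)
    for (s in seq(-nrow(qq) + min_overlap, nrow(r) - min_overlap)) {
      iq <- which(seq_len(nrow(qq)) + s >= 1 & seq_len(nrow(qq)) + s <= nrow(r))
      if (length(iq) < min_overlap) next
      ir <- iq + s
      cc <- mean(vapply(seq_along(iq), function(t) {
        suppressWarnings(cor(qq[iq[t], ], r[ir[t], ]))
      }, numeric(1)), na.rm = TRUE)
      if (!is.na(cc) && cc > best$correlation)
        best <- list(correlation = cc, shift = s, orientation = orient)
    }
  }
  best
}

#' Write a PWM in MEME minimal motif format and as a matrix TSV
#' @param pwm a `pwm` object
#' @param prefix path prefix; writes `<prefix>.meme` and `<prefix>.tsv`
#' @param name motif name used in the MEME header
#' @return `prefix`, invisibly
#' @export
write_pwm <- function(pwm, prefix, name = "motif1") {
  m <- pwm$matrix
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "",
             "strands: + -", "",
             "Background letter frequencies",
             "A 0.25 C 0.25 G 0.25 T 0.25", "",
             sprintf("MOTIF %s", name),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                     nrow(m), pwm$n_contributing_kmers),
             apply(m, 1, function(p) paste(sprintf("%.6f", p), collapse = " ")))
  writeLines(lines, paste0(prefix, ".meme"))
  fwrite(as.data.table(m), paste0(prefix, ".tsv"), sep = "\t")
  invisible(prefix)
}
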