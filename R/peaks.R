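#' Planted motif specification
#'
#' @param pwm L x 4 probability matrix with columns A, C, G, T; each row must
#'   sum to 1 (tolerance 1e-9) and L must be at least 6
#' @param name motif name
#' @param planting_probability fraction of positive peaks receiving at least
#'   one instance
#' @param strand_policy `"forward"` or `"both"`
#' @return object of class `motif_spec`
#' @export
motif_spec <- function(pwm, name = "motif",
                       planting_probability = 1, strand_policy = c("both", "forward")) {
  strand_policy <- match.arg(strand_policy)
  pwm <- as.matrix(pwm)
  if (ncol(pwm) != 4) stop("pwm must have 4 columns (A, C, G, T)")
  if (nrow(pwm) < 6) stop("motif length must be >= 6")
  if (any(abs(rowSums(pwm) - 1) > 1e-9)) stop("pwm rows must sum to 1")
  if (planting_probability < 0 || planting_probability > 1)
    stop("planting_probability must lie in [0, 1]")
  colnames(pwm) <- c("A", "C", "G", "T")
  structure(list(pwm = pwm, name = name,
                 planting_probability = planting_probability,
                 strand_policy = strand_policy),
            class = "motif_spec")
}

#' Default planted motif
#'
#' A strong 8 bp homeodomain-like motif (consensus TTAAGTGG) emulating the
#' class of cardiac transcription-factor binding sites the classifier must
#' learn.  Per-position consensus probability `strength`, remainder split
#' evenly; `strength = 0.95` gives roughly 1.8 bits per position, emulating a
#' high-information cardiac TF site.
#'
#' @param strength consensus base probability per position, in (0.25, 1]
#' @param planting_probability see [motif_spec()]
#' @return a `motif_spec`
#' @export
default_motif <- function(strength = 0.95, planting_probability = 1) {
  consensus <- strsplit("TTAAGTGG", "")[[1]]
  bases <- c("A", "C", "G", "T")
  pwm <- t(vapply(consensus, function(b) {
    p <- rep((1 - strength) / 3, 4)
    p[bases == b] <- strength
    p
  }, numeric(4)))
  dimnames(pwm) <- list(NULL, bases)
  motif_spec(pwm, name = "TTAAGTGG", planting_probability = planting_probability)
}

#' @noRd
sample_motif_instance <- function(pwm) {
  bases <- c("A", "C", "G", "T")
  idx <- vapply(seq_len(nrow(pwm)), function(i) {
    sample.int(4, 1, prob = pwm[i, ])
  }, integer(1))
  list(seq = paste(bases[idx], collapse = ""),
       logodds = sum(log2(pwm[cbind(seq_len(nrow(pwm)), idx)] / 0.25)))
}

#' Generate motif-planted peaks on a synthetic genome
#'
#' Peaks are placed on a non-overlapping grid of `peak_length` bins.  Each
#' peak receives a motif instance with probability
#' `motif$planting_probability`; instances are sampled from the motif PWM,
#' written into the genome sequence, and recorded in the ground-truth table.
#' Peak signal follows the additive model
#' `base_signal + gain * log-odds(instance) + N(0, noise_sd)`, so signal
#' ranks correlate with motif strength — the structure a signal-sorted
#' ChIP-seq peak list presents to model training.
#'
#' @param genome a `synthetic_genome`
#' @param motif a [motif_spec()]
#' @param n_peaks number of peaks
#' @param peak_length peak width in bp (must be >= motif length)
#' @param seed integer seed
#' @param gain signal gain per log-odds unit
#' @param noise_sd standard deviation of the signal noise
#' @param base_signal baseline signal level
#' @return list with `genome` (the motif-planted genome), `peaks`
#'   ([GenomicRanges::GRanges] sorted by signal descending, metadata `name`
#'   and `score`), and `truth` (data.table: peak id, coordinates, signal,
#'   `planted`, 0-based instance `offset`, `strand`, instance sequence in
#'   motif orientation, `logodds`)
#' @export
generate_peaks <- function(genome, motif = default_motif(), n_peaks = 500,
                           peak_length = 100, seed = 1, gain = 2,
                           noise_sd = 0.5, base_signal = 10) {
  stopifnot(inherits(motif, "motif_spec"))
  L <- nrow(motif$pwm)
  if (peak_length < L) stop("peak_length is smaller than the motif length")
  seqs <- as.character(genome_seqs(genome))
  bins <- lapply(names(seqs), function(ch) {
    nb <- nchar(seqs[[ch]]) %/% peak_length
    if (nb < 1) return(NULL)
    data.table(chrom = ch, start0 = (seq_len(nb) - 1L) * peak_length)
  })
  bins <- rbindlist(bins)
  if (nrow(bins) < n_peaks)
    stop("genome too small to host ", n_peaks, " non-overlapping peaks")
  withr::with_seed(fan_seed(seed, "peaks"), {
    sel <- bins[sample.int(nrow(bins), n_peaks), ]
    planted <- runif(n_peaks) < motif$planting_probability
    truth <- vector("list", n_peaks)
    for (i in seq_len(n_peaks)) {
      ch <- sel$chrom[i]; s0 <- sel$start0[i]
      if (planted[i]) {
        inst <- sample_motif_instance(motif$pwm)
        strand <- if (motif$strand_policy == "both" && runif(1) < 0.5) "-" else "+"
        off <- sample.int(peak_length - L + 1L, 1) - 1L
        written <- if (strand == "+") inst$seq else revcomp(inst$seq)
        substr(seqs[[ch]], s0 + off + 1L, s0 + off + L) <- written
        sig <- base_signal + gain * inst$logodds + rnorm(1, 0, noise_sd)
        truth[[i]] <- data.table(chrom = ch, start0 = s0, signal = sig,
                                 planted = TRUE, offset = off, strand = strand,
                                 instance = inst$seq, logodds = inst$logodds)
      } else {
        sig <- base_signal + rnorm(1, 0, noise_sd)
        truth[[i]] <- data.table(chrom = ch, start0 = s0, signal = sig,
                                 planted = FALSE, offset = NA_integer_,
                                 strand = NA_character_,
                                 instance = NA_character_, logodds = NA_real_)
      }
    }
  })
  truth <- rbindlist(truth)
  setorder(truth, -signal, chrom, start0)
  truth[, `:=`(peak_id = sprintf("peak_%04d", .I),
               end0 = start0 + peak_length)]
  gr <- GenomicRanges::GRanges(
    truth$chrom,
    IRanges::IRanges(start = truth$start0 + 1L, end = truth$end0),
    name = truth$peak_id, score = truth$signal
  )
  new_genome <- genome
  if (inherits(genome, "synthetic_genome")) {
    new_genome$sequences <- Biostrings::DNAStringSet(seqs)
  } else {
    new_genome <- Biostrings::DNAStringSet(seqs)
  }
  list(genome = new_genome, peaks = gr,
       truth = truth[, .(peak_id, chrom, start0, end0, signal, planted,
                         offset, strand, instance, logodds)])
}

#' Select the top-scoring peaks
#'
#' Sorts descending by score with ties broken by (chromosome, start) so the
#' selected set is deterministic, and returns `min(n, available)` peaks.
#'
#' @param peaks [GenomicRanges::GRanges] with a numeric `score` column
#' @param n number of peaks to keep (default 1000, the size of the positive
#'   training set)
#' @return reordered, truncated `GRanges`
#' @export
select_top_peaks <- function(peaks, n = 1000) {
  o <- order(-peaks$score, as.character(GenomicRanges::seqnames(peaks)),
             GenomicRanges::start(peaks))
  peaks[o][seq_len(min(n, length(peaks)))]
}

#' Generate a GC- and chromosome-matched null (unbound) set
#'
#' For each positive interval, draws random same-length windows on the same
#' chromosome until one matches the positive's GC content within
#' `gc_tolerance` and overlaps no positive, excluded, or previously accepted
#' negative interval.
#'
#' @param genome `synthetic_genome` or `DNAStringSet`
#' @param positives [GenomicRanges::GRanges] positive intervals
#' @param gc_tolerance maximum allowed |GC(neg) - GC(pos)| (fraction;
#'   default 0.02)
#' @param excluded optional `GRanges` of additional forbidden intervals
#' @param max_attempts draws per positive before giving up
#' @param seed integer seed
#' @return `GRanges` of negatives, one per positive, with `name` and
#'   `matched_to` metadata
#' @export
generate_null_set <- function(genome, positives, gc_tolerance = 0.02,
                              excluded = NULL, max_attempts = 1000, seed = 1) {
  seqs <- genome_seqs(genome)
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  forbidden <- GenomicRanges::granges(positives)
  if (!is.null(excluded)) {
    forbidden <- suppressWarnings(c(forbidden, GenomicRanges::granges(excluded)))
  }
  GenomeInfoDb::seqlevels(forbidden) <-
    union(GenomeInfoDb::seqlevels(forbidden), names(seqs))
  pos_seq <- extract_sequences(genome, positives)
  pos_gc <- gc_fraction(pos_seq$sequence)
  chr <- as.character(GenomicRanges::seqnames(positives))
  w <- GenomicRanges::width(positives)
  out <- vector("list", length(positives))
  unmatched <- character(0)
  withr::with_seed(fan_seed(seed, "nullset"), {
    for (i in seq_along(positives)) {
      hit <- NULL
      for (a in seq_len(max_attempts)) {
        st <- sample.int(lens[[chr[i]]] - w[i] + 1L, 1)
        cand <- GenomicRanges::GRanges(
          factor(chr[i], levels = GenomeInfoDb::seqlevels(forbidden)),
          IRanges::IRanges(st, width = w[i]))
        if (length(GenomicRanges::findOverlaps(cand, forbidden)) > 0) next
        cand_seq <- toupper(as.character(
          Biostrings::subseq(seqs[[chr[i]]], st, st + w[i] - 1L)))
        if (grepl("[^ACGT]", cand_seq)) next
        if (abs(gc_fraction(cand_seq) - pos_gc[i]) > gc_tolerance) next
        hit <- cand
        break
      }
      if (is.null(hit)) {
        unmatched <- c(unmatched, pos_seq$id[i])
      } else {
        forbidden <- c(forbidden, hit)
        hit$name <- sprintf("neg_%04d", i)
        hit$matched_to <- pos_seq$id[i]
        out[[i]] <- hit
      }
    }
  })
  if (length(unmatched))
    stop("could not match negatives for positives: ",
         paste(unmatched, collapse = ", "))
  suppressWarnings(do.call(c, out[!vapply(out, is.null, logical(1))]))
}
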