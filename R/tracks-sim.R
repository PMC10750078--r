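#' Generate enhancer and DNase-footprint tracks
#'
#' Enhancers are placed on a non-overlapping grid; each receives
#' `dgfs_per_enhancer` footprints fully contained within it.  An orphan
#' fraction of additional footprints falls outside every enhancer, so that
#' intersection logic has something to reject: with `n_in` contained
#' footprints the generator emits `n_in * f / (1 - f)` orphans, making
#' orphans an `f` fraction of all footprints.  Optional `anchors` force the
#' first enhancers (each with one centered footprint) onto given positions —
#' the hook the study orchestrator uses to guarantee that planted variants
#' fall inside both tracks.
#'
#' @param genome a `synthetic_genome`
#' @param n_enhancers number of enhancers (including anchored ones)
#' @param enhancer_length enhancer width in bp
#' @param dgfs_per_enhancer footprints contained in each enhancer
#' @param dgf_length footprint width in bp (must not exceed
#'   `enhancer_length`)
#' @param orphan_dgf_fraction fraction of all footprints lying outside every
#'   enhancer
#' @param seed integer seed
#' @param anchors optional data.table with `chrom`, `pos` (1-based centers)
#' @return list with `enhancers` and `footprints`
#'   ([GenomicRanges::GRanges], `name` metadata; footprints carry a logical
#'   `inside`), and `truth` (planned counts)
#' @export
generate_regulatory_tracks <- function(genome, n_enhancers = 10,
                                       enhancer_length = 1000,
                                       dgfs_per_enhancer = 3,
                                       dgf_length = 20,
                                       orphan_dgf_fraction = 0.25,
                                       seed = 1, anchors = NULL) {
  if (dgf_length > enhancer_length)
    stop("dgf_length must not exceed enhancer_length")
  if (orphan_dgf_fraction < 0 || orphan_dgf_fraction >= 1)
    stop("orphan_dgf_fraction must lie in [0, 1)")
  seqs <- genome_seqs(genome)
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  n_anchor <- if (is.null(anchors)) 0L else nrow(anchors)
  if (n_anchor > n_enhancers) stop("more anchors than enhancers")
  withr::with_seed(fan_seed(seed, "tracks"), {
    enh <- vector("list", n_enhancers)
    if (n_anchor > 0) {
      for (i in seq_len(n_anchor)) {
        ch <- anchors$chrom[i]
        st <- max(1L, as.integer(anchors$pos[i]) - enhancer_length %/% 2L)
        st <- min(st, lens[[ch]] - enhancer_length + 1L)
        enh[[i]] <- GenomicRanges::GRanges(
          ch, IRanges::IRanges(st, width = enhancer_length))
      }
    }
    ## remaining enhancers on a grid, away from anchored ones
    bins <- rbindlist(lapply(names(lens), function(ch) {
      nb <- lens[[ch]] %/% enhancer_length
      data.table(chrom = ch, start = (seq_len(nb) - 1L) * enhancer_length + 1L)
    }))
    if (n_anchor > 0) {
      agr <- suppressWarnings(do.call(c, enh[seq_len(n_anchor)]))
      bgr <- GenomicRanges::GRanges(bins$chrom,
                                    IRanges::IRanges(bins$start,
                                                     width = enhancer_length))
      bins <- bins[!IRanges::overlapsAny(bgr, agr)]
    }
    n_rand <- n_enhancers - n_anchor
    if (nrow(bins) < n_rand) stop("genome too small for requested enhancers")
    sel <- bins[sample.int(nrow(bins), n_rand)]
    for (i in seq_len(n_rand)) {
      enh[[n_anchor + i]] <- GenomicRanges::GRanges(
        sel$chrom[i], IRanges::IRanges(sel$start[i], width = enhancer_length))
    }
    enhancers <- suppressWarnings(do.call(c, enh))
    enhancers$name <- sprintf("enh_%03d", seq_len(n_enhancers))
    ## contained footprints
    fp <- vector("list", 0)
    for (i in seq_len(n_enhancers)) {
      st_e <- GenomicRanges::start(enhancers)[i]
      ch <- as.character(GenomicRanges::seqnames(enhancers))[i]
      n_here <- dgfs_per_enhancer
      offs <- integer(0)
      if (i <= n_anchor) {
        center <- as.integer(anchors$pos[i])
        offs <- c(offs, max(0L, min(center - dgf_length %/% 2L - st_e,
                                    enhancer_length - dgf_length)))
        n_here <- n_here - 1L
      }
      if (n_here > 0)
        offs <- c(offs, sample.int(enhancer_length - dgf_length + 1L,
                                   n_here, replace = TRUE) - 1L)
      fp[[length(fp) + 1L]] <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(st_e + offs, width = dgf_length))
    }
    inside <- suppressWarnings(do.call(c, fp))
    ## orphan footprints, outside every enhancer
    f <- orphan_dgf_fraction
    n_orphan <- round(length(inside) * f / (1 - f))
    orphans <- vector("list", n_orphan)
    if (n_orphan > 0) {
      for (j in seq_len(n_orphan)) {
        repeat {
          ch <- sample(names(lens), 1)
          st <- sample.int(lens[[ch]] - dgf_length + 1L, 1)
          cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(st, width = dgf_length))
          if (!any(IRanges::overlapsAny(cand, enhancers))) break
        }
        orphans[[j]] <- cand
      }
    }
    footprints <- if (n_orphan > 0)
      suppressWarnings(c(inside, do.call(c, orphans))) else inside
    footprints$name <- sprintf("dgf_%04d", seq_along(footprints))
    footprints$inside <- c(rep(TRUE, length(inside)), rep(FALSE, n_orphan))
  })
  list(enhancers = enhancers, footprints = footprints,
       truth = list(n_enhancers = n_enhancers,
                    n_footprints = length(footprints),
                    n_contained = length(footprints) - n_orphan,
                    n_orphans = n_orphan))
}
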