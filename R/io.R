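#' Write intervals to BED
#'
#' BED is 0-based half-open on disk; the in-memory representation is the
#' 1-based closed [GenomicRanges::GRanges] convention.  The conversion
#' lives here (and in [read_bed()]) and nowhere else.
#'
#' @param gr [GenomicRanges::GRanges], optionally with `name` and `score`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_bed <- function(gr, path) {
  dt <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else ".",
    score = if (!is.null(gr$score)) gr$score else 0,
    strand = {
      s <- as.character(GenomicRanges::strand(gr))
      ifelse(s == "*", ".", s)
    })
  fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path BED file (at least 3 columns; name/score/strand read when
#'   present)
#' @return [GenomicRanges::GRanges] (1-based closed)
#' @export
read_bed <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 3) stop("BED file needs at least 3 columns")
  gr <- GenomicRanges::GRanges(
    as.character(dt[[1]]),
    IRanges::IRanges(start = dt[[2]] + 1L, end = dt[[3]]),
    strand = if (ncol(dt) >= 6)
      ifelse(dt[[6]] %in% c("+", "-"), dt[[6]], "*") else "*")
  if (ncol(dt) >= 4) gr$name <- as.character(dt[[4]])
  if (ncol(dt) >= 5) gr$score <- as.numeric(dt[[5]])
  gr
}
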