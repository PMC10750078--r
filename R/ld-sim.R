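#' Default population panel
#' @return character vector of population codes
#' @export
default_populations <- function() c("EUR", "AFR", "SAS", "EAS", "AMR")

#' Generate a block-structured LD pair table
#'
#' Each lead variant receives `n_linked_per_lead` proxy variants within
#' `block_size` bp on the same chromosome.  The squared genotype correlation
#' decays exponentially with genomic distance, `r2 = exp(-r2_decay * d)`,
#' plus a small population-specific perturbation, so different populations
#' report different r2 for the same pair.  Every lead also appears linked to
#' itself at `r2 = 1` in each population.  Proxy positions avoid the
#' intervals in `avoid` (e.g. planted motif instances) so proxies stay
#' scoring-neutral.
#'
#' @param genome a `synthetic_genome` (supplies proxy reference alleles)
#' @param lead_variants data.table with `rsid`, `chrom`, `pos`
#' @param populations population codes (nonempty)
#' @param block_size LD block extent in bp
#' @param r2_decay exponential decay rate per bp
#' @param n_linked_per_lead proxies per lead
#' @param seed integer seed
#' @param avoid optional [GenomicRanges::GRanges] proxies must not touch
#' @param edge_margin minimum distance of proxies from chromosome ends
#' @return list with `ld` (data.table: `lead_rsid`, `linked_rsid`,
#'   `population`, `R2`, `distance`, `linked_chrom`, `linked_pos`,
#'   `linked_ref`, `linked_alt`) and `truth` (`expanded_rsids`: rsids with
#'   r2 > 0.8 in at least one population, leads included)
#' @export
generate_ld_table <- function(genome, lead_variants,
                              populations = default_populations(),
                              block_size = 50000, r2_decay = 2e-4,
                              n_linked_per_lead = 3, seed = 1,
                              avoid = NULL, edge_margin = 50) {
  if (length(populations) == 0) stop("populations must be nonempty")
  lead_variants <- as.data.table(lead_variants)
  seqs <- genome_seqs(genome)
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  bases <- c("A", "C", "G", "T")
  rows <- list()
  proxy_truth <- list()
  counter <- 0L
  withr::with_seed(fan_seed(seed, "ld"), {
    for (i in seq_len(nrow(lead_variants))) {
      lead <- lead_variants[i]
      for (pop in populations) {
        rows[[length(rows) + 1L]] <- data.table(
          lead_rsid = lead$rsid, linked_rsid = lead$rsid, population = pop,
          R2 = 1.0, distance = 0L, linked_chrom = lead$chrom,
          linked_pos = lead$pos, linked_ref = "", linked_alt = "")
      }
      for (j in seq_len(n_linked_per_lead)) {
        counter <- counter + 1L
        rsid <- sprintf("rs9%06d", counter)
        dist <- sample.int(block_size, 1)
        sgn <- if (runif(1) < 0.5) -1L else 1L
        pos <- lead$pos + sgn * dist
        pos <- max(edge_margin, min(pos, lens[[lead$chrom]] - edge_margin))
        if (!is.null(avoid)) {
          tries <- 0L
          while (tries < 200L &&
                 any(IRanges::overlapsAny(
                   GenomicRanges::GRanges(lead$chrom,
                                          IRanges::IRanges(pos, pos)), avoid))) {
            pos <- max(edge_margin, min(pos + 37L, lens[[lead$chrom]] - edge_margin))
            tries <- tries + 1L
          }
        }
        dist_eff <- abs(pos - lead$pos)
        ref <- toupper(as.character(
          Biostrings::subseq(seqs[[lead$chrom]], pos, pos)))
        alt <- sample(setdiff(bases, ref), 1)
        r2_base <- exp(-r2_decay * dist_eff)
        r2 <- pmin(0.999, pmax(0, r2_base + rnorm(length(populations), 0, 0.05)))
        rows[[length(rows) + 1L]] <- data.table(
          lead_rsid = lead$rsid, linked_rsid = rsid, population = populations,
          R2 = r2, distance = dist_eff, linked_chrom = lead$chrom,
          linked_pos = as.integer(pos), linked_ref = ref, linked_alt = alt)
        proxy_truth[[length(proxy_truth) + 1L]] <- data.table(
          rsid = rsid, lead_rsid = lead$rsid, max_r2 = max(r2))
      }
    }
  })
  ld <- rbindlist(rows)
  proxies <- if (length(proxy_truth)) rbindlist(proxy_truth) else
    data.table(rsid = character(), lead_rsid = character(), max_r2 = numeric())
  expanded <- union(lead_variants$rsid, proxies[max_r2 > 0.8, rsid])
  list(ld = ld, truth = list(proxies = proxies, expanded_rsids = expanded))
}

#' Write an LD pair TSV
#' @param ld data.table from [generate_ld_table()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_ld_table <- function(ld, path) {
  fwrite(ld, path, sep = "\t", quote = FALSE)
  invisible(path)
}
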