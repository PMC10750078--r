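#' Catalog-stage configuration
#'
#' @param trait_pattern regular expression applied to `DISEASE/TRAIT`
#' @param case_sensitive match traits case-sensitively (default FALSE: GWAS
#'   trait strings are mixed-case and the lowercase keyword alternation is
#'   meant to match substrings within them)
#' @param r2_threshold LD proxy threshold; strictly-greater comparison
#' @param p_threshold eQTL p-value threshold; strictly-less comparison
#' @param tissues eQTL tissues retained
#' @param populations LD populations considered
#' @param require_nested_footprint if TRUE a variant's footprint must
#'   itself lie inside an enhancer; default applies both containment tests
#'   to the variant point independently
#' @param refilter_proxies if TRUE, LD proxies are re-filtered for
#'   enhancer/footprint overlap before the eQTL join (default FALSE:
#'   proxies flow directly to the join)
#' @return object of class `catalog_config`
#' @export
catalog_config <- function(trait_pattern = cvd_trait_pattern(),
                           case_sensitive = FALSE,
                           r2_threshold = 0.8, p_threshold = 0.1,
                           tissues = heart_tissues(),
                           populations = default_populations(),
                           require_nested_footprint = FALSE,
                           refilter_proxies = FALSE) {
  if (r2_threshold <= 0 || r2_threshold > 1) stop("r2_threshold must be in (0, 1]")
  if (p_threshold <= 0 || p_threshold > 1) stop("p_threshold must be in (0, 1]")
  structure(list(trait_pattern = trait_pattern,
                 case_sensitive = case_sensitive,
                 r2_threshold = r2_threshold, p_threshold = p_threshold,
                 tissues = tissues, populations = populations,
                 require_nested_footprint = require_nested_footprint,
                 refilter_proxies = refilter_proxies),
            class = "catalog_config")
}

#' Parse a GWAS-catalog-dialect TSV
#'
#' Requires the columns `SNPS`, `CHR_ID`, `CHR_POS`, `DISEASE/TRAIT` and
#' `STRONGEST SNP-RISK ALLELE`; optional `REF_ALLELE` / `ALT_ALLELE`
#' columns supply both alleles where present.  Rows whose rsid,
#' chromosome, or position is missing or unparseable are returned in the
#' rejection report with a reason — never silently dropped.
#'
#' @param path TSV file
#' @return list with `associations` (data.table: `rsid`, `chrom`, `pos`,
#'   `trait`, `ref`, `alt`) and `rejects` (data.table: `rsid`, `reason`)
#' @export
parse_gwas_catalog <- function(path) {
  required <- c("SNPS", "CHR_ID", "CHR_POS", "DISEASE/TRAIT",
                "STRONGEST SNP-RISK ALLELE")
  raw <- fread(path, sep = "\t", colClasses = "character", header = TRUE)
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("GWAS catalog file lacks required column(s): ",
         paste(missing, collapse = ", "))
  n <- nrow(raw)
  if (n == 0) {
    return(list(associations = data.table(rsid = character(),
                                          chrom = character(),
                                          pos = integer(), trait = character(),
                                          ref = character(), alt = character()),
                rejects = data.table(rsid = character(), reason = character())))
  }
  rsid <- trimws(raw$SNPS)
  chrom <- trimws(raw$CHR_ID)
  pos_raw <- trimws(raw$CHR_POS)
  pos <- suppressWarnings(as.integer(pos_raw))
  ref <- if ("REF_ALLELE" %in% names(raw)) trimws(raw$REF_ALLELE) else
    rep(NA_character_, n)
  alt <- if ("ALT_ALLELE" %in% names(raw)) trimws(raw$ALT_ALLELE) else {
    ## fall back to the risk-allele suffix "rsID-X"
    sub("^.*-", "", trimws(raw$`STRONGEST SNP-RISK ALLELE`))
  }
  reason <- rep(NA_character_, n)
  reason[is.na(pos) & nzchar(pos_raw)] <- "non-numeric position"
  reason[!nzchar(pos_raw)] <- "missing position"
  reason[!nzchar(chrom)] <- "missing chromosome"
  reason[!nzchar(rsid)] <- "missing rsid"
  reason[!is.na(pos) & pos < 1] <- "non-positive position"
  keep <- is.na(reason)
  list(associations = data.table(rsid = rsid[keep], chrom = chrom[keep],
                                 pos = pos[keep], trait = raw$`DISEASE/TRAIT`[keep],
                                 ref = ref[keep], alt = alt[keep]),
       rejects = data.table(rsid = rsid[!keep], reason = reason[!keep]))
}

#' Filter associations to cardiovascular traits
#'
#' Keeps a row iff its trait matches the pattern.  Order is preserved;
#' duplicated alternation terms in the pattern have no effect on the
#' result.
#'
#' @param associations data.table from [parse_gwas_catalog()]
#' @param pattern trait regular expression
#' @param case_sensitive match case-sensitively
#' @return filtered data.table
#' @export
filter_cvd_traits <- function(associations, pattern = cvd_trait_pattern(),
                              case_sensitive = FALSE) {
  ok <- tryCatch(suppressWarnings(grepl(pattern, associations$trait,
                                        ignore.case = !case_sensitive,
                                        perl = TRUE)),
                 error = function(e) stop("invalid trait pattern: ",
                                          conditionMessage(e)))
  associations[ok]
}

#' Drop indels and incomplete entries, keeping simple SNVs
#'
#' A record survives iff rsid, chromosome, position and both alleles are
#' present, both alleles are single characters in {A, C, G, T}, and the
#' alleles differ.
#'
#' @param associations data.table with `rsid`, `chrom`, `pos`, `ref`, `alt`
#' @return data.table of variant records (same columns, trait retained when
#'   present)
#' @export
drop_non_snv <- function(associations) {
  a <- as.data.table(associations)
  single <- function(x) !is.na(x) & x %in% c("A", "C", "G", "T")
  keep <- !is.na(a$rsid) & nzchar(a$rsid) &
    !is.na(a$chrom) & nzchar(a$chrom) &
    !is.na(a$pos) &
    single(a$ref) & single(a$alt) & a$ref != a$alt
  a[keep]
}

#' @noRd
variants_as_granges <- function(variants) {
  GenomicRanges::GRanges(variants$chrom,
                         IRanges::IRanges(variants$pos, variants$pos))
}

#' Keep variants inside both a footprint and an enhancer
#'
#' A 1-based variant position `p` is inside a 0-based half-open interval
#' `[start, end)` iff `start < p <= end`; the BED-to-1-based conversion is
#' performed once, in the BED reader.  By default the two containment tests
#' are independent (the footprint need not be nested in the enhancer); set
#' `require_nested_footprint` to demand a footprint that itself lies within
#' an enhancer.  Variants on chromosomes absent from both tracks are
#' dropped with a warning.
#'
#' @param variants data.table with `rsid`, `chrom`, `pos`
#' @param enhancers,footprints [GenomicRanges::GRanges]
#' @param require_nested_footprint see [catalog_config()]
#' @return subset of `variants`
#' @export
intersect_with_regulatory <- function(variants, enhancers, footprints,
                                      require_nested_footprint = FALSE) {
  variants <- as.data.table(variants)
  track_chr <- union(as.character(GenomicRanges::seqnames(enhancers)),
                     as.character(GenomicRanges::seqnames(footprints)))
  absent <- setdiff(unique(variants$chrom), track_chr)
  if (length(absent))
    warning("variant chromosome(s) absent from both tracks, dropped: ",
            paste(absent, collapse = ", "))
  gr <- variants_as_granges(variants)
  fp <- footprints
  if (require_nested_footprint) {
    nested <- suppressWarnings(
      IRanges::overlapsAny(footprints, enhancers, type = "within"))
    fp <- footprints[nested]
  }
  in_fp <- suppressWarnings(IRanges::overlapsAny(gr, fp))
  in_enh <- suppressWarnings(IRanges::overlapsAny(gr, enhancers))
  variants[in_fp & in_enh]
}

#' Expand a variant set with LD proxies
#'
#' Adds every variant linked to an input lead at `r2` strictly greater than
#' the threshold in at least one requested population.  Duplicates collapse
#' by rsid; provenance (lead, population, r2) is retained for every
#' qualifying link.  The output is always a superset of the input.
#'
#' @param variants data.table with `rsid`, `chrom`, `pos`, `ref`, `alt`
#' @param ld data.table as written by [write_ld_table()]
#' @param r2_threshold strict lower bound on r2
#' @param populations populations to consider; every code must belong to
#'   the configured vocabulary
#' @param known_populations the population vocabulary
#' @return list with `variants` (expanded, deduplicated; `source` column
#'   marks `lead` vs `ld_proxy`) and `provenance` (data.table: linked rsid,
#'   lead, population, r2)
#' @export
expand_ld <- function(variants, ld, r2_threshold = 0.8,
                      populations = default_populations(),
                      known_populations = default_populations()) {
  variants <- as.data.table(variants)
  ld <- as.data.table(ld)
  unknown <- setdiff(populations,
                     union(known_populations, unique(ld$population)))
  if (length(unknown))
    stop("unknown population code(s): ", paste(unknown, collapse = ", "))
  hits <- ld[lead_rsid %in% variants$rsid &
               population %in% populations &
               R2 > r2_threshold &
               linked_rsid != lead_rsid]
  provenance <- hits[, .(rsid = linked_rsid, lead_rsid, population, r2 = R2)]
  new <- unique(hits[!linked_rsid %in% variants$rsid],
                by = "linked_rsid")
  proxies <- if (nrow(new)) {
    data.table(rsid = new$linked_rsid, chrom = new$linked_chrom,
               pos = new$linked_pos, ref = new$linked_ref,
               alt = new$linked_alt, source = "ld_proxy")
  } else {
    data.table(rsid = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), source = character())
  }
  leads <- variants[, .(rsid, chrom, pos, ref, alt)]
  leads[, source := "lead"]
  list(variants = rbind(leads, proxies), provenance = provenance)
}

#' Join variants to tissue eQTL pairs
#'
#' Keeps eQTL rows whose variant is in the set, whose tissue is requested,
#' and whose p-value is strictly below the threshold.
#'
#' @param variants data.table with `rsid`
#' @param eqtl data.table as written by [write_eqtl_table()]
#' @param tissues tissues retained
#' @param p_threshold strict upper bound on p-values
#' @return data.table of pairs (`variant_rsid`, `gene_id`, `tissue`,
#'   `slope`, `pval`); attributes `n_unique_genes`, `n_unique_variants`
#' @export
join_eqtl <- function(variants, eqtl, tissues = heart_tissues(),
                      p_threshold = 0.1) {
  eqtl <- as.data.table(eqtl)
  hits <- eqtl[variant_id %in% variants$rsid &
                 tissue %in% tissues & pval < p_threshold]
  out <- hits[, .(variant_rsid = variant_id, gene_id, tissue, slope, pval)]
  attr(out, "n_unique_genes") <- length(unique(out$gene_id))
  attr(out, "n_unique_variants") <- length(unique(out$variant_rsid))
  out
}

#' Run the full variant-identification pipeline
#'
#' Parse, trait-filter, SNV-filter, intersect with regulatory tracks,
#' expand by LD, and join to tissue eQTLs.  LD proxies flow directly to the
#' eQTL join unless `config$refilter_proxies` is set.
#'
#' @param gwas_path GWAS-catalog TSV path
#' @param enhancers,footprints [GenomicRanges::GRanges] tracks
#' @param ld LD data.table (or path to the TSV)
#' @param eqtl eQTL data.table (or path to the TSV)
#' @param config a [catalog_config()]
#' @return list of stage outputs: `parsed`, `cvd`, `snv`, `in_regulatory`,
#'   `expanded`, `eqtl_pairs`, plus `counts` (named stage survivor counts)
#' @export
run_catalog <- function(gwas_path, enhancers, footprints, ld, eqtl,
                        config = catalog_config()) {
  if (is.character(ld)) ld <- fread(ld, sep = "\t")
  if (is.character(eqtl)) eqtl <- fread(eqtl, sep = "\t")
  parsed <- parse_gwas_catalog(gwas_path)
  cvd <- filter_cvd_traits(parsed$associations, config$trait_pattern,
                           config$case_sensitive)
  snv <- drop_non_snv(cvd)
  in_reg <- intersect_with_regulatory(snv, enhancers, footprints,
                                      config$require_nested_footprint)
  expanded <- expand_ld(in_reg, ld, config$r2_threshold, config$populations)
  eqtl_input <- expanded$variants
  if (config$refilter_proxies) {
    eqtl_input <- intersect_with_regulatory(eqtl_input, enhancers, footprints,
                                            config$require_nested_footprint)
  }
  pairs <- join_eqtl(eqtl_input, eqtl, config$tissues, config$p_threshold)
  list(parsed = parsed, cvd = cvd, snv = snv, in_regulatory = in_reg,
       expanded = expanded, eqtl_pairs = pairs,
       counts = c(parsed = nrow(parsed$associations),
                  parse_rejected = nrow(parsed$rejects),
                  cvd = nrow(cvd), snv = nrow(snv),
                  in_regulatory = nrow(in_reg),
                  expanded = nrow(expanded$variants),
                  eqtl_pairs = nrow(pairs),
                  eqtl_genes = attr(pairs, "n_unique_genes"),
                  eqtl_variants = attr(pairs, "n_unique_variants")))
}
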