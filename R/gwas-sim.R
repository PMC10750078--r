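#' Cardiovascular trait regular expression
#'
#' The alternation of cardiovascular keywords used to filter the
#' `DISEASE/TRAIT` column of a GWAS-catalog table.
#'
#' @return a single regular-expression string
#' @export
cvd_trait_pattern <- function() {
  "heart|cardiac|aortic|atrial|ventric|cardio|vascular|artery|coronary|myocardial|valve|cardium|stroke"
}

#' @noRd
cvd_trait_pool <- function() {
  c("Atrial fibrillation", "Coronary artery disease", "Stroke",
    "Myocardial infarction", "Heart failure", "Aortic aneurysm",
    "Cardiomyopathy", "QRS duration (ventricular conduction)",
    "Aortic valve stenosis", "Heart rate variability")
}

#' @noRd
other_trait_pool <- function() {
  c("Height", "Body mass index", "Type 2 diabetes",
    "Educational attainment", "Schizophrenia", "Bone mineral density",
    "Inflammatory bowel disease", "Hair color", "Asthma",
    "Rheumatoid arthritis")
}

#' Generate a GWAS-catalog-format association table
#'
#' Emits a tab-separated table in the GWAS-catalog dialect (columns `SNPS`,
#' `CHR_ID`, `CHR_POS`, `DISEASE/TRAIT`, `STRONGEST SNP-RISK ALLELE`, plus
#' `REF_ALLELE` / `ALT_ALLELE`).  Planned class counts are exact: traits are
#' drawn from a cardiovascular pool and a non-matching pool, a fixed number
#' of rows are indels (multi-base alleles), and a fixed number are malformed
#' (empty `CHR_POS` or empty allele fields, alternating).  Indel and
#' malformed classes are mutually exclusive.  Reference alleles of intact
#' single-nucleotide rows equal the genome base at the stated position.
#'
#' @param genome a `synthetic_genome`
#' @param n_associations number of rows
#' @param fraction_cvd fraction of rows given cardiovascular traits
#' @param fraction_indel fraction of rows realized as indels
#' @param fraction_malformed fraction of rows with missing fields
#' @param seed integer seed
#' @param plan optional data.table overriding the random plan; columns
#'   `chrom`, `pos` (1-based), `cvd`, `indel`, `malformed`, optionally
#'   `rsid` and `alt`
#' @param edge_margin keep positions at least this many bp from chromosome
#'   ends (leaves scoring context for downstream allele scoring)
#' @return list with `catalog` (data.table in file dialect) and `truth`
#'   (row-wise flags and clean fields)
#' @export
generate_gwas_catalog <- function(genome, n_associations = 200,
                                  fraction_cvd = 0.5, fraction_indel = 0.1,
                                  fraction_malformed = 0.1, seed = 1,
                                  plan = NULL, edge_margin = 50) {
  if (fraction_indel + fraction_malformed > 1)
    stop("fraction_indel + fraction_malformed must not exceed 1")
  seqs <- genome_seqs(genome)
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  bases <- c("A", "C", "G", "T")
  withr::with_seed(fan_seed(seed, "gwas"), {
    if (is.null(plan)) {
      n <- n_associations
      chrom <- sample(names(lens), n, replace = TRUE)
      pos <- vapply(chrom, function(ch) {
        sample(seq(edge_margin, lens[[ch]] - edge_margin), 1)
      }, numeric(1))
      n_cvd <- round(fraction_cvd * n)
      n_ind <- round(fraction_indel * n)
      n_mal <- round(fraction_malformed * n)
      cls <- sample(n)
      indel <- seq_len(n) %in% cls[seq_len(n_ind)]
      malformed <- seq_len(n) %in% cls[n_ind + seq_len(n_mal)]
      cvd <- seq_len(n) %in% sample(n, n_cvd)
      plan <- data.table(chrom = chrom, pos = as.integer(pos),
                         cvd = cvd, indel = indel, malformed = malformed)
    }
    plan <- as.data.table(plan)
    n <- nrow(plan)
    if (is.null(plan$rsid)) plan$rsid <- sprintf("rs%07d", seq_len(n))
    trait <- ifelse(plan$cvd,
                    sample(cvd_trait_pool(), n, replace = TRUE),
                    sample(other_trait_pool(), n, replace = TRUE))
    ref <- vapply(seq_len(n), function(i) {
      toupper(as.character(Biostrings::subseq(
        seqs[[plan$chrom[i]]], plan$pos[i], plan$pos[i])))
    }, character(1))
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1),
                  USE.NAMES = FALSE)
    if (!is.null(plan$alt)) {
      forced <- !is.na(plan$alt)
      alt[forced] <- plan$alt[forced]
    }
    ## realize indels as insertions (even rows) or deletions (odd rows)
    idx_ind <- which(plan$indel)
    for (j in seq_along(idx_ind)) {
      i <- idx_ind[j]
      extra <- paste(sample(bases, 1 + j %% 3, replace = TRUE), collapse = "")
      if (j %% 2 == 0) alt[i] <- paste0(ref[i], extra)
      else ref[i] <- paste0(ref[i], extra)
    }
    malformed_kind <- rep(NA_character_, n)
    idx_mal <- which(plan$malformed)
    malformed_kind[idx_mal] <- ifelse(seq_along(idx_mal) %% 2 == 0,
                                      "empty_position", "empty_alleles")
    chr_pos <- as.character(plan$pos)
    chr_pos[malformed_kind %in% "empty_position"] <- ""
    ref_out <- ref; alt_out <- alt
    ref_out[malformed_kind %in% "empty_alleles"] <- ""
    alt_out[malformed_kind %in% "empty_alleles"] <- ""
    risk <- ifelse(alt_out == "", "", paste0(plan$rsid, "-", alt_out))
    catalog <- data.table(
      SNPS = plan$rsid, CHR_ID = plan$chrom, CHR_POS = chr_pos,
      `DISEASE/TRAIT` = trait, `STRONGEST SNP-RISK ALLELE` = risk,
      REF_ALLELE = ref_out, ALT_ALLELE = alt_out
    )
    truth <- data.table(
      rsid = plan$rsid, chrom = plan$chrom, pos = plan$pos, trait = trait,
      ref = ref, alt = alt, cvd = plan$cvd, indel = plan$indel,
      malformed = plan$malformed, malformed_kind = malformed_kind
    )
  })
  list(catalog = catalog, truth = truth)
}

#' Write a GWAS-catalog-dialect TSV
#' @param catalog data.table from [generate_gwas_catalog()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gwas_catalog <- function(catalog, path) {
  fwrite(catalog, path, sep = "\t", quote = FALSE)
  invisible(path)
}
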