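#' Default tissue vocabulary
#' @return character vector; the first two entries are the cardiac tissues
#' @export
default_tissues <- function() {
  c("heart atrial appendage", "heart left ventricle", "whole blood", "liver")
}

#' Cardiac tissues used for the eQTL join
#' @return character vector of length 2
#' @export
heart_tissues <- function() default_tissues()[1:2]

#' Generate a tissue-labeled eQTL pair table
#'
#' Every variant receives a few variant-gene-tissue rows.  A planted set of
#' pairs in the two cardiac tissues gets p-values below `p_threshold`
#' (either a random `fraction_significant` of variants, or exactly the
#' variants named in `significant_variants`); all other rows get p-values
#' at or above the threshold.  A small decoy fraction receives small
#' p-values in non-cardiac tissues to exercise the tissue filter.
#'
#' @param variants data.table with an `rsid` column
#' @param n_genes gene pool size
#' @param tissues controlled tissue vocabulary (must contain the cardiac
#'   tissues)
#' @param effect_size_sd standard deviation of slopes
#' @param fraction_significant fraction of variants planted as cardiac
#'   significant (ignored when `significant_variants` is given)
#' @param p_threshold significance boundary the downstream join will use
#' @param seed integer seed
#' @param significant_variants optional rsids forced to carry one cardiac
#'   significant pair each
#' @param decoy_fraction fraction of variants given a significant-looking
#'   p-value in a non-cardiac tissue
#' @return list with `eqtl` (data.table: `variant_id`, `gene_id`, `tissue`,
#'   `slope`, `pval`) and `truth` (`planted`: the cardiac significant pairs)
#' @export
generate_eqtl_table <- function(variants, n_genes = 40,
                                tissues = default_tissues(),
                                effect_size_sd = 0.5,
                                fraction_significant = 0.1,
                                p_threshold = 0.1, seed = 1,
                                significant_variants = NULL,
                                decoy_fraction = 0.1) {
  variants <- as.data.table(variants)
  if (!all(heart_tissues() %in% tissues))
    stop("tissues must include the cardiac tissues: ",
         paste(heart_tissues(), collapse = ", "))
  genes <- sprintf("GENE_%03d", seq_len(n_genes))
  withr::with_seed(fan_seed(seed, "eqtl"), {
    sig <- if (is.null(significant_variants)) {
      n_sig <- round(fraction_significant * nrow(variants))
      if (n_sig > 0) sample(variants$rsid, n_sig) else character(0)
    } else {
      missing <- setdiff(significant_variants, variants$rsid)
      if (length(missing))
        stop("significant_variants not in variants: ",
             paste(missing, collapse = ", "))
      significant_variants
    }
    rows <- list()
    planted <- list()
    for (i in seq_len(nrow(variants))) {
      v <- variants$rsid[i]
      if (v %in% sig) {
        g <- sample(genes, 1)
        tis <- sample(heart_tissues(), 1)
        p <- runif(1, 1e-8, p_threshold / 2)
        rows[[length(rows) + 1L]] <- data.table(
          variant_id = v, gene_id = g, tissue = tis,
          slope = rnorm(1, 0, effect_size_sd), pval = p)
        planted[[length(planted) + 1L]] <- data.table(
          variant_rsid = v, gene_id = g, tissue = tis, pval = p)
      }
      if (runif(1) < decoy_fraction) {
        rows[[length(rows) + 1L]] <- data.table(
          variant_id = v, gene_id = sample(genes, 1),
          tissue = sample(setdiff(tissues, heart_tissues()), 1),
          slope = rnorm(1, 0, effect_size_sd),
          pval = runif(1, 1e-8, p_threshold / 2))
      }
      ## background rows: any tissue, p-value at or above threshold
      for (j in seq_len(2)) {
        rows[[length(rows) + 1L]] <- data.table(
          variant_id = v, gene_id = sample(genes, 1),
          tissue = sample(tissues, 1),
          slope = rnorm(1, 0, effect_size_sd),
          pval = runif(1, p_threshold, 1))
      }
    }
  })
  planted <- if (length(planted)) rbindlist(planted) else
    data.table(variant_rsid = character(), gene_id = character(),
               tissue = character(), pval = numeric())
  list(eqtl = rbindlist(rows), truth = list(planted = planted))
}

#' Write an eQTL pair TSV
#' @param eqtl data.table from [generate_eqtl_table()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_eqtl_table <- function(eqtl, path) {
  fwrite(eqtl, path, sep = "\t", quote = FALSE)
  invisible(path)
}
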