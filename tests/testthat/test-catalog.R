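make_catalog_file <- function(dt) {
  f <- tempfile(fileext = ".tsv")
  data.table::fwrite(dt, f, sep = "\t", quote = FALSE)
  f
}

test_that("catalog parser separates clean rows from rejects with reasons", {
  st <- small_study()
  parsed <- parse_gwas_catalog(st$paths$gwas)
  truth <- st$gwas$truth
  n_bad_pos <- sum(truth$malformed_kind %in% "empty_position")
  expect_equal(nrow(parsed$rejects), n_bad_pos)
  expect_equal(nrow(parsed$associations), nrow(truth) - n_bad_pos)
  ## explicit malformed variants
  dt <- data.table::data.table(
    SNPS = c("rs1", "rs2", "rs3", ""),
    CHR_ID = c("chr1", "chr1", "chr1", "chr1"),
    CHR_POS = c("100", "abc", "", "50"),
    `DISEASE/TRAIT` = "Stroke",
    `STRONGEST SNP-RISK ALLELE` = c("rs1-A", "rs2-C", "rs3-G", "rs4-T"))
  res <- parse_gwas_catalog(make_catalog_file(dt))
  expect_equal(nrow(res$associations), 1)
  expect_setequal(res$rejects$reason,
                  c("non-numeric position", "missing position", "missing rsid"))
})

test_that("parser handles empty files and missing columns", {
  hdr_only <- make_catalog_file(data.table::data.table(
    SNPS = character(), CHR_ID = character(), CHR_POS = character(),
    `DISEASE/TRAIT` = character(),
    `STRONGEST SNP-RISK ALLELE` = character()))
  res <- parse_gwas_catalog(hdr_only)
  expect_equal(nrow(res$associations), 0)
  expect_equal(nrow(res$rejects), 0)
  bad <- make_catalog_file(data.table::data.table(SNPS = "rs1", CHR_ID = "1"))
  expect_error(parse_gwas_catalog(bad), "CHR_POS")
})

test_that("trait filtering matches the cardiovascular pattern", {
  a <- data.table::data.table(
    rsid = c("rs1", "rs2", "rs3"), chrom = "chr1", pos = 1:3,
    trait = c("Atrial fibrillation", "Height", "stroke risk"),
    ref = "A", alt = "C")
  kept <- filter_cvd_traits(a)
  expect_setequal(kept$rsid, c("rs1", "rs3"))
  ## duplicated alternation terms do not change the result
  dup_pattern <- paste0(cvd_trait_pattern(), "|cardio|cardio")
  expect_identical(filter_cvd_traits(a, dup_pattern), kept)
  ## case-sensitive mode distinguishes case
  expect_equal(nrow(filter_cvd_traits(a, case_sensitive = TRUE)), 1)
  expect_error(filter_cvd_traits(a, pattern = "(unclosed"), "invalid")
  ## order preserved
  expect_identical(kept$rsid, c("rs1", "rs3"))
})

test_that("SNV filter removes indels and incomplete entries", {
  a <- data.table::data.table(
    rsid = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    chrom = c("chr1", "chr1", "chr1", NA, "chr1"),
    pos = c(10L, 20L, 30L, 40L, 50L),
    ref = c("A", "A", "G", "C", "T"),
    alt = c("AT", "A", "C", "G", ""))
  out <- drop_non_snv(a)
  expect_equal(out$rsid, "rs3")
  st <- small_study()
  parsed <- parse_gwas_catalog(st$paths$gwas)
  cvd <- filter_cvd_traits(parsed$associations)
  snv <- drop_non_snv(cvd)
  expect_equal(nrow(snv), st$truth$counts$snv)
})

test_that("regulatory intersection applies both containment tests half-open", {
  enh_bed <- tempfile(); fp_bed <- tempfile()
  writeLines("chr1\t100\t200\tenh1\t0\t.", enh_bed)
  writeLines(c("chr1\t150\t160\tfp1\t0\t.",
               "chr1\t300\t310\tfp_orphan\t0\t."), fp_bed)
  enh <- read_bed(enh_bed); fp <- read_bed(fp_bed)
  v <- data.table::data.table(
    rsid = c("in_both", "orphan_fp", "enh_only", "left_edge", "right_edge",
             "past_end"),
    chrom = "chr1",
    pos = c(155L, 305L, 120L, 150L, 160L, 161L),
    ref = "A", alt = "C")
  kept <- intersect_with_regulatory(v, enh, fp)
  ## 1-based p is inside [start, end) iff start < p <= end
  expect_setequal(kept$rsid, c("in_both", "right_edge"))
  v2 <- data.table::data.table(rsid = "off_chrom", chrom = "chr9",
                               pos = 155L, ref = "A", alt = "C")
  expect_warning(res <- intersect_with_regulatory(v2, enh, fp), "absent")
  expect_equal(nrow(res), 0)
})

test_that("nested-footprint mode is stricter than both-containment", {
  enh_bed <- tempfile(); fp_bed <- tempfile()
  writeLines("chr1\t100\t200\tenh1\t0\t.", enh_bed)
  ## footprint straddles the enhancer edge: contains the variant but is not
  ## nested within the enhancer
  writeLines("chr1\t190\t210\tfp1\t0\t.", fp_bed)
  enh <- read_bed(enh_bed); fp <- read_bed(fp_bed)
  v <- data.table::data.table(rsid = "v", chrom = "chr1", pos = 195L,
                              ref = "A", alt = "C")
  expect_equal(nrow(intersect_with_regulatory(v, enh, fp)), 1)
  expect_equal(nrow(intersect_with_regulatory(v, enh, fp,
                                              require_nested_footprint = TRUE)),
               0)
})

test_that("LD expansion is a strict-threshold superset with provenance", {
  v <- data.table::data.table(rsid = c("rs1", "rs2"), chrom = "chr1",
                              pos = c(100L, 500L), ref = "A", alt = "C")
  empty <- data.table::data.table(
    lead_rsid = character(), linked_rsid = character(),
    population = character(), R2 = numeric(), distance = integer(),
    linked_chrom = character(), linked_pos = integer(),
    linked_ref = character(), linked_alt = character())
  ident <- expand_ld(v, empty)
  expect_setequal(ident$variants$rsid, v$rsid)
  ld <- data.table::data.table(
    lead_rsid = c("rs1", "rs1", "rs2", "rs2"),
    linked_rsid = c("rsP1", "rsP2", "rsP2", "rsP3"),
    population = c("EUR", "AFR", "EUR", "EUR"),
    R2 = c(0.9, 0.85, 0.95, 0.8),
    distance = c(100L, 200L, 300L, 400L),
    linked_chrom = "chr1", linked_pos = c(200L, 300L, 300L, 900L),
    linked_ref = "G", linked_alt = "T")
  res <- expand_ld(v, ld, r2_threshold = 0.8)
  ## rsP3 at exactly 0.8 is excluded (strict >); rsP2 appears once with two
  ## provenance rows
  expect_setequal(res$variants$rsid, c("rs1", "rs2", "rsP1", "rsP2"))
  expect_equal(sum(res$provenance$rsid == "rsP2"), 2)
  expect_true(all(v$rsid %in% res$variants$rsid))
  expect_error(expand_ld(v, ld, populations = c("EUR", "XXX")), "XXX")
})

test_that("eQTL join filters by identity, tissue and strict p-value", {
  v <- data.table::data.table(rsid = c("rs1", "rs2"))
  eq <- data.table::data.table(
    variant_id = c("rs1", "rs1", "rs2", "rs9"),
    gene_id = c("G1", "G2", "G1", "G3"),
    tissue = c("heart left ventricle", "liver", "heart atrial appendage",
               "heart left ventricle"),
    slope = 0.5, pval = c(0.01, 0.01, 0.1, 0.001))
  res <- join_eqtl(v, eq, p_threshold = 0.1)
  expect_equal(nrow(res), 1)   # rs2 at p = 0.1 fails the strict threshold
  expect_equal(res$variant_rsid, "rs1")
  all_heart <- join_eqtl(v, eq, p_threshold = 1)
  expect_equal(nrow(all_heart), 2)
  expect_equal(attr(all_heart, "n_unique_genes"), 1)
})

test_that("pipeline stages are monotone and order-invariant", {
  st <- small_study()
  enh <- read_bed(st$paths$enhancers)
  fp <- read_bed(st$paths$footprints)
  res <- run_catalog(st$paths$gwas, enh, fp, st$paths$ld, st$paths$eqtl)
  expect_true(all(res$cvd$rsid %in% res$parsed$associations$rsid))
  expect_true(all(res$snv$rsid %in% res$cvd$rsid))
  expect_true(all(res$in_regulatory$rsid %in% res$snv$rsid))
  expect_true(all(res$in_regulatory$rsid %in% res$expanded$variants$rsid))
  ## shuffling the catalog rows leaves every stage's variant set unchanged
  raw <- data.table::fread(st$paths$gwas, sep = "\t", colClasses = "character")
  shuf <- raw[rev(seq_len(nrow(raw)))]
  f <- tempfile(fileext = ".tsv")
  data.table::fwrite(shuf, f, sep = "\t", quote = FALSE)
  res2 <- run_catalog(f, enh, fp, st$paths$ld, st$paths$eqtl)
  expect_setequal(res2$snv$rsid, res$snv$rsid)
  expect_setequal(res2$expanded$variants$rsid, res$expanded$variants$rsid)
  expect_setequal(res2$eqtl_pairs$variant_rsid, res$eqtl_pairs$variant_rsid)
})
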