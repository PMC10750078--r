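test_that("GWAS generator plants exact class counts", {
  g <- generate_genome(2, 50000, 0.41, seed = 4)
  gw <- generate_gwas_catalog(g, n_associations = 100, fraction_cvd = 0.5,
                              fraction_indel = 0.1, fraction_malformed = 0.1,
                              seed = 4)
  expect_equal(nrow(gw$catalog), 100)
  expect_equal(sum(gw$truth$cvd), 50)
  expect_equal(sum(gw$truth$indel), 10)
  expect_equal(sum(gw$truth$malformed), 10)
  expect_equal(sum(gw$truth$indel & gw$truth$malformed), 0)
  ## intact SNV rows carry the genome base as reference
  intact <- gw$truth[!gw$truth$indel & !gw$truth$malformed]
  seqs <- g$sequences
  for (i in sample(nrow(intact), 10)) {
    row <- intact[i]
    expect_identical(
      as.character(Biostrings::subseq(seqs[[row$chrom]], row$pos, row$pos)),
      row$ref)
  }
})

test_that("all-CVD catalogs match the trait pattern everywhere", {
  g <- generate_genome(1, 20000, 0.41, seed = 2)
  gw <- generate_gwas_catalog(g, 50, fraction_cvd = 1, fraction_indel = 0,
                              fraction_malformed = 0, seed = 2)
  expect_true(all(grepl(cvd_trait_pattern(), gw$truth$trait,
                        ignore.case = TRUE)))
  gw0 <- generate_gwas_catalog(g, 50, fraction_cvd = 0, fraction_indel = 0,
                               fraction_malformed = 0, seed = 2)
  expect_false(any(grepl(cvd_trait_pattern(), gw0$truth$trait,
                         ignore.case = TRUE)))
})

test_that("GWAS TSV output is deterministic under the seed", {
  g <- generate_genome(1, 20000, 0.41, seed = 2)
  f1 <- tempfile(); f2 <- tempfile()
  write_gwas_catalog(generate_gwas_catalog(g, 40, seed = 8)$catalog, f1)
  write_gwas_catalog(generate_gwas_catalog(g, 40, seed = 8)$catalog, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("regulatory tracks honor containment and orphan arithmetic", {
  g <- generate_genome(2, 100000, 0.41, seed = 6)
  tk <- generate_regulatory_tracks(g, n_enhancers = 10, enhancer_length = 1000,
                                   dgfs_per_enhancer = 3, dgf_length = 20,
                                   orphan_dgf_fraction = 0.25, seed = 6)
  expect_length(tk$footprints, 40)
  expect_equal(tk$truth$n_orphans, 10)
  inside <- IRanges::overlapsAny(tk$footprints, tk$enhancers, type = "within")
  expect_equal(sum(inside), 30)
  expect_identical(unname(inside), tk$footprints$inside)
  tk0 <- generate_regulatory_tracks(g, n_enhancers = 5,
                                    orphan_dgf_fraction = 0, seed = 6)
  expect_true(all(IRanges::overlapsAny(tk0$footprints, tk0$enhancers,
                                       type = "within")))
  expect_error(generate_regulatory_tracks(g, dgf_length = 2000,
                                          enhancer_length = 1000),
               "dgf_length")
})

test_that("LD table contains self pairs and distance-decaying proxies", {
  g <- generate_genome(1, 200000, 0.41, seed = 13)
  leads <- data.table::data.table(rsid = c("rs1", "rs2"), chrom = "chr1",
                                  pos = c(50000L, 150000L))
  ld <- generate_ld_table(g, leads, seed = 13)
  self <- ld$ld[ld$ld$lead_rsid == ld$ld$linked_rsid]
  expect_equal(nrow(self), 2 * length(default_populations()))
  expect_true(all(self$R2 == 1))
  proxies <- ld$ld[ld$ld$lead_rsid != ld$ld$linked_rsid]
  expect_equal(length(unique(proxies$population)), 5)
  ## every proxy carries one r2 per population
  expect_true(all(table(proxies$linked_rsid) == 5))
  ## a steep decay leaves no proxy above the threshold
  ld_steep <- generate_ld_table(g, leads, r2_decay = 1, seed = 13)
  expect_setequal(ld_steep$truth$expanded_rsids, leads$rsid)
  expect_error(generate_ld_table(g, leads, populations = character(0)),
               "nonempty")
})

test_that("eQTL generator plants exactly the requested significant pairs", {
  vars <- data.table::data.table(rsid = sprintf("rs%03d", 1:60))
  eq <- generate_eqtl_table(vars, significant_variants = vars$rsid[1:37],
                            seed = 5)
  expect_equal(nrow(eq$truth$planted), 37)
  joined <- join_eqtl(vars, eq$eqtl)
  expect_equal(nrow(joined), 37)
  expect_setequal(joined$variant_rsid, vars$rsid[1:37])
  ## no significance planted: the join returns nothing
  eq0 <- generate_eqtl_table(vars, fraction_significant = 0,
                             decoy_fraction = 0, seed = 5)
  expect_equal(nrow(join_eqtl(vars, eq0$eqtl)), 0)
  ## shuffling variant identities breaks the planted joins
  shuffled <- data.table::copy(vars)
  shuffled$rsid <- sprintf("rsX%03d", 1:60)
  expect_equal(nrow(join_eqtl(shuffled, eq$eqtl)), 0)
})

test_that("EMSA lanes follow the one-site law exactly when noiseless", {
  sim <- generate_emsa_data(kd = 200, bmax = 1,
                            concentrations = c(50, 100, 500, 1000, 2000),
                            noise_sd = 0, n_replicates = 1, seed = 1)
  pts <- binding_points(sim$lanes)
  expect_equal(pts$fraction, c(0.2, 1 / 3, 5 / 7, 5 / 6, 10 / 11),
               tolerance = 1e-12)
  half <- generate_emsa_data(kd = 100, bmax = 0.8, concentrations = c(100, 50, 200),
                             noise_sd = 0, n_replicates = 1, seed = 1)
  expect_equal(binding_points(half$lanes)$fraction[1], 0.4, tolerance = 1e-12)
  expect_error(generate_emsa_data(kd = -5), "positive")
  expect_error(generate_emsa_data(kd = 10, concentrations = c(0, 10)),
               "positive")
})

test_that("seed fan-out is stable and generator-local", {
  expect_identical(stable_hash("genome"), stable_hash("genome"))
  expect_false(fan_seed(1, "genome") == fan_seed(1, "peaks"))
  expect_true(fan_seed(1, "genome") < 2^31)
})
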