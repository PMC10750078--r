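## helper: in-place single-base genome edit returning a new DNAStringSet
edit_genome <- function(genome, chrom, pos, base) {
  seqs <- as.character(genome_seqs <- if (inherits(genome, "synthetic_genome"))
    genome$sequences else genome)
  substr(seqs[[chrom]], pos, pos) <- base
  Biostrings::DNAStringSet(seqs)
}

test_that("deltaSVM is zero for identical alleles and antisymmetric", {
  wt <- small_table()
  st <- small_study()
  v <- st$planted[1]
  same <- data.table::data.table(rsid = "same", chrom = v$chrom, pos = v$pos,
                                 ref = v$ref, alt = v$ref)
  expect_identical(delta_svm(wt, st$genome, same)$delta, 0)
  fwd <- delta_svm(wt, st$genome,
                   data.table::data.table(rsid = "v", chrom = v$chrom,
                                          pos = v$pos, ref = v$ref,
                                          alt = v$alt))
  ## score the reverse substitution on the alt-substituted genome
  g_alt <- edit_genome(st$genome, v$chrom, v$pos, v$alt)
  rev <- delta_svm(wt, g_alt,
                   data.table::data.table(rsid = "v", chrom = v$chrom,
                                          pos = v$pos, ref = v$alt,
                                          alt = v$ref))
  expect_identical(rev$delta, -fwd$delta)
  expect_identical(rev$ref_score, fwd$alt_score)
  expect_identical(rev$alt_score, fwd$ref_score)
})

test_that("delta is local to the scoring window and strand-invariant", {
  wt <- small_table()
  st <- small_study()
  v <- st$planted[2]
  var <- data.table::data.table(rsid = "v", chrom = v$chrom, pos = v$pos,
                                ref = v$ref, alt = v$alt)
  d0 <- delta_svm(wt, st$genome, var)$delta
  ## edits outside the (2l-1) window do not move delta
  g_edit <- edit_genome(st$genome, v$chrom, v$pos + 15L, "A")
  g_edit <- edit_genome(g_edit, v$chrom, v$pos - 15L, "C")
  expect_identical(delta_svm(wt, g_edit, var)$delta, d0)
  ## reverse-complemented genome with complemented alleles and mirrored
  ## coordinates gives the identical delta
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  seqs <- as.character(st$genome$sequences)
  rc_seqs <- Biostrings::DNAStringSet(setNames(revcomp(unname(seqs)),
                                               names(seqs)))
  len <- nchar(seqs[[v$chrom]])
  var_rc <- data.table::data.table(rsid = "v", chrom = v$chrom,
                                   pos = len - v$pos + 1L,
                                   ref = unname(comp[v$ref]),
                                   alt = unname(comp[v$alt]))
  ## summation runs over the windows in mirrored order, so agreement is to
  ## floating-point accumulation error, not bitwise
  expect_equal(delta_svm(wt, rc_seqs, var_rc)$delta, d0, tolerance = 1e-12)
})

test_that("deltaSVM guards its preconditions", {
  wt <- small_table()
  st <- small_study()
  v <- st$planted[1]
  wrong_ref <- setdiff(c("A", "C", "G", "T"), c(v$ref, v$alt))[1]
  expect_error(delta_svm(wt, st$genome,
                         data.table::data.table(rsid = "x", chrom = v$chrom,
                                                pos = v$pos, ref = wrong_ref,
                                                alt = v$alt)),
               "reference mismatch")
  edge_base <- as.character(
    Biostrings::subseq(st$genome$sequences[["chr1"]], 3, 3))
  expect_error(delta_svm(wt, st$genome,
                         data.table::data.table(rsid = "edge", chrom = "chr1",
                                                pos = 3L, ref = edge_base,
                                                alt = "A")),
               "edge")
})

test_that("batch scoring equals per-variant scoring and is order-invariant", {
  wt <- small_table()
  st <- small_study()
  vars <- st$gwas$truth[!st$gwas$truth$indel & !st$gwas$truth$malformed][1:15,
    .(rsid, chrom, pos, ref, alt)]
  batch <- delta_svm_batch(wt, st$genome, vars)
  singles <- vapply(seq_len(nrow(vars)), function(i) {
    delta_svm(wt, st$genome, vars[i])$delta
  }, numeric(1))
  expect_equal(batch$scores$delta, singles)
  shuf <- delta_svm_batch(wt, st$genome, vars[rev(seq_len(nrow(vars)))])
  expect_setequal(shuf$scores$rsid, batch$scores$rsid)
  m <- merge(batch$scores, shuf$scores, by = "rsid")
  expect_equal(m$delta.x, m$delta.y)
  expect_named(batch$summary[1:2], c("mean", "sd"))
})

test_that("prioritization enforces the delta AND cardiac-eQTL conjunction", {
  dres <- list(TF1 = list(scores = data.table::data.table(
    rsid = c("big_no_eqtl", "big_eqtl", "small_eqtl"),
    ref_score = 0, alt_score = 0,
    delta = c(-8, -5, 0.01))))
  eq <- data.table::data.table(
    variant_rsid = c("big_eqtl", "small_eqtl"), gene_id = c("G1", "G2"),
    tissue = "heart left ventricle", slope = 1, pval = 0.01)
  res <- prioritize(dres, eq, selection = "abs_delta_threshold",
                    threshold = 1)
  expect_equal(res$rsid, "big_eqtl")   # no eQTL excluded; small delta excluded
  expect_equal(res$rank, 1L)
  topk <- prioritize(dres, eq, selection = "top_k", k = 1)
  expect_equal(topk$rsid, "big_eqtl")
  expect_warning(
    empty <- prioritize(dres, eq[0], selection = "top_k", k = 2),
    "empty")
  expect_equal(nrow(empty), 0)
})
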