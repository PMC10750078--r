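test_that("canonical k-mer counts match brute-force enumeration", {
  for (l in 1:5) {
    kmers <- enumerate_canonical_kmers(l)
    ## brute force: all l-mers collapsed by reverse complement
    all_l <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), l)))
    canon <- unique(pmin(all_l, revcomp(all_l)))
    expect_setequal(kmers, canon)
  }
  expect_length(enumerate_canonical_kmers(1), 2)
  expect_length(enumerate_canonical_kmers(2), 10)
  expect_length(enumerate_canonical_kmers(3), 32)  # 4^3/2 (odd l, no palindromes)
  expect_error(enumerate_canonical_kmers(0), ">= 1")
})

test_that("weight-table lookup reproduces direct model scoring", {
  m <- small_model()
  wt <- small_table()
  set.seed(6)
  seqs <- random_dna(20, sample(25:60, 20, replace = TRUE))
  for (s in seqs) {
    wins <- substring(s, seq_len(nchar(s) - 10), 11:nchar(s))
    direct <- sum(decision_values(m, wins))
    via_table <- sum(kmer_weight_lookup(wt, wins))
    expect_lt(abs(direct - via_table), 1e-9)
  }
  ## canonical representation: a k-mer and its reverse complement share one
  ## weight
  km <- substring(seqs[1], 1, 11)
  expect_identical(kmer_weight_lookup(wt, km), kmer_weight_lookup(wt, revcomp(km)))
})

test_that("top-weighted k-mers carry the planted motif consensus", {
  v <- kmer_weight_view(small_table())
  expect_equal(nrow(v), 4^11 / 2)
  expect_false(is.unsorted(rev(v$weight)))
  top1 <- v$kmer[1]
  expect_true(grepl("TTAAGTGG", top1) || grepl("CCACTTAA", top1) ||
                grepl(substr("TTAAGTGG", 1, 6), top1) ||
                grepl(revcomp(substr("TTAAGTGG", 3, 8)), top1))
})

test_that("region scoring supports sliding-sum and centered-window modes", {
  wt <- small_table()
  st <- small_study()
  ## an 11 bp region's sliding sum is the single k-mer weight
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 111))
  seq11 <- extract_sequences(st$genome, gr)$sequence
  res <- score_regions(wt, st$genome, gr)
  expect_equal(res$score, unname(kmer_weight_lookup(wt, seq11)))
  expect_equal(res$n_windows, 1)
  ## centered mode scores only the middle window bp
  gr50 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1050))
  full <- score_regions(wt, st$genome, gr50, mode = "sliding_sum")
  center <- score_regions(wt, st$genome, gr50, mode = "center_window",
                          window = 18)
  expect_equal(center$n_windows, 8)   # 18 - 11 + 1
  expect_false(isTRUE(all.equal(full$score, center$score)))
  ## too-short regions are skipped with a reason
  gr_short <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 8))
  res_s <- score_regions(wt, st$genome, gr_short)
  expect_equal(nrow(res_s), 0)
  expect_match(attr(res_s, "skipped")$reason, "shorter")
})

test_that("planted motif regions outscore random regions", {
  wt <- small_table()
  st <- small_study()
  tr <- st$peaks$truth[st$peaks$truth$planted][1:20]
  motif_gr <- GenomicRanges::GRanges(
    tr$chrom, IRanges::IRanges(tr$start0 + tr$offset + 1 - 2,
                               width = nchar(tr$instance[1]) + 4))
  motif_scores <- score_regions(wt, st$genome, motif_gr)$score
  set.seed(8)
  lens <- setNames(Biostrings::width(st$genome$sequences),
                   names(st$genome$sequences))
  rand_pos <- sample(2e4, 200)
  rand_gr <- GenomicRanges::GRanges("chr2",
                                    IRanges::IRanges(1e5 + rand_pos,
                                                     width = 12))
  rand_scores <- score_regions(wt, st$genome, rand_gr)$score
  expect_gt(mean(motif_scores), quantile(rand_scores, 0.99))
})

test_that("PWM construction produces probabilities anchored on the seed", {
  wt <- small_table()
  pwm <- build_pwm_from_top_kmers(wt, top_n = 1000)
  expect_equal(rowSums(pwm$matrix), rep(1, 11), tolerance = 1e-9)
  expect_equal(pwm$n_contributing_kmers, 1000)
  ## a single contributing k-mer gives near-point-mass columns
  p1 <- build_pwm_from_top_kmers(wt, top_n = 1)
  chars <- strsplit(p1$seed_kmer, "")[[1]]
  for (i in seq_len(11)) {
    expect_equal(unname(p1$matrix[i, chars[i]]), (1 + 0.25) / 2,
                 tolerance = 1e-9)
  }
  ## clamping checked on a toy-order table (512 canonical 5-mers)
  toy_ts <- training_set(c(a = "TTAAGTGGTTAAGTGG", b = "GTTAAGTGGA"),
                         c(c = "ACCACCACCACCACC", d = "GAGAGAGAGAG"))
  toy_model <- train_gkm_svm(toy_ts, gkm_config(l = 5, k = 3, d = 2))
  toy_wt <- build_kmer_weight_table(toy_model)
  expect_warning(p_all <- build_pwm_from_top_kmers(toy_wt, top_n = 1000),
                 "clamped")
  expect_equal(p_all$n_contributing_kmers, 4^5 / 2)
})

test_that("information content spans uniform to point-mass", {
  m <- rbind(rep(0.25, 4), c(1, 0, 0, 0), c(0.5, 0.5, 0, 0))
  ic <- pwm_information_content(m)
  expect_equal(ic, c(0, 2, 1), tolerance = 1e-12)
})

test_that("PWM matching finds the planted orientation and its reverse", {
  planted <- default_motif()$pwm
  rc <- planted[rev(seq_len(nrow(planted))), c(4, 3, 2, 1)]
  m <- pwm_match_correlation(rc, planted)
  expect_equal(m$orientation, "revcomp")
  expect_gt(m$correlation, 0.999)
})

test_that("PWM files are written in MEME minimal format", {
  pwm <- build_pwm_from_top_kmers(small_table(), top_n = 50)
  prefix <- file.path(tempdir(), "pwm_out")
  write_pwm(pwm, prefix)
  lines <- readLines(paste0(prefix, ".meme"))
  expect_true(any(grepl("^MEME version", lines)))
  expect_true(any(grepl("letter-probability matrix", lines)))
  mat <- data.table::fread(paste0(prefix, ".tsv"))
  expect_equal(dim(mat), c(11, 4))
})
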