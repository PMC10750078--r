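## Shared fixtures, built once per test run and memoised.  The small study
## exercises every module quickly; the full-scale study reproduces the
## default study conditions (500 training positives, strong planted motif)
## used by the acceptance checks.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

small_study <- function() {
  memo("small_study", function() {
    dir <- file.path(tempdir(), "gkmvar_small_study")
    st <- simulate_study(
      synthetic_study_config(n_peaks = 150, n_train = 100,
                             n_associations = 100, seed = 3),
      out_dir = dir)
    st
  })
}

small_model <- function() {
  memo("small_model", function() {
    st <- small_study()
    top <- select_top_peaks(st$peaks$peaks, 100)
    pos <- extract_sequences(st$genome, top)
    neg <- extract_sequences(st$genome,
                             generate_null_set(st$genome, top, seed = 3))
    train_gkm_svm(training_set(pos, neg))
  })
}

small_table <- function() {
  memo("small_table", function() build_kmer_weight_table(small_model()))
}

full_study <- function() {
  memo("full_study", function() {
    dir <- file.path(tempdir(), "gkmvar_full_study")
    simulate_study(synthetic_study_config(seed = 101), out_dir = dir)
  })
}

full_training_set <- function() {
  memo("full_training_set", function() {
    st <- full_study()
    top <- select_top_peaks(st$peaks$peaks, st$config$n_train)
    pos <- extract_sequences(st$genome, top)
    neg <- extract_sequences(st$genome,
                             generate_null_set(st$genome, top, seed = 101))
    training_set(pos, neg)
  })
}

full_cv <- function() {
  memo("full_cv", function() cross_validate(full_training_set(),
                                            gkm_config(), seed = 101))
}

full_model <- function() {
  memo("full_model", function() train_gkm_svm(full_training_set()))
}

full_table <- function() {
  memo("full_table", function() build_kmer_weight_table(full_model()))
}

random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = "")
  }, character(1))
}

## independent inner product of two named feature-count vectors
feature_dot <- function(a, b) {
  ks <- intersect(names(a), names(b))
  sum(as.numeric(a[ks]) * as.numeric(b[ks]))
}
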