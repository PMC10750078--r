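## a compact, clearly separable planted-motif training set
toy_training_set <- function(n = 40, len = 60, seed = 5) {
  withr::with_seed(seed, {
    motif <- "TTAAGTGG"
    pos <- vapply(seq_len(n), function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
      off <- sample(len - nchar(motif), 1)
      substr(s, off + 1, off + nchar(motif)) <- motif
      s
    }, character(1))
    neg <- random_dna(n, len)
  })
  training_set(setNames(pos, sprintf("p%03d", seq_len(n))),
               setNames(neg, sprintf("n%03d", seq_len(n))))
}

test_that("SVM separates planted-motif positives from random negatives", {
  ts <- toy_training_set()
  m <- train_gkm_svm(ts)
  dec <- decision_values(m, c(ts$positives$sequence, ts$negatives$sequence))
  y <- c(rep(1, nrow(ts$positives)), rep(-1, nrow(ts$negatives)))
  expect_gte(mean(sign(dec) == y), 0.99)
  expect_true(all(abs(m$dual_coefficients) <= m$config$C + 1e-6))
})

test_that("decision values are exactly strand-invariant", {
  m <- small_model()
  set.seed(3)
  seqs <- random_dna(10, 50)
  expect_identical(decision_values(m, seqs), decision_values(m, revcomp(seqs)))
  expect_error(decision_values(m, "ACGT"), "shorter")
})

test_that("duplicating the training data leaves the decision function stable", {
  ts <- toy_training_set(n = 30)
  m1 <- train_gkm_svm(ts)
  ts2 <- training_set(
    rbind(ts$positives, ts$positives[, .(id = paste0(id, "b"), sequence)]),
    rbind(ts$negatives, ts$negatives[, .(id = paste0(id, "b"), sequence)]))
  m2 <- train_gkm_svm(ts2)
  set.seed(9)
  probe <- random_dna(20, 60)
  expect_lt(max(abs(decision_values(m1, probe) - decision_values(m2, probe))),
            0.05)
})

test_that("flipping the class labels negates the decision function", {
  ts <- toy_training_set(n = 30)
  m1 <- train_gkm_svm(ts)
  flipped <- training_set(ts$negatives, ts$positives)
  m2 <- train_gkm_svm(flipped)
  set.seed(10)
  probe <- random_dna(20, 60)
  expect_lt(max(abs(decision_values(m1, probe) + decision_values(m2, probe))),
            0.05)
})

test_that("AUROC and AUPRC behave at the extremes and under the null", {
  labels <- c(rep(TRUE, 5), rep(FALSE, 5))
  perfect <- c(6:10, 1:5)
  expect_equal(auroc(labels, perfect), 1)
  expect_equal(auprc(labels, perfect), 1)
  expect_equal(auroc(labels, -perfect), 0)
  set.seed(123)
  lab <- rep(c(TRUE, FALSE), each = 1000)
  sc <- rnorm(2000)
  expect_lt(abs(auroc(lab, sc) - 0.5), 0.04)
  ## tie-awareness: constant scores give exactly 0.5
  expect_equal(auroc(lab, rep(1, 2000)), 0.5)
})

test_that("in-package metrics agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  lab <- runif(300) < 0.4
  sc <- rnorm(300) + lab
  ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(lab, sc), ref, tolerance = 1e-12)
})

test_that("cross-validation is stratified, order-invariant and errors on degenerate folds", {
  ts <- toy_training_set(n = 30)
  cv1 <- cross_validate(ts, gkm_config(cv_folds = 3), seed = 2)
  expect_true(all(cv1$per_fold$auroc >= 0 & cv1$per_fold$auroc <= 1))
  ## shuffle inputs: fold assignment hashes ids, so metrics are identical
  perm_p <- sample(nrow(ts$positives)); perm_n <- sample(nrow(ts$negatives))
  ts_shuf <- training_set(ts$positives[perm_p], ts$negatives[perm_n])
  cv2 <- cross_validate(ts_shuf, gkm_config(cv_folds = 3), seed = 2)
  expect_equal(cv2$mean_auroc, cv1$mean_auroc, tolerance = 1e-12)
  expect_equal(cv2$mean_auprc, cv1$mean_auprc, tolerance = 1e-12)
  tiny <- training_set(ts$positives[1:2], ts$negatives[1:8])
  expect_error(cross_validate(tiny, gkm_config(cv_folds = 5), seed = 1),
               "single class|fewer folds")
})

test_that("model serialization round-trips", {
  m <- small_model()
  prefix <- file.path(tempdir(), "model_rt")
  write_gkm_model(m, prefix)
  m2 <- read_gkm_model(prefix)
  set.seed(4)
  probe <- random_dna(5, 40)
  expect_equal(decision_values(m2, probe), decision_values(m, probe),
               tolerance = 1e-12)
})

test_that("model configuration validates its invariants", {
  expect_error(gkm_config(l = 11, k = 12), "k")
  expect_error(gkm_config(l = 11, k = 7, d = 5), "d")
  expect_error(gkm_config(C = 0), "positive")
  expect_error(gkm_config(cv_folds = 1), "folds")
})
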