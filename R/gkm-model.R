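#' Gapped k-mer SVM model configuration
#'
#' Defaults mirror the standard training recipe for transcription-factor
#' ChIP-seq sequence classifiers: word length 11 with 7 informative
#' positions, box constraint `C = 1`, stopping tolerance 0.005 and 5-fold
#' cross-validation.  `kernel_variant = "exact_gkm"` computes the full
#' mismatch-weighted kernel; `"truncated_gkm"` zeroes window-pair
#' contributions beyond `max_mismatch` mismatches (a speed knob; at desk
#' scale the exact kernel is the reference).
#'
#' @param l word length
#' @param k informative positions (`0 < k <= l`)
#' @param d maximum mismatches for the truncated kernel (`d <= l - k`)
#' @param C soft-margin box constraint (> 0)
#' @param eps solver stopping tolerance (> 0)
#' @param cv_folds cross-validation folds (>= 2)
#' @param kernel_variant `"exact_gkm"` or `"truncated_gkm"`
#' @return object of class `gkm_config`
#' @export
gkm_config <- function(l = 11, k = 7, d = 3, C = 1, eps = 0.005,
                       cv_folds = 5,
                       kernel_variant = c("exact_gkm", "truncated_gkm")) {
  kernel_variant <- match.arg(kernel_variant)
  if (k <= 0 || k > l) stop("need 0 < k <= l")
  if (d > l - k) stop("need d <= l - k")
  if (C <= 0 || eps <= 0) stop("C and eps must be positive")
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  structure(list(l = l, k = k, d = d, C = C, eps = eps,
                 cv_folds = cv_folds, kernel_variant = kernel_variant),
            class = "gkm_config")
}

#' Assemble a training set
#' @param positives,negatives data.tables with `id`, `sequence` columns (as
#'   returned by [extract_sequences()]) or named character vectors
#' @return object of class `gkm_training_set`
#' @export
training_set <- function(positives, negatives) {
  norm <- function(x, prefix) {
    if (is.character(x)) {
      ids <- names(x) %||% sprintf("%s_%04d", prefix, seq_along(x))
      x <- data.table(id = ids, sequence = unname(x))
    }
    x <- as.data.table(x)[, .(id, sequence)]
    assert_dna(x$sequence, prefix)
    x
  }
  pos <- norm(positives, "pos")
  neg <- norm(negatives, "neg")
  if (nrow(pos) == 0 || nrow(neg) == 0)
    stop("both classes must be nonempty")
  structure(list(positives = pos, negatives = neg),
            class = "gkm_training_set")
}

#' @noRd
ts_sequences <- function(ts) c(ts$positives$sequence, ts$negatives$sequence)
#' @noRd
ts_ids <- function(ts) c(ts$positives$id, ts$negatives$id)
#' @noRd
ts_labels <- function(ts) {
  c(rep(1L, nrow(ts$positives)), rep(-1L, nrow(ts$negatives)))
}

## solve the soft-margin dual on a precomputed normalized kernel; returns
## support indices (into K's rows), coefficients a_i * y_i, and bias such
## that f(x) = sum_i coef_i * K(x, sv_i) + bias
#' @noRd
solve_svm_dual <- function(K, y, C, eps) {
  yf <- factor(ifelse(y > 0, "pos", "neg"), levels = c("pos", "neg"))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), yf, type = "C-svc",
                       C = C, tol = eps, scaled = FALSE)
  sv <- kernlab::SVindex(fit)
  coefs <- kernlab::coef(fit)[[1]]
  bias <- -kernlab::b(fit)
  ## normalize orientation: positives must score higher than negatives
  dec <- as.numeric(K[, sv, drop = FALSE] %*% coefs + bias)
  if (mean(dec[y > 0]) < mean(dec[y < 0])) {
    coefs <- -coefs
    bias <- -bias
  }
  list(sv_index = sv, coefficients = coefs, bias = bias)
}

#' Train a gapped k-mer SVM
#'
#' Computes the normalized gkm kernel matrix over the training sequences
#' and solves the soft-margin SVM dual (box constraint `C`, stopping
#' tolerance `eps`).  The decision function is
#' `f(x) = sum_i a_i y_i K(s_i, x) + b` over the support sequences.
#'
#' @param ts a [training_set()]
#' @param config a [gkm_config()]
#' @param kernel optional precomputed normalized kernel matrix over
#'   `c(positives, negatives)` (in that order), to avoid recomputation
#' @return object of class `gkm_model` with fields `config`,
#'   `support_sequences`, `support_ids`, `dual_coefficients` (a_i y_i),
#'   `bias`, `n_train`
#' @export
train_gkm_svm <- function(ts, config = gkm_config(), kernel = NULL) {
  stopifnot(inherits(ts, "gkm_training_set"), inherits(config, "gkm_config"))
  seqs <- ts_sequences(ts)
  y <- ts_labels(ts)
  K <- kernel %||% gkm_kernel_matrix(seqs, l = config$l, k = config$k)
  sol <- solve_svm_dual(K, y, config$C, config$eps)
  structure(list(
    config = config,
    support_sequences = seqs[sol$sv_index],
    support_ids = ts_ids(ts)[sol$sv_index],
    support_labels = y[sol$sv_index],
    dual_coefficients = sol$coefficients,
    bias = sol$bias,
    n_train = length(seqs)
  ), class = "gkm_model")
}

#' @export
print.gkm_model <- function(x, ...) {
  cat(sprintf(
    "gkm SVM model: l=%d k=%d C=%g eps=%g | %d support sequences of %d training\n",
    x$config$l, x$config$k, x$config$C, x$config$eps,
    length(x$support_sequences), x$n_train))
  invisible(x)
}

#' SVM decision values for new sequences
#' @param model a `gkm_model`
#' @param seqs character vector of sequences (each of length >= `l`)
#' @return numeric vector of decision values (positive predicts binding)
#' @export
decision_values <- function(model, seqs) {
  if (any(nchar(seqs) < model$config$l))
    stop("sequence(s) shorter than word length l = ", model$config$l)
  K <- gkm_kernel_matrix(seqs, model$support_sequences,
                         l = model$config$l, k = model$config$k)
  as.numeric(K %*% model$dual_coefficients + model$bias)
}

#' Tie-aware AUROC by the rank statistic
#' @param labels logical or 0/1 vector (TRUE/1 = positive)
#' @param scores numeric scores
#' @return area under the ROC curve in `[0, 1]`
#' @export
auroc <- function(labels, scores) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("need both classes to compute AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' AUPRC by step-interpolated precision-recall integration
#'
#' Processes distinct score thresholds in descending order (tie groups as
#' blocks, so the value is invariant to input order) and accumulates
#' `sum (R_i - R_{i-1}) * P_i`.
#'
#' @param labels logical or 0/1 vector (TRUE/1 = positive)
#' @param scores numeric scores
#' @return area under the precision-recall curve in `[0, 1]`
#' @export
auprc <- function(labels, scores) {
  labels <- as.logical(labels)
  np <- sum(labels)
  if (np == 0) stop("need at least one positive to compute AUPRC")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp_cum <- cumsum(vapply(thr, function(t) sum(labels[scores == t]), numeric(1)))
  n_cum <- cumsum(vapply(thr, function(t) sum(scores == t), numeric(1)))
  prec <- tp_cum / n_cum
  rec <- tp_cum / np
  sum(diff(c(0, rec)) * prec)
}

#' @noRd
assign_folds <- function(ids, labels, folds, seed) {
  fold <- integer(length(ids))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    h <- stable_hash(paste0(seed, ":", ids[idx]))
    o <- order(h, ids[idx])
    fold[idx[o]] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Stratified cross-validation of the gapped k-mer SVM
#'
#' Folds are assigned by a stable hash of sequence id (stratified within
#' class), so fold membership — and therefore every reported metric — is
#' independent of input row order.  Each sequence is scored exactly once by
#' a model whose training fold excluded it.
#'
#' @param ts a [training_set()]
#' @param config a [gkm_config()] (`cv_folds` controls the fold count)
#' @param seed integer seed entering the fold-assignment hash
#' @return object of class `gkm_cv_report`: per-fold AUROC/AUPRC, their
#'   means, fold assignments, and the out-of-fold decision values
#' @export
cross_validate <- function(ts, config = gkm_config(), seed = 1) {
  stopifnot(inherits(ts, "gkm_training_set"))
  seqs <- ts_sequences(ts)
  ids <- ts_ids(ts)
  y <- ts_labels(ts)
  fold <- assign_folds(ids, y, config$cv_folds, seed)
  for (f in seq_len(config$cv_folds)) {
    if (length(unique(y[fold == f])) < 2)
      stop("fold ", f, " contains a single class; use fewer folds")
  }
  K <- gkm_kernel_matrix(seqs, l = config$l, k = config$k)
  dec <- numeric(length(seqs))
  per_fold <- vector("list", config$cv_folds)
  for (f in seq_len(config$cv_folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    sol <- solve_svm_dual(K[tr, tr, drop = FALSE], y[tr], config$C, config$eps)
    dec[te] <- as.numeric(
      K[te, tr[sol$sv_index], drop = FALSE] %*% sol$coefficients + sol$bias)
    per_fold[[f]] <- data.table(
      fold = f,
      auroc = auroc(y[te] > 0, dec[te]),
      auprc = auprc(y[te] > 0, dec[te]))
  }
  per_fold <- rbindlist(per_fold)
  structure(list(
    per_fold = per_fold,
    mean_auroc = mean(per_fold$auroc),
    mean_auprc = mean(per_fold$auprc),
    fold = fold, ids = ids, labels = y, decision = dec, seed = seed
  ), class = "gkm_cv_report")
}

#' @export
print.gkm_cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV: mean AUROC = %.3f, mean AUPRC = %.3f\n",
              nrow(x$per_fold), x$mean_auroc, x$mean_auprc))
  invisible(x)
}

#' Serialize a trained model
#'
#' Written as a JSON header (config, bias, labels), a TSV of support ids
#' and dual coefficients, and a FASTA of support sequences.
#'
#' @param model a `gkm_model`
#' @param prefix path prefix; creates `<prefix>.json`, `<prefix>.tsv`,
#'   `<prefix>.fa`
#' @return `prefix`, invisibly
#' @export
write_gkm_model <- function(model, prefix) {
  jsonlite::write_json(
    list(config = unclass(model$config), bias = model$bias,
         n_train = model$n_train),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  fwrite(data.table(id = model$support_ids,
                    label = model$support_labels,
                    coefficient = model$dual_coefficients),
         paste0(prefix, ".tsv"), sep = "\t")
  sv <- Biostrings::DNAStringSet(setNames(model$support_sequences,
                                          model$support_ids))
  Biostrings::writeXStringSet(sv, paste0(prefix, ".fa"))
  invisible(prefix)
}

#' Read a serialized model
#' @param prefix path prefix used by [write_gkm_model()]
#' @return a `gkm_model`
#' @export
read_gkm_model <- function(prefix) {
  hdr <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  tab <- fread(paste0(prefix, ".tsv"))
  sv <- Biostrings::readDNAStringSet(paste0(prefix, ".fa"))
  cfg <- do.call(gkm_config, hdr$config[c("l", "k", "d", "C", "eps",
                                          "cv_folds", "kernel_variant")])
  structure(list(config = cfg,
                 support_sequences = as.character(sv),
                 support_ids = tab$id,
                 support_labels = tab$label,
                 dual_coefficients = tab$coefficient,
                 bias = hdr$bias,
                 n_train = hdr$n_train), class = "gkm_model")
}
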