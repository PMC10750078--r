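#' deltaSVM score of a single variant
#'
#' Extracts the `(2l - 1)` bp window centered on the variant, scores the
#' reference window as the sliding sum of canonical k-mer weights over its
#' `l` windows, substitutes the center base with the alternate allele,
#' rescores, and reports `delta = alt_score - ref_score`.  The genome base
#' at the variant position must equal the stated reference allele — a guard
#' against coordinate convention bugs.
#'
#' @param table a `kmer_weight_table`
#' @param genome `synthetic_genome` or `DNAStringSet`
#' @param variant one-row data.table (or list) with `rsid`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`
#' @return object of class `delta_svm_result`: list with `rsid`,
#'   `ref_score`, `alt_score`, `delta`, `window_ref`, `window_alt`
#' @export
delta_svm <- function(table, genome, variant) {
  l <- table$l
  seqs <- genome_seqs(genome)
  ch <- as.character(variant$chrom)
  if (!ch %in% names(seqs)) stop("chromosome not in genome: ", ch)
  len <- Biostrings::width(seqs[names(seqs) == ch])
  pos <- as.integer(variant$pos)
  if (pos - (l - 1) < 1 || pos + (l - 1) > len)
    stop(sprintf("variant %s within %d bp of a chromosome edge: insufficient context",
                 variant$rsid, l - 1))
  win <- toupper(as.character(
    Biostrings::subseq(seqs[[ch]], pos - (l - 1), pos + (l - 1))))
  center <- l
  if (substr(win, center, center) != variant$ref)
    stop(sprintf("reference mismatch for %s at %s:%d (genome %s, stated %s)",
                 variant$rsid, ch, pos, substr(win, center, center),
                 variant$ref))
  alt_win <- win
  substr(alt_win, center, center) <- variant$alt
  ref_score <- cpp_sliding_scan(win, table$weights, l)$sum
  alt_score <- cpp_sliding_scan(alt_win, table$weights, l)$sum
  structure(list(rsid = variant$rsid, ref_score = ref_score,
                 alt_score = alt_score, delta = alt_score - ref_score,
                 window_ref = win, window_alt = alt_win),
            class = "delta_svm_result")
}

#' deltaSVM scores for a batch of variants
#'
#' One result per scorable variant; variants that cannot be scored (edge
#' proximity, reference mismatch, unknown chromosome) are reported with
#' reasons rather than erroring the batch.
#'
#' @param table a `kmer_weight_table`
#' @param genome `synthetic_genome` or `DNAStringSet`
#' @param variants data.table with `rsid`, `chrom`, `pos`, `ref`, `alt`
#' @return list with `scores` (data.table: `rsid`, `ref_score`,
#'   `alt_score`, `delta`), `skipped` (data.table: `rsid`, `reason`) and
#'   `summary` (mean, sd, quantiles of delta)
#' @export
delta_svm_batch <- function(table, genome, variants) {
  variants <- as.data.table(variants)
  rows <- vector("list", nrow(variants))
  skipped <- list()
  for (i in seq_len(nrow(variants))) {
    res <- tryCatch(delta_svm(table, genome, variants[i]),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped[[length(skipped) + 1L]] <-
        data.table(rsid = variants$rsid[i], reason = res)
    } else {
      rows[[i]] <- data.table(rsid = res$rsid, ref_score = res$ref_score,
                              alt_score = res$alt_score, delta = res$delta)
    }
  }
  scores <- rbindlist(rows[!vapply(rows, is.null, logical(1))])
  skipped <- if (length(skipped)) rbindlist(skipped) else
    data.table(rsid = character(), reason = character())
  summary <- if (nrow(scores)) {
    c(mean = mean(scores$delta), sd = sd(scores$delta),
      quantile(scores$delta, c(0.01, 0.25, 0.5, 0.75, 0.99)))
  } else numeric(0)
  list(scores = scores, skipped = skipped, summary = summary)
}

#' Prioritize variants by predicted binding change and cardiac eQTL support
#'
#' A candidate must carry at least one cardiac-tissue eQTL pair AND pass
#' the delta criterion for at least one TF model.  Under
#' `selection = "abs_delta_threshold"` the criterion is
#' `|delta| >= threshold` (default: the 99th percentile of the pooled
#' |delta| distribution); under `"top_k"` the `k` eQTL-supported variants
#' with the largest max |delta| are taken.  Ranking is by max |delta|
#' across models, descending, ties broken by rsid; ranks are contiguous
#' from 1.
#'
#' @param delta_results named list (one entry per TF model) of
#'   [delta_svm_batch()] outputs
#' @param eqtl_pairs data.table from [join_eqtl()]
#' @param selection `"abs_delta_threshold"` or `"top_k"`
#' @param k number of variants in `top_k` mode
#' @param threshold |delta| cutoff in threshold mode (NULL: pooled 99th
#'   percentile)
#' @return data.table: `rank`, `rsid`, `max_abs_delta`, `best_tf`,
#'   per-model delta columns, `n_eqtl_pairs`, `eqtl_genes`,
#'   `large_delta`, `heart_eqtl`
#' @export
prioritize <- function(delta_results, eqtl_pairs,
                       selection = c("abs_delta_threshold", "top_k"),
                       k = 5, threshold = NULL) {
  selection <- match.arg(selection)
  if (is.null(names(delta_results)))
    names(delta_results) <- paste0("model", seq_along(delta_results))
  all_scores <- rbindlist(lapply(names(delta_results), function(tf) {
    s <- delta_results[[tf]]$scores
    data.table(tf = tf, rsid = s$rsid, delta = s$delta)
  }))
  if (nrow(eqtl_pairs) == 0) {
    warning("no eQTL pairs supplied; prioritization list is empty")
    return(data.table(rank = integer(), rsid = character(),
                      max_abs_delta = numeric(), best_tf = character()))
  }
  per_var <- all_scores[, .(max_abs_delta = max(abs(delta)),
                            best_tf = tf[which.max(abs(delta))]),
                        by = rsid]
  wide <- data.table::dcast(all_scores, rsid ~ tf, value.var = "delta")
  setnames_delta <- paste0("delta_", setdiff(names(wide), "rsid"))
  data.table::setnames(wide, setdiff(names(wide), "rsid"), setnames_delta)
  eqtl_summary <- as.data.table(eqtl_pairs)[, .(
    n_eqtl_pairs = .N,
    eqtl_genes = paste(sort(unique(gene_id)), collapse = ",")),
    by = .(rsid = variant_rsid)]
  cand <- merge(per_var, eqtl_summary, by = "rsid")  # eQTL support required
  cand <- merge(cand, wide, by = "rsid")
  if (selection == "abs_delta_threshold") {
    if (is.null(threshold))
      threshold <- quantile(abs(all_scores$delta), 0.99, names = FALSE)
    cand <- cand[max_abs_delta >= threshold]
  }
  setorder(cand, -max_abs_delta, rsid)
  if (selection == "top_k") cand <- head(cand, k)
  cand[, `:=`(rank = seq_len(.N), large_delta = TRUE, heart_eqtl = TRUE)]
  data.table::setcolorder(cand, c("rank", "rsid", "max_abs_delta", "best_tf"))
  cand[]
}
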