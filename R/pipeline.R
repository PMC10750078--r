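#' Run the full prioritization pipeline on a study directory
#'
#' Reads every input through the package's own readers, runs the variant
#' catalog (trait filter, SNV filter, regulatory intersection, LD
#' expansion, cardiac eQTL join), trains the gapped k-mer SVM on the
#' top-signal peaks against GC/chromosome-matched null sequences, builds
#' the exhaustive k-mer weight table, computes deltaSVM scores for the
#' expanded variant set, and prioritizes candidates that combine a large
#' predicted binding change with cardiac eQTL support.
#'
#' @param dir directory written by [simulate_study()] (or any directory
#'   with the same file layout)
#' @param n_train positives for model training
#' @param model_config a [gkm_config()]
#' @param catalog_cfg a [catalog_config()]
#' @param top_k number of prioritized variants returned
#' @param seed seed for null-set sampling
#' @return list with `catalog`, `model`, `weight_table`, `delta`,
#'   `prioritized`
#' @export
run_study <- function(dir, n_train = 500, model_config = gkm_config(),
                      catalog_cfg = catalog_config(), top_k = 5, seed = 1) {
  genome <- read_genome_fasta(file.path(dir, "genome.fa"))
  peaks <- read_bed(file.path(dir, "peaks.bed"))
  enhancers <- read_bed(file.path(dir, "enhancers.bed"))
  footprints <- read_bed(file.path(dir, "footprints.bed"))

  catalog <- run_catalog(file.path(dir, "gwas_catalog.tsv"),
                         enhancers, footprints,
                         file.path(dir, "ld_pairs.tsv"),
                         file.path(dir, "eqtl_pairs.tsv"),
                         catalog_cfg)

  top <- select_top_peaks(peaks, n_train)
  pos <- extract_sequences(genome, top)
  neg_gr <- generate_null_set(genome, top, seed = seed)
  neg <- extract_sequences(genome, neg_gr)
  ts <- training_set(pos, neg)
  model <- train_gkm_svm(ts, model_config)
  table <- build_kmer_weight_table(model)

  delta <- delta_svm_batch(table, genome, catalog$expanded$variants)
  prioritized <- prioritize(list(model1 = delta), catalog$eqtl_pairs,
                            selection = "top_k", k = top_k)
  list(catalog = catalog, model = model, weight_table = table,
       delta = delta, prioritized = prioritized)
}
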