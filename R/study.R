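#' Synthetic study configuration
#'
#' Defines the complete synthetic study: a two-chromosome genome, a
#' motif-planted peak set for model training, a GWAS-catalog table with
#' cardiovascular and non-cardiovascular traits plus indels and malformed
#' rows, anchored enhancer/footprint tracks, a block-structured LD table,
#' tissue-labeled eQTLs, and EMSA series for one prioritized variant.
#' Five planted variants sit at the centers of strong motif instances
#' inside footprint-in-enhancer anchors and carry cardiac eQTLs — the
#' ground-truth answer the end-to-end pipeline must recover.
#'
#' @param n_chromosomes,chromosome_length,gc_content genome shape
#' @param n_peaks,peak_length,motif_strength peak set and planted motif
#' @param n_train positives used for model training (top peaks by signal)
#' @param n_associations GWAS rows
#' @param fraction_cvd,fraction_indel,fraction_malformed GWAS class mix
#' @param n_planted planted large-delta + cardiac-eQTL variants
#' @param n_background_regulatory background variants inside both tracks
#' @param n_background_eqtl background regulatory variants also given a
#'   cardiac eQTL (small delta — tests the conjunction rule)
#' @param n_proxy_eqtl LD proxies given a cardiac eQTL
#' @param n_extra_enhancers unanchored enhancers beyond the anchors
#' @param enhancer_length,dgfs_per_enhancer,dgf_length,orphan_dgf_fraction
#'   track shape
#' @param populations,ld_block_size,r2_decay,n_linked_per_lead LD table
#' @param n_genes,eqtl_tissues,p_threshold eQTL table
#' @param emsa_kd_ref,emsa_kd_alt,emsa_noise_sd,emsa_replicates EMSA series
#' @param seed global seed fanned out to every generator
#' @return object of class `study_config`
#' @export
synthetic_study_config <- function(
    n_chromosomes = 2, chromosome_length = 3e5, gc_content = 0.41,
    n_peaks = 550, peak_length = 100, motif_strength = 0.95,
    n_train = 500,
    n_associations = 200, fraction_cvd = 0.6, fraction_indel = 0.1,
    fraction_malformed = 0.1,
    n_planted = 5, n_background_regulatory = 15,
    n_background_eqtl = 4, n_proxy_eqtl = 2,
    n_extra_enhancers = 3,
    enhancer_length = 1000, dgfs_per_enhancer = 3, dgf_length = 20,
    orphan_dgf_fraction = 0.25,
    populations = default_populations(), ld_block_size = 5e4,
    r2_decay = 2e-4, n_linked_per_lead = 3,
    n_genes = 40, eqtl_tissues = default_tissues(), p_threshold = 0.1,
    emsa_kd_ref = 200, emsa_kd_alt = 800, emsa_noise_sd = 0.02,
    emsa_replicates = 3,
    seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_planted + cfg$n_background_regulatory +
              round(cfg$n_associations * (cfg$fraction_indel + cfg$fraction_malformed)) <
              cfg$n_associations)
  structure(cfg, class = "study_config")
}

#' @noRd
motif_center_info <- function(motif) {
  pwm <- motif$pwm
  center <- ceiling(nrow(pwm) / 2)
  bases <- c("A", "C", "G", "T")
  consensus <- bases[apply(pwm, 1, which.max)]
  worst <- bases[apply(pwm, 1, which.min)]
  list(center = center, consensus_base = consensus[center],
       worst_base = worst[center])
}

#' @noRd
complement_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

## pick planted-variant sites: strong planted instances whose center base
## matches the motif consensus, pairwise separated enough for anchored
## enhancers, away from chromosome edges
#' @noRd
choose_planted_sites <- function(peak_truth, motif, n_planted,
                                 min_separation, chrom_lengths, margin) {
  info <- motif_center_info(motif)
  L <- nrow(motif$pwm)
  cand <- peak_truth[peak_truth$planted &
                       substr(peak_truth$instance, info$center, info$center) ==
                       info$consensus_base]
  cand <- cand[order(-cand$logodds)]
  chosen <- list()
  for (i in seq_len(nrow(cand))) {
    row <- cand[i]
    motif_start <- row$start0 + row$offset + 1L  # 1-based genome start
    pos <- if (row$strand == "+") motif_start + info$center - 1L else
      motif_start + (L - info$center)
    if (pos < margin || pos > chrom_lengths[[row$chrom]] - margin) next
    too_close <- any(vapply(chosen, function(cc) {
      cc$chrom == row$chrom && abs(cc$pos - pos) < min_separation
    }, logical(1)))
    if (too_close) next
    ref <- if (row$strand == "+") info$consensus_base else
      complement_base(info$consensus_base)
    alt <- if (row$strand == "+") info$worst_base else
      complement_base(info$worst_base)
    chosen[[length(chosen) + 1L]] <- data.table(
      chrom = row$chrom, pos = as.integer(pos), ref = unname(ref),
      alt = unname(alt), peak_id = row$peak_id, logodds = row$logodds)
    if (length(chosen) == n_planted) break
  }
  if (length(chosen) < n_planted)
    stop("could not place ", n_planted, " planted variants; ",
         "increase n_peaks or genome size")
  rbindlist(chosen)
}

## deterministic positions away from given intervals and from each other
#' @noRd
sample_clear_positions <- function(n, chrom_lengths, avoid, min_gap,
                                   margin, rng_tag, seed) {
  out <- data.table(chrom = character(), pos = integer())
  withr::with_seed(fan_seed(seed, rng_tag), {
    guard <- 0L
    while (nrow(out) < n && guard < 50000L) {
      guard <- guard + 1L
      ch <- sample(names(chrom_lengths), 1)
      pos <- sample(seq(margin, chrom_lengths[[ch]] - margin), 1)
      cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(pos, pos))
      if (!is.null(avoid) && any(IRanges::overlapsAny(cand, avoid))) next
      if (nrow(out) && any(out$chrom == ch & abs(out$pos - pos) < min_gap)) next
      out <- rbind(out, data.table(chrom = ch, pos = as.integer(pos)))
    }
  })
  if (nrow(out) < n) stop("could not place ", n, " clear positions")
  out
}

#' Generate the full synthetic study
#'
#' Runs every generator with subseeds fanned out from the global seed,
#' writes all pipeline inputs to `out_dir` (FASTA genome, BED peaks and
#' tracks, GWAS/LD/eQTL TSVs, EMSA CSVs) together with a ground-truth
#' sidecar `truth.json`, and returns the in-memory objects.  The sidecar
#' records, by construction rather than by running the pipeline, the exact
#' number of records that must survive each catalog stage, the planted
#' variant rsids, and the planted eQTL pairs.
#'
#' @param config a [synthetic_study_config()]
#' @param out_dir output directory (created if needed); NULL to skip
#'   writing
#' @return list with `genome`, `peaks`, `tracks`, `gwas`, `ld`, `eqtl`,
#'   `emsa`, `planted`, `truth`, `paths`
#' @export
simulate_study <- function(config = synthetic_study_config(), out_dir = NULL) {
  cfg <- config
  seed <- cfg$seed
  motif <- default_motif(cfg$motif_strength, planting_probability = 1)
  L <- nrow(motif$pwm)
  genome0 <- generate_genome(cfg$n_chromosomes, cfg$chromosome_length,
                             cfg$gc_content, seed)
  pk <- generate_peaks(genome0, motif, cfg$n_peaks, cfg$peak_length, seed)
  genome <- pk$genome
  lens <- setNames(Biostrings::width(genome$sequences),
                   names(genome$sequences))
  margin <- cfg$enhancer_length %/% 2 + 50L

  planted <- choose_planted_sites(pk$truth, motif, cfg$n_planted,
                                  min_separation = cfg$enhancer_length + 10L,
                                  chrom_lengths = lens, margin = margin)
  peak_gr <- GenomicRanges::granges(pk$peaks)
  bg_reg <- sample_clear_positions(
    cfg$n_background_regulatory, lens,
    avoid = suppressWarnings(c(
      peak_gr,
      GenomicRanges::GRanges(planted$chrom,
                             IRanges::IRanges(planted$pos - cfg$enhancer_length,
                                              planted$pos + cfg$enhancer_length)))),
    min_gap = cfg$enhancer_length + 10L, margin = margin,
    rng_tag = "bg_regulatory", seed = seed)

  anchors <- rbind(planted[, .(chrom, pos)], bg_reg)
  n_anchor <- nrow(anchors)
  tracks <- generate_regulatory_tracks(
    genome, n_enhancers = n_anchor + cfg$n_extra_enhancers,
    enhancer_length = cfg$enhancer_length,
    dgfs_per_enhancer = cfg$dgfs_per_enhancer,
    dgf_length = cfg$dgf_length,
    orphan_dgf_fraction = cfg$orphan_dgf_fraction,
    seed = seed, anchors = anchors)

  ## remaining GWAS rows live outside every track
  n_forced <- cfg$n_planted + cfg$n_background_regulatory
  n_rest <- cfg$n_associations - n_forced
  track_gr <- suppressWarnings(c(GenomicRanges::granges(tracks$enhancers),
                                 GenomicRanges::granges(tracks$footprints)))
  rest <- sample_clear_positions(n_rest, lens, avoid = track_gr,
                                 min_gap = 1L, margin = 50L,
                                 rng_tag = "gwas_rest", seed = seed)
  n_cvd_total <- round(cfg$fraction_cvd * cfg$n_associations)
  n_ind <- round(cfg$fraction_indel * cfg$n_associations)
  n_mal <- round(cfg$fraction_malformed * cfg$n_associations)
  n_cvd_rest <- n_cvd_total - n_forced
  if (n_cvd_rest < 0) stop("fraction_cvd too small for the forced variants")
  if (n_ind + n_mal + n_cvd_rest > n_rest)
    stop("class fractions exceed the unforced row budget")
  rest_flags <- withr::with_seed(fan_seed(seed, "gwas_classes"), {
    idx <- sample(n_rest)
    data.table(indel = seq_len(n_rest) %in% idx[seq_len(n_ind)],
               malformed = seq_len(n_rest) %in% idx[n_ind + seq_len(n_mal)],
               cvd = seq_len(n_rest) %in% sample(n_rest, n_cvd_rest))
  })
  plan <- rbind(
    data.table(chrom = planted$chrom, pos = planted$pos, cvd = TRUE,
               indel = FALSE, malformed = FALSE, alt = planted$alt),
    data.table(chrom = bg_reg$chrom, pos = bg_reg$pos, cvd = TRUE,
               indel = FALSE, malformed = FALSE, alt = NA_character_),
    data.table(chrom = rest$chrom, pos = rest$pos, cvd = rest_flags$cvd,
               indel = rest_flags$indel, malformed = rest_flags$malformed,
               alt = NA_character_))
  plan[, rsid := sprintf("rs%07d", seq_len(.N))]
  gw <- generate_gwas_catalog(genome, seed = seed, plan = plan)
  planted[, rsid := plan$rsid[seq_len(cfg$n_planted)]]
  bg_rsids <- plan$rsid[cfg$n_planted + seq_len(cfg$n_background_regulatory)]

  ## LD over the variants that survive the regulatory intersection
  leads <- gw$truth[rsid %in% c(planted$rsid, bg_rsids),
                    .(rsid, chrom, pos)]
  motif_gr <- with(pk$truth[pk$truth$planted],
                   GenomicRanges::GRanges(chrom,
                                          IRanges::IRanges(start0 + offset + 1L - 10L,
                                                           start0 + offset + L + 10L)))
  ldres <- generate_ld_table(genome, leads, cfg$populations,
                             cfg$ld_block_size, cfg$r2_decay,
                             cfg$n_linked_per_lead, seed, avoid = motif_gr)

  ## cardiac eQTLs: all planted variants, some background, some proxies
  expanded <- data.table(rsid = ldres$truth$expanded_rsids)
  proxy_pool <- setdiff(ldres$truth$expanded_rsids, leads$rsid)
  forced_eqtl <- withr::with_seed(fan_seed(seed, "eqtl_pick"), {
    c(planted$rsid,
      sample(bg_rsids, min(cfg$n_background_eqtl, length(bg_rsids))),
      sample(proxy_pool, min(cfg$n_proxy_eqtl, length(proxy_pool))))
  })
  eq <- generate_eqtl_table(expanded, n_genes = cfg$n_genes,
                            tissues = cfg$eqtl_tissues,
                            p_threshold = cfg$p_threshold, seed = seed,
                            significant_variants = forced_eqtl)

  emsa_ref <- generate_emsa_data(cfg$emsa_kd_ref, bmax = 1,
                                 noise_sd = cfg$emsa_noise_sd,
                                 n_replicates = cfg$emsa_replicates,
                                 seed = fan_seed(seed, "emsa_ref"))
  emsa_alt <- generate_emsa_data(cfg$emsa_kd_alt, bmax = 1,
                                 noise_sd = cfg$emsa_noise_sd,
                                 n_replicates = cfg$emsa_replicates,
                                 seed = fan_seed(seed, "emsa_alt"))

  n_empty_pos <- sum(gw$truth$malformed_kind %in% "empty_position")
  truth <- list(
    seed = seed,
    counts = list(
      associations = cfg$n_associations,
      parse_rejected = n_empty_pos,
      parsed = cfg$n_associations - n_empty_pos,
      cvd = sum(gw$truth$cvd & !(gw$truth$malformed_kind %in% "empty_position")),
      snv = sum(gw$truth$cvd & !gw$truth$indel & !gw$truth$malformed),
      in_regulatory = n_forced,
      expanded = length(ldres$truth$expanded_rsids),
      eqtl_pairs = nrow(eq$truth$planted),
      eqtl_genes = length(unique(eq$truth$planted$gene_id)),
      eqtl_variants = length(unique(eq$truth$planted$variant_rsid))),
    planted_rsids = planted$rsid,
    background_regulatory_rsids = bg_rsids,
    forced_eqtl_rsids = forced_eqtl,
    expanded_rsids = ldres$truth$expanded_rsids,
    planted_sites = as.data.frame(planted),
    motif_pwm = unname(as.data.frame(motif$pwm)),
    emsa = list(kd_ref = cfg$emsa_kd_ref, kd_alt = cfg$emsa_kd_alt))

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genome = file.path(out_dir, "genome.fa"),
      peaks = file.path(out_dir, "peaks.bed"),
      enhancers = file.path(out_dir, "enhancers.bed"),
      footprints = file.path(out_dir, "footprints.bed"),
      gwas = file.path(out_dir, "gwas_catalog.tsv"),
      ld = file.path(out_dir, "ld_pairs.tsv"),
      eqtl = file.path(out_dir, "eqtl_pairs.tsv"),
      emsa_ref = file.path(out_dir, "emsa_ref.csv"),
      emsa_alt = file.path(out_dir, "emsa_alt.csv"),
      truth = file.path(out_dir, "truth.json"))
    write_genome_fasta(genome, paths$genome)
    write_bed(pk$peaks, paths$peaks)
    write_bed(tracks$enhancers, paths$enhancers)
    write_bed(tracks$footprints, paths$footprints)
    write_gwas_catalog(gw$catalog, paths$gwas)
    write_ld_table(ldres$ld, paths$ld)
    write_eqtl_table(eq$eqtl, paths$eqtl)
    write_emsa_lanes(emsa_ref$lanes, paths$emsa_ref)
    write_emsa_lanes(emsa_alt$lanes, paths$emsa_alt)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  list(config = cfg, genome = genome, peaks = pk, tracks = tracks,
       gwas = gw, ld = ldres, eqtl = eq,
       emsa = list(ref = emsa_ref, alt = emsa_alt),
       planted = planted, truth = truth, paths = paths)
}
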